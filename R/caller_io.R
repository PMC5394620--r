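# Readers and writers for the two supported somatic-caller VCF dialects:
# Mutect2 as shipped in GATK 3.5 (per-sample AD allele depths, TLOD score,
# filter vocabulary incl. alt_allele_in_normal / clustered_events) and
# Strelka v1 (separate SNV and indel files; per-base tier-1/tier-2 counts in
# AU/CU/GU/TU for SNVs, TAR/TIR for indels; QSS_NT / QSI_NT scores).
# VCF parsing is delegated to VariantAnnotation.

read_vcf_quiet <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  suppressWarnings(VariantAnnotation::readVcf(path))
}

vcf_filters <- function(vcf) {
  f <- VariantAnnotation::filt(vcf)
  blank <- is.na(f) | f == "PASS" | f == ""
  dot <- !is.na(f) & f == "."
  if (any(dot)) {
    warning(sum(dot), " record(s) with FILTER '.' treated as unfiltered",
            call. = FALSE)
  }
  f[blank | dot] <- ""
  f
}

vcf_core <- function(vcf) {
  rr <- SummarizedExperiment::rowRanges(vcf)
  list(chrom = as.character(GenomicRanges::seqnames(rr)),
       pos = GenomicRanges::start(rr),
       ref = as.character(VariantAnnotation::ref(vcf)),
       alts = lapply(as.list(VariantAnnotation::alt(vcf)), as.character),
       filters = vcf_filters(vcf))
}

info_scalar <- function(vcf, tag, i, k = 1L) {
  v <- VariantAnnotation::info(vcf)[[tag]]
  if (is.null(v)) return(NA_real_)
  if (is.list(v) || methods::is(v, "List")) {
    x <- v[[i]]
    if (length(x) >= k) as.numeric(x[k]) else NA_real_
  } else {
    as.numeric(v[i])
  }
}

#' Read a Mutect2 (GATK 3.5 dialect) somatic VCF
#'
#' Multiallelic records are decomposed into one record per alternate allele.
#' Allele depths come from the per-sample `AD` field (reference count first,
#' one count per alt); sample depth is the sum of the `AD` entries, so counts
#' always win over any fraction field. `TLOD` is captured when present.
#' Samples are located by header name, never by column position.
#'
#' @param path VCF path.
#' @param tumour_label,normal_label Sample names as they appear in the VCF
#'   header line.
#' @param aligner Aligner/pipeline label recorded in provenance.
#' @param reference Optional reference for representation normalization.
#' @return A `CallSet` with `caller = "mutect2"`.
#' @export
read_mutect2 <- function(path, tumour_label = "TUMOR", normal_label = "NORMAL",
                         aligner = "unknown", reference = NULL) {
  vcf <- read_vcf_quiet(path)
  smp <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  missing <- setdiff(c(tumour_label, normal_label), smp)
  if (length(missing) > 0L) {
    stop("sample(s) ", paste(missing, collapse = ", "),
         " not present in VCF header (found: ", paste(smp, collapse = ", "),
         ")", call. = FALSE)
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("Mutect2 dialect error: no AD FORMAT field", call. = FALSE)
  ad_vec <- function(i, smp) {
    if (length(dim(ad)) == 3L) as.numeric(ad[i, smp, ]) else
      as.numeric(unlist(ad[i, smp]))
  }
  core <- vcf_core(vcf)
  rows <- vector("list", sum(lengths(core$alts)))
  ri <- 0L
  for (i in seq_along(core$alts)) {
    ad_t <- ad_vec(i, tumour_label)
    ad_n <- ad_vec(i, normal_label)
    for (k in seq_along(core$alts[[i]])) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        chrom = core$chrom[i], pos = core$pos[i], ref = core$ref[i],
        alt = core$alts[[i]][k], filters = core$filters[i],
        tumour_depth = sum(ad_t), tumour_alt = ad_t[k + 1L],
        normal_depth = sum(ad_n), normal_alt = ad_n[k + 1L],
        qual_score = info_scalar(vcf, "TLOD", i, k),
        stringsAsFactors = FALSE)
    }
  }
  rec <- if (ri > 0L) do.call(rbind, rows) else empty_records()
  rec <- normalize_records_checked(rec, reference)
  call_set(rec, caller = "mutect2", aligner = aligner, sample = tumour_label,
           vclass = "MIXED")
}

normalize_records_checked <- function(rec, reference) {
  if (is.null(reference) || nrow(rec) == 0L) return(rec)
  normalize_records(rec, reference)
}

strelka_samples <- function(vcf, tumour_label, normal_label) {
  smp <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  missing <- setdiff(c(tumour_label, normal_label), smp)
  if (length(missing) > 0L) {
    stop("Strelka dialect error: sample(s) ", paste(missing, collapse = ", "),
         " not in VCF header", call. = FALSE)
  }
  invisible(smp)
}

#' Read Strelka v1 somatic SNV / indel VCFs
#'
#' SNV files carry per-base tiered counts (`AU`/`CU`/`GU`/`TU`, each
#' `tier1,tier2`); tier depth is the sum of the four base counts at that tier
#' and the alt count is the alt base's count. Indel files carry
#' `TAR` (ref-supporting) and `TIR` (indel-supporting) tiered counts; depth is
#' their sum. The record's headline tumour/normal counts are the tumour tier-1
#' counts; both samples' tier-1 and tier-2 counts are retained so either
#' tier policy can be expressed downstream. `qual_score` is `QSS_NT` for SNVs
#' and `QSI_NT` for indels.
#'
#' @param path VCF path.
#' @param tumour_label,normal_label Sample names (Strelka writes `TUMOR` and
#'   `NORMAL`).
#' @param aligner Aligner/pipeline label recorded in provenance.
#' @param reference Optional reference for normalization.
#' @return A `CallSet` with `caller = "strelka"`.
#' @export
read_strelka_snv <- function(path, tumour_label = "TUMOR",
                             normal_label = "NORMAL", aligner = "unknown",
                             reference = NULL) {
  vcf <- read_vcf_quiet(path)
  strelka_samples(vcf, tumour_label, normal_label)
  g <- VariantAnnotation::geno(vcf)
  if (is.null(g$AU) || is.null(g$CU) || is.null(g$GU) || is.null(g$TU)) {
    stop("Strelka SNV dialect error: missing AU/CU/GU/TU tier counts",
         call. = FALSE)
  }
  if (is.null(VariantAnnotation::info(vcf)$QSS_NT)) {
    stop("Strelka SNV dialect error: missing QSS_NT", call. = FALSE)
  }
  core <- vcf_core(vcf)
  counts <- list(A = g$AU, C = g$CU, G = g$GU, T = g$TU)
  base_count <- function(base, i, sample, tier) {
    as.numeric(counts[[base]][i, sample, tier])
  }
  tier_dp <- function(i, sample, tier) {
    sum(vapply(c("A", "C", "G", "T"), base_count, numeric(1),
               i = i, sample = sample, tier = tier))
  }
  rows <- vector("list", sum(lengths(core$alts)))
  ri <- 0L
  for (i in seq_along(core$alts)) {
    for (k in seq_along(core$alts[[i]])) {
      a <- core$alts[[i]][k]; r <- core$ref[i]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        chrom = core$chrom[i], pos = core$pos[i], ref = r, alt = a,
        filters = core$filters[i],
        tum_t1_ref = base_count(r, i, tumour_label, 1L),
        tum_t1_alt = base_count(a, i, tumour_label, 1L),
        tum_t1_dp = tier_dp(i, tumour_label, 1L),
        tum_t2_ref = base_count(r, i, tumour_label, 2L),
        tum_t2_alt = base_count(a, i, tumour_label, 2L),
        tum_t2_dp = tier_dp(i, tumour_label, 2L),
        nrm_t1_ref = base_count(r, i, normal_label, 1L),
        nrm_t1_alt = base_count(a, i, normal_label, 1L),
        nrm_t1_dp = tier_dp(i, normal_label, 1L),
        nrm_t2_ref = base_count(r, i, normal_label, 2L),
        nrm_t2_alt = base_count(a, i, normal_label, 2L),
        nrm_t2_dp = tier_dp(i, normal_label, 2L),
        qual_score = info_scalar(vcf, "QSS_NT", i),
        stringsAsFactors = FALSE)
    }
  }
  rec <- finish_strelka_records(rows, ri, reference)
  call_set(rec, caller = "strelka", aligner = aligner, sample = tumour_label,
           vclass = "SNV")
}

finish_strelka_records <- function(rows, ri, reference) {
  rec <- if (ri > 0L) do.call(rbind, rows) else empty_records()
  if (ri > 0L) {
    rec$tumour_depth <- rec$tum_t1_dp
    rec$tumour_alt <- rec$tum_t1_alt
    rec$normal_depth <- rec$nrm_t1_dp
    rec$normal_alt <- rec$nrm_t1_alt
  }
  normalize_records_checked(rec, reference)
}

#' @rdname read_strelka_snv
#' @export
read_strelka_indel <- function(path, tumour_label = "TUMOR",
                               normal_label = "NORMAL", aligner = "unknown",
                               reference = NULL) {
  vcf <- read_vcf_quiet(path)
  strelka_samples(vcf, tumour_label, normal_label)
  g <- VariantAnnotation::geno(vcf)
  if (is.null(g$TAR) || is.null(g$TIR)) {
    stop("Strelka indel dialect error: missing TAR/TIR tier counts", call. = FALSE)
  }
  if (is.null(VariantAnnotation::info(vcf)$QSI_NT)) {
    stop("Strelka indel dialect error: missing QSI_NT", call. = FALSE)
  }
  core <- vcf_core(vcf)
  cnt <- function(arr, i, sample, tier) as.numeric(arr[i, sample, tier])
  rows <- vector("list", sum(lengths(core$alts)))
  ri <- 0L
  for (i in seq_along(core$alts)) {
    for (k in seq_along(core$alts[[i]])) {
      ri <- ri + 1L
      tt1r <- cnt(g$TAR, i, tumour_label, 1L); tt1a <- cnt(g$TIR, i, tumour_label, 1L)
      tt2r <- cnt(g$TAR, i, tumour_label, 2L); tt2a <- cnt(g$TIR, i, tumour_label, 2L)
      nt1r <- cnt(g$TAR, i, normal_label, 1L); nt1a <- cnt(g$TIR, i, normal_label, 1L)
      nt2r <- cnt(g$TAR, i, normal_label, 2L); nt2a <- cnt(g$TIR, i, normal_label, 2L)
      rows[[ri]] <- data.frame(
        chrom = core$chrom[i], pos = core$pos[i], ref = core$ref[i],
        alt = core$alts[[i]][k], filters = core$filters[i],
        tum_t1_ref = tt1r, tum_t1_alt = tt1a, tum_t1_dp = tt1r + tt1a,
        tum_t2_ref = tt2r, tum_t2_alt = tt2a, tum_t2_dp = tt2r + tt2a,
        nrm_t1_ref = nt1r, nrm_t1_alt = nt1a, nrm_t1_dp = nt1r + nt1a,
        nrm_t2_ref = nt2r, nrm_t2_alt = nt2a, nrm_t2_dp = nt2r + nt2a,
        qual_score = info_scalar(vcf, "QSI_NT", i),
        stringsAsFactors = FALSE)
    }
  }
  rec <- finish_strelka_records(rows, ri, reference)
  call_set(rec, caller = "strelka", aligner = aligner, sample = tumour_label,
           vclass = "INDEL")
}

#' Variant allele frequencies of a CallSet
#'
#' `alt / depth` per record for the chosen sample; 0 (with a warning) where
#' depth is 0. For Strelka records `tier` selects the tier-1 or tier-2 counts;
#' requesting a tier for Mutect2 records is an error as Mutect2 has no tiers.
#'
#' @param cs A `CallSet`.
#' @param sample `"tumour"` or `"normal"`.
#' @param tier `NULL` (headline counts) or 1 or 2.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
vaf <- function(cs, sample = c("tumour", "normal"), tier = NULL) {
  sample <- match.arg(sample)
  rec <- cs$records
  if (!is.null(tier)) {
    if (identical(cs$caller, "mutect2")) {
      stop("tier counts are a Strelka concept; mutect2 records have none",
           call. = FALSE)
    }
    if (!tier %in% c(1, 2)) stop("tier must be 1 or 2", call. = FALSE)
    pre <- if (sample == "tumour") "tum" else "nrm"
    alt <- rec[[sprintf("%s_t%d_alt", pre, tier)]]
    dp <- rec[[sprintf("%s_t%d_dp", pre, tier)]]
  } else if (sample == "tumour") {
    alt <- rec$tumour_alt; dp <- rec$tumour_depth
  } else {
    alt <- rec$normal_alt; dp <- rec$normal_depth
  }
  zero <- !is.na(dp) & dp == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero ", sample,
            " depth; VAF reported as 0", call. = FALSE)
  }
  out <- ifelse(zero, 0, alt / dp)
  as.numeric(out)
}
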