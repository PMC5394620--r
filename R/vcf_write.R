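# VCF emission. The merged/filtered product is written as VCF 4.2 with the
# package's own INFO tags (ITC_CALLERS, ITC_ALIGNERS, ITC_PROV, ITC_SCORE);
# the synthetic module uses the dialect writers below to fabricate
# Mutect2-style and Strelka-v1-style inputs. Records are emitted sorted by
# (chrom, pos, ref, alt) so equal inputs give byte-identical files.

sort_records <- function(rec) {
  rec[order(rec$chrom, rec$pos, rec$ref, rec$alt, method = "radix"), ,
      drop = FALSE]
}

fmt_num <- function(x, fmt = "%.2f") {
  ifelse(is.na(x), ".", sprintf(fmt, x))
}

fmt_int <- function(x) {
  ifelse(is.na(x), ".", sprintf("%d", as.integer(round(x))))
}

contig_lines <- function(contigs) {
  if (is.null(contigs)) return(character(0))
  sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
}

filter_header_lines <- function(filters) {
  ids <- sort(unique(unlist(strsplit(filters[filters != ""], ";", fixed = TRUE))))
  sprintf("##FILTER=<ID=%s,Description=\"%s\">", ids, ids)
}

filter_field <- function(filters) ifelse(filters == "", "PASS", filters)

#' Write a CallSet as a VCF 4.2 file
#'
#' Provenance is serialized into INFO tags: `ITC_CALLERS` and `ITC_ALIGNERS`
#' (comma-joined supporting labels), `ITC_PROV` (the exact caller/aligner
#' pairs) and `ITC_SCORE` (the original caller quality score). A write-then-
#' read round trip through [read_callset()] recovers keys, filter sets,
#' headline depths, scores and provenance.
#'
#' @param cs A `CallSet`.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path, contigs = NULL) {
  rec <- sort_records(cs$records)
  prov <- strsplit(rec$provenance, ",", fixed = TRUE)
  callers <- vapply(prov, function(p) {
    paste(sort(unique(vapply(strsplit(p, "/", fixed = TRUE), `[`, "", 1L))),
          collapse = ",")
  }, character(1))
  aligners <- vapply(prov, function(p) {
    paste(sort(unique(vapply(strsplit(p, "/", fixed = TRUE), `[`, "", 2L))),
          collapse = ",")
  }, character(1))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=itcombine-%s", as.character(utils::packageVersion("itcombine"))),
    contig_lines(contigs),
    filter_header_lines(rec$filters),
    "##INFO=<ID=ITC_CALLERS,Number=.,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=ITC_ALIGNERS,Number=.,Type=String,Description=\"Supporting aligners\">",
    "##INFO=<ID=ITC_PROV,Number=.,Type=String,Description=\"Supporting caller/aligner pairs\">",
    "##INFO=<ID=ITC_SCORE,Number=1,Type=Float,Description=\"Original caller quality score\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  fmt_sample <- function(dp, alt) {
    ad <- ifelse(is.na(dp) | is.na(alt), ".",
                 paste(fmt_int(dp - alt), fmt_int(alt), sep = ","))
    paste(ad, fmt_int(dp), sep = ":")
  }
  body <- if (nrow(rec) == 0L) character(0) else {
    info <- sprintf("ITC_CALLERS=%s;ITC_ALIGNERS=%s;ITC_PROV=%s;ITC_SCORE=%s",
                    callers, aligners, gsub("/", "|", rec$provenance),
                    fmt_num(rec$qual_score, "%.4f"))
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".",
          filter_field(rec$filters), info, "AD:DP",
          fmt_sample(rec$tumour_depth, rec$tumour_alt),
          fmt_sample(rec$normal_depth, rec$normal_alt), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF previously written by [write_callset()]
#'
#' @param path VCF path.
#' @param reference Optional reference for re-normalization.
#' @return A `CallSet`; caller/aligner labels are reconstructed from the
#'   provenance tags (`"combined"` when several callers contributed).
#' @export
read_callset <- function(path, reference = NULL) {
  vcf <- read_vcf_quiet(path)
  core <- vcf_core(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  prov_raw <- VariantAnnotation::info(vcf)$ITC_PROV
  n <- length(core$chrom)
  if (n == 0L) {
    return(call_set(empty_records(), caller = "combined", aligner = "combined"))
  }
  ad_pair <- function(i, smp) {
    x <- if (length(dim(ad)) == 3L) as.numeric(ad[i, smp, ]) else
      as.numeric(unlist(ad[i, smp]))
    if (length(x) < 2L || all(is.na(x))) c(NA_real_, NA_real_) else x[1:2]
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    adt <- ad_pair(i, "TUMOR"); adn <- ad_pair(i, "NORMAL")
    prov <- if (is.null(prov_raw)) NA_character_ else
      paste(gsub("|", "/", unlist(prov_raw[i]), fixed = TRUE), collapse = ",")
    rows[[i]] <- data.frame(
      chrom = core$chrom[i], pos = core$pos[i], ref = core$ref[i],
      alt = core$alts[[i]][1], filters = core$filters[i],
      tumour_depth = sum(adt), tumour_alt = adt[2],
      normal_depth = sum(adn), normal_alt = adn[2],
      qual_score = info_scalar(vcf, "ITC_SCORE", i),
      provenance = prov, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec <- normalize_records_checked(rec, reference)
  pairs <- unique(unlist(strsplit(rec$provenance, ",", fixed = TRUE)))
  pairs <- pairs[!is.na(pairs)]
  lab <- function(k) {
    u <- unique(vapply(strsplit(pairs, "/", fixed = TRUE), `[`, "", k))
    if (length(u) == 1L) u else "combined"
  }
  caller <- if (length(pairs) > 0L) lab(1L) else "combined"
  aligner <- if (length(pairs) > 0L) lab(2L) else "combined"
  call_set(rec, caller = caller, aligner = aligner)
}

#' Write a CallSet in the Mutect2 (GATK 3.5) VCF dialect
#'
#' Used by the synthetic-data module to fabricate caller inputs; emits
#' per-sample `AD`/`DP` and an INFO `TLOD` taken from `qual_score`.
#'
#' @param cs A `CallSet` (caller `"mutect2"`).
#' @param path Output path.
#' @param tumour_label,normal_label Sample column names.
#' @param contigs Optional named contig-length vector.
#' @return `path`, invisibly.
#' @export
write_mutect2_vcf <- function(cs, path, tumour_label = "TUMOR",
                              normal_label = "NORMAL", contigs = NULL) {
  rec <- sort_records(cs$records)
  hdr <- c(
    "##fileformat=VCFv4.1",
    "##source=itcombine-synthetic(mutect2-dialect)",
    contig_lines(contigs),
    filter_header_lines(rec$filters),
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"Tumor LOD (t_lod_fstar)\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           tumour_label, "\t", normal_label)
  )
  body <- if (nrow(rec) == 0L) character(0) else {
    info <- ifelse(is.na(rec$qual_score), "SOMATIC",
                   sprintf("SOMATIC;TLOD=%.2f", rec$qual_score))
    smp <- function(dp, alt) sprintf("%s,%s:%s", fmt_int(dp - alt),
                                     fmt_int(alt), fmt_int(dp))
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".",
          filter_field(rec$filters), info, "AD:DP",
          smp(rec$tumour_depth, rec$tumour_alt),
          smp(rec$normal_depth, rec$normal_alt), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

strelka_common_header <- function(kind, contigs, filters) {
  score <- if (kind == "snv") "QSS" else "QSI"
  c("##fileformat=VCFv4.1",
    "##source=itcombine-synthetic(strelka-v1-dialect)",
    contig_lines(contigs),
    filter_header_lines(filters),
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic event\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Quality score\">", score),
    sprintf("##INFO=<ID=%s_NT,Number=1,Type=Integer,Description=\"Quality score joint with normal genotype\">", score),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
}

#' Write CallSets in the Strelka v1 somatic VCF dialects
#'
#' `write_strelka_snv_vcf` emits per-base tier counts (`AU`/`CU`/`GU`/`TU`):
#' the alt base carries the record's tier alt counts, the ref base the tier
#' ref counts, the other two bases zero. `write_strelka_indel_vcf` emits
#' `TAR`/`TIR`. Sample columns are `NORMAL` then `TUMOR`, as Strelka writes
#' them.
#'
#' @param cs A `CallSet` (caller `"strelka"`).
#' @param path Output path.
#' @param contigs Optional named contig-length vector.
#' @return `path`, invisibly.
#' @export
write_strelka_snv_vcf <- function(cs, path, contigs = NULL) {
  rec <- sort_records(cs$records)
  hdr <- c(strelka_common_header("snv", contigs, rec$filters),
           "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"A counts tier1,tier2\">",
           "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"C counts tier1,tier2\">",
           "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"G counts tier1,tier2\">",
           "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"T counts tier1,tier2\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
  body <- if (nrow(rec) == 0L) character(0) else {
    vapply(seq_len(nrow(rec)), function(i) {
      r <- rec[i, ]
      base_counts <- function(t1_ref, t1_alt, t2_ref, t2_alt, t1_dp, t2_dp) {
        cnt <- list(A = c(0, 0), C = c(0, 0), G = c(0, 0), T = c(0, 0))
        cnt[[r$ref]] <- c(t1_ref, t2_ref)
        cnt[[r$alt]] <- cnt[[r$alt]] + c(t1_alt, t2_alt)
        paste(fmt_int(t1_dp),
              paste(fmt_int(cnt$A[1]), fmt_int(cnt$A[2]), sep = ","),
              paste(fmt_int(cnt$C[1]), fmt_int(cnt$C[2]), sep = ","),
              paste(fmt_int(cnt$G[1]), fmt_int(cnt$G[2]), sep = ","),
              paste(fmt_int(cnt$T[1]), fmt_int(cnt$T[2]), sep = ","), sep = ":")
      }
      q <- as.integer(round(r$qual_score))
      paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", filter_field(r$filters),
            sprintf("SOMATIC;QSS=%d;QSS_NT=%d", q, q), "DP:AU:CU:GU:TU",
            base_counts(r$nrm_t1_ref, r$nrm_t1_alt, r$nrm_t2_ref, r$nrm_t2_alt,
                        r$nrm_t1_dp, r$nrm_t2_dp),
            base_counts(r$tum_t1_ref, r$tum_t1_alt, r$tum_t2_ref, r$tum_t2_alt,
                        r$tum_t1_dp, r$tum_t2_dp), sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_strelka_snv_vcf
#' @export
write_strelka_indel_vcf <- function(cs, path, contigs = NULL) {
  rec <- sort_records(cs$records)
  hdr <- c(strelka_common_header("indel", contigs, rec$filters),
           "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"Reads supporting ref tier1,tier2\">",
           "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"Reads supporting indel tier1,tier2\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR")
  body <- if (nrow(rec) == 0L) character(0) else {
    smp <- function(t1_ref, t1_alt, t2_ref, t2_alt) {
      paste(fmt_int(t1_ref + t1_alt),
            paste(fmt_int(t1_ref), fmt_int(t2_ref), sep = ","),
            paste(fmt_int(t1_alt), fmt_int(t2_alt), sep = ","), sep = ":")
    }
    q <- as.integer(round(rec$qual_score))
    paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".",
          filter_field(rec$filters),
          sprintf("SOMATIC;QSI=%d;QSI_NT=%d", q, q), "DP:TAR:TIR",
          smp(rec$nrm_t1_ref, rec$nrm_t1_alt, rec$nrm_t2_ref, rec$nrm_t2_alt),
          smp(rec$tum_t1_ref, rec$tum_t1_alt, rec$tum_t2_ref, rec$tum_t2_alt),
          sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
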