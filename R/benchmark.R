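# Truth-set evaluation. A TruthSet holds normalized truth variants plus the
# evaluation regions: confident intervals intersected with the capture target
# and with every truth footprint subtracted, so a call is a TP if it matches
# a truth key, an FP if it lies inside the remaining (known homozygous
# reference) regions, and unclassified outside them. Sens = TP / (TP + FN);
# FPR/Mb = FP / n_ref * 1e6 with n_ref = total_bp(regions).

#' Construct a TruthSet
#'
#' Truth variants are normalized when a reference is given; duplicate keys
#' and multiallelic rows (comma in alt) are rejected. Evaluation regions are
#' built as `confident` (optionally intersected with `target`) minus each
#' truth variant's reference footprint.
#'
#' @param variants Truth variant data.frame (chrom, pos, ref, alt).
#' @param confident Confident regions (`RegionSet`, BED path, GRanges or BED
#'   data.frame).
#' @param target Optional capture-target regions.
#' @param reference Optional reference for normalization.
#' @return A `TruthSet` with elements `variants` and `regions`.
#' @export
truth_set <- function(variants, confident, target = NULL, reference = NULL) {
  if (any(grepl(",", variants$alt, fixed = TRUE))) {
    stop("multiallelic truth rows are not allowed; they are excluded from ",
         "evaluation", call. = FALSE)
  }
  v <- variants(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (!is.null(reference)) v <- normalize_variants(v, reference)
  dup <- duplicated(variant_key(v))
  if (any(dup)) {
    stop("duplicate truth variants: ",
         paste(utils::head(variant_key(v)[dup], 3), collapse = ", "),
         call. = FALSE)
  }
  v$key <- variant_key(v)
  regions <- region_set(confident)
  if (!is.null(target)) regions <- intersect_regions(regions, target)
  regions <- subtract_loci(regions, v)
  structure(list(variants = v, regions = regions), class = "TruthSet")
}

#' @export
print.TruthSet <- function(x, ...) {
  tab <- table(factor(x$variants$vtype, levels = c("SNV", "MNV", "INS", "DEL")))
  cat(sprintf("TruthSet: %d variants (%s); n_ref = %.0f bp\n",
              nrow(x$variants),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              total_bp(x$regions)))
  invisible(x)
}

#' Read a truth set's variants from VCF or TSV
#'
#' TSV input needs columns chrom, pos, ref, alt (a header line is detected
#' automatically; extra columns are ignored). VCF input takes rows as-is and
#' rejects multiallelic records.
#'
#' @param path File path.
#' @return Variant data.frame.
#' @export
read_truth_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    vcf <- read_vcf_quiet(path)
    core <- vcf_core(vcf)
    if (any(lengths(core$alts) != 1L)) {
      stop("multiallelic truth rows are not allowed", call. = FALSE)
    }
    return(variants(core$chrom, core$pos, core$ref,
                    vapply(core$alts, `[`, "", 1L)))
  }
  header <- is.na(suppressWarnings(as.integer(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
  variants(df$chrom, df$pos, df$ref, df$alt)
}

truth_subset <- function(truth, vclass) {
  keep <- switch(vclass,
                 SNV = truth$variants$vtype %in% c("SNV", "MNV"),
                 INDEL = truth$variants$vtype %in% c("INS", "DEL"),
                 MIXED = rep(TRUE, nrow(truth$variants)),
                 stop("unknown vclass ", vclass, call. = FALSE))
  truth$variants[keep, , drop = FALSE]
}

#' Classify calls against a truth set
#'
#' TPs are calls matching a truth key (of the evaluated variant class); FNs
#' are unmatched truth variants; the remaining calls are FPs when their start
#' position lies inside the evaluation regions and unclassified otherwise
#' (truth loci were subtracted from the regions at construction, so a TP can
#' never double-count as in-region). Sensitivity and FPR/Mb are filled in.
#'
#' @param cs A `CallSet`.
#' @param truth A `TruthSet`.
#' @param vclass Variant class to evaluate; defaults to the call set's.
#' @return A `BenchmarkResult`.
#' @export
classify <- function(cs, truth, vclass = cs$vclass) {
  if (!identical(vclass, cs$vclass) && !identical(cs$vclass, "MIXED")) {
    stop("requested vclass ", vclass, " but call set is ", cs$vclass,
         call. = FALSE)
  }
  if (identical(cs$vclass, "MIXED") && vclass %in% c("SNV", "INDEL")) {
    cs <- subset_callset(cs, vclass)
  }
  tv <- truth_subset(truth, vclass)
  keys <- callset_keys(cs)
  is_tp <- keys %in% tv$key
  fn_idx <- !(tv$key %in% keys)
  extras <- cs$records[!is_tp, , drop = FALSE]
  in_region <- point_in_regions(truth$regions, extras$chrom, extras$pos)
  tp <- sum(is_tp); fn <- sum(fn_idx)
  fp <- sum(in_region); uncl <- sum(!in_region)
  n_ref <- total_bp(truth$regions)
  structure(list(tp = tp, fp = fp, fn = fn, unclassified = uncl,
                 sensitivity = sensitivity(tp, fn),
                 fpr_per_mb = fpr_per_mb(fp, n_ref),
                 n_ref_bp = n_ref, vclass = vclass,
                 tp_keys = keys[is_tp],
                 fp_keys = extras$key[in_region],
                 fn_variants = tv[fn_idx, , drop = FALSE]),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat(sprintf(paste0("BenchmarkResult<%s>: TP=%d FP=%d FN=%d unclassified=%d",
                     " | Sens=%.1f%% FPR/Mb=%.3f (n_ref=%.0f bp)\n"),
              x$vclass, x$tp, x$fp, x$fn, x$unclassified,
              100 * x$sensitivity, x$fpr_per_mb, x$n_ref_bp))
  invisible(x)
}

#' Sensitivity
#'
#' `TP / (TP + FN)`; `NA` when there are no truth variants to recover.
#'
#' @param tp,fn Counts.
#' @return Fraction in `[0, 1]` or `NA`.
#' @export
sensitivity <- function(tp, fn) {
  ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
}

#' False positives per megabase
#'
#' `FP / n_ref_bp * 1e6` over the evaluation (reference) regions.
#'
#' @param fp Count of false positives.
#' @param n_ref_bp Total reference-region size in bp (> 0).
#' @return Rate per Mb.
#' @export
fpr_per_mb <- function(fp, n_ref_bp) {
  if (any(n_ref_bp <= 0)) stop("n_ref_bp must be positive", call. = FALSE)
  fp / n_ref_bp * 1e6
}

#' Evaluate a dilution series
#'
#' One row per dilution point with sensitivity; FPR/Mb is reported only for
#' the minimum-purity point. In the more concentrated samples apparent FPs
#' are dominated by genuine (drift) mutations of the tumour line, so their
#' FPR is withheld rather than silently reported.
#'
#' @param callsets List of `CallSet`s, one per dilution point.
#' @param purities Numeric vector of tumour purities in `(0, 1]`, aligned
#'   with `callsets`.
#' @param truth A `TruthSet`.
#' @param labels Optional point labels (default `"purity_<pct>"`); must be
#'   unique.
#' @param vclass Variant class to evaluate.
#' @return Data.frame with columns label, purity, tp, fp, fn, unclassified,
#'   sensitivity, fpr_per_mb.
#' @export
evaluate_dilution_series <- function(callsets, purities, truth,
                                     labels = NULL, vclass = "SNV") {
  stopifnot(length(callsets) == length(purities), length(callsets) >= 1L)
  if (any(purities <= 0 | purities > 1)) {
    stop("purities must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("purity_%g", 100 * purities)
  if (anyDuplicated(labels)) stop("duplicate dilution point labels", call. = FALSE)
  res <- lapply(callsets, classify, truth = truth, vclass = vclass)
  out <- data.frame(label = labels, purity = purities,
                    tp = vapply(res, `[[`, 0, "tp"),
                    fp = vapply(res, `[[`, 0, "fp"),
                    fn = vapply(res, `[[`, 0, "fn"),
                    unclassified = vapply(res, `[[`, 0, "unclassified"),
                    sensitivity = vapply(res, `[[`, 0, "sensitivity"),
                    fpr_per_mb = NA_real_, stringsAsFactors = FALSE)
  minp <- which.min(purities)
  out$fpr_per_mb[minp] <- res[[minp]]$fpr_per_mb
  out
}

#' Expected variant allele frequency in a dilution mixture
#'
#' A heterozygous variant is carried by half the tumour-derived chromosomes,
#' so its expected VAF is `purity / 2`; a homozygous variant's is `purity`.
#'
#' @param purity Fraction of tumour DNA in `[0, 1]`.
#' @param zygosity `"het"` or `"hom"` (vectorized).
#' @return Expected VAF.
#' @export
expected_vaf <- function(purity, zygosity = c("het", "hom")) {
  if (length(zygosity) == 1L) zygosity <- rep(zygosity, length(purity))
  stopifnot(all(zygosity %in% c("het", "hom")), all(purity >= 0 & purity <= 1))
  ifelse(zygosity == "het", purity / 2, purity)
}

#' Break down false negatives by locus evidence
#'
#' Partitions a result's FN loci using a per-locus pileup table
#' (chrom, pos, depth, alt_count): `low_coverage` when depth `< min_depth`,
#' `allele_dropout` when depth is adequate but no alt read was observed,
#' `other` otherwise. Loci missing from the pileup count as depth 0.
#'
#' @param result A `BenchmarkResult` (from [classify()]).
#' @param pileup Data.frame with columns chrom, pos, depth, alt_count, or a
#'   TSV path with those columns.
#' @param min_depth Coverage cut-off (default 10).
#' @return List with `counts`, `pct` (of total FN, one decimal, half up) and
#'   `total_fn`.
#' @export
fn_breakdown <- function(result, pileup, min_depth = 10L) {
  if (is.character(pileup)) {
    pileup <- utils::read.table(pileup, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  fnv <- result$fn_variants
  idx <- match(paste(fnv$chrom, fnv$pos), paste(pileup$chrom, pileup$pos))
  depth <- ifelse(is.na(idx), 0, pileup$depth[idx])
  altc <- ifelse(is.na(idx), 0, pileup$alt_count[idx])
  cat_low <- depth < min_depth
  cat_drop <- !cat_low & altc == 0
  counts <- c(low_coverage = sum(cat_low), allele_dropout = sum(cat_drop),
              other = sum(!cat_low & !cat_drop))
  total <- nrow(fnv)
  pct <- if (total == 0L) counts * 0 else
    round_half_up(100 * counts / total, 1L)
  list(counts = counts, pct = pct, total_fn = total)
}

#' Replicate-vs-replicate false positive rates
#'
#' In a replicate-versus-replicate comparison there is no somatic signal, so
#' every call is a false positive. Computes FPR/Mb per comparison and a
#' five-number summary for boxplot-style reporting.
#'
#' @param callsets Non-empty list of `CallSet`s, one per comparison.
#' @param region_bp Reference-region size in bp.
#' @return List with `per_comparison` and `summary` (min, q1, median, q3,
#'   max; type-7 quantiles).
#' @export
replicate_fpr <- function(callsets, region_bp) {
  if (length(callsets) == 0L) stop("no comparisons supplied", call. = FALSE)
  per <- vapply(callsets, function(cs) fpr_per_mb(length(cs), region_bp),
                numeric(1))
  s <- stats::quantile(per, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  names(s) <- c("min", "q1", "median", "q3", "max")
  list(per_comparison = per, summary = s)
}

#' Overlap between two replicate call sets
#'
#' @param r1,r2 `CallSet`s of the same variant class.
#' @return List with `n_overlap`, `pct_of_r1`, `pct_of_r2` (0 when a set is
#'   empty).
#' @export
replicate_overlap <- function(r1, r2) {
  check_vclass(r1, r2)
  n <- length(intersect(callset_keys(r1), callset_keys(r2)))
  pct <- function(k) if (k == 0L) 0 else 100 * n / k
  list(n_overlap = n, pct_of_r1 = pct(length(r1)), pct_of_r2 = pct(length(r2)))
}
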