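# Caller-specific admission rules. Two policies are supported:
#
#  * default   — what each caller ships with: Mutect2 records passing all
#    internal filters, rescuing only 'clustered_events' and/or
#    'homologous_mapping_event' failures (germline variation clusters);
#    Strelka Tier 1 calls with QSS_NT > 15 (SNV) / QSI_NT > 30 (indel).
#  * optimized — the tuned criteria: Mutect2 additionally re-admits
#    'alt_allele_in_normal' failures when the normal alt fraction is at most
#    7% AND the tumour/normal VAF ratio exceeds 5 (the T/N-ratio rule, applied
#    uniformly to all candidates); Strelka admits Tier 1 and Tier 2 supported
#    calls with QSS_NT > 25 / QSI_NT > 35. All score comparisons are strict.

MUTECT2_FILTER_VOCAB <- c(
  "t_lod_fstar", "alt_allele_in_normal", "clustered_events",
  "homologous_mapping_event", "germline_risk", "panel_of_normals",
  "multi_event_alt_allele_in_normal", "str_contraction", "triallelic_site",
  "clustered_read_position", "strand_artifact")

#' Construct a filter policy
#'
#' Thresholds default to the tuned values in optimized mode and to the
#' callers' shipped values in default mode. All score cut-offs are strict
#' (`>`); the normal-allele-fraction bound is inclusive (`<=`, "up to 7%").
#'
#' @param mode `"optimized"` or `"default"`.
#' @param max_normal_af Maximum alt-allele fraction tolerated in the normal
#'   for re-admitted Mutect2 calls (optimized default 0.07).
#' @param min_tn_ratio Minimum tumour/normal VAF ratio, strict (optimized
#'   default 5).
#' @param qss_nt_min Strelka SNV score cut-off (15 default mode, 25 optimized).
#' @param qsi_nt_min Strelka indel score cut-off (30 default mode, 35 optimized).
#' @param tlod_min Mutect2 TLOD cut-off, applied only when a TLOD value is
#'   present (6.3).
#' @param rescue_filters Mutect2 internal filters whose sole failure does not
#'   reject a call.
#' @param include_tier2 Whether Strelka tier-2 alt support can rescue a record
#'   with no tier-1 alt reads (FALSE in default mode, TRUE optimized).
#' @param tn_ratio_all Apply the T/N-ratio rule to every Mutect2 candidate
#'   (TRUE, the reading used throughout) or only to re-admitted
#'   `alt_allele_in_normal` failures.
#' @param proximity_window Optional window (bp) for [proximity_filter()];
#'   `NULL` disables it.
#' @param min_neighbours Neighbour count triggering proximity removal.
#' @return A `FilterPolicy` object.
#' @export
filter_policy <- function(mode = c("optimized", "default"),
                          max_normal_af = 0.07,
                          min_tn_ratio = 5,
                          qss_nt_min = NULL,
                          qsi_nt_min = NULL,
                          tlod_min = 6.3,
                          rescue_filters = c("clustered_events",
                                             "homologous_mapping_event"),
                          include_tier2 = NULL,
                          tn_ratio_all = TRUE,
                          proximity_window = NULL,
                          min_neighbours = 2L) {
  mode <- match.arg(mode)
  if (is.null(qss_nt_min)) qss_nt_min <- if (mode == "optimized") 25 else 15
  if (is.null(qsi_nt_min)) qsi_nt_min <- if (mode == "optimized") 35 else 30
  if (is.null(include_tier2)) include_tier2 <- mode == "optimized"
  stopifnot(max_normal_af >= 0, min_tn_ratio >= 0, qss_nt_min >= 0,
            qsi_nt_min >= 0, tlod_min >= 0)
  unknown <- setdiff(rescue_filters, MUTECT2_FILTER_VOCAB)
  if (length(unknown) > 0L) {
    warning("rescue filter(s) not in the known Mutect2 vocabulary: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(mode = mode, max_normal_af = max_normal_af,
                 min_tn_ratio = min_tn_ratio, qss_nt_min = qss_nt_min,
                 qsi_nt_min = qsi_nt_min, tlod_min = tlod_min,
                 rescue_filters = rescue_filters,
                 include_tier2 = include_tier2, tn_ratio_all = tn_ratio_all,
                 proximity_window = proximity_window,
                 min_neighbours = as.integer(min_neighbours)),
            class = "FilterPolicy")
}

#' @export
print.FilterPolicy <- function(x, ...) {
  cat(sprintf(paste0("FilterPolicy<%s>: normal AF <= %g, T/N > %g, ",
                     "QSS_NT > %g, QSI_NT > %g, TLOD >= %g, tier2 %s\n"),
              x$mode, x$max_normal_af, x$min_tn_ratio, x$qss_nt_min,
              x$qsi_nt_min, x$tlod_min,
              if (x$include_tier2) "on" else "off"))
  invisible(x)
}

#' Tumour/normal VAF ratio
#'
#' Total by convention: `+Inf` when the normal VAF is 0 and the tumour VAF is
#' positive (passes any finite threshold); 0 when the tumour VAF is 0 (fails
#' any positive threshold).
#'
#' @param t_vaf,n_vaf Numeric vectors of fractions in `[0, 1]`.
#' @return Numeric vector in `[0, Inf]`.
#' @export
tn_ratio <- function(t_vaf, n_vaf) {
  ifelse(t_vaf == 0, 0, ifelse(n_vaf == 0, Inf, t_vaf / n_vaf))
}

check_caller <- function(cs, expected) {
  if (!identical(cs$caller, expected)) {
    stop("expected a ", expected, " CallSet, got caller '", cs$caller, "'",
         call. = FALSE)
  }
}

#' Per-record admission decisions
#'
#' `mutect2_admit_default`: admit iff the record's filter set minus the rescue
#' filters is empty. `mutect2_admit_optimized`: additionally forgive
#' `alt_allele_in_normal`, replacing it with the explicit rule normal VAF
#' `<= max_normal_af` and T/N ratio `> min_tn_ratio` (applied to every
#' candidate when `tn_ratio_all`); a present TLOD must also reach `tlod_min`.
#' `strelka_admit`: internal filters must pass; default mode requires tier-1
#' tumour alt support and score strictly above the default cut-off, optimized
#' mode uses the tuned cut-off and lets tier-2 alt support rescue records
#' without tier-1 support when `include_tier2`.
#'
#' @param cs A `CallSet` from the matching caller.
#' @param policy A `FilterPolicy`.
#' @return Logical vector, one decision per record.
#' @export
mutect2_admit_default <- function(cs, policy = filter_policy("default")) {
  check_caller(cs, "mutect2")
  fs <- filters_as_set(cs$records$filters)
  vapply(fs, function(f) length(setdiff(f, policy$rescue_filters)) == 0L,
         logical(1))
}

#' @rdname mutect2_admit_default
#' @export
mutect2_admit_optimized <- function(cs, policy = filter_policy("optimized")) {
  check_caller(cs, "mutect2")
  fs <- filters_as_set(cs$records$filters)
  forgiven <- c(policy$rescue_filters, "alt_allele_in_normal")
  filt_ok <- vapply(fs, function(f) length(setdiff(f, forgiven)) == 0L,
                    logical(1))
  tv <- suppressWarnings(vaf(cs, "tumour"))
  nv <- suppressWarnings(vaf(cs, "normal"))
  af_ok <- !is.na(nv) & nv <= policy$max_normal_af
  tn_ok <- tn_ratio(tv, nv) > policy$min_tn_ratio
  had_aain <- vapply(fs, function(f) "alt_allele_in_normal" %in% f, logical(1))
  if (!policy$tn_ratio_all) {
    af_ok <- af_ok | !had_aain
    tn_ok <- tn_ok | !had_aain
  }
  tlod <- cs$records$qual_score
  tlod_ok <- is.na(tlod) | tlod >= policy$tlod_min
  filt_ok & af_ok & tn_ok & tlod_ok
}

#' @rdname mutect2_admit_default
#' @export
strelka_admit <- function(cs, policy = filter_policy("optimized")) {
  check_caller(cs, "strelka")
  rec <- cs$records
  fs <- filters_as_set(rec$filters)
  filt_ok <- lengths(fs) == 0L
  is_indel <- rec$vtype %in% c("INS", "DEL")
  cutoff <- ifelse(is_indel, policy$qsi_nt_min, policy$qss_nt_min)
  if (any(is.na(rec$tum_t1_alt))) {
    stop("Strelka records without tier counts cannot be filtered", call. = FALSE)
  }
  score_ok <- !is.na(rec$qual_score) & rec$qual_score > cutoff
  tier1 <- rec$tum_t1_alt > 0
  support <- if (policy$mode == "optimized" && policy$include_tier2) {
    tier1 | rec$tum_t2_alt > 0
  } else {
    tier1
  }
  filt_ok & score_ok & support
}

#' Apply an admission policy to a CallSet
#'
#' Dispatches on the set's caller; the result is always a subset of the
#' input. A summary of admitted/rejected counts is reported via `message()`.
#'
#' @param cs A single-caller `CallSet`.
#' @param policy A `FilterPolicy`.
#' @param verbose Emit the summary message.
#' @return The admitted `CallSet`.
#' @export
apply_policy <- function(cs, policy = filter_policy("optimized"),
                         verbose = FALSE) {
  admit <- switch(cs$caller,
    mutect2 = if (policy$mode == "optimized") {
      mutect2_admit_optimized(cs, policy)
    } else {
      mutect2_admit_default(cs, policy)
    },
    strelka = strelka_admit(cs, policy),
    stop("cannot filter CallSet with caller '", cs$caller,
         "' (mixed or unknown caller)", call. = FALSE))
  out <- cs
  out$records <- cs$records[admit, , drop = FALSE]
  rownames(out$records) <- NULL
  if (verbose) {
    message(sprintf("apply_policy[%s/%s]: admitted %d of %d records",
                    cs$caller, policy$mode, nrow(out$records), nrow(cs$records)))
  }
  if (!is.null(policy$proximity_window)) {
    out <- proximity_filter(out, policy$proximity_window,
                            policy$min_neighbours)
  }
  out
}

#' Remove clusters of nearby calls
#'
#' Drops every record having at least `min_neighbours` other records within
#' `window` bp on the same chromosome — an optional guard against clustered
#' artifact calls. Off unless requested.
#'
#' @param cs A `CallSet`.
#' @param window Distance in bp (> 0).
#' @param min_neighbours Neighbour count at which a record is removed.
#' @return The pruned `CallSet`.
#' @export
proximity_filter <- function(cs, window, min_neighbours = 2L) {
  stopifnot(window > 0)
  rec <- cs$records
  if (nrow(rec) == 0L) return(cs)
  neigh <- integer(nrow(rec))
  for (ch in unique(rec$chrom)) {
    idx <- which(rec$chrom == ch)
    p <- rec$pos[idx]
    neigh[idx] <- vapply(seq_along(p), function(i) {
      sum(abs(p - p[i]) <= window) - 1L
    }, integer(1))
  }
  out <- cs
  out$records <- rec[neigh < min_neighbours, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}
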