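# The intersect-then-combine set algebra. Call sets are matched on normalized
# variant keys; per caller the calls found by BOTH alignment pipelines are
# kept (alignment-specific artifacts drop out), then the per-caller
# intersections are unioned across callers (caller disagreement is mostly
# complementary true positives).

#' Round half away from zero
#'
#' Plain decimal rounding (0.05 -> 0.1), used for all reported percentages;
#' base R's `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_vclass <- function(a, b) {
  if (!identical(a$vclass, b$vclass)) {
    stop("incompatible variant classes: ", a$vclass, " vs ", b$vclass,
         call. = FALSE)
  }
}

merge_meta <- function(a, b) {
  list(caller = if (identical(a$caller, b$caller)) a$caller else "combined",
       aligner = if (identical(a$aligner, b$aligner)) a$aligner else "combined",
       sample = if (identical(a$sample, b$sample)) a$sample else NA_character_)
}

#' Intersect two call sets by variant key
#'
#' Keeps records whose keys occur in both sets. Record bodies (representation,
#' depths, scores) are taken from the first operand; provenance is the union
#' of both records' provenance, so the key set is commutative even though the
#' bodies are not. Callers should order operands deterministically (the ITC
#' driver uses lexicographic aligner labels).
#'
#' @param a,b `CallSet`s of the same variant class.
#' @return A `CallSet`.
#' @export
intersect_callsets <- function(a, b) {
  check_vclass(a, b)
  common <- a$records$key %in% b$records$key
  rec <- a$records[common, , drop = FALSE]
  if (nrow(rec) > 0L) {
    bidx <- match(rec$key, b$records$key)
    rec$provenance <- merge_provenance(rec$provenance,
                                       b$records$provenance[bidx])
  }
  rownames(rec) <- NULL
  m <- merge_meta(a, b)
  call_set(rec, caller = m$caller, aligner = m$aligner, sample = m$sample,
           vclass = a$vclass)
}

#' Union of call sets by variant key
#'
#' Every key from every input appears exactly once; for keys present in
#' several inputs the earliest input's record body is kept and provenance is
#' merged.
#'
#' @param sets Non-empty list of `CallSet`s with a common variant class.
#' @return A `CallSet`.
#' @export
union_callsets <- function(sets) {
  if (length(sets) == 0L) stop("union of an empty list of call sets", call. = FALSE)
  out <- sets[[1]]
  for (b in sets[-1]) {
    check_vclass(out, b)
    dupe <- match(b$records$key, out$records$key)
    hit <- !is.na(dupe)
    if (any(hit)) {
      out$records$provenance[dupe[hit]] <-
        merge_provenance(out$records$provenance[dupe[hit]],
                         b$records$provenance[hit])
    }
    m <- merge_meta(out, b)
    rec <- rbind(out$records, b$records[!hit, , drop = FALSE])
    rownames(rec) <- NULL
    out <- call_set(rec, caller = m$caller, aligner = m$aligner,
                    sample = m$sample, vclass = out$vclass)
  }
  out
}

#' The intersect-then-combine operation
#'
#' For each caller, intersect its two aligners' call sets (aligners taken in
#' lexicographic order so output is deterministic); then union the per-caller
#' intersections across callers. Each output record's provenance names every
#' supporting (caller, aligner) pair.
#'
#' @param calls Named list: caller label -> named list of exactly two
#'   `CallSet`s keyed by aligner label. Aligner labels must agree across
#'   callers.
#' @return A `CallSet` of the final combined calls.
#' @export
itc <- function(calls) {
  if (length(calls) < 1L) stop("need at least one caller", call. = FALSE)
  aligner_sets <- lapply(calls, function(x) sort(names(x)))
  if (length(unique(aligner_sets)) != 1L) {
    stop("aligner labels differ across callers: ",
         paste(vapply(aligner_sets, paste, "", collapse = "+"), collapse = " vs "),
         call. = FALSE)
  }
  if (length(aligner_sets[[1]]) != 2L) {
    stop("exactly two aligners per caller are required", call. = FALSE)
  }
  per_caller <- lapply(names(calls)[order(names(calls))], function(cl) {
    al <- sort(names(calls[[cl]]))
    intersect_callsets(calls[[cl]][[al[1]]], calls[[cl]][[al[2]]])
  })
  union_callsets(per_caller)
}

#' Two-set overlap statistics
#'
#' Counts of keys unique to each operand and shared, with each unique count
#' also expressed as a percentage of that operand's total,
#' `100 * x_only / (x_only + shared)`, reported to one decimal (half up) and
#' defined as 0 when the denominator is 0.
#'
#' @param a,b `CallSet`s of the same variant class.
#' @param labels Length-2 character vector naming the operands.
#' @return An `overlap_stats` object.
#' @export
overlap_stats <- function(a, b, labels = c(a$aligner, b$aligner)) {
  check_vclass(a, b)
  ka <- callset_keys(a); kb <- callset_keys(b)
  shared <- length(intersect(ka, kb))
  a_only <- length(ka) - shared
  b_only <- length(kb) - shared
  pct <- function(x) if (x + shared == 0L) 0 else
    round_half_up(100 * x / (x + shared), 1L)
  structure(list(a_only = a_only, shared = shared, b_only = b_only,
                 pct_a_only = pct(a_only), pct_b_only = pct(b_only),
                 labels = labels),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("%s only: %d (%.1f%%) | shared: %d | %s only: %d (%.1f%%)\n",
              x$labels[1], x$a_only, x$pct_a_only, x$shared,
              x$labels[2], x$b_only, x$pct_b_only))
  invisible(x)
}

#' Three-way partition of the union of two call sets
#'
#' Splits `union(first, second)` into first-only / shared / second-only counts
#' (e.g. Mutect2-only, both callers, Strelka-only).
#'
#' @param first,second `CallSet`s of the same variant class.
#' @param labels Length-2 character vector naming the operands.
#' @return A `three_way` object.
#' @export
three_way <- function(first, second, labels = c(first$caller, second$caller)) {
  check_vclass(first, second)
  ka <- callset_keys(first); kb <- callset_keys(second)
  shared <- length(intersect(ka, kb))
  structure(list(first_only = length(ka) - shared, shared = shared,
                 second_only = length(kb) - shared, labels = labels),
            class = "three_way")
}

#' @export
print.three_way <- function(x, ...) {
  cat(sprintf("%s only: %d | both: %d | %s only: %d\n", x$labels[1],
              x$first_only, x$shared, x$labels[2], x$second_only))
  invisible(x)
}
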