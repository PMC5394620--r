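# CallSet: a keyed collection of call records from one (caller, aligner)
# combination or a merged product. Records live in a data.frame with one row
# per biallelic call; `filters` is a ";"-joined set of caller filter strings
# ("" means PASS) and `provenance` a comma-joined, sorted set of
# "caller/aligner" labels supporting the record.

RECORD_COLS <- c("chrom", "pos", "ref", "alt", "vtype", "key", "filters",
                 "tumour_depth", "tumour_alt", "normal_depth", "normal_alt",
                 "qual_score",
                 "tum_t1_ref", "tum_t1_alt", "tum_t1_dp",
                 "tum_t2_ref", "tum_t2_alt", "tum_t2_dp",
                 "nrm_t1_ref", "nrm_t1_alt", "nrm_t1_dp",
                 "nrm_t2_ref", "nrm_t2_alt", "nrm_t2_dp",
                 "provenance")

empty_records <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), vtype = character(0), key = character(0),
                   filters = character(0), stringsAsFactors = FALSE)
  for (cc in setdiff(RECORD_COLS, names(df))) {
    df[[cc]] <- if (cc == "provenance") character(0) else numeric(0)
  }
  df[RECORD_COLS]
}

#' Construct a CallSet
#'
#' @param records Data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   missing annotation columns are filled with `NA`.
#' @param caller Caller label (`"mutect2"`, `"strelka"`, or a merged label).
#' @param aligner Aligner/pipeline label (e.g. `"bwa"`, `"novoalign"`).
#' @param sample Optional sample label.
#' @param vclass One of `"SNV"`, `"INDEL"`, `"MIXED"`; inferred from `vtype`
#'   when omitted (MNVs ride with SNVs).
#' @return A `CallSet` object.
#' @export
call_set <- function(records, caller, aligner, sample = NA_character_,
                     vclass = NULL) {
  if (nrow(records) == 0L) {
    records <- empty_records()
  } else {
    records$chrom <- as.character(records$chrom)
    records$pos <- as.integer(records$pos)
    records$vtype <- variant_type(records$ref, records$alt)
    records$key <- variant_key(records)
    if (is.null(records$filters)) records$filters <- ""
    if (is.null(records$provenance) || all(is.na(records$provenance))) {
      records$provenance <- paste(caller, aligner, sep = "/")
    }
    for (cc in setdiff(RECORD_COLS, names(records))) records[[cc]] <- NA_real_
    records <- records[RECORD_COLS]
    rownames(records) <- NULL
    dup <- duplicated(records$key)
    if (any(dup)) {
      stop("duplicate variant keys in CallSet: ",
           paste(utils::head(records$key[dup], 3), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(vclass)) vclass <- infer_vclass(records$vtype)
  structure(list(records = records, caller = caller, aligner = aligner,
                 sample = sample, vclass = vclass),
            class = "CallSet")
}

infer_vclass <- function(vtype) {
  if (length(vtype) == 0L) return("MIXED")
  snv <- vtype %in% c("SNV", "MNV")
  if (all(snv)) "SNV" else if (!any(snv)) "INDEL" else "MIXED"
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet<%s/%s> %s: %d records\n", x$caller, x$aligner,
              x$vclass, nrow(x$records)))
  invisible(x)
}

#' @export
length.CallSet <- function(x) nrow(x$records)

#' Variant keys of a CallSet
#' @param cs A `CallSet`.
#' @return Character vector of keys.
#' @export
callset_keys <- function(cs) cs$records$key

#' Subset a CallSet by variant class
#'
#' @param cs A `CallSet`.
#' @param vclass `"SNV"` (SNVs and MNVs) or `"INDEL"` (insertions/deletions).
#' @return A `CallSet` of the requested class.
#' @export
subset_callset <- function(cs, vclass = c("SNV", "INDEL")) {
  vclass <- match.arg(vclass)
  keep <- if (vclass == "SNV") cs$records$vtype %in% c("SNV", "MNV")
          else cs$records$vtype %in% c("INS", "DEL")
  out <- cs
  out$records <- cs$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$vclass <- vclass
  out
}

# Normalize the variant fields of a record table against a reference and
# re-key. Records that collapse to the same key keep the first occurrence.
normalize_records <- function(records, reference) {
  if (is.null(reference) || nrow(records) == 0L) return(records)
  v <- normalize_variants(records[c("chrom", "pos", "ref", "alt")], reference)
  records$pos <- v$pos
  records$ref <- v$ref
  records$alt <- v$alt
  records$vtype <- v$vtype
  records$key <- variant_key(records)
  dup <- duplicated(records$key)
  if (any(dup)) {
    warning(sum(dup), " record(s) collapsed to an existing key after ",
            "normalization; keeping the first occurrence", call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  records
}

#' Normalize all records of a CallSet
#' @param cs A `CallSet`.
#' @param reference Reference accepted by [normalize_variants()].
#' @return The `CallSet` with left-aligned, trimmed records.
#' @export
normalize_callset <- function(cs, reference) {
  cs$records <- normalize_records(cs$records, reference)
  rownames(cs$records) <- NULL
  cs
}

filters_as_set <- function(filters) {
  f <- strsplit(filters, ";", fixed = TRUE)
  lapply(f, function(x) setdiff(x, c("", "PASS", ".")))
}

merge_provenance <- function(a, b) {
  vapply(seq_along(a), function(i) {
    paste(sort(unique(c(strsplit(a[i], ",")[[1]], strsplit(b[i], ",")[[1]]))),
          collapse = ",")
  }, character(1))
}
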