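# Core variant representation: a variant table is a data.frame with columns
# chrom, pos (1-based first ref base), ref, alt, vtype. All set operations in
# the package key on the normalized (chrom, pos, ref, alt) tuple.

VALID_BASES_RE <- "^[ACGT]+$"

#' Construct a variant table
#'
#' Builds the canonical variant data.frame used throughout the package. Input
#' alleles must be non-empty ACGT strings; `ref != alt` row-wise. Positions are
#' 1-based (VCF convention).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector, 1-based position of the first reference base.
#' @param ref,alt Character vectors of reference / alternate alleles.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `vtype`
#'   where `vtype` is one of `"SNV"`, `"INS"`, `"DEL"`, `"MNV"`.
#' @examples
#' variants("chr1", 100L, "A", "G")
#' @export
variants <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be positive integers", call. = FALSE)
  }
  bad <- !grepl(VALID_BASES_RE, ref) | !grepl(VALID_BASES_RE, alt)
  if (any(bad)) {
    stop("ref/alt alleles must be non-empty ACGT strings (offending: ",
         paste(utils::head(paste0(ref[bad], ">", alt[bad]), 3), collapse = ", "),
         ")", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             vtype = variant_type(ref, alt), stringsAsFactors = FALSE)
}

#' Classify variants by allele lengths
#'
#' @param ref,alt Character vectors of alleles.
#' @return Character vector: `"SNV"` (1 bp substitution), `"MNV"` (multi-base
#'   substitution of equal length), `"INS"` or `"DEL"`.
#' @export
variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNV"),
         ifelse(lr < la, "INS", "DEL"))
}

#' Variant identity keys
#'
#' Stable string key identifying a variant by its (chrom, pos, ref, alt)
#' tuple. Two records have equal keys iff all four fields are equal; matching
#' across call sets is done on these keys, so variants should be normalized
#' first when a reference is available.
#'
#' @param v A variant data.frame (see [variants()]).
#' @return Character vector of keys.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

# Coerce any supported reference input to a named list of plain upper-case
# chromosome strings. Accepts a FASTA path, a DNAStringSet, or a named
# character vector.
as_ref_seqs <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (is.list(reference) && !is.null(attr(reference, "itc_ref"))) return(reference)
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.list(toupper(as.character(reference)))
    names(out) <- sub("\\s.*$", "", names(reference))
  } else if (is.character(reference) && length(reference) == 1L &&
             is.null(names(reference)) && file.exists(reference)) {
    return(as_ref_seqs(Biostrings::readDNAStringSet(reference)))
  } else if (is.character(reference)) {
    if (is.null(names(reference))) {
      stop("character reference must be a FASTA path or a named vector of sequences",
           call. = FALSE)
    }
    out <- as.list(toupper(reference))
  } else {
    stop("unsupported reference type: ", class(reference)[1], call. = FALSE)
  }
  attr(out, "itc_ref") <- TRUE
  out
}

ref_slice <- function(seqs, chrom, start, end) {
  s <- seqs[[chrom]]
  if (is.null(s)) stop("chromosome '", chrom, "' not present in reference", call. = FALSE)
  if (start < 1L || end > nchar(s)) {
    stop("coordinates ", start, "-", end, " outside chromosome '", chrom, "'",
         call. = FALSE)
  }
  substr(s, start, end)
}

# Left-align and trim one variant (the classic parsimony/left-alignment loop):
# repeatedly drop a shared terminal base, extending to the left with reference
# sequence whenever an allele empties, then strip any shared prefix beyond the
# single anchor base.
normalize_one <- function(chrom, pos, ref, alt, seqs) {
  obs <- ref_slice(seqs, chrom, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop("reference mismatch at ", chrom, ":", pos, " (variant ref '", ref,
         "', reference has '", obs, "')", call. = FALSE)
  }
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L && (lr > 1L || la > 1L) &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      next
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) {
        stop("cannot left-align variant at start of chromosome '", chrom, "'",
             call. = FALSE)
      }
      pos <- pos - 1L
      b <- ref_slice(seqs, chrom, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      next
    }
    break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants against a reference
#'
#' Canonicalizes each variant to its left-aligned, minimal representation so
#' that equivalent descriptions of the same genomic change (common around
#' repetitive sequence, e.g. an insertion reported at either end of a
#' homopolymer run) compare equal by key. The operation is idempotent and
#' haplotype-preserving: applying the variant to the reference yields the same
#' sequence before and after normalization.
#'
#' With `reference = NULL` the input is returned unchanged (after re-deriving
#' `vtype`) and a warning is emitted once: matching then degrades to exact
#' (chrom, pos, ref, alt) equality.
#'
#' @param v Variant data.frame.
#' @param reference FASTA path, `DNAStringSet`, named character vector of
#'   chromosome sequences, or `NULL`.
#' @return The variant data.frame with normalized `pos`, `ref`, `alt`, `vtype`.
#' @export
normalize_variants <- function(v, reference = NULL) {
  v$vtype <- variant_type(v$ref, v$alt)
  if (is.null(reference)) {
    warning("no reference supplied: variants left as-is, matching is exact",
            call. = FALSE)
    return(v)
  }
  seqs <- as_ref_seqs(reference)
  if (nrow(v) == 0L) return(v)
  for (i in seq_len(nrow(v))) {
    nv <- normalize_one(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], seqs)
    v$pos[i] <- nv$pos
    v$ref[i] <- nv$ref
    v$alt[i] <- nv$alt
  }
  v$vtype <- variant_type(v$ref, v$alt)
  v
}

#' Apply a variant to its reference chromosome
#'
#' Returns the full haplotype sequence produced by substituting `alt` for
#' `ref` at `pos`. Used as the ground-truth equivalence test for variant
#' representations: two representations are the same variant iff they produce
#' identical haplotypes.
#'
#' @param chrom,pos,ref,alt Scalar variant fields.
#' @param reference Reference accepted by [normalize_variants()].
#' @return A single character string.
#' @export
apply_variant <- function(chrom, pos, ref, alt, reference) {
  seqs <- as_ref_seqs(reference)
  s <- seqs[[chrom]]
  if (is.null(s)) stop("chromosome '", chrom, "' not present in reference", call. = FALSE)
  obs <- substr(s, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    stop("reference mismatch at ", chrom, ":", pos, call. = FALSE)
  }
  paste0(substr(s, 1L, pos - 1L), alt, substr(s, pos + nchar(ref), nchar(s)))
}

#' Split a multiallelic record into biallelic variants
#'
#' One variant row per alternate allele, each independently normalizable.
#' Multiallelic truth-set rows are instead rejected at load (they are excluded
#' from evaluation), but caller outputs may legitimately contain them.
#'
#' @param chrom,pos,ref Scalar record fields.
#' @param alts Character vector of alternate alleles (length >= 1).
#' @return Variant data.frame with one row per alt.
#' @export
decompose_multiallelic <- function(chrom, pos, ref, alts) {
  if (length(alts) == 0L) stop("empty alt allele list", call. = FALSE)
  variants(chrom = rep(chrom, length(alts)), pos = rep(pos, length(alts)),
           ref = rep(ref, length(alts)), alt = alts)
}
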