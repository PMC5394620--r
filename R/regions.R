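# Genomic interval algebra. A RegionSet wraps a reduced (merged, sorted)
# GRanges; all user-facing coordinates follow the BED convention (0-based,
# half-open) and are converted at the boundary. n_ref for FPR/Mb reporting is
# total_bp() of the evaluation RegionSet.

harmonize_seqlevels <- function(a, b) {
  sl <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- sl
  GenomeInfoDb::seqlevels(b) <- sl
  list(a = a, b = b)
}

#' Build a RegionSet
#'
#' @param x A `GRanges`, a data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, BED convention), or a path to a BED file (>= 3
#'   columns, no header).
#' @return A `RegionSet`: merged, sorted, strand-free intervals.
#' @export
region_set <- function(x) {
  if (inherits(x, "RegionSet")) return(x)
  if (methods::is(x, "GRanges")) {
    gr <- x
  } else if (is.data.frame(x)) {
    bad <- x$start >= x$end
    if (any(bad)) {
      stop("malformed interval: start >= end at row ", which(bad)[1], call. = FALSE)
    }
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(start = x$start + 1L, end = x$end))
  } else if (is.character(x) && length(x) == 1L) {
    gr <- read_bed_granges(x)
  } else {
    stop("cannot build RegionSet from ", class(x)[1], call. = FALSE)
  }
  GenomicRanges::strand(gr) <- "*"
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(gr = gr), class = "RegionSet")
}

read_bed_granges <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer", rep("NULL", 20))[1:3],
                          fill = TRUE, comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (any(df$start >= df$end)) stop("malformed BED interval (start >= end)", call. = FALSE)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' @export
print.RegionSet <- function(x, ...) {
  cat("RegionSet:", length(x$gr), "intervals,", total_bp(x), "bp on",
      length(GenomeInfoDb::seqlevels(x$gr)), "sequence(s)\n")
  invisible(x)
}

#' Total base pairs covered by a RegionSet
#' @param r A `RegionSet`.
#' @return Integer-valued numeric, the sum of interval widths.
#' @export
total_bp <- function(r) {
  sum(as.numeric(GenomicRanges::width(r$gr)))
}

#' Region set operations
#'
#' `intersect_regions` and `subtract_regions` implement per-base intersection
#' and difference; `subtract_loci` removes the reference-spanning footprint
#' (`pos .. pos + nchar(ref) - 1`) of each variant, which is how truth loci
#' are excised from confident regions before FP accounting.
#'
#' @param a,b `RegionSet` objects.
#' @return A merged `RegionSet`.
#' @export
intersect_regions <- function(a, b) {
  h <- harmonize_seqlevels(region_set(a)$gr, region_set(b)$gr)
  region_set(suppressWarnings(GenomicRanges::intersect(h$a, h$b)))
}

#' @rdname intersect_regions
#' @export
subtract_regions <- function(a, b) {
  h <- harmonize_seqlevels(region_set(a)$gr, region_set(b)$gr)
  region_set(suppressWarnings(GenomicRanges::setdiff(h$a, h$b)))
}

#' @rdname intersect_regions
#' @param r A `RegionSet`.
#' @param v Variant data.frame whose footprints are removed.
#' @export
subtract_loci <- function(r, v) {
  if (nrow(v) == 0L) return(region_set(r))
  foot <- GenomicRanges::GRanges(v$chrom,
                                 IRanges::IRanges(start = v$pos,
                                                  end = v$pos + nchar(v$ref) - 1L))
  h <- harmonize_seqlevels(region_set(r)$gr, foot)
  region_set(suppressWarnings(GenomicRanges::setdiff(h$a, h$b)))
}

#' Point membership in a RegionSet
#'
#' @param r A `RegionSet`.
#' @param chrom,pos Vectors of 1-based positions to test.
#' @return Logical vector.
#' @export
point_in_regions <- function(r, chrom, pos) {
  r <- region_set(r)
  if (length(pos) == 0L) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos))
  h <- harmonize_seqlevels(q, r$gr)
  GenomicRanges::countOverlaps(h$a, h$b) > 0L
}

#' Export a RegionSet as a BED data.frame or file
#'
#' @param r A `RegionSet`.
#' @param path Optional output path; when given, a 3-column BED is written.
#' @return Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
regions_as_bed <- function(r, path = NULL) {
  r <- region_set(r)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(r$gr)),
                   start = GenomicRanges::start(r$gr) - 1L,
                   end = GenomicRanges::end(r$gr),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  df
}
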