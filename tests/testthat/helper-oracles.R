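# Independent brute-force oracles and fixture builders. Nothing here calls
# the package's normalization/classification code paths; these implement the
# checked operations from first principles on tiny inputs.

# Splice a variant into a reference string (the ground-truth haplotype).
bf_apply <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

# All anchor+indel representations of the single indel separating S and H,
# found by scanning every anchor position and deriving the candidate alleles
# from the two strings. Returns a data.frame of (pos, ref, alt).
bf_representations <- function(S, H) {
  m <- nchar(H) - nchar(S)
  stopifnot(m != 0)
  out <- list()
  for (p in seq_len(nchar(S))) {
    if (m > 0) {
      if (p + m > nchar(H)) next
      ref <- substr(S, p, p)
      alt <- paste0(ref, substr(H, p + 1L, p + m))
    } else {
      if (p - m > nchar(S)) next
      ref <- substr(S, p, p - m)
      alt <- substr(S, p, p)
    }
    hap <- tryCatch(bf_apply(S, p, ref, alt), error = function(e) NULL)
    if (identical(hap, H)) out[[length(out) + 1L]] <- list(pos = p, ref = ref, alt = alt)
  }
  do.call(rbind, lapply(out, as.data.frame, stringsAsFactors = FALSE))
}

# Minimality of a normalized representation: no full shared suffix, shared
# prefix at most the single anchor base.
bf_is_minimal <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr > 1L || la > 1L) {
    if (substr(ref, lr, lr) == substr(alt, la, la)) return(FALSE)
  }
  if (lr >= 2L && la >= 2L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    return(FALSE)
  }
  TRUE
}

# Per-base coverage oracle for region algebra on a single chromosome.
bf_coverage <- function(bed, L) {
  cov <- logical(L)
  for (i in seq_len(nrow(bed))) cov[(bed$start[i] + 1L):bed$end[i]] <- TRUE
  cov
}

# Classification oracle: naive scan comparing fields, no keys.
bf_classify <- function(calls, truth, region_cov) {
  same <- function(a, b) {
    a$chrom == b$chrom & a$pos == b$pos & a$ref == b$ref & a$alt == b$alt
  }
  tp <- 0L; fp <- 0L; uncl <- 0L
  for (i in seq_len(nrow(calls))) {
    hit <- any(vapply(seq_len(nrow(truth)), function(j) {
      same(calls[i, ], truth[j, ])
    }, logical(1)))
    if (hit) tp <- tp + 1L
    else if (region_cov[calls$pos[i]]) fp <- fp + 1L
    else uncl <- uncl + 1L
  }
  fn <- 0L
  for (j in seq_len(nrow(truth))) {
    hit <- any(vapply(seq_len(nrow(calls)), function(i) {
      same(calls[i, ], truth[j, ])
    }, logical(1)))
    if (!hit) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, unclassified = uncl)
}

# --- fixture builders -------------------------------------------------------

# A CallSet of n distinct SNV keys; `start` offsets the position grid so sets
# with controlled overlaps can be engineered.
toy_callset <- function(n, start = 1L, caller = "toy", aligner = "x",
                        chrom = "chr1", alt = "G") {
  if (n == 0L) {
    return(call_set(data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0)),
                    caller, aligner, vclass = "SNV"))
  }
  rec <- data.frame(chrom = chrom, pos = (start - 1L + seq_len(n)) * 10L,
                    ref = "A", alt = alt, stringsAsFactors = FALSE)
  call_set(rec, caller, aligner, vclass = "SNV")
}

# Two CallSets with exactly (a_only, shared, b_only) key counts.
overlap_pair <- function(a_only, shared, b_only) {
  a <- toy_callset(a_only + shared, start = 1L, aligner = "a")
  b <- toy_callset(b_only + shared, start = a_only + 1L, aligner = "b")
  list(a = a, b = b)
}

# Minimal dialect VCF texts for reader tests.
write_mutect2_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##FILTER=<ID=alt_allele_in_normal,Description=\"x\">",
    "##FILTER=<ID=clustered_events,Description=\"x\">",
    "##FILTER=<ID=homologous_mapping_event,Description=\"x\">",
    "##INFO=<ID=TLOD,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##contig=<ID=chr1,length=100000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    "chr1\t100\t.\tA\tG\t.\tPASS\tTLOD=21.5\tAD:DP\t75,25:100\t80,0:80",
    "chr1\t200\t.\tC\tT\t.\tclustered_events;homologous_mapping_event\tTLOD=9.1\tAD:DP\t50,10:60\t70,2:72",
    "chr1\t300\t.\tG\tA,T\t.\talt_allele_in_normal\tTLOD=7.0\tAD:DP\t40,5,6:51\t60,3,0:63"
  ), path)
  path
}

write_strelka_snv_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=QSS,Number=1,Type=Integer,Description=\"x\">",
    "##INFO=<ID=QSS_NT,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=AU,Number=2,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=CU,Number=2,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GU,Number=2,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=TU,Number=2,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    "chr1\t150\t.\tA\tC\t.\tPASS\tQSS=30;QSS_NT=27\tDP:AU:CU:GU:TU\t40:40,41:0,0:0,0:0,0\t41:30,30:10,12:0,0:1,1"
  ), path)
  path
}

write_strelka_indel_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=QSI,Number=1,Type=Integer,Description=\"x\">",
    "##INFO=<ID=QSI_NT,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=TAR,Number=2,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=TIR,Number=2,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORMAL\tTUMOR",
    "chr1\t500\t.\tAT\tA\t.\tPASS\tQSI=40;QSI_NT=33\tDP:TAR:TIR\t95:95,96:0,0\t100:90,92:10,11"
  ), path)
  path
}

# A strelka-dialect CallSet built directly (tier counts supplied), for filter
# tests that need full control.
strelka_record <- function(pos, ref = "A", alt = "C", qual, t1_alt, t2_alt,
                           t1_dp = 40, t2_dp = 42, filters = "") {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             filters = filters, qual_score = qual,
             tumour_depth = t1_dp, tumour_alt = t1_alt,
             normal_depth = 40, normal_alt = 0,
             tum_t1_ref = t1_dp - t1_alt, tum_t1_alt = t1_alt, tum_t1_dp = t1_dp,
             tum_t2_ref = t2_dp - t2_alt, tum_t2_alt = t2_alt, tum_t2_dp = t2_dp,
             nrm_t1_ref = 40, nrm_t1_alt = 0, nrm_t1_dp = 40,
             nrm_t2_ref = 40, nrm_t2_alt = 0, nrm_t2_dp = 40,
             stringsAsFactors = FALSE)
}

mutect2_record <- function(pos, ref = "A", alt = "G", filters = "",
                           t_dp = 100, t_alt = 30, n_dp = 100, n_alt = 0,
                           tlod = 20) {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             filters = filters, tumour_depth = t_dp, tumour_alt = t_alt,
             normal_depth = n_dp, normal_alt = n_alt, qual_score = tlod,
             stringsAsFactors = FALSE)
}
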