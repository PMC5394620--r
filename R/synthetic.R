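# Synthetic dilution-series generator. Emulates, at the call level (no reads),
# the statistical structure of a platinum-genome dilution experiment: a mini
# reference with low-complexity runs, a truth set of het/hom SNVs and indels
# inside confident capture regions, binomial allele-depth sampling at each
# purity, pipeline-specific vs shared false positives, caller-dialect VCF
# output, and jittered (right-shifted) indel representations in the Strelka
# sets so representation-aware matching is exercised.

#' Simulation configuration
#'
#' Defaults describe the emulated study: an 11-point purity series from 100%
#' down to 0.2%, mean coverage 100x, a 200 kb single-chromosome "exome" with
#' 15% of its length in homopolymer/dinucleotide runs, 500 truth SNVs and 50
#' indels at 2:1 het:hom. The false-positive intensity is expressed per Mb
#' and scaled so a mini genome yields absolute FP counts of the same order as
#' a real exome study (tens per call set).
#'
#' @param genome_length Reference length in bp (>= 10 kb).
#' @param repeat_density Fraction of the genome covered by low-complexity
#'   runs.
#' @param n_snv,n_indel Truth variant counts.
#' @param het_fraction Fraction of truth variants heterozygous.
#' @param purities Strictly decreasing tumour-DNA fractions.
#' @param depth_mean Expected read depth.
#' @param fp_rate_per_mb Per-pipeline false-positive intensity.
#' @param shared_fp_fraction Fraction of a caller's FPs placed identically in
#'   both aligners' call sets.
#' @param representation_jitter_prob Chance a Strelka indel is emitted in a
#'   right-shifted/padded equivalent representation.
#' @param detection_alt_threshold Minimum sampled alt reads for a call to be
#'   emitted.
#' @param detection_prob Independent per-pipeline detection probability.
#' @param aain_fraction Fraction of true Mutect2 calls flagged
#'   `alt_allele_in_normal`, with normal alt counts drawn across the 7%
#'   boundary so re-admission is exercised on both sides.
#' @param clustered_fraction Fraction of true Mutect2 calls flagged
#'   `clustered_events` (rescued by every policy).
#' @param tier2_only_prob Chance a true Strelka call has alt support only at
#'   tier 2.
#' @param tumour_label,normal_label Sample names written to Mutect2 VCFs.
#' @param seed Master seed; purpose-specific streams are derived from it.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(genome_length = 200000L,
                       repeat_density = 0.15,
                       n_snv = 500L,
                       n_indel = 50L,
                       het_fraction = 2 / 3,
                       purities = c(1, 0.8, 0.6, 0.4, 0.2, 0.1, 0.05,
                                    0.02, 0.01, 0.005, 0.002),
                       depth_mean = 100,
                       fp_rate_per_mb = 150,
                       shared_fp_fraction = 0.25,
                       representation_jitter_prob = 0.3,
                       detection_alt_threshold = 3L,
                       detection_prob = 0.95,
                       aain_fraction = 0.15,
                       clustered_fraction = 0.05,
                       tier2_only_prob = 0.04,
                       tumour_label = "TUMOR",
                       normal_label = "NORMAL",
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              repeat_density = repeat_density, n_snv = as.integer(n_snv),
              n_indel = as.integer(n_indel), het_fraction = het_fraction,
              purities = purities, depth_mean = depth_mean,
              fp_rate_per_mb = fp_rate_per_mb,
              shared_fp_fraction = shared_fp_fraction,
              representation_jitter_prob = representation_jitter_prob,
              detection_alt_threshold = as.integer(detection_alt_threshold),
              detection_prob = detection_prob,
              aain_fraction = aain_fraction,
              clustered_fraction = clustered_fraction,
              tier2_only_prob = tier2_only_prob,
              tumour_label = tumour_label, normal_label = normal_label,
              seed = as.integer(seed))
  fr <- c("repeat_density", "het_fraction", "shared_fp_fraction",
          "representation_jitter_prob", "detection_prob", "aain_fraction",
          "clustered_fraction", "tier2_only_prob")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$genome_length < 10000L) stop("genome_length must be >= 10 kb", call. = FALSE)
  if (cfg$n_snv <= 0L || cfg$n_indel < 0L) stop("truth counts must be positive", call. = FALSE)
  if (any(diff(cfg$purities) >= 0) || any(cfg$purities <= 0 | cfg$purities > 1)) {
    stop("purities must be strictly decreasing fractions in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# Per-purpose substream seed so changing one parameter perturbs only its own
# stream. Kept below 2^31.
stream_seed <- function(seed, purpose, extra = 0) {
  u <- utf8ToInt(purpose)
  h <- sum(u * seq_along(u))
  as.integer((as.numeric(seed) * 10007 + h * 101 +
                round(as.numeric(extra) * 100000)) %% 2147483563)
}

#' Generate a synthetic mini reference
#'
#' Random sequence with homopolymer and dinucleotide runs (8-30 bp) inserted
#' until the merged run annotation covers `repeat_density` of the genome.
#' Deterministic given the config seed.
#'
#' @param cfg A `SimulationConfig`.
#' @return List with `seqs` (named chromosome strings), `runs` (a `RegionSet`
#'   of annotated low-complexity runs) and `contigs` (named lengths).
#' @export
make_reference <- function(cfg) {
  set.seed(stream_seed(cfg$seed, "reference"))
  L <- cfg$genome_length
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  runs <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
  if (cfg$repeat_density > 0) {
    target <- cfg$repeat_density * L
    placed <- list()
    covered <- 0
    mask <- logical(L)
    while (covered < target) {
      len <- sample(8:30, 1L)
      start <- sample.int(L - len, 1L)
      motif <- if (stats::runif(1) < 0.5) {
        sample(c("A", "C", "G", "T"), 1L)
      } else {
        paste(sample(c("A", "C", "G", "T"), 2L), collapse = "")
      }
      unit <- strsplit(motif, "")[[1]]
      idx <- start:(start + len - 1L)
      bases[idx] <- rep_len(unit, len)
      covered <- covered + sum(!mask[idx])
      mask[idx] <- TRUE
      placed[[length(placed) + 1L]] <- c(start, start + len - 1L)
    }
    pm <- do.call(rbind, placed)
    runs <- data.frame(chrom = "chr1", start = pm[, 1] - 1L, end = pm[, 2],
                       stringsAsFactors = FALSE)
  }
  seqs <- c(chr1 = paste(bases, collapse = ""))
  list(seqs = seqs,
       runs = if (nrow(runs)) region_set(runs) else
         region_set(data.frame(chrom = character(0), start = integer(0),
                               end = integer(0))[0, ]),
       contigs = c(chr1 = L))
}

region_positions <- function(r) {
  bed <- regions_as_bed(r)
  if (nrow(bed) == 0L) return(data.frame(chrom = character(0), pos = integer(0)))
  pos <- unlist(mapply(function(s, e) seq(s + 1L, e), bed$start, bed$end,
                       SIMPLIFY = FALSE))
  data.frame(chrom = rep(bed$chrom, bed$end - bed$start), pos = pos,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic truth set with regions
#'
#' Tiles the genome with exon-like target intervals (350 bp every 500 bp),
#' removes a few confident-region gaps, then places `n_snv` SNVs and
#' `n_indel` 1-3 bp indels (half of the indels anchored at low-complexity
#' runs so representation jitter has something to act on) inside
#' target-and-confident sequence, left-aligned, with a minimum spacing of
#' 10 bp. Zygosity is het with probability `het_fraction`.
#'
#' @param reference Output of [make_reference()].
#' @param cfg A `SimulationConfig`.
#' @return List with `truth` (a `TruthSet`), `variants` (truth variants plus
#'   `zygosity`), `confident` and `target` (`RegionSet`s), and the reference.
#' @export
make_truth <- function(reference, cfg) {
  set.seed(stream_seed(cfg$seed, "truth"))
  L <- cfg$genome_length
  s <- reference$seqs[["chr1"]]
  starts <- seq(1L, max(1L, L - 400L), by = 500L)
  target <- region_set(data.frame(chrom = "chr1", start = starts - 1L,
                                  end = pmin(starts + 349L, L)))
  n_gaps <- max(1L, L %/% 20000L)
  gap_start <- sort(sample.int(L - 900L, n_gaps))
  gap_len <- sample(200:600, n_gaps, replace = TRUE)
  gaps <- region_set(data.frame(chrom = "chr1", start = gap_start,
                                end = gap_start + gap_len))
  confident <- subtract_regions(
    region_set(data.frame(chrom = "chr1", start = 0L, end = L)), gaps)
  pool <- intersect_regions(target, confident)
  allowed <- region_positions(pool)$pos
  allowed <- allowed[allowed > 20L & allowed < L - 20L]
  occupied <- logical(L)
  reserve <- function(p, w = 10L) {
    occupied[max(1L, p - w):min(L, p + w)] <<- TRUE
  }
  draw_pos <- function() {
    for (i in 1:50) {
      p <- allowed[sample.int(length(allowed), 1L)]
      if (!occupied[p]) return(p)
    }
    stop("genome too small for the requested truth variant counts", call. = FALSE)
  }
  base_at <- function(p) substr(s, p, p)
  # SNVs
  snv_pos <- integer(cfg$n_snv)
  snv_ref <- snv_alt <- character(cfg$n_snv)
  for (i in seq_len(cfg$n_snv)) {
    p <- draw_pos(); reserve(p)
    snv_pos[i] <- p
    snv_ref[i] <- base_at(p)
    snv_alt[i] <- sample(setdiff(c("A", "C", "G", "T"), snv_ref[i]), 1L)
  }
  # indels: half anchored just before a low-complexity run
  run_bed <- regions_as_bed(reference$runs)
  run_anchor <- run_bed$start[run_bed$start > 20L & run_bed$start < L - 40L]
  run_anchor <- run_anchor[point_in_regions(pool, rep("chr1", length(run_anchor)),
                                            run_anchor)]
  ind_pos <- integer(0); ind_ref <- ind_alt <- character(0)
  n_run_ind <- if (length(run_anchor) > 0L) min(cfg$n_indel %/% 2L, length(run_anchor))
               else 0L
  if (n_run_ind > 0L) run_anchor <- sample(run_anchor, n_run_ind)
  for (i in seq_len(cfg$n_indel)) {
    if (i <= n_run_ind) {
      p <- run_anchor[i]
      if (occupied[p]) p <- draw_pos()
    } else {
      p <- draw_pos()
    }
    reserve(p)
    k <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {  # insertion
      ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
      ind_ref <- c(ind_ref, base_at(p))
      ind_alt <- c(ind_alt, paste0(base_at(p), ins))
    } else {                      # deletion
      ind_ref <- c(ind_ref, substr(s, p, p + k))
      ind_alt <- c(ind_alt, base_at(p))
    }
    ind_pos <- c(ind_pos, p)
  }
  v <- variants(chrom = "chr1", pos = c(snv_pos, ind_pos),
                ref = c(snv_ref, ind_ref), alt = c(snv_alt, ind_alt))
  v <- normalize_variants(v, reference$seqs)
  dup <- duplicated(variant_key(v))
  v <- v[!dup, , drop = FALSE]
  v$zygosity <- ifelse(stats::runif(nrow(v)) < cfg$het_fraction, "het", "hom")
  rownames(v) <- NULL
  ts <- truth_set(v, confident = confident, target = target,
                  reference = reference$seqs)
  ts$variants$zygosity <- v$zygosity[match(ts$variants$key, variant_key(v))]
  list(truth = ts, variants = ts$variants, confident = confident,
       target = target, reference = reference)
}

# Equivalent, non-canonical representation of an indel: right-shift through
# repeat sequence where possible and/or pad with a shared trailing reference
# base. Haplotype equality with the input is verified; on any failure the
# input representation is returned unchanged.
denormalize_indel <- function(chrom, pos, ref, alt, seqs, max_shift = 3L,
                              pad = FALSE) {
  s <- seqs[[chrom]]
  orig <- list(pos = pos, ref = ref, alt = alt)
  hap0 <- apply_variant(chrom, pos, ref, alt, seqs)
  for (step in seq_len(max_shift)) {
    if (nchar(alt) > nchar(ref) && nchar(ref) == 1L) {        # insertion
      ins <- substr(alt, 2L, nchar(alt))
      nxt <- substr(s, pos + 1L, pos + 1L)
      if (nzchar(nxt) && nxt == substr(ins, 1L, 1L)) {
        pos <- pos + 1L
        ref <- nxt
        alt <- paste0(nxt, substr(ins, 2L, nchar(ins)), substr(ins, 1L, 1L))
      } else break
    } else if (nchar(ref) > nchar(alt) && nchar(alt) == 1L) { # deletion
      m <- nchar(ref) - 1L
      nxt <- substr(s, pos + m + 1L, pos + m + 1L)
      if (nzchar(nxt) && substr(s, pos + 1L, pos + 1L) == nxt) {
        pos <- pos + 1L
        ref <- substr(s, pos, pos + m)
        alt <- substr(s, pos, pos)
      } else break
    } else break
  }
  if (pad && pos + nchar(ref) <= nchar(s)) {
    nxt <- substr(s, pos + nchar(ref), pos + nchar(ref))
    ref <- paste0(ref, nxt)
    alt <- paste0(alt, nxt)
  }
  out <- list(pos = pos, ref = ref, alt = alt)
  ok <- tryCatch(identical(hap0, apply_variant(chrom, out$pos, out$ref,
                                               out$alt, seqs)),
                 error = function(e) FALSE)
  if (ok) out else orig
}

empty_sim_records <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), filters = character(0),
             tumour_depth = numeric(0), tumour_alt = numeric(0),
             normal_depth = numeric(0), normal_alt = numeric(0),
             qual_score = numeric(0), stringsAsFactors = FALSE)
}

sample_fp_records <- function(n, allowed, seqs, score_fun, cfg, used_keys) {
  if (n == 0L) return(empty_sim_records())
  s <- seqs[["chr1"]]
  L <- nchar(s)
  rows <- list()
  tries <- 0L
  while (length(rows) < n && tries < 50L * n + 50L) {
    tries <- tries + 1L
    p <- allowed[sample.int(length(allowed), 1L)]
    b <- substr(s, p, p)
    u <- stats::runif(1)
    if (u < 0.85) {
      ref <- b; alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    } else if (u < 0.925 || p + 2L > L) {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:2, 1L),
                          replace = TRUE), collapse = "")
      ref <- b; alt <- paste0(b, ins)
    } else {
      k <- sample(1:2, 1L)
      ref <- substr(s, p, p + k); alt <- b
    }
    nv <- normalize_one("chr1", p, ref, alt, as_ref_seqs(seqs))
    key <- paste("chr1", nv$pos, nv$ref, nv$alt, sep = ":")
    if (key %in% used_keys) next
    used_keys <- c(used_keys, key)
    depth <- stats::rpois(1L, cfg$depth_mean)
    altc <- min(depth, cfg$detection_alt_threshold + stats::rpois(1L, 2))
    ndepth <- stats::rpois(1L, cfg$depth_mean)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", pos = nv$pos, ref = nv$ref, alt = nv$alt, filters = "",
      tumour_depth = depth, tumour_alt = altc, normal_depth = ndepth,
      normal_alt = 0, qual_score = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_sim_records())
  fp <- do.call(rbind, rows)
  fp$qual_score <- score_fun(fp)
  fp
}

#' Simulate the four pipelines' call sets at one purity
#'
#' Per truth variant, depth is Poisson(`depth_mean`) and the alt count
#' binomial with expected VAF `expected_vaf(purity, zygosity)`; these sampled
#' counts are shared by all four pipelines (they resequence the same
#' library), while each (caller, aligner) pipeline applies an independent
#' detection coin on top of the `alt >= detection_alt_threshold` requirement.
#' A fraction of true Mutect2 calls carries planted `alt_allele_in_normal`
#' or `clustered_events` filter strings; Strelka records carry tier-1/tier-2
#' counts and occasionally tier-2-only alt support. False positives are drawn
#' inside the evaluation regions at `fp_rate_per_mb` per pipeline, a
#' `shared_fp_fraction` of them placed identically in both aligners' sets for
#' a caller; FP quality scores are uniform over (threshold - 10, threshold
#' + 10) so admission rules are exercised on both sides. Strelka indels are
#' emitted in a right-shifted/padded equivalent representation with
#' probability `representation_jitter_prob`.
#'
#' @param study Output of [make_truth()].
#' @param purity Tumour-DNA fraction in (0, 1].
#' @param cfg A `SimulationConfig`.
#' @return List with elements `mutect2`, `strelka_snv`, `strelka_indel`
#'   (each a list of `CallSet`s keyed by aligner `bwa` / `novoalign`) and
#'   `pileup` (truth-locus depth/alt table).
#' @export
simulate_callsets <- function(study, purity, cfg) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]", call. = FALSE)
  set.seed(stream_seed(cfg$seed, "calls", purity))
  seqs <- study$reference$seqs
  tv <- study$variants
  n <- nrow(tv)
  depth <- stats::rpois(n, cfg$depth_mean)
  evaf <- expected_vaf(purity, tv$zygosity)
  altc <- stats::rbinom(n, depth, evaf)
  ndepth <- stats::rpois(n, cfg$depth_mean)
  # Mutect2 per-variant attributes, shared by both aligners
  u <- stats::runif(n)
  fclass <- ifelse(u < cfg$aain_fraction, "alt_allele_in_normal",
                   ifelse(u < cfg$aain_fraction + cfg$clustered_fraction,
                          "clustered_events", ""))
  nalt <- integer(n)
  aain <- fclass == "alt_allele_in_normal"
  nalt[aain] <- stats::rbinom(sum(aain), ndepth[aain],
                              stats::runif(sum(aain), 0.005, 0.12))
  tlod <- pmax(0, round(altc + stats::rnorm(n, 0, 2), 2))
  # Strelka per-variant attributes
  qss <- pmax(0, round(15 + 2.5 * altc + stats::rnorm(n, 0, 3)))
  qsi <- pmax(0, round(20 + 2.2 * altc + stats::rnorm(n, 0, 3)))
  t2_extra_alt <- stats::rbinom(n, 4, 0.3)
  t2_extra_dp <- stats::rbinom(n, 8, 0.5)
  tier2_only <- stats::runif(n) < cfg$tier2_only_prob
  st1_alt <- ifelse(tier2_only, 0L, altc)
  st2_alt <- altc + t2_extra_alt
  is_indel <- tv$vtype %in% c("INS", "DEL")
  jit <- stats::runif(n) < cfg$representation_jitter_prob & is_indel
  jit_pad <- stats::runif(n) < 0.5
  coins <- matrix(stats::runif(4L * n) < cfg$detection_prob, n, 4L,
                  dimnames = list(NULL, c("mutect2.bwa", "mutect2.novoalign",
                                          "strelka.bwa", "strelka.novoalign")))
  detected <- altc >= cfg$detection_alt_threshold
  # jittered strelka representations, drawn once (same in both aligner sets)
  jrep <- tv[c("chrom", "pos", "ref", "alt")]
  for (i in which(jit)) {
    d <- denormalize_indel(tv$chrom[i], tv$pos[i], tv$ref[i], tv$alt[i], seqs,
                           max_shift = sample(1:3, 1L), pad = jit_pad[i])
    jrep$pos[i] <- d$pos; jrep$ref[i] <- d$ref; jrep$alt[i] <- d$alt
  }
  # false positive pools
  mb <- total_bp(study$truth$regions) / 1e6
  allowed <- region_positions(study$truth$regions)$pos
  allowed <- allowed[allowed > 20L & allowed < cfg$genome_length - 20L]
  used <- tv$key
  lam_sh <- cfg$fp_rate_per_mb * mb * cfg$shared_fp_fraction
  lam_sp <- cfg$fp_rate_per_mb * mb * (1 - cfg$shared_fp_fraction)
  m2_score <- function(fp) round(stats::runif(nrow(fp), 0, 16.3), 2)
  sk_score <- function(fp) {
    ifelse(variant_type(fp$ref, fp$alt) %in% c("INS", "DEL"),
           round(stats::runif(nrow(fp), 25, 45)),
           round(stats::runif(nrow(fp), 15, 35)))
  }
  draw_fp <- function(score_fun) {
    sh <- sample_fp_records(stats::rpois(1L, lam_sh), allowed, seqs,
                            score_fun, cfg, used)
    used <<- c(used, variant_key(sh))
    spec <- lapply(1:2, function(j) {
      sp <- sample_fp_records(stats::rpois(1L, lam_sp), allowed, seqs,
                              score_fun, cfg, used)
      used <<- c(used, variant_key(sp))
      sp
    })
    list(shared = sh, bwa = spec[[1]], novoalign = spec[[2]])
  }
  fp_m2 <- draw_fp(m2_score)
  fp_sk <- draw_fp(sk_score)

  truth_m2_records <- function(keep) {
    data.frame(chrom = tv$chrom[keep], pos = tv$pos[keep], ref = tv$ref[keep],
               alt = tv$alt[keep], filters = fclass[keep],
               tumour_depth = depth[keep], tumour_alt = altc[keep],
               normal_depth = ndepth[keep], normal_alt = nalt[keep],
               qual_score = tlod[keep], stringsAsFactors = FALSE)
  }
  strelka_tiers <- function(rec, keep) {
    rec$tum_t1_alt <- st1_alt[keep]
    rec$tum_t1_dp <- depth[keep]
    rec$tum_t1_ref <- depth[keep] - st1_alt[keep]
    rec$tum_t2_alt <- st2_alt[keep]
    rec$tum_t2_dp <- depth[keep] + t2_extra_dp[keep]
    rec$tum_t2_ref <- rec$tum_t2_dp - rec$tum_t2_alt
    rec$nrm_t1_alt <- rep(0, nrow(rec)); rec$nrm_t1_dp <- ndepth[keep]
    rec$nrm_t1_ref <- ndepth[keep]
    rec$nrm_t2_alt <- rep(0, nrow(rec)); rec$nrm_t2_dp <- ndepth[keep] + 2L
    rec$nrm_t2_ref <- rec$nrm_t2_dp
    rec$tumour_depth <- rec$tum_t1_dp; rec$tumour_alt <- rec$tum_t1_alt
    rec$normal_depth <- rec$nrm_t1_dp; rec$normal_alt <- rec$nrm_t1_alt
    rec
  }
  truth_sk_records <- function(keep, want_indel) {
    keep <- keep & (is_indel == want_indel)
    rec <- data.frame(chrom = jrep$chrom[keep], pos = jrep$pos[keep],
                      ref = jrep$ref[keep], alt = jrep$alt[keep],
                      filters = rep("", sum(keep)),
                      qual_score = if (want_indel) qsi[keep] else qss[keep],
                      stringsAsFactors = FALSE)
    strelka_tiers(rec, keep)
  }
  fp_tiers <- function(fp) {
    fp$tum_t1_alt <- fp$tumour_alt; fp$tum_t1_dp <- fp$tumour_depth
    fp$tum_t1_ref <- fp$tumour_depth - fp$tumour_alt
    fp$tum_t2_alt <- fp$tumour_alt; fp$tum_t2_dp <- fp$tumour_depth
    fp$tum_t2_ref <- fp$tum_t1_ref
    fp$nrm_t1_alt <- rep(0, nrow(fp)); fp$nrm_t1_dp <- fp$normal_depth
    fp$nrm_t1_ref <- fp$normal_depth
    fp$nrm_t2_alt <- rep(0, nrow(fp)); fp$nrm_t2_dp <- fp$normal_depth
    fp$nrm_t2_ref <- fp$normal_depth
    fp
  }
  build <- function(caller, aligner) {
    keep <- detected & coins[, paste(caller, aligner, sep = ".")]
    if (caller == "mutect2") {
      rec <- rbind(truth_m2_records(keep),
                   fp_m2$shared, fp_m2[[aligner]])
      call_set(rec, caller = "mutect2", aligner = aligner,
               sample = cfg$tumour_label, vclass = "MIXED")
    } else {
      fps <- fp_tiers(rbind(fp_sk$shared, fp_sk[[aligner]]))
      fp_ind <- variant_type(fps$ref, fps$alt) %in% c("INS", "DEL")
      snv <- rbind(truth_sk_records(keep, FALSE),
                   fps[!fp_ind, , drop = FALSE])
      ind <- rbind(truth_sk_records(keep, TRUE),
                   fps[fp_ind, , drop = FALSE])
      list(snv = call_set(snv, caller = "strelka", aligner = aligner,
                          sample = cfg$tumour_label, vclass = "SNV"),
           indel = call_set(ind, caller = "strelka", aligner = aligner,
                            sample = cfg$tumour_label, vclass = "INDEL"))
    }
  }
  sk_bwa <- build("strelka", "bwa")
  sk_novo <- build("strelka", "novoalign")
  list(mutect2 = list(bwa = build("mutect2", "bwa"),
                      novoalign = build("mutect2", "novoalign")),
       strelka_snv = list(bwa = sk_bwa$snv, novoalign = sk_novo$snv),
       strelka_indel = list(bwa = sk_bwa$indel, novoalign = sk_novo$indel),
       pileup = data.frame(chrom = tv$chrom, pos = tv$pos, depth = depth,
                           alt_count = altc, stringsAsFactors = FALSE))
}

#' Simulate and write a full dilution study
#'
#' Writes the reference FASTA (+ .fai), run annotation, truth TSV, BED files
#' (target, confident, evaluation regions), one directory of six
#' caller-dialect VCFs plus a truth-locus pileup per purity, a `study.json`
#' provenance record and an md5 `manifest.tsv`. Deterministic given the
#' config.
#'
#' @param cfg A `SimulationConfig`.
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the study objects and the manifest.
#' @export
simulate_study <- function(cfg, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(cfg)
  study <- make_truth(ref, cfg)
  fa <- file.path(out_dir, "reference.fa")
  dss <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(dss, fa, width = 70L)
  Rsamtools::indexFa(fa)
  regions_as_bed(ref$runs, file.path(out_dir, "repeat_runs.bed"))
  regions_as_bed(study$target, file.path(out_dir, "target.bed"))
  regions_as_bed(study$confident, file.path(out_dir, "confident.bed"))
  regions_as_bed(study$truth$regions, file.path(out_dir, "regions.bed"))
  tr <- study$variants[c("chrom", "pos", "ref", "alt", "zygosity")]
  utils::write.table(tr, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in cfg$purities) {
    lab <- sprintf("purity_%g", 100 * p)
    pd <- file.path(out_dir, lab)
    dir.create(pd, showWarnings = FALSE)
    cs <- simulate_callsets(study, p, cfg)
    write_mutect2_vcf(cs$mutect2$bwa, file.path(pd, "mutect2_bwa.vcf"),
                      cfg$tumour_label, cfg$normal_label, ref$contigs)
    write_mutect2_vcf(cs$mutect2$novoalign,
                      file.path(pd, "mutect2_novoalign.vcf"),
                      cfg$tumour_label, cfg$normal_label, ref$contigs)
    write_strelka_snv_vcf(cs$strelka_snv$bwa,
                          file.path(pd, "strelka_snv_bwa.vcf"), ref$contigs)
    write_strelka_snv_vcf(cs$strelka_snv$novoalign,
                          file.path(pd, "strelka_snv_novoalign.vcf"),
                          ref$contigs)
    write_strelka_indel_vcf(cs$strelka_indel$bwa,
                            file.path(pd, "strelka_indel_bwa.vcf"),
                            ref$contigs)
    write_strelka_indel_vcf(cs$strelka_indel$novoalign,
                            file.path(pd, "strelka_indel_novoalign.vcf"),
                            ref$contigs)
    utils::write.table(cs$pileup, file.path(pd, "pileup.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  meta <- list(package = "itcombine",
               version = as.character(utils::packageVersion("itcombine")),
               config = unclass(cfg),
               n_ref_bp = total_bp(study$truth$regions),
               n_truth_snv = sum(study$variants$vtype %in% c("SNV", "MNV")),
               n_truth_indel = sum(study$variants$vtype %in% c("INS", "DEL")))
  jsonlite::write_json(meta, file.path(out_dir, "study.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- sort(setdiff(dir(out_dir, recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))),
                         bytes = file.size(file.path(out_dir, files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dir = out_dir, manifest = manifest, truth = study, cfg = cfg))
}
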