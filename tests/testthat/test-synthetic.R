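# The dilution-series generator: determinism, stated-world structure, and
# parameter-recovery properties.

small_cfg <- function(...) {
  sim_config(genome_length = 30000L, n_snv = 60L, n_indel = 16L,
             purities = c(1, 0.1), seed = 5L, ...)
}

test_that("reference generation is deterministic and honours repeat density", {
  cfg <- sim_config(genome_length = 100000L, repeat_density = 0.2, seed = 8L)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1$seqs, r2$seqs)
  span <- total_bp(r1$runs)
  expect_gt(span, 0.8 * 20000)
  expect_lt(span, 1.2 * 20000)
  r0 <- make_reference(sim_config(genome_length = 20000L, repeat_density = 0,
                                  seed = 8L))
  expect_equal(total_bp(r0$runs), 0)
  # a different seed gives a different genome
  r3 <- make_reference(sim_config(genome_length = 100000L,
                                  repeat_density = 0.2, seed = 9L))
  expect_false(identical(r1$seqs, r3$seqs))
})

test_that("truth generation delivers the requested counts, regions and zygosity", {
  cfg <- small_cfg()
  study <- make_truth(make_reference(cfg), cfg)
  v <- study$variants
  expect_equal(sum(v$vtype %in% c("SNV", "MNV")), cfg$n_snv)
  expect_equal(sum(v$vtype %in% c("INS", "DEL")), cfg$n_indel)
  # truth variants are normalized (minimal) and match the reference
  S <- study$reference$seqs[["chr1"]]
  expect_true(all(mapply(function(p, r) substr(S, p, p + nchar(r) - 1L) == r,
                         v$pos, v$ref)))
  expect_true(all(mapply(bf_is_minimal, v$ref, v$alt)))
  # confident covers >= 90% of target
  expect_gte(total_bp(intersect_regions(study$confident, study$target)),
             0.9 * total_bp(study$target))
  # all het when het_fraction = 1
  cfg1 <- small_cfg(het_fraction = 1)
  st1 <- make_truth(make_reference(cfg1), cfg1)
  expect_true(all(st1$variants$zygosity == "het"))
})

test_that("evaluation regions equal target∩confident minus truth footprints (per-base)", {
  cfg <- sim_config(genome_length = 10000L, n_snv = 25L, n_indel = 6L,
                    purities = c(1, 0.1), seed = 13L)
  study <- make_truth(make_reference(cfg), cfg)
  L <- cfg$genome_length
  cov_t <- bf_coverage(regions_as_bed(study$target), L)
  cov_c <- bf_coverage(regions_as_bed(study$confident), L)
  foot <- logical(L)
  v <- study$variants
  for (i in seq_len(nrow(v))) {
    foot[v$pos[i]:(v$pos[i] + nchar(v$ref[i]) - 1L)] <- TRUE
  }
  expect_equal(total_bp(study$truth$regions), sum(cov_t & cov_c & !foot))
  # no truth variant footprint intersects the evaluation regions
  expect_false(any(point_in_regions(study$truth$regions, v$chrom, v$pos)))
})

test_that("same seed reproduces a byte-identical study tree", {
  cfg <- small_cfg()
  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  m1 <- utils::read.table(file.path(d1, "manifest.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  m2 <- utils::read.table(file.path(d2, "manifest.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  expect_equal(m1$file, m2$file)
  expect_equal(m1$md5, m2$md5)
  # expected tree: 2 purities x (6 VCFs + pileup) + study-level files
  expect_equal(sum(grepl("\\.vcf$", m1$file)), 12L)
  expect_true(all(c("reference.fa", "truth.tsv", "confident.bed",
                    "target.bed", "regions.bed", "study.json") %in% m1$file))
  # refuses to overwrite without force
  expect_error(simulate_study(cfg, d1), "not empty")
})

test_that("detection follows the binomial-tail x detection-coin closed form", {
  # at purity 1, depth 100, threshold 3: P(Binom(100, 0.5) >= 3) ~ 1, so
  # per-pipeline sensitivity before filtering ~ detection_prob
  n_seeds <- 12L
  hits <- 0L; tot <- 0L
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(genome_length = 30000L, n_snv = 80L, n_indel = 0L,
                      het_fraction = 1, purities = c(1, 0.5),
                      fp_rate_per_mb = 0, seed = 100L + s)
    study <- make_truth(make_reference(cfg), cfg)
    sim <- simulate_callsets(study, 1, cfg)
    hits <- hits + sum(callset_keys(sim$mutect2$bwa) %in% study$variants$key)
    tot <- tot + nrow(study$variants)
  }
  p_hat <- hits / tot
  se <- sqrt(cfg$detection_prob * (1 - cfg$detection_prob) / tot)
  expect_lt(abs(p_hat - cfg$detection_prob), 3 * se + 1e-6)
})

test_that("shared FP fraction is recovered from cross-aligner overlap", {
  s_target <- 0.25
  shared <- 0; per_aligner <- 0
  for (s in 1:10) {
    cfg <- sim_config(genome_length = 40000L, n_snv = 10L, n_indel = 0L,
                      purities = c(1, 0.5), fp_rate_per_mb = 1200,
                      shared_fp_fraction = s_target, seed = 300L + s)
    study <- make_truth(make_reference(cfg), cfg)
    sim <- simulate_callsets(study, 1, cfg)
    tk <- study$variants$key
    fp_keys <- function(cs) setdiff(callset_keys(cs), tk)
    a <- fp_keys(sim$mutect2$bwa); b <- fp_keys(sim$mutect2$novoalign)
    shared <- shared + length(intersect(a, b))
    per_aligner <- per_aligner + length(a) + length(b)
  }
  frac <- shared / (per_aligner / 2)
  se <- sqrt(s_target * (1 - s_target) / (per_aligner / 2))
  expect_lt(abs(frac - s_target), 3 * se + 0.01)
  # and with shared_fp_fraction = 0 the intersection is collisions only
  cfg0 <- sim_config(genome_length = 40000L, n_snv = 10L, n_indel = 0L,
                     purities = c(1, 0.5), fp_rate_per_mb = 800,
                     shared_fp_fraction = 0, seed = 999L)
  st0 <- make_truth(make_reference(cfg0), cfg0)
  sim0 <- simulate_callsets(st0, 1, cfg0)
  tk <- st0$variants$key
  both <- intersect(setdiff(callset_keys(sim0$mutect2$bwa), tk),
                    setdiff(callset_keys(sim0$mutect2$novoalign), tk))
  expect_equal(length(both), 0L)
})

test_that("representation jitter is neutralized by normalization, not without it", {
  cfg <- sim_config(genome_length = 30000L, n_snv = 5L, n_indel = 25L,
                    purities = c(1, 0.5), representation_jitter_prob = 1,
                    detection_prob = 1, fp_rate_per_mb = 0, seed = 17L)
  study <- make_truth(make_reference(cfg), cfg)
  ref <- study$reference$seqs
  simj <- simulate_callsets(study, 1, cfg)
  cfg0 <- cfg; cfg0$representation_jitter_prob <- 0
  sim0 <- simulate_callsets(study, 1, cfg0)
  # with a reference, cross-caller matching of true indels is unchanged
  m2_ind <- subset_callset(simj$mutect2$bwa, "INDEL")
  skj <- normalize_callset(simj$strelka_indel$bwa, ref)
  sk0 <- sim0$strelka_indel$bwa
  expect_setequal(callset_keys(skj), callset_keys(sk0))
  expect_equal(length(intersect_callsets(m2_ind, skj)),
               length(intersect_callsets(m2_ind, sk0)))
  # without a reference, matching collapses for every actually-shifted indel
  raw_keys <- callset_keys(simj$strelka_indel$bwa)
  jittered <- setdiff(raw_keys, study$variants$key)
  expect_gt(length(jittered), 0L)
  expect_equal(length(intersect(callset_keys(m2_ind), jittered)), 0L)
  # every jittered record still encodes the same haplotype as some truth indel
  S <- ref[["chr1"]]
  jr <- simj$strelka_indel$bwa$records
  for (i in seq_len(nrow(jr))) {
    hap <- bf_apply(S, jr$pos[i], jr$ref[i], jr$alt[i])
    truth_ind <- study$variants[study$variants$vtype %in% c("INS", "DEL"), ]
    haps <- mapply(function(p, r, a) bf_apply(S, p, r, a),
                   truth_ind$pos, truth_ind$ref, truth_ind$alt)
    expect_true(hap %in% haps)
  }
})

test_that("planted alt_allele_in_normal records admit exactly per the enumerated rule", {
  cfg <- sim_config(genome_length = 40000L, n_snv = 150L, n_indel = 10L,
                    purities = c(1, 0.5), aain_fraction = 0.5,
                    fp_rate_per_mb = 100, seed = 23L)
  study <- make_truth(make_reference(cfg), cfg)
  d <- withr::local_tempdir()
  sim <- simulate_callsets(study, 1, cfg)
  path <- file.path(d, "m2.vcf")
  write_mutect2_vcf(sim$mutect2$bwa, path, contigs = study$reference$contigs)
  cs <- read_mutect2(path, aligner = "bwa")
  got <- mutect2_admit_optimized(cs, filter_policy("optimized"))
  # enumerated oracle, straight from the emitted record fields
  r <- cs$records
  want <- vapply(seq_len(nrow(r)), function(i) {
    f <- setdiff(strsplit(r$filters[i], ";")[[1]], "")
    if (length(setdiff(f, c("alt_allele_in_normal", "clustered_events",
                            "homologous_mapping_event"))) > 0) return(FALSE)
    tvaf <- if (r$tumour_depth[i] == 0) 0 else r$tumour_alt[i] / r$tumour_depth[i]
    nvaf <- if (r$normal_depth[i] == 0) 0 else r$normal_alt[i] / r$normal_depth[i]
    ratio <- if (tvaf == 0) 0 else if (nvaf == 0) Inf else tvaf / nvaf
    nvaf <= 0.07 && ratio > 5 &&
      (is.na(r$qual_score[i]) || r$qual_score[i] >= 6.3)
  }, logical(1))
  expect_equal(got, want)
  expect_gt(sum(grepl("alt_allele_in_normal", r$filters)), 0)
  expect_gt(sum(want), 0)
  expect_lt(sum(want), nrow(r))
})

test_that("end-to-end conservation: tp + fn equals the truth count", {
  cfg <- small_cfg()
  study <- make_truth(make_reference(cfg), cfg)
  sim <- simulate_callsets(study, 0.1, cfg)
  pol <- filter_policy("optimized")
  comb <- itc(list(
    mutect2 = lapply(sim$mutect2, function(cs) {
      subset_callset(apply_policy(cs, pol), "SNV")
    }),
    strelka = lapply(sim$strelka_snv, apply_policy, policy = pol)))
  res <- classify(comb, study$truth, vclass = "SNV")
  expect_equal(res$tp + res$fn,
               sum(study$variants$vtype %in% c("SNV", "MNV")))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(genome_length = 500L), "10 kb")
  expect_error(sim_config(purities = c(0.5, 0.5)), "decreasing")
  expect_error(sim_config(purities = c(1, 1.2)[2:1]), "decreasing")
  expect_error(sim_config(het_fraction = 1.4), "\\[0, 1\\]")
  cfg <- small_cfg()
  study <- make_truth(make_reference(cfg), cfg)
  expect_error(simulate_callsets(study, 0, cfg), "purity")
  expect_error(simulate_callsets(study, 1.5, cfg), "purity")
})
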