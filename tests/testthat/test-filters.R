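# Admission rules: default and optimized policies, the T/N-ratio filter,
# monotonicity, and the proximity filter.

m2set <- function(...) call_set(rbind(...), caller = "mutect2", aligner = "bwa")
skset <- function(...) call_set(rbind(...), caller = "strelka", aligner = "bwa")

test_that("tn_ratio follows the stated conventions", {
  expect_equal(tn_ratio(0.25, 0.04), 6.25)
  expect_equal(tn_ratio(0.30, 0), Inf)
  expect_equal(tn_ratio(0, 0), 0)
  expect_equal(tn_ratio(0, 0.1), 0)
  expect_true(tn_ratio(0.3, 0) > 1e12)  # passes any finite threshold
})

test_that("default mutect2 admission rescues only the clustered/homologous filters", {
  cs <- m2set(mutect2_record(100L, filters = ""),
              mutect2_record(110L, filters = "clustered_events"),
              mutect2_record(120L, filters = "homologous_mapping_event"),
              mutect2_record(130L, filters = "clustered_events;homologous_mapping_event"),
              mutect2_record(140L, filters = "alt_allele_in_normal"),
              mutect2_record(150L, filters = "t_lod_fstar;clustered_events"))
  expect_equal(mutect2_admit_default(cs),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(mutect2_admit_default(skset(strelka_record(1L, qual = 20,
                                                          t1_alt = 5,
                                                          t2_alt = 5))),
               "mutect2")
})

test_that("optimized mutect2 admission applies the 7% bound and T/N > 5 rule", {
  cs <- m2set(
    # re-admitted: normal VAF 0.05 <= 0.07, ratio 6 > 5
    mutect2_record(100L, filters = "alt_allele_in_normal",
                   t_dp = 100, t_alt = 30, n_dp = 100, n_alt = 5),
    # rejected: normal VAF 0.08 > 0.07
    mutect2_record(110L, filters = "alt_allele_in_normal",
                   t_dp = 100, t_alt = 30, n_dp = 100, n_alt = 8),
    # rejected although PASS: ratio 4 <= 5 (T/N applies to all candidates)
    mutect2_record(120L, filters = "",
                   t_dp = 100, t_alt = 20, n_dp = 100, n_alt = 5),
    # PASS with clean normal: ratio Inf, admitted
    mutect2_record(130L, filters = "", t_dp = 100, t_alt = 20, n_dp = 100,
                   n_alt = 0),
    # other internal filter failures stay rejected
    mutect2_record(140L, filters = "t_lod_fstar", n_alt = 0),
    # boundary: exactly 7% passes the bound ("up to 7%"), ratio 30/7 <= 5 fails
    mutect2_record(150L, filters = "alt_allele_in_normal",
                   t_dp = 100, t_alt = 30, n_dp = 100, n_alt = 7))
  expect_equal(mutect2_admit_optimized(cs),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("TLOD gate applies only when a TLOD is present", {
  cs <- m2set(mutect2_record(100L, tlod = 5.0, n_alt = 0),
              mutect2_record(110L, tlod = NA, n_alt = 0),
              mutect2_record(120L, tlod = 6.3, n_alt = 0))
  expect_equal(mutect2_admit_optimized(cs), c(FALSE, TRUE, TRUE))
})

test_that("strelka admission thresholds are strict and tier-aware", {
  # QSS_NT 20: above default 15, not above optimized 25
  a <- skset(strelka_record(100L, qual = 20, t1_alt = 8, t2_alt = 8))
  expect_true(strelka_admit(a, filter_policy("default")))
  expect_false(strelka_admit(a, filter_policy("optimized")))
  # tier-2-only support: rejected by default, rescued in optimized mode
  b <- skset(strelka_record(100L, qual = 30, t1_alt = 0, t2_alt = 3))
  expect_false(strelka_admit(b, filter_policy("default")))
  expect_true(strelka_admit(b, filter_policy("optimized")))
  expect_false(strelka_admit(b, filter_policy("optimized",
                                              include_tier2 = FALSE)))
  # score equal to the threshold is rejected (strict >)
  ind <- skset(strelka_record(100L, ref = "AT", alt = "A", qual = 35,
                              t1_alt = 6, t2_alt = 6))
  expect_false(strelka_admit(ind, filter_policy("optimized")))
  expect_true(strelka_admit(skset(strelka_record(100L, ref = "AT", alt = "A",
                                                 qual = 36, t1_alt = 6,
                                                 t2_alt = 6)),
                            filter_policy("optimized")))
  # internal filters must pass in both modes
  f <- skset(strelka_record(100L, qual = 60, t1_alt = 8, t2_alt = 8,
                            filters = "BCNoise"))
  expect_false(strelka_admit(f, filter_policy("default")))
  expect_false(strelka_admit(f, filter_policy("optimized")))
})

test_that("apply_policy returns the admitted subset and dispatches by caller", {
  cs <- m2set(mutect2_record(100L, filters = "", n_alt = 0),
              mutect2_record(110L, filters = "t_lod_fstar"))
  out <- apply_policy(cs, filter_policy("optimized"))
  expect_equal(callset_keys(out), callset_keys(cs)[1])
  expect_true(all(callset_keys(out) %in% callset_keys(cs)))
  empty <- m2set(mutect2_record(100L))$records[0, ]
  e <- apply_policy(call_set(empty, "mutect2", "bwa"), filter_policy("default"))
  expect_equal(length(e), 0L)
  expect_error(apply_policy(toy_callset(3), filter_policy("default")),
               "caller")
})

test_that("admission is monotone in thresholds", {
  set.seed(7)
  rec <- do.call(rbind, lapply(1:40, function(i) {
    strelka_record(100L + 10L * i, qual = sample(5:45, 1),
                   t1_alt = sample(0:6, 1), t2_alt = sample(0:8, 1))
  }))
  cs <- call_set(rec, caller = "strelka", aligner = "bwa")
  prev <- rep(TRUE, 40)
  for (thr in c(10, 20, 30, 40)) {
    cur <- strelka_admit(cs, filter_policy("optimized", qss_nt_min = thr))
    expect_true(all(prev | !cur))  # raising the cut-off never admits anew
    prev <- cur
  }
  m2rec <- do.call(rbind, lapply(1:40, function(i) {
    mutect2_record(100L + 10L * i, filters = "alt_allele_in_normal",
                   t_dp = 100, t_alt = sample(10:50, 1), n_dp = 100,
                   n_alt = sample(0:12, 1))
  }))
  m2 <- call_set(m2rec, caller = "mutect2", aligner = "bwa")
  prev <- rep(FALSE, 40)
  for (af in c(0.01, 0.05, 0.1, 0.2)) {
    cur <- mutect2_admit_optimized(m2, filter_policy("optimized",
                                                     max_normal_af = af))
    expect_true(all(cur | !prev))  # relaxing the bound never rejects anew
    prev <- cur
  }
})

test_that("default strelka policy equals optimized at 15/tier-1-only on tier-1 fixtures", {
  set.seed(21)
  rec <- do.call(rbind, lapply(1:30, function(i) {
    a <- sample(1:9, 1)
    strelka_record(100L + 10L * i, qual = sample(5:40, 1), t1_alt = a,
                   t2_alt = a)  # tier-2 adds nothing
  }))
  cs <- call_set(rec, caller = "strelka", aligner = "bwa")
  expect_equal(strelka_admit(cs, filter_policy("default")),
               strelka_admit(cs, filter_policy("optimized", qss_nt_min = 15,
                                               include_tier2 = FALSE)))
})

test_that("proximity filter removes clustered calls via pairwise distances", {
  cs <- call_set(data.frame(chrom = "chr1", pos = c(100L, 150L, 180L, 5000L),
                            ref = "A", alt = "G", stringsAsFactors = FALSE),
                 caller = "toy", aligner = "x")
  out <- proximity_filter(cs, window = 100, min_neighbours = 2L)
  expect_equal(out$records$pos, 5000L)        # the three clustered SNVs go
  # isolated pair 500 bp apart is retained
  cs2 <- call_set(data.frame(chrom = "chr1", pos = c(1000L, 1500L),
                             ref = "A", alt = "G", stringsAsFactors = FALSE),
                  caller = "toy", aligner = "x")
  expect_equal(length(proximity_filter(cs2, 100)), 2L)
  # brute-force check on a random set
  set.seed(5)
  pos <- sort(sample(1:2000, 30))
  cs3 <- call_set(data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                             stringsAsFactors = FALSE), "toy", "x")
  keep_bf <- vapply(seq_along(pos), function(i) {
    sum(abs(pos - pos[i]) <= 100) - 1L < 2L
  }, logical(1))
  expect_equal(proximity_filter(cs3, 100)$records$pos, pos[keep_bf])
})

test_that("unknown rescue filters trigger a vocabulary warning", {
  expect_warning(filter_policy("default", rescue_filters = "not_a_filter"),
                 "vocabulary")
})
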