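test_that("top_variance_probes ranks by n-1 variance with ID tie-breaks", {
  set.seed(103)
  # construct probes whose variances are exactly 1..10 around random means
  base <- scale(rnorm(20)) # mean 0, sd 1 exactly
  m <- t(vapply(1:10, function(v) rnorm(1) + sqrt(v) * as.numeric(base),
                numeric(20)))
  dimnames(m) <- list(sprintf("p%02d", 1:10), sprintf("s%02d", 1:20))
  expect_equal(top_variance_probes(m, 3), c("p10", "p09", "p08"))
  expect_warning(all_probes <- top_variance_probes(m, 99), "eligible")
  expect_equal(all_probes, sprintf("p%02d", 10:1))
  # constant probe ranks last; missing values disqualify a probe
  m2 <- rbind(m, zz_const = rep(5, 20))
  expect_equal(tail(top_variance_probes(m2, 11), 1), "zz_const")
  m2["p10", 1] <- NA
  expect_false("p10" %in% top_variance_probes(m2, 5))
  expect_error(top_variance_probes(m, 0), "positive")
  # exact ties resolve by probe ID
  m3 <- rbind(b_dup = m["p05", ], a_dup = m["p05", ], m)
  expect_equal(top_variance_probes(m3, 12)[6:8], c("a_dup", "b_dup", "p05"))
})

test_that("pairwise_correlations behaves on constructed geometries", {
  set.seed(107)
  base <- rnorm(1000)
  m <- cbind(s1 = base, s2 = base + rnorm(1000, sd = 0.01), s3 = -base,
             s4 = rnorm(1000))
  rownames(m) <- sprintf("p%04d", 1:1000)
  pc <- pairwise_correlations(m)
  expect_equal(nrow(pc), 6)
  r <- function(a, b) pc$r[pc$sample_a == a & pc$sample_b == b]
  expect_gt(r("s1", "s2"), 0.99)
  expect_equal(r("s1", "s3"), -1)
  expect_lt(abs(r("s1", "s4")), 0.1)
  # zero-variance sample: flagged, correlations recorded as missing
  m5 <- cbind(m, s5 = rep(1, 1000))
  expect_warning(pc5 <- pairwise_correlations(m5), "s5")
  expect_true(all(is.na(pc5$r[pc5$sample_a == "s5" | pc5$sample_b == "s5"])))
})

test_that("independent samples rarely exceed |r| = 0.1 at 1000 probes", {
  set.seed(109)
  m <- matrix(rnorm(1000 * 30), nrow = 1000,
              dimnames = list(sprintf("p%04d", 1:1000), sprintf("s%02d", 1:30)))
  pc <- pairwise_correlations(m)
  expect_gte(mean(abs(pc$r) < 0.1), 0.99)
})

test_that("gap_split isolates the dominant admissible gap", {
  gs <- gap_split(c(0.99, 0.50, 0.45, 0.40), r_min = 0.95)
  expect_equal(gs$gap_index, 1L)
  expect_true(gs$gap_threshold > 0.5 && gs$gap_threshold < 0.99)
  # everything below r_min: no duplicates
  expect_true(is.na(gap_split(c(0.9, 0.5, 0.4), r_min = 0.95)$gap_threshold))
  # upper block too large: inadmissible
  expect_true(is.na(gap_split(c(rep(0.99, 50), 0.5), r_min = 0.95,
                              max_frac = 0.1)$gap_threshold))
  # duplicate-range correlations split from tight re-run-control range
  r <- c(0.993, 0.990, seq(0.985, 0.910, length.out = 100))
  gs2 <- gap_split(r, r_min = 0.95, max_frac = 0.1)
  expect_equal(gs2$gap_index, 2L)
  expect_true(gs2$gap_threshold < 0.990 && gs2$gap_threshold > 0.985)
})

test_that("injected duplicates are recovered exactly, clean cohorts stay empty", {
  for (seed in 1:20) {
    cfg <- synthetic_config(n_samples = 50, n_background_probes = 300,
                            n_duplicates = 2, duplicate_noise_sd = 0.01,
                            seed = seed)
    sim <- simulate_cohort(cfg)
    rep <- suppressWarnings(find_duplicates(sim$matrix, k = 300))
    truth_pairs <- with(sim$truth$duplicate_pairs,
                        paste(pmin(original, copy), pmax(original, copy)))
    found_pairs <- with(rep$pairs, paste(sample_a, sample_b))
    expect_setequal(found_pairs, truth_pairs)
    expect_true(all(rep$pairs$r > 0.99))

    clean <- simulate_cohort(synthetic_config(
      n_samples = 50, n_background_probes = 300, seed = seed + 1000))
    rep0 <- suppressWarnings(find_duplicates(clean$matrix, k = 300))
    expect_equal(nrow(rep0$pairs), 0)
  }
})

test_that("duplicate report is invariant to sample order", {
  cfg <- synthetic_config(n_samples = 40, n_background_probes = 300,
                          n_duplicates = 2, seed = 113)
  sim <- simulate_cohort(cfg)
  set.seed(5)
  perm <- sample(ncol(sim$matrix))
  r1 <- suppressWarnings(find_duplicates(sim$matrix, k = 300))
  r2 <- suppressWarnings(find_duplicates(sim$matrix[, perm], k = 300))
  expect_equal(r1$pairs, r2$pairs)
  expect_true(all(r1$pairs$sample_a <= r1$pairs$sample_b))
})

test_that("triplicates come back as three pairs plus one connected group", {
  cfg <- synthetic_config(n_samples = 40, n_background_probes = 300, seed = 127)
  sim <- simulate_cohort(cfg)
  m <- sim$matrix
  set.seed(128)
  extra <- m[, "SIM_S0001"] + rnorm(nrow(m), sd = 0.01)
  extra2 <- m[, "SIM_S0001"] + rnorm(nrow(m), sd = 0.01)
  m <- cbind(m, SIM_T001 = extra, SIM_T002 = extra2)
  rep <- suppressWarnings(find_duplicates(m, k = 300))
  expect_equal(nrow(rep$pairs), 3)
  expect_length(rep$groups, 1)
  expect_setequal(rep$groups[[1]], c("SIM_S0001", "SIM_T001", "SIM_T002"))
})

test_that("cross_check_duplicates reports the explained fraction", {
  verdicts <- data.frame(
    sample_id = sprintf("s%02d", 1:60),
    category = c(rep("misclassified", 54), rep("correct", 6)))
  pairs <- data.frame(sample_a = sprintf("s%02d", 1:9),
                      sample_b = sprintf("s%02d", 31:39))
  # s01..s09 are misclassified members; s31..s39 are also misclassified
  res <- cross_check_duplicates(pairs[1:9, ][0, ], verdicts)
  expect_equal(res$pct_explained, 0)
  res9 <- cross_check_duplicates(
    data.frame(sample_a = sprintf("s%02d", 1:9), sample_b = rep("s60", 9)),
    verdicts)
  expect_equal(res9$n_misclassified, 54)
  expect_equal(res9$n_explained, 9)
  expect_equal(res9$pct_explained, 16.7)
  all_in <- cross_check_duplicates(
    data.frame(sample_a = sprintf("s%02d", 1:54), sample_b = rep("s60", 54)),
    verdicts)
  expect_equal(all_in$pct_explained, 100)
})
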