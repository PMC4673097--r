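test_that("evidence scores use strict inequality and ignore missing values", {
  cuts <- list(
    m1 = cut_point(0, 0.1, probe_id = "m1"),
    m2 = cut_point(0, 0.1, probe_id = "m2"),
    m3 = cut_point(0, 0, probe_id = "m3") # non-informative
  )
  vals <- c(m1 = 0.9, m2 = cuts$m2$cut, m3 = 99)
  sc <- evidence_scores(vals, cuts)
  expect_equal(unname(sc), c(1L, 0L, 0L)) # above, tie, non-informative
  expect_equal(unname(evidence_scores(c(m1 = NA, m2 = NA, m3 = NA), cuts)),
               c(0L, 0L, 0L))
})

test_that("combination rule: 3 male, 3 female, 10 unconfident", {
  combos <- expand.grid(f1 = 0:1, f2 = 0:1, m1 = 0:1, m2 = 0:1)
  pred <- apply(combos, 1, function(r) {
    combine_evidence(c(r[["f1"]], r[["f2"]]), c(r[["m1"]], r[["m2"]]))
  })
  expect_equal(sum(pred == "male"), 3)
  expect_equal(sum(pred == "female"), 3)
  expect_equal(sum(pred == "unconfident"), 10)
  expect_equal(combine_evidence(c(1, 0), c(0, 0)), "female")
  expect_equal(combine_evidence(c(1, 0), c(0, 1)), "unconfident")
  expect_equal(combine_evidence(c(0, 0), c(0, 0)), "unconfident")
  expect_equal(combine_evidence(c(0, 0), c(1, 1)), "male")
})

test_that("verdict categories follow the annotation comparison rules", {
  expect_equal(
    verdict_category(
      c("female", "female", "unconfident", "male", "unconfident"),
      c("male", "female", "male", "unknown", "unknown")),
    c("misclassified", "correct", "unconfident", "unannotated", "unconfident"))
})

test_that("classify_cohort flags exactly an injected cross-sex mislabel", {
  cfg <- synthetic_config(n_samples = 200, mislabel_rate = 1 / 200, seed = 53)
  sim <- simulate_cohort(cfg)
  report <- classify_cohort(sim$matrix, sim$annotation)
  flagged <- report$verdicts$sample_id[report$verdicts$category == "misclassified"]
  expect_equal(flagged, sim$truth$mislabeled)
  expect_equal(report$counts[["misclassified"]], 1L)
})

test_that("a clean, well-separated cohort classifies 100% correct", {
  fix <- make_mixed_cohort(n = 100, seed = 59)
  report <- classify_cohort(fix$matrix, fix$annotation)
  expect_equal(report$counts[["correct"]], 100L)
  expect_equal(report$percentages[["correct"]], 100)
})

test_that("a male profile in an all-female cohort is caught via Y evidence", {
  cfg <- synthetic_config(n_samples = 80, female_fraction = 1, seed = 61)
  sim <- simulate_cohort(cfg)
  panel <- default_marker_panel()
  intruder <- colnames(sim$matrix)[5]
  # overwrite the intruder's marker profile with male geometry; the label
  # stays female (the annotation refers to someone else's tissue)
  set.seed(62)
  high <- panel$evidence_sex == "male"
  sim$matrix[panel$probe_id, intruder] <-
    rnorm(4, ifelse(high, cfg$markers$mu_high, cfg$markers$mu_low), 0.4)
  report <- classify_cohort(sim$matrix, sim$annotation)
  v <- report$verdicts[report$verdicts$sample_id == intruder, ]
  expect_equal(v$predicted_sex, "male")
  expect_equal(v$category, "misclassified")
  expect_equal(report$counts[["misclassified"]], 1L)
  expect_equal(report$mislabel_directions[["female_to_male"]], 1L)
})

test_that("unknown annotations are scored and reported as unannotated", {
  fix <- make_mixed_cohort(n = 40, seed = 67)
  fix$annotation$sex[1:3] <- "unknown"
  report <- classify_cohort(fix$matrix, fix$annotation)
  expect_equal(report$counts[["unannotated"]], 3L)
  expect_true(all(report$verdicts$predicted_sex[1:3] %in% c("female", "male")))
})

test_that("missing panel probes are dropped with a warning; none is an error", {
  fix <- make_mixed_cohort(n = 40, seed = 71)
  m <- fix$matrix[rownames(fix$matrix) != "221728_x_at", ]
  expect_warning(report <- classify_cohort(m, fix$annotation), "221728_x_at")
  expect_equal(report$counts[["correct"]], 40L) # three probes still suffice
  bg_only <- fix$matrix[grep("^bg", rownames(fix$matrix)), ]
  expect_error(classify_cohort(bg_only, fix$annotation), "221728_x_at")
})

test_that("classification is deterministic", {
  fix <- make_mixed_cohort(n = 50, seed = 73)
  r1 <- classify_cohort(fix$matrix, fix$annotation)
  r2 <- classify_cohort(fix$matrix, fix$annotation)
  expect_identical(r1, r2)
})

test_that("fixed-cut deployment mode accepts an external cut table", {
  fix <- make_mixed_cohort(n = 60, seed = 79)
  report <- classify_cohort(fix$matrix, fix$annotation, cut_mode = "panel")
  expect_equal(report$counts[["correct"]], 60L)
})

test_that("counts always sum to the cohort size", {
  for (seed in 1:5) {
    cfg <- synthetic_config(n_samples = 60, mislabel_rate = 0.05,
                            n_duplicates = 2, seed = seed)
    sim <- simulate_cohort(cfg)
    report <- classify_cohort(sim$matrix, sim$annotation)
    expect_equal(sum(report$counts), report$n_samples)
    expect_equal(report$n_samples, 62L)
  }
})
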