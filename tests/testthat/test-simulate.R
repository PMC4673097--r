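test_that("simulation is fully reproducible from its seed", {
  cfg <- synthetic_config(n_samples = 50, mislabel_rate = 0.04,
                          n_duplicates = 2, seed = 131)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth, s2$truth)
})

test_that("mislabel and duplicate bookkeeping matches the configuration", {
  cfg <- synthetic_config(n_samples = 400, mislabel_rate = 0.01, seed = 137)
  sim <- simulate_cohort(cfg)
  expect_length(sim$truth$mislabeled, 4) # exactly round(0.01 * 400)
  flipped <- sim$truth$mislabeled
  expect_true(all(sim$annotation$sex[match(flipped, sim$annotation$sample_id)] !=
                    sim$truth$true_sex[flipped]))
  untouched <- setdiff(sim$annotation$sample_id, flipped)
  expect_true(all(sim$annotation$sex[match(untouched, sim$annotation$sample_id)] ==
                    sim$truth$true_sex[untouched]))

  cfg_d <- synthetic_config(n_samples = 60, n_duplicates = 3,
                            duplicate_noise_sd = 0.01, seed = 139)
  sim_d <- simulate_cohort(cfg_d)
  expect_equal(ncol(sim_d$matrix), 63)
  for (i in 1:3) {
    pair <- sim_d$truth$duplicate_pairs[i, ]
    r <- cor(sim_d$matrix[, pair$original], sim_d$matrix[, pair$copy])
    expect_gt(r, 0.99)
    # the copy keeps the original's expression-level sex
    expect_equal(sim_d$truth$true_sex[[pair$copy]],
                 sim_d$truth$true_sex[[pair$original]])
  }
  expect_error(simulate_cohort(synthetic_config(n_samples = 5, n_duplicates = 5)),
               "n_duplicates")
})

test_that("marker geometry follows sex and the cohort affine shift", {
  cfg <- synthetic_config(n_samples = 300, cohort_shift = 2.5,
                          cohort_scale = 1.5, seed = 149)
  sim <- simulate_cohort(cfg)
  females <- names(sim$truth$true_sex)[sim$truth$true_sex == "female"]
  xist <- sim$matrix["221728_x_at", ]
  expect_gt(min(xist[females]), max(xist[setdiff(colnames(sim$matrix), females)]))
  # background probes carry the affine transform: N(0,1) -> N(2.5, 1.5^2)
  bg <- sim$matrix[grep("^bg", rownames(sim$matrix)), ]
  expect_equal(mean(bg), 2.5, tolerance = 0.05)
  expect_equal(sd(bg), 1.5, tolerance = 0.05)
})

test_that("same-sex identity swaps are invisible to the sex classifier", {
  cfg <- synthetic_config(n_samples = 100, seed = 151)
  sim <- simulate_cohort(cfg)
  females <- names(sim$truth$true_sex)[sim$truth$true_sex == "female"]
  # swap the expression columns of two female patients: a genuine mix-up
  # that no sex marker can see
  tmp <- sim$matrix[, females[1]]
  sim$matrix[, females[1]] <- sim$matrix[, females[2]]
  sim$matrix[, females[2]] <- tmp
  report <- classify_cohort(sim$matrix, sim$annotation)
  expect_equal(report$counts[["correct"]], 100L)
})

test_that("survival generation respects censoring and effect structure", {
  cfg <- synthetic_config(
    n_samples = 100, seed = 157,
    survival = list(censor_rate = 1, simulate = TRUE))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$survival$event == 0))

  cfg2 <- synthetic_config(
    n_samples = 100, n_background_probes = 20, seed = 163,
    survival = list(censor_rate = 0.2, prognostic_probe_ids = "bg_0001_at",
                    effect_sizes = 1.5))
  sim2 <- simulate_cohort(cfg2)
  expect_equal(nrow(sim2$truth$survival), 100)
  # strong positive effect: high expression hazards earlier events
  x <- sim2$matrix["bg_0001_at", ]
  ev <- sim2$truth$survival$event == 1
  expect_lt(cor(x[ev], sim2$truth$survival$time[ev], method = "spearman"), 0)
})

test_that("the benchmark collection mirrors the reference cohort mix", {
  configs <- benchmark_cohort_configs(seed = 5)
  expect_length(configs, 45)
  tab <- cohort_table()
  expect_equal(vapply(configs, `[[`, integer(1), "n_samples"),
               setNames(tab$n_female + tab$n_male, tab$cohort_id))
  fr <- vapply(configs, `[[`, numeric(1), "female_fraction")
  expect_equal(sum(fr == 1), 12) # breast + ovarian cohorts
  expect_equal(sum(fr == 0), 4)  # prostate cohorts
})
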