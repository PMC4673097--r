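test_that("fit_affine maps the group medians onto 0 and 1", {
  s <- two_group_split(c(5, 5, 5, 7, 7, 7))
  map <- fit_affine(s)
  expect_equal(map$a * 5 + map$b, 0)
  expect_equal(map$a * 7 + map$b, 1)
  expect_equal(map$a * 6 + map$b, 0.5) # midpoint
  s01 <- two_group_split(c(0, 0, 0, 1, 1, 1))
  map01 <- fit_affine(s01)
  expect_equal(c(map01$a, map01$b), c(1, 0)) # identity

  expect_error(fit_affine(two_group_split(c(2, 2, 2, 2))), "degenerate")
})

test_that("two-group normalization puts group medians exactly at 0 and 1", {
  marker <- default_marker_panel()[1, ]
  set.seed(31)
  for (rep in 1:10) {
    v <- c(rnorm(25, 6, 0.4), rnorm(35, 10, 0.4))
    np <- normalize_probe(v, marker)
    expect_equal(np$provenance, "two_group")
    expect_equal(median(np$values[np$split$low]), 0, tolerance = 1e-12)
    expect_equal(median(np$values[np$split$high]), 1, tolerance = 1e-12)
    expect_identical(order(v), order(np$values)) # monotone
  }
})

test_that("cohort-level shifts are removed by normalization", {
  marker <- default_marker_panel()[3, ] # RPS4Y1, male evidence
  set.seed(37)
  base <- function() c(rnorm(30, 6, 0.4), rnorm(30, 10, 0.4))
  v1 <- base() + 2
  v2 <- base() - 3
  n1 <- normalize_probe(v1, marker)
  n2 <- normalize_probe(v2, marker)
  pooled_low <- c(n1$values[n1$split$low], n2$values[n2$split$low])
  pooled_high <- c(n1$values[n1$split$high], n2$values[n2$split$high])
  expect_lt(abs(median(pooled_low)), 0.1)
  expect_lt(abs(median(pooled_high) - 1), 0.1)
})

test_that("single-sex cohorts anchor the lone group by evidence direction", {
  set.seed(41)
  labels <- rep("female", 50)
  y_marker <- default_marker_panel()[3, ] # male evidence: low in females
  x_marker <- default_marker_panel()[1, ] # female evidence: high in females
  v_low <- rnorm(50, 6, 0.4)
  v_high <- rnorm(50, 10, 0.4)
  np_y <- normalize_probe(v_low, y_marker, sex_labels = labels)
  expect_equal(np_y$provenance, "single_group_low")
  expect_equal(median(np_y$values), 0, tolerance = 1e-12)
  np_x <- normalize_probe(v_high, x_marker, sex_labels = labels)
  expect_equal(np_x$provenance, "single_group_high")
  expect_equal(median(np_x$values), 1, tolerance = 1e-12)
  # a reference scale steepens/flattens the slope but keeps the anchor
  np_ref <- normalize_probe(v_low, y_marker, sex_labels = labels,
                            reference_scale = 4)
  expect_equal(median(np_ref$values), 0, tolerance = 1e-12)
  expect_equal(sd(np_ref$values), sd(v_low) / 4, tolerance = 1e-12)
})

test_that("orientation tolerates a few mislabels but not a mixed cohort", {
  set.seed(43)
  y_marker <- default_marker_panel()[4, ]
  v <- rnorm(50, 6, 0.4)
  labels <- c(rep("female", 47), "male", "male", "unknown") # 94% female
  expect_equal(normalize_probe(v, y_marker, sex_labels = labels)$provenance,
               "single_group_low")
  labels_mixed <- rep(c("female", "male"), 25)
  expect_equal(normalize_probe(v, y_marker, sex_labels = labels_mixed)$provenance,
               "failed")
})

test_that("unlabelled unimodal cohorts need a pooled reference", {
  set.seed(47)
  marker <- default_marker_panel()[1, ]
  v <- rnorm(40, 6, 0.4)
  np <- normalize_probe(v, marker) # no labels, no pooled reference
  expect_equal(np$provenance, "failed")
  expect_true(all(is.na(np$values)))
  np2 <- normalize_probe(v, marker,
                         pooled_medians = list(low = 6, high = 10),
                         reference_scale = 4)
  expect_equal(np2$provenance, "single_group_low")
  np3 <- normalize_probe(v + 4, marker,
                         pooled_medians = list(low = 6, high = 10),
                         reference_scale = 4)
  expect_equal(np3$provenance, "single_group_high")
})

test_that("missing values ride through normalization as missing", {
  marker <- default_marker_panel()[1, ]
  v <- c(rnorm(20, 6, 0.3), rnorm(20, 10, 0.3), NA)
  np <- normalize_probe(v, marker)
  expect_true(is.na(np$values[41]))
  expect_equal(sum(is.na(np$values)), 1)
})
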