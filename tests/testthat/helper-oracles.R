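# independent brute-force oracle for the Qn estimator: enumerate every
# pairwise absolute difference, full sort, take the k-th
qn_brute <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  h <- n %/% 2 + 1
  k <- h * (h - 1) / 2
  diffs <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- c(diffs, abs(x[i] - x[j]))
  }
  2.2219 * sort(diffs)[k]
}

# a small mixed-sex cohort matrix with clean marker geometry and a few
# background probes; labels match expression unless flipped downstream
make_mixed_cohort <- function(n = 60, n_female = n / 2, seed = 1,
                              mu_low = 6, mu_high = 10, sd = 0.4,
                              n_background = 20, shift = 0, scale = 1,
                              cohort_id = "FIX") {
  set.seed(seed)
  sex <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
  ids <- sprintf("%s_%03d", cohort_id, seq_len(n))
  panel <- default_marker_panel()
  mat <- t(vapply(seq_len(nrow(panel)), function(i) {
    high <- sex == panel$evidence_sex[i]
    rnorm(n, ifelse(high, mu_high, mu_low), sd)
  }, numeric(n)))
  rownames(mat) <- panel$probe_id
  bg <- matrix(rnorm(n_background * n), nrow = n_background,
               dimnames = list(sprintf("bg%03d", seq_len(n_background)), NULL))
  mat <- rbind(mat, bg)
  colnames(mat) <- ids
  list(matrix = scale * mat + shift,
       annotation = data.frame(sample_id = ids, sex = sex,
                               stringsAsFactors = FALSE),
       sex = setNames(sex, ids))
}
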