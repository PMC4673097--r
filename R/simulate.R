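#' Configuration for a synthetic cohort
#'
#' The generator emulates the statistical structure the classifier
#' assumes: sex-marker probes with bimodal expression (low/high component
#' per sex), a sea of uninformative background probes, a cohort-level
#' affine intensity shift (the cross-study batch effect that motivates
#' normalization), injected cross-sex annotation flips, injected
#' near-exact duplicate measurements filed under another patient's label,
#' and exponential survival times optionally driven by a few prognostic
#' probes.
#'
#' Marker geometry defaults to `mu_low = 6`, `mu_high = 10`,
#' `sd = 0.4` — a plausible log2 intensity range for strongly sex-specific
#' transcripts on expression arrays, giving a low/high separation of
#' 10 Qn units, comfortably above the bimodality threshold.
#'
#' @param n_samples cohort size.
#' @param female_fraction probability a sample is female (1 or 0 give
#'   single-sex cohorts).
#' @param n_background_probes number of uninformative N(0,1) probes.
#' @param panel marker panel whose probes get bimodal sex-specific values.
#' @param mu_low,mu_high,sd_low,sd_high marker component parameters,
#'   recycled over panel probes.
#' @param cohort_shift,cohort_scale affine transform applied to the whole
#'   matrix (`scale * x + shift`), emulating study-level processing shifts.
#' @param mislabel_rate fraction of samples whose sex label is flipped;
#'   exactly `round(rate * n_samples)` flips are made and recorded.
#' @param n_duplicates number of duplicate measurements appended.
#' @param duplicate_noise_sd technical noise added to a duplicate copy.
#' @param survival list with `baseline_scale` (mean event time when the
#'   linear predictor is 0), `censor_rate`, `prognostic_probe_ids`,
#'   `effect_sizes` (log hazard ratios per SD of expression), and
#'   `decouple_flagged` (default `TRUE`: mislabeled and duplicate samples
#'   get survival generated from another patient's expression, modelling
#'   a genuine annotation-row swap).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @param cohort_id identifier used in sample IDs.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 200L, female_fraction = 0.5,
                             n_background_probes = 100L,
                             panel = default_marker_panel(),
                             mu_low = 6, mu_high = 10,
                             sd_low = 0.4, sd_high = 0.4,
                             cohort_shift = 0, cohort_scale = 1,
                             mislabel_rate = 0, n_duplicates = 0L,
                             duplicate_noise_sd = 0.01,
                             survival = list(), seed = 1L,
                             cohort_id = "SIM") {
  stopifnot(cohort_scale > 0, n_samples >= 2,
            female_fraction >= 0, female_fraction <= 1,
            mislabel_rate >= 0, mislabel_rate <= 1,
            n_duplicates >= 0, duplicate_noise_sd >= 0)
  nm <- nrow(panel)
  markers <- data.frame(
    probe_id = panel$probe_id, evidence_sex = panel$evidence_sex,
    mu_low = rep_len(mu_low, nm), mu_high = rep_len(mu_high, nm),
    sd_low = rep_len(sd_low, nm), sd_high = rep_len(sd_high, nm),
    stringsAsFactors = FALSE
  )
  if (any(markers$mu_high <= markers$mu_low)) {
    abort("synthetic_config(): mu_high must exceed mu_low for every marker")
  }
  surv_defaults <- list(baseline_scale = 5, censor_rate = 0.3,
                        prognostic_probe_ids = character(0),
                        effect_sizes = numeric(0), decouple_flagged = TRUE)
  surv_defaults[names(survival)] <- survival
  structure(list(
    n_samples = as.integer(n_samples), female_fraction = female_fraction,
    n_background_probes = as.integer(n_background_probes), panel = panel,
    markers = markers, cohort_shift = cohort_shift,
    cohort_scale = cohort_scale, mislabel_rate = mislabel_rate,
    n_duplicates = as.integer(n_duplicates),
    duplicate_noise_sd = duplicate_noise_sd,
    survival = surv_defaults, seed = as.integer(seed),
    cohort_id = cohort_id
  ), class = "synthetic_config")
}

#' Simulate one expression cohort with known ground truth
#'
#' True sex is drawn by `female_fraction`. Female-evidence (X) markers are
#' Normal(`mu_high`, `sd_high`) in females and Normal(`mu_low`, `sd_low`)
#' in males; male-evidence (Y) markers the reverse. Background probes are
#' i.i.d. N(0,1). The whole matrix then gets the cohort-level affine
#' shift. The annotation equals the true sex with exactly
#' `round(mislabel_rate * n)` labels flipped (IDs recorded). Each
#' duplicate is a copy of one existing sample's measured profile plus
#' technical noise, appended under a new sample ID carrying the sex label
#' of a randomly chosen *other* sample — the same mRNA measured twice and
#' filed under the wrong patient.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort` with `matrix`
#'   (probes x samples), `annotation` (data.frame `sample_id`, `sex`, and
#'   `time`/`event` when prognostic structure or survival was requested)
#'   and `truth` (list: `true_sex` named vector, `mislabeled` IDs,
#'   `duplicate_pairs` data.frame `original`/`copy`, `survival`
#'   data.frame or `NULL`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_duplicates >= config$n_samples) {
    abort("n_duplicates must be smaller than n_samples")
  }
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("%s_S%04d", config$cohort_id, seq_len(n))
  true_sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  names(true_sex) <- ids

  mk <- config$markers
  marker_vals <- t(vapply(seq_len(nrow(mk)), function(i) {
    high <- true_sex == mk$evidence_sex[i]
    stats::rnorm(n,
                 mean = ifelse(high, mk$mu_high[i], mk$mu_low[i]),
                 sd = ifelse(high, mk$sd_high[i], mk$sd_low[i]))
  }, numeric(n)))
  rownames(marker_vals) <- mk$probe_id

  nb <- config$n_background_probes
  bg <- matrix(stats::rnorm(nb * n), nrow = nb, ncol = n,
               dimnames = list(sprintf("bg_%04d_at", seq_len(nb)), NULL))
  mat <- rbind(marker_vals, bg)
  colnames(mat) <- ids
  mat <- config$cohort_scale * mat + config$cohort_shift

  labels <- true_sex
  n_flip <- round(config$mislabel_rate * n)
  mislabeled <- character(0)
  if (n_flip > 0) {
    mislabeled <- sample(ids, n_flip)
    labels[mislabeled] <- ifelse(labels[mislabeled] == "female",
                                 "male", "female")
  }

  dup_pairs <- data.frame(original = character(0), copy = character(0),
                          stringsAsFactors = FALSE)
  if (config$n_duplicates > 0) {
    originals <- sample(ids, config$n_duplicates)
    copies <- sprintf("%s_D%03d", config$cohort_id,
                      seq_len(config$n_duplicates))
    dup_cols <- mat[, originals, drop = FALSE] +
      matrix(stats::rnorm(nrow(mat) * config$n_duplicates,
                          sd = config$duplicate_noise_sd), nrow = nrow(mat))
    colnames(dup_cols) <- copies
    mat <- cbind(mat, dup_cols)
    # label comes from some other patient's record, not the original's
    label_donor <- vapply(originals, function(o) sample(setdiff(ids, o), 1),
                          character(1))
    labels <- c(labels, stats::setNames(labels[label_donor], copies))
    true_sex <- c(true_sex, stats::setNames(true_sex[originals], copies))
    dup_pairs <- data.frame(original = originals, copy = copies,
                            stringsAsFactors = FALSE)
  }

  annotation <- data.frame(sample_id = colnames(mat), sex = unname(labels),
                           stringsAsFactors = FALSE)
  truth <- list(true_sex = true_sex, mislabeled = mislabeled,
                duplicate_pairs = dup_pairs, survival = NULL)

  sv <- config$survival
  if (length(sv$prognostic_probe_ids) > 0 || isTRUE(sv$simulate)) {
    flagged <- if (isTRUE(sv$decouple_flagged)) {
      c(mislabeled, dup_pairs$copy)
    } else character(0)
    surv <- simulate_survival(mat, config, decouple_ids = flagged)
    truth$survival <- surv
    annotation$time <- surv$time[match(annotation$sample_id, surv$sample_id)]
    annotation$event <- surv$event[match(annotation$sample_id, surv$sample_id)]
  }

  structure(list(matrix = mat, annotation = annotation, truth = truth,
                 config = config), class = "synthetic_cohort")
}

#' Simulate right-censored survival times from expression
#'
#' Exponential event times with log hazard linear in the designated
#' prognostic probes (each standardized to unit SD, so effect sizes read
#' as log hazard ratios per SD of expression). Samples listed in
#' `decouple_ids` get the linear predictor of a randomly chosen other
#' sample — their clinical record belongs to a different patient, which
#' is exactly what an annotation swap does to a survival analysis.
#' Censoring: each sample is censored with probability `censor_rate`, at
#' a uniform fraction of its event time.
#'
#' @param matrix probes-by-samples expression matrix.
#' @param config a [synthetic_config()] (its `survival` entry is used).
#' @param decouple_ids sample IDs whose survival is decoupled from their
#'   own expression.
#' @return data.frame with `sample_id`, `time`, `event` (1 = event,
#'   0 = censored).
#' @export
simulate_survival <- function(matrix, config, decouple_ids = character(0)) {
  sv <- config$survival
  ids <- colnames(matrix)
  n <- length(ids)
  lp <- rep(0, n)
  prog <- intersect(sv$prognostic_probe_ids, rownames(matrix))
  if (length(prog) > 0) {
    betas <- rep_len(sv$effect_sizes, length(prog))
    stopifnot(all(is.finite(betas)))
    z <- scale(t(matrix[prog, , drop = FALSE]))
    lp <- drop(z %*% betas)
  }
  dec <- match(intersect(decouple_ids, ids), ids)
  if (length(dec) > 0) {
    donors <- vapply(dec, function(i) sample(setdiff(seq_len(n), i), 1),
                     integer(1))
    lp[dec] <- lp[donors]
  }
  time <- stats::rexp(n, rate = exp(lp) / sv$baseline_scale)
  censored <- stats::runif(n) < sv$censor_rate
  time[censored] <- time[censored] * stats::runif(sum(censored))
  data.frame(sample_id = ids, time = time,
             event = as.integer(!censored), stringsAsFactors = FALSE)
}

#' Synthetic 45-cohort benchmark configurations
#'
#' One [synthetic_config()] per cohort of the reference collection
#' ([cohort_table()]), reproducing its mix of cohort sizes and sex ratios
#' (mixed-sex lung/colon/other cohorts, all-female breast and ovarian,
#' all-male prostate). Cohort-level intensity shifts are drawn uniformly
#' from \[-3, 3\] and scales from \[0.8, 1.25\] — shifts of the order seen
#' between public studies — so cross-cohort normalization is actually
#' exercised.
#'
#' @param seed master seed; per-cohort seeds are derived from it.
#' @param mislabel_rate cross-sex label flip rate per cohort (default
#'   0.01, the order of magnitude observed in public collections).
#' @param n_background_probes background probes per cohort.
#' @param ... further arguments forwarded to every [synthetic_config()].
#' @return named list of `synthetic_config` objects, one per cohort.
#' @export
benchmark_cohort_configs <- function(seed = 1L, mislabel_rate = 0.01,
                                     n_background_probes = 50L, ...) {
  tab <- cohort_table()
  set.seed(seed)
  shifts <- stats::runif(nrow(tab), -3, 3)
  scales <- stats::runif(nrow(tab), 0.8, 1.25)
  seeds <- sample.int(1e6, nrow(tab))
  configs <- lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$n_female[i] + tab$n_male[i]
    synthetic_config(
      n_samples = n,
      female_fraction = tab$n_female[i] / n,
      n_background_probes = n_background_probes,
      cohort_shift = shifts[i], cohort_scale = scales[i],
      mislabel_rate = mislabel_rate,
      seed = seeds[i], cohort_id = tab$cohort_id[i], ...
    )
  })
  stats::setNames(configs, tab$cohort_id)
}

#' Simulate a collection of cohorts
#'
#' @param configs list of [synthetic_config()] objects (e.g. from
#'   [benchmark_cohort_configs()]).
#' @return list with `cohorts` (named list of `list(matrix, annotation)`
#'   ready for [classify_cohorts()]) and `truths` (named list of ground
#'   truths).
#' @export
simulate_cohort_collection <- function(configs) {
  sims <- lapply(configs, simulate_cohort)
  list(
    cohorts = lapply(sims, function(s) list(matrix = s$matrix,
                                            annotation = s$annotation)),
    truths = lapply(sims, `[[`, "truth")
  )
}
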