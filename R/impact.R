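#' Univariate Cox proportional-hazards screen over all probes
#'
#' One Cox model per probe with that probe's expression as the single
#' covariate; the reported p-value is the Wald test of its coefficient.
#' Ties in event times use the Efron approximation. Probes with zero
#' variance (no information) are skipped with a recorded reason, as are
#' fits that fail or do not converge cleanly; such probes should be
#' excluded symmetrically from any before/after comparison.
#'
#' @param matrix probes-by-samples expression matrix.
#' @param survival data.frame with `sample_id`, `time`, `event` covering
#'   (at least) the matrix samples.
#' @return data.frame with `probe_id`, `p` (`NA` when skipped), `reason`
#'   (`"ok"`, `"zero_variance"`, `"fit_failed"`).
#' @export
univariate_survival_screen <- function(matrix, survival) {
  validate_expression_matrix(matrix)
  m <- match(colnames(matrix), survival$sample_id)
  if (anyNA(m)) {
    abort("survival records missing for sample(s): %s",
          paste(utils::head(colnames(matrix)[is.na(m)], 5), collapse = ", "))
  }
  time <- survival$time[m]
  event <- survival$event[m]
  if (any(!is.finite(time)) || any(time <= 0)) {
    abort("survival times must be positive and finite")
  }
  if (sum(event) < 2) abort("need at least 2 events for the survival screen")
  y <- survival::Surv(time, event)

  res <- lapply(rownames(matrix), function(p) {
    x <- matrix[p, ]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      return(list(p = NA_real_, reason = "zero_variance"))
    }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        # ride through convergence warnings; the fit object is still usable
        suppressWarnings(survival::coxph(y ~ x, ties = "efron"))
      })
    if (is.null(fit) || is.na(fit$coefficients[1])) {
      return(list(p = NA_real_, reason = "fit_failed"))
    }
    z <- fit$coefficients[1] / sqrt(fit$var[1, 1])
    list(p = 2 * stats::pnorm(-abs(z)), reason = "ok")
  })
  data.frame(
    probe_id = rownames(matrix),
    p = vapply(res, `[[`, numeric(1), "p"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
}

#' Significance churn between two p-value maps
#'
#' Given per-probe p-values before (`p_original`) and after (`p_reduced`)
#' removal of flagged samples, reports how many of the originally
#' significant probes lost significance and how many new ones appeared,
#' both as percentages of the original significant set. The threshold is
#' applied unadjusted — no multiplicity correction — matching how such
#' per-gene screens are typically summarized. Probes with a missing
#' p-value on either side are excluded from both sets symmetrically.
#'
#' @param p_original,p_reduced named numeric vectors of p-values over the
#'   same probe set.
#' @param alpha significance threshold (default 0.01, unadjusted).
#' @return list of class `churn_result`: `n_original_significant`,
#'   `pct_no_longer_significant`, `pct_newly_significant` (both `NA` when
#'   nothing was originally significant), `alpha`.
#' @export
churn <- function(p_original, p_reduced, alpha = 0.01) {
  probes <- intersect(names(p_original), names(p_reduced))
  if (length(probes) == 0) abort("churn(): p-value maps share no probes")
  po <- p_original[probes]
  pr <- p_reduced[probes]
  keep <- !is.na(po) & !is.na(pr)
  s0 <- probes[keep & po < alpha]
  s1 <- probes[keep & pr < alpha]
  n0 <- length(s0)
  structure(list(
    n_original_significant = n0,
    pct_no_longer_significant =
      if (n0 == 0) NA_real_ else round_half_up(100 * length(setdiff(s0, s1)) / n0, 2),
    pct_newly_significant =
      if (n0 == 0) NA_real_ else round_half_up(100 * length(setdiff(s1, s0)) / n0, 2),
    alpha = alpha
  ), class = "churn_result")
}

#' @export
print.churn_result <- function(x, ...) {
  cat(sprintf(
    "churn at alpha = %g: %d originally significant; %.2f%% lost, %.2f%% new\n",
    x$alpha, x$n_original_significant, x$pct_no_longer_significant,
    x$pct_newly_significant))
  invisible(x)
}

#' Impact of removing flagged samples on a survival screen
#'
#' Convenience wrapper: runs the univariate Cox screen on the full cohort
#' and again after dropping `flagged_ids`, then summarizes the
#' significance churn.
#'
#' @param matrix probes-by-samples expression matrix.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param flagged_ids sample IDs to remove (e.g. misclassified samples
#'   and duplicate-pair members).
#' @param alpha unadjusted significance threshold (default 0.01).
#' @return `churn_result` with the two p-value maps attached as
#'   attributes `p_original` and `p_reduced`.
#' @export
removal_impact <- function(matrix, survival, flagged_ids, alpha = 0.01) {
  p0 <- univariate_survival_screen(matrix, survival)
  keep <- setdiff(colnames(matrix), flagged_ids)
  if (length(keep) < 3) abort("removal would leave fewer than 3 samples")
  p1 <- univariate_survival_screen(matrix[, keep, drop = FALSE], survival)
  out <- churn(stats::setNames(p0$p, p0$probe_id),
               stats::setNames(p1$p, p1$probe_id), alpha = alpha)
  attr(out, "p_original") <- p0
  attr(out, "p_reduced") <- p1
  out
}
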