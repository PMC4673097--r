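#' Affine map sending group medians to 0 and 1
#'
#' From a bimodal [two_group_split()], the orientation-preserving linear
#' transformation `y = a x + b` with `a = 1 / (median_high - median_low)`
#' and `b = -median_low * a`, so the low-group median maps to 0 and the
#' high-group median to 1. This is what makes evidence scores comparable
#' across cohorts despite study-level intensity shifts.
#'
#' @param split a `group_split` with `bimodal = TRUE` and
#'   `median_high > median_low`.
#' @return list with slope `a` (> 0) and intercept `b`.
#' @export
fit_affine <- function(split) {
  if (!inherits(split, "group_split")) abort("fit_affine() expects a group_split")
  if (is.na(split$median_high) || split$median_high <= split$median_low) {
    abort("fit_affine(): degenerate split (median_high must exceed median_low)")
  }
  a <- 1 / (split$median_high - split$median_low)
  list(a = a, b = -split$median_low * a)
}

#' Normalize one probe's expression values within one cohort
#'
#' The workhorse behind cross-cohort comparability. Three paths:
#'
#' * **two_group** — the values split bimodally into low/high groups: apply
#'   [fit_affine()], putting the group medians exactly at 0 and 1.
#' * **single_group_low / single_group_high** — no bimodal split, but the
#'   cohort is effectively single-sex (at least `single_sex_majority` of
#'   labelled samples share one sex), so the probe's expected side is known
#'   from its evidence direction: a male-evidence (Y) probe in an
#'   all-female cohort is the *low* group, a female-evidence (X) probe
#'   there is the *high* group, and vice versa. The single group's median
#'   is anchored at 0 (low) or 1 (high) with slope `1 / reference_scale`.
#'   Annotated sex orients the group as a whole; it never scores
#'   individual samples. If the cohort is unlabelled but a pooled
#'   raw-scale reference from bimodal cohorts in the same run is supplied,
#'   the group is oriented to the nearer pooled group median instead.
#' * **failed** — neither applies; the probe contributes no evidence in
#'   this cohort (values come back all-`NA`, not an exception).
#'
#' @param values numeric vector of raw (log-scale) expression values for
#'   one probe across the cohort's samples; `NA` allowed.
#' @param marker one-row slice of a marker panel (needs `probe_id`,
#'   `evidence_sex`).
#' @param sex_labels character vector over the same samples with values in
#'   `sex_levels()`, or `NULL` for an unlabelled cohort.
#' @param min_group,sep_min passed to [two_group_split()].
#' @param single_sex_majority fraction of labelled samples that must share
#'   one sex for the single-sex path (default 0.9; protects orientation
#'   against a few mislabels).
#' @param reference_scale raw-scale spread (median_high - median_low)
#'   used as `1/slope` on the single-group paths; default 1. In a
#'   multi-cohort run, [classify_cohorts()] supplies the pooled value from
#'   the bimodal cohorts.
#' @param pooled_medians optional list with raw-scale `low` and `high`
#'   pooled group medians for this probe, enabling the unlabelled path.
#' @return object of class `normalized_probe`: list with `probe_id`,
#'   `values` (normalized, `NA` preserved), `provenance`, `split`, `map`.
#' @export
normalize_probe <- function(values, marker, sex_labels = NULL,
                            min_group = 2L, sep_min = 3,
                            single_sex_majority = 0.9,
                            reference_scale = NULL,
                            pooled_medians = NULL) {
  probe_id <- as.character(marker$probe_id)
  out <- function(vals, provenance, split = NULL, map = NULL) {
    structure(list(probe_id = probe_id, values = vals,
                   provenance = provenance, split = split, map = map),
              class = "normalized_probe")
  }
  if (sum(!is.na(values)) < 2) return(out(rep(NA_real_, length(values)), "failed"))

  split <- two_group_split(values, min_group = min_group, sep_min = sep_min)
  if (split$bimodal) {
    map <- fit_affine(split)
    return(out(map$a * values + map$b, "two_group", split, map))
  }

  ref <- if (is.null(reference_scale) || !is.finite(reference_scale) ||
             reference_scale <= 0) 1 else reference_scale
  med <- stats::median(values, na.rm = TRUE)

  side <- NA_character_
  any_labelled <- FALSE
  if (!is.null(sex_labels)) {
    lab <- sex_labels[sex_labels %in% c("female", "male")]
    any_labelled <- length(lab) > 0
    if (any_labelled) {
      tab <- table(factor(lab, levels = c("female", "male")))
      frac <- max(tab) / length(lab)
      if (frac >= single_sex_majority) {
        majority <- names(tab)[which.max(tab)]
        side <- if (marker$evidence_sex == majority) "high" else "low"
      }
    }
  }
  # raw-scale proximity orientation is a last resort for cohorts with no
  # labels at all: it is not invariant to cohort-level affine shifts, so a
  # labelled cohort that fails both the bimodal and the single-sex test
  # contributes no evidence instead of guessing
  if (is.na(side) && !any_labelled && !is.null(pooled_medians) &&
      is.finite(pooled_medians$low) && is.finite(pooled_medians$high)) {
    side <- if (abs(med - pooled_medians$high) < abs(med - pooled_medians$low))
      "high" else "low"
  }
  if (is.na(side)) return(out(rep(NA_real_, length(values)), "failed", split))

  a <- 1 / ref
  b <- (if (side == "high") 1 else 0) - med * a
  out(a * values + b,
      if (side == "high") "single_group_high" else "single_group_low",
      split, list(a = a, b = b))
}

#' @export
print.normalized_probe <- function(x, ...) {
  cat(sprintf("normalized probe %s: provenance %s, %d values (%d missing)\n",
              x$probe_id, x$provenance, length(x$values), sum(is.na(x$values))))
  invisible(x)
}
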