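#' Rousseeuw-Croux Qn scale estimator
#'
#' Robust scale of a one-dimensional sample: the k-th smallest absolute
#' pairwise difference, `k = h*(h-1)/2` with `h = floor(n/2) + 1`, scaled by
#' the asymptotic normal-consistency constant `d = 2.2219`. No finite-sample
#' correction factor is applied (the estimator is used here only to set
#' tail cut points on groups of at least a handful of samples, where the
#' correction is immaterial and would complicate cross-checks against the
#' plain order-statistic definition).
#'
#' For moderate n the k-th order statistic is selected directly among the
#' pairwise differences; for large n (> 1500) it is located by bisection
#' on the value axis with an O(n) two-pointer pair count per step, then
#' snapped to the smallest achieved difference above the final lower
#' bound. Both paths compare the rounded differences themselves, so the
#' result is bit-identical to brute-force enumeration at any n, without
#' materializing the O(n^2) difference matrix for large groups.
#'
#' @param x numeric vector; `NA`s are dropped. At least 2 non-missing
#'   values are required.
#' @return non-negative scalar; 0 for a constant vector.
#' @references Rousseeuw & Croux (1993), "Alternatives to the Median
#'   Absolute Deviation", JASA 88(424).
#' @export
#' @examples
#' qn_scale(c(1, 2, 3, 4, 5)) # 2.2219: 3rd smallest pairwise diff is 1
qn_scale <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("qn_scale() needs at least 2 non-missing values, got %d", n)
  x <- sort(x)
  h <- n %/% 2 + 1
  k <- h * (h - 1) / 2
  d <- 2.2219
  if (x[n] == x[1]) return(0)

  if (n <= 1500) {
    # direct selection among all pairwise differences of the sorted values
    diffs <- outer(x, x, `-`)
    dv <- diffs[lower.tri(diffs)] # x[j] - x[i], j > i, all >= 0
    return(d * sort(dv, partial = k)[k])
  }

  # large n: bisect on the value axis with an O(n) two-pointer pair count,
  # comparing the rounded differences x[j] - x[i] themselves so the result
  # is bit-identical to the direct selection above
  count_le <- function(t) {
    i <- 1L
    total <- 0
    for (j in seq_len(n)) {
      while (x[j] - x[i] > t) i <- i + 1L
      total <- total + (j - i)
    }
    total
  }
  lo <- 0
  hi <- x[n] - x[1]
  if (count_le(0) >= k) return(0)
  repeat {
    mid <- lo + (hi - lo) / 2
    if (mid <= lo || mid >= hi) break
    if (count_le(mid) >= k) hi <- mid else lo <- mid
  }
  # smallest achieved difference strictly above lo is the k-th
  best <- hi
  j <- 2L
  for (i in seq_len(n - 1L)) {
    if (j <= i) j <- i + 1L
    while (j <= n && x[j] - x[i] <= lo) j <- j + 1L
    if (j > n) break
    if (x[j] - x[i] < best) best <- x[j] - x[i]
  }
  d * best
}

#' Split one probe's values into low and high expression groups
#'
#' Deterministic one-dimensional two-group clustering: an exhaustive scan of
#' the n-1 candidate thresholds between consecutive distinct sorted values,
#' minimizing the pooled within-group sum of squared deviations (equivalent
#' to optimal 2-means in one dimension), subject to both groups holding at
#' least `min_group` members. No random initialization is involved, so the
#' split is reproducible and invariant under increasing affine transforms.
#'
#' Each group gets a robust location (median) and scale ([qn_scale()];
#' 0 for singleton groups). The separation statistic
#' `(median_high - median_low) / (qn_low + qn_high + eps)` with
#' `eps = 1e-12 * max(1, |median_high|)` decides bimodality:
#' `bimodal = separation >= sep_min`.
#'
#' Degenerate inputs (all values equal, or fewer than `2 * min_group`
#' values) yield a single low group with `bimodal = FALSE`.
#'
#' @param values numeric vector, `NA` allowed (ignored; group index sets
#'   refer to positions in `values`). At least 2 non-missing values.
#' @param min_group smallest admissible group size (default 2).
#' @param sep_min separation at or above which the split counts as bimodal
#'   (default 3).
#' @return object of class `group_split`: list with `threshold`, `low`,
#'   `high` (integer index vectors), `median_low`, `median_high`, `qn_low`,
#'   `qn_high`, `separation`, `bimodal`, `n_used`.
#' @export
two_group_split <- function(values, min_group = 2L, sep_min = 3) {
  stopifnot(min_group >= 1)
  idx <- which(!is.na(values))
  x <- values[idx]
  n <- length(x)
  if (n < 2) abort("two_group_split() needs at least 2 non-missing values")

  degenerate <- function() {
    structure(list(
      threshold = max(x), low = idx, high = integer(0),
      median_low = stats::median(x), median_high = NA_real_,
      qn_low = if (length(unique(x)) == 1L) 0 else qn_scale(x),
      qn_high = NA_real_,
      separation = 0, bimodal = FALSE, n_used = n
    ), class = "group_split")
  }
  if (n < 2 * min_group || length(unique(x)) == 1L) return(degenerate())

  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  i_seq <- seq_len(n - 1L)
  # pooled within-group SSQ for split after sorted position i
  ssq <- (cs2[i_seq] - cs[i_seq]^2 / i_seq) +
    ((tot2 - cs2[i_seq]) - (tot - cs[i_seq])^2 / (n - i_seq))
  ok <- i_seq >= min_group & (n - i_seq) >= min_group &
    xs[i_seq] < xs[i_seq + 1L] # no split inside a tie block
  if (!any(ok)) return(degenerate())
  cand <- i_seq[ok]
  split_at <- cand[which.min(ssq[ok])]

  low_s <- o[seq_len(split_at)]
  high_s <- o[(split_at + 1L):n]
  med_lo <- stats::median(x[low_s])
  med_hi <- stats::median(x[high_s])
  qn_lo <- if (length(low_s) < 2) 0 else qn_scale(x[low_s])
  qn_hi <- if (length(high_s) < 2) 0 else qn_scale(x[high_s])
  eps <- 1e-12 * max(1, abs(med_hi))
  sep <- (med_hi - med_lo) / (qn_lo + qn_hi + eps)

  structure(list(
    threshold = xs[split_at],
    low = idx[low_s], high = idx[high_s],
    median_low = med_lo, median_high = med_hi,
    qn_low = qn_lo, qn_high = qn_hi,
    separation = sep, bimodal = sep >= sep_min, n_used = n
  ), class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf(
    "two-group split: n=%d, low=%d high=%d, medians %.4g/%.4g, Qn %.4g/%.4g, separation %.3g (%s)\n",
    x$n_used, length(x$low), length(x$high), x$median_low, x$median_high,
    x$qn_low, x$qn_high, x$separation,
    if (x$bimodal) "bimodal" else "not bimodal"
  ))
  invisible(x)
}

#' Upper-tail cut point of a robustly fitted normal distribution
#'
#' The `level` quantile of Normal(median, Qn^2) fitted to a (low expression)
#' group: `cut = median + qnorm(level) * qn`. Values above the cut are
#' inconsistent with the group and count as evidence of membership in the
#' other group. A zero scale makes the cut non-informative: downstream
#' evidence for that probe/cohort is forced to 0 rather than firing on
#' every tie-break.
#'
#' @param median_low robust location of the group.
#' @param qn_low robust scale of the group (Qn), must be >= 0.
#' @param level quantile probability in (0, 1); default 0.999.
#' @param probe_id optional probe identifier carried into the result.
#' @return object of class `cut_point`: list with `probe_id`, `level`,
#'   `cut`, `informative`.
#' @export
#' @examples
#' cut_point(0, 1)$cut # ~3.090232
cut_point <- function(median_low, qn_low, level = 0.999, probe_id = NA_character_) {
  if (!is.finite(level) || level <= 0 || level >= 1) {
    abort("cut_point(): level must lie strictly inside (0, 1), got %s",
          format(level))
  }
  if (is.na(qn_low) || qn_low < 0) abort("cut_point(): qn_low must be >= 0")
  structure(list(
    probe_id = probe_id,
    level = level,
    cut = median_low + stats::qnorm(level) * qn_low,
    informative = qn_low > 0
  ), class = "cut_point")
}
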