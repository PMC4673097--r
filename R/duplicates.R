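#' Probes with the highest expression variance
#'
#' Sample variance (n-1 denominator) per probe across all samples of the
#' cohort; the top `k` probes are the substrate of the duplicate screen.
#' Probes with any missing value are excluded before ranking (a duplicate
#' signature should not hinge on imputation); ties are broken by probe ID
#' ascending for reproducibility.
#'
#' @param matrix probes-by-samples numeric matrix.
#' @param k number of probes to keep (default 1000).
#' @return character vector of probe IDs, length `min(k, eligible)`.
#' @export
top_variance_probes <- function(matrix, k = 1000L) {
  validate_expression_matrix(matrix)
  if (k <= 0) abort("top_variance_probes(): k must be positive")
  if (ncol(matrix) < 2) abort("top_variance_probes(): need at least 2 samples")
  complete <- rowSums(is.na(matrix)) == 0
  m <- matrix[complete, , drop = FALSE]
  if (nrow(m) == 0) abort("no probe without missing values")
  v <- apply(m, 1, stats::var)
  if (nrow(m) < k) {
    warnf("only %d eligible probes for k = %d; returning all", nrow(m), k)
    k <- nrow(m)
  }
  ids <- rownames(m)[order(-v, rownames(m))]
  ids[seq_len(k)]
}

#' All-pairs Pearson correlation between samples
#'
#' Correlations over the selected probes' raw expression values (the
#' duplicate screen runs before any normalization). Samples with zero
#' variance over the probes have undefined correlations; their pairs are
#' recorded with `r = NA` and excluded from the gap analysis, with a
#' warning.
#'
#' @param matrix probes-by-samples matrix, typically restricted to
#'   [top_variance_probes()].
#' @return data.frame with `sample_a`, `sample_b` (lexicographically
#'   ordered within each pair), `r`; `n*(n-1)/2` rows.
#' @export
pairwise_correlations <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2) abort("pairwise_correlations(): need at least 2 samples")
  if (nrow(matrix) < 3) abort("pairwise_correlations(): need at least 3 probes")
  sds <- apply(matrix, 2, stats::sd, na.rm = TRUE)
  flat <- colnames(matrix)[!is.na(sds) & sds == 0]
  if (length(flat)) {
    warnf("zero-variance sample(s), correlations undefined: %s",
          paste(flat, collapse = ", "))
  }
  cc <- suppressWarnings(
    stats::cor(matrix, use = "pairwise.complete.obs", method = "pearson"))
  cc[flat, ] <- NA_real_
  cc[, flat] <- NA_real_
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  a <- colnames(matrix)[idx[, 1]]
  b <- colnames(matrix)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(sample_a = a, sample_b = b, r = cc[idx],
                    stringsAsFactors = FALSE)
  out[order(out$sample_a, out$sample_b), , drop = FALSE]
}

#' Split ordered correlations at the largest admissible gap
#'
#' The duplicate/non-duplicate boundary is the largest difference between
#' consecutive ordered correlation values — but the naked rule would fire
#' on any cohort, so a split is admissible only when the upper block lies
#' entirely at or above `r_min` and contains at most `max_frac` of all
#' pairs (the single top pair is always size-admissible; a zero-width
#' "gap" inside a tie block never splits). With `r_min = -1` and
#' `max_frac = 1` the literal largest-gap rule is recovered.
#'
#' @param correlations numeric vector of pairwise correlations (any order;
#'   sorted internally, `NA` dropped).
#' @param r_min smallest correlation a duplicate pair may have
#'   (default 0.95: observed duplicates sit at r >= 0.99 while technical
#'   re-runs of distinct samples reach about 0.91-0.99).
#' @param max_frac largest admissible fraction of pairs above the gap
#'   (default 0.1).
#' @return list with `gap_threshold` (midpoint of the gap, or `NA` when no
#'   admissible split exists), `gap_index` (number of pairs above the
#'   gap, or `NA`), and `ordered` (the descending correlations used).
#' @export
gap_split <- function(correlations, r_min = 0.95, max_frac = 0.1) {
  r <- sort(correlations[!is.na(correlations)], decreasing = TRUE)
  empty <- list(gap_threshold = NA_real_, gap_index = NA_integer_, ordered = r)
  m <- length(r)
  if (m < 2) return(empty)
  i_seq <- seq_len(m - 1L)
  gaps <- r[i_seq] - r[i_seq + 1L]
  # the single top pair is always a candidate; otherwise the upper block
  # may hold at most max_frac of all pairs
  admissible <- r[i_seq] >= r_min & (i_seq == 1L | i_seq <= max_frac * m)
  if (!any(admissible)) return(empty)
  cand <- i_seq[admissible]
  gi <- cand[which.max(gaps[cand])]
  if (gaps[gi] <= 0) return(empty) # tie block, not a gap
  list(gap_threshold = (r[gi] + r[gi + 1L]) / 2, gap_index = gi, ordered = r)
}

#' Detect duplicate sample measurements in one cohort
#'
#' Pipeline: select the `k` highest-variance probes, correlate all sample
#' pairs on their raw values, and flag the pairs above the largest
#' admissible gap in the ordered correlations. Flagged pairs are reported
#' individually (a triplicated sample appears as three pairs); connected
#' groups are available in the `groups` element as a convenience.
#'
#' @param matrix probes-by-samples expression matrix.
#' @param k number of top-variance probes (default 1000).
#' @param r_min,max_frac see [gap_split()].
#' @param cohort_id identifier stamped into the report.
#' @return object of class `duplicate_report`: list with `cohort_id`,
#'   `k_probes_used`, `ordered_correlations`, `gap_index`,
#'   `gap_threshold`, `pairs` (data.frame `sample_a`, `sample_b`, `r`,
#'   sorted by `r` descending) and `groups`.
#' @export
find_duplicates <- function(matrix, k = 1000L, r_min = 0.95, max_frac = 0.1,
                            cohort_id = "cohort") {
  probes <- top_variance_probes(matrix, k)
  cors <- pairwise_correlations(matrix[probes, , drop = FALSE])
  gs <- gap_split(cors$r, r_min = r_min, max_frac = max_frac)
  if (is.na(gs$gap_threshold)) {
    pairs <- cors[0, , drop = FALSE]
  } else {
    pairs <- cors[!is.na(cors$r) & cors$r > gs$gap_threshold & cors$r >= r_min, ,
                  drop = FALSE]
    pairs <- pairs[order(-pairs$r, pairs$sample_a, pairs$sample_b), , drop = FALSE]
  }
  rownames(pairs) <- NULL
  groups <- list()
  if (nrow(pairs)) {
    # connected components over the pair graph
    parent <- stats::setNames(unique(c(pairs$sample_a, pairs$sample_b)),
                              unique(c(pairs$sample_a, pairs$sample_b)))
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs$sample_a[i]); rb <- find(pairs$sample_b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
    roots <- vapply(names(parent), find, character(1))
    groups <- unname(split(names(parent), roots))
  }
  structure(list(
    cohort_id = cohort_id, k_probes_used = length(probes),
    ordered_correlations = gs$ordered, gap_index = gs$gap_index,
    gap_threshold = gs$gap_threshold, pairs = pairs, groups = groups
  ), class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("cohort %s: %d probes, %d pairs examined, %d duplicate pair(s)\n",
              x$cohort_id, x$k_probes_used, length(x$ordered_correlations),
              nrow(x$pairs)))
  if (nrow(x$pairs)) {
    cat(sprintf("  gap threshold %.4f\n", x$gap_threshold))
    print(x$pairs)
  }
  invisible(x)
}

#' Overlap between duplicate pairs and misclassified samples
#'
#' How many sex-misclassified samples are members of at least one
#' duplicate pair — the fraction of annotation discrepancies explainable
#' by a sample having been measured twice under another patient's ID.
#'
#' @param pairs data.frame with `sample_a`, `sample_b` (e.g. the `pairs`
#'   element of a `duplicate_report`, or several of them row-bound).
#' @param verdicts data.frame with `sample_id` and `category` (e.g. the
#'   `verdicts` of one or more `cohort_report`s).
#' @return list with `n_misclassified`, `n_explained`, `pct_explained`
#'   (one-decimal percentage of misclassified samples in duplicate pairs).
#' @export
cross_check_duplicates <- function(pairs, verdicts) {
  mis <- verdicts$sample_id[verdicts$category == "misclassified"]
  members <- unique(c(pairs$sample_a, pairs$sample_b))
  n_exp <- sum(mis %in% members)
  list(
    n_misclassified = length(mis),
    n_explained = n_exp,
    pct_explained = pct_of(n_exp, length(mis))
  )
}
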