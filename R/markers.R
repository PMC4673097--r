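#' Univariate male-female classification accuracy of one probe
#'
#' The same deterministic machinery used everywhere else in the pipeline:
#' split the probe's values into two groups with [two_group_split()],
#' assign each group the majority sex among its members, and score the
#' fraction of labelled samples whose group's sex matches their label.
#' Majority ties within a group are broken toward the assignment that
#' maximizes overall accuracy. Samples labelled `unknown` are excluded.
#'
#' @param values numeric expression vector for one probe.
#' @param labels character sex labels over the same samples.
#' @param min_group,sep_min passed to [two_group_split()].
#' @return accuracy in `[0, 1]`.
#' @export
probe_accuracy <- function(values, labels, min_group = 2L, sep_min = 3) {
  keep <- labels %in% c("female", "male") & !is.na(values)
  v <- values[keep]
  lab <- labels[keep]
  if (length(unique(lab)) < 2) {
    abort("probe_accuracy() needs both sexes among labelled samples")
  }
  split <- two_group_split(v, min_group = min_group, sep_min = sep_min)
  membership <- rep("low", length(v))
  membership[split$high] <- "high"

  acc_for <- function(low_sex, high_sex) {
    assigned <- ifelse(membership == "low", low_sex, high_sex)
    mean(assigned == lab)
  }
  # the two orientation hypotheses; ties resolve toward higher accuracy
  max(acc_for("female", "male"), acc_for("male", "female"))
}

#' Select sex-marker candidates across labelled datasets
#'
#' For each probe shared by all datasets, computes the univariate
#' classification accuracy per dataset and ranks probes by the median
#' accuracy across datasets. Probes with more than `max_missing_frac`
#' missing values in a dataset skip that dataset (the accuracy vector is
#' shortened and the median taken over the remaining entries).
#'
#' @param datasets list; each element a list with `matrix` (probes by
#'   samples) and `annotation` (data.frame or named label vector).
#' @param accuracy_threshold keep probes with median accuracy at or above
#'   this value (default 0.75).
#' @param top_k truncate the ranked list to this many probes
#'   (default `Inf`).
#' @param max_missing_frac per-dataset missingness tolerance (default 0.2).
#' @param min_group,sep_min passed to [two_group_split()].
#' @return data.frame with `probe_id`, `median_accuracy`, `n_datasets`,
#'   sorted by median accuracy descending, probe ID ascending; per-dataset
#'   accuracies in the attribute `"per_dataset"`.
#' @export
select_markers <- function(datasets, accuracy_threshold = 0.75, top_k = Inf,
                           max_missing_frac = 0.2, min_group = 2L,
                           sep_min = 3) {
  stopifnot(length(datasets) >= 1)
  probe_sets <- lapply(datasets, function(d) rownames(d$matrix))
  shared <- Reduce(intersect, probe_sets)
  if (length(shared) == 0) abort("datasets share no probes")

  acc <- matrix(NA_real_, nrow = length(shared), ncol = length(datasets),
                dimnames = list(shared, NULL))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    labels <- if (is.character(d$annotation)) {
      unname(d$annotation[colnames(d$matrix)])
    } else {
      unname(annotation_for(colnames(d$matrix), d$annotation))
    }
    for (p in shared) {
      v <- d$matrix[p, ]
      if (mean(is.na(v)) > max_missing_frac) next
      acc[p, j] <- probe_accuracy(v, labels, min_group = min_group,
                                  sep_min = sep_min)
    }
  }
  med <- apply(acc, 1, stats::median, na.rm = TRUE)
  n_ds <- rowSums(!is.na(acc))
  out <- data.frame(probe_id = shared, median_accuracy = unname(med),
                    n_datasets = unname(n_ds), stringsAsFactors = FALSE)
  out <- out[!is.na(out$median_accuracy) &
               out$median_accuracy >= accuracy_threshold, , drop = FALSE]
  out <- out[order(-out$median_accuracy, out$probe_id), , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  attr(out, "per_dataset") <- acc
  out
}
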