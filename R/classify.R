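#' Binary evidence scores for one sample
#'
#' A marker's evidence score is 1 exactly when the sample's normalized
#' value lies strictly above that probe's cohort cut point and the cut is
#' informative (non-zero robust scale in the fitted group). Missing values
#' and non-informative cuts yield 0 — absence of evidence, never evidence.
#' Ties at the cut go to "no evidence" (thresholds are published as strict
#' ">" bounds).
#'
#' @param values named numeric vector: normalized value per marker probe
#'   for one sample (`NA` allowed).
#' @param cuts named list of [cut_point()] objects over the same probes.
#' @return named integer vector of 0/1 scores over the probes in `values`.
#' @export
evidence_scores <- function(values, cuts) {
  probes <- names(values)
  vapply(probes, function(p) {
    cp <- cuts[[p]]
    v <- values[[p]]
    if (is.null(cp) || !isTRUE(cp$informative) || is.na(v)) return(0L)
    as.integer(v > cp$cut)
  }, integer(1))
}

#' Combine marker evidence into a predicted sex
#'
#' A sample is called male when at least one male-evidence score is 1 and
#' all female-evidence scores are 0; female by the mirrored rule; anything
#' else — conflicting evidence on both sides, or no evidence at all — is
#' `unconfident`. Over the four-marker panel this maps exactly 3 of the 16
#' score combinations to male, 3 to female and 10 to unconfident.
#'
#' @param female_scores,male_scores numeric/integer vectors of 0/1 scores
#'   (length may differ from 2 when panel probes are absent from the
#'   platform; an absent probe simply contributes no evidence).
#' @return one of `"female"`, `"male"`, `"unconfident"`.
#' @export
combine_evidence <- function(female_scores, male_scores) {
  f <- sum(female_scores, na.rm = TRUE)
  m <- sum(male_scores, na.rm = TRUE)
  if (m >= 1 && f == 0) return("male")
  if (f >= 1 && m == 0) return("female")
  "unconfident"
}

#' Compare predicted with annotated sex
#'
#' Category rules: `unconfident` whenever the prediction is unconfident;
#' `unannotated` when a confident prediction meets an `unknown` annotation
#' (the sample is scored, there is just nothing to contradict); otherwise
#' `correct` iff prediction and annotation agree, else `misclassified`.
#'
#' @param predicted character vector over `{female, male, unconfident}`.
#' @param annotated character vector over `sex_levels()`.
#' @return character vector over
#'   `{correct, misclassified, unconfident, unannotated}`.
#' @export
verdict_category <- function(predicted, annotated) {
  ifelse(predicted == "unconfident", "unconfident",
         ifelse(annotated == "unknown", "unannotated",
                ifelse(predicted == annotated, "correct", "misclassified")))
}

report_categories <- c("correct", "misclassified", "unconfident", "unannotated")

#' Build a cohort report from a verdict table
#'
#' @param cohort_id cohort identifier.
#' @param verdicts data.frame with columns `sample_id`, `annotated_sex`,
#'   `predicted_sex`, `category`.
#' @return object of class `cohort_report`: counts and percentages per
#'   category, mislabel direction counts, and the verdict table.
#' @export
new_cohort_report <- function(cohort_id, verdicts) {
  n <- nrow(verdicts)
  counts <- vapply(report_categories,
                   function(cat) sum(verdicts$category == cat), integer(1))
  percentages <- vapply(counts, pct_of, numeric(1), total = n)
  mis <- verdicts[verdicts$category == "misclassified", , drop = FALSE]
  directions <- c(
    female_to_male = sum(mis$annotated_sex == "female" & mis$predicted_sex == "male"),
    male_to_female = sum(mis$annotated_sex == "male" & mis$predicted_sex == "female")
  )
  structure(list(
    cohort_id = cohort_id, n_samples = n,
    counts = counts, percentages = percentages,
    mislabel_directions = directions, verdicts = verdicts
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort %s: %d samples\n", x$cohort_id, x$n_samples))
  for (cat_ in report_categories) {
    cat(sprintf("  %-13s %5d (%.1f%%)\n", cat_, x$counts[[cat_]],
                x$percentages[[cat_]]))
  }
  cat(sprintf("  mislabel directions: female->male %d, male->female %d\n",
              x$mislabel_directions[["female_to_male"]],
              x$mislabel_directions[["male_to_female"]]))
  invisible(x)
}

# per-probe normalized values + cohort cut, shared by classify_cohort
probe_evidence <- function(values, marker, sex_labels, level, min_group,
                           sep_min, single_sex_majority, reference_scale,
                           pooled_medians, cut_mode) {
  np <- normalize_probe(values, marker, sex_labels,
                        min_group = min_group, sep_min = sep_min,
                        single_sex_majority = single_sex_majority,
                        reference_scale = reference_scale,
                        pooled_medians = pooled_medians)
  cp <- cut_point(0, 0, level, probe_id = np$probe_id) # non-informative default
  if (np$provenance != "failed") {
    if (cut_mode == "panel") {
      if (is.finite(marker$default_cut)) {
        cp <- structure(list(probe_id = np$probe_id, level = level,
                             cut = marker$default_cut, informative = TRUE),
                        class = "cut_point")
      } else {
        warnf("probe %s has no fixed cut point; evidence disabled", np$probe_id)
      }
    } else if (np$provenance == "two_group") {
      low <- np$values[np$split$low]
      low <- low[!is.na(low)]
      qn <- if (length(low) >= 2) qn_scale(low) else 0
      cp <- cut_point(stats::median(low), qn, level, probe_id = np$probe_id)
    } else if (np$provenance == "single_group_low") {
      v <- np$values[!is.na(np$values)]
      qn <- if (length(v) >= 2) qn_scale(v) else 0
      cp <- cut_point(stats::median(v), qn, level, probe_id = np$probe_id)
    } else { # single_group_high: lower tail bound of the high group
      v <- np$values[!is.na(np$values)]
      qn <- if (length(v) >= 2) qn_scale(v) else 0
      cp <- cut_point(stats::median(v), qn, 1 - level, probe_id = np$probe_id)
    }
  }
  scores <- rep(0L, length(values))
  if (isTRUE(cp$informative)) {
    scores <- as.integer(!is.na(np$values) & np$values > cp$cut)
  }
  list(normalized = np, cut = cp, scores = scores)
}

#' Classify one cohort's samples as female or male and audit annotations
#'
#' Runs the full per-cohort pipeline: for each marker probe present on the
#' platform, split the cohort's values into low/high groups, normalize
#' onto the common 0/1 scale, derive the robust tail cut point, and score
#' each sample; then combine female and male evidence into a predicted sex
#' and compare with the annotation.
#'
#' @param matrix numeric probes-by-samples expression matrix (log scale)
#'   with probe row names and sample column names.
#' @param annotation data.frame (as [read_annotation_tsv()]) or named
#'   character vector of sex labels; `NULL` for an unlabelled cohort.
#' @param panel marker panel data.frame; default [default_marker_panel()].
#' @param level tail quantile for cut points (default 0.999; the
#'   deployment tables were printed at 0.99 — configurable, see vignette).
#' @param cut_mode `"cohort"` derives cut points from the cohort itself
#'   (the construction mode); `"panel"` applies the fixed `default_cut`
#'   column of the panel (deployment mode).
#' @param min_group,sep_min,single_sex_majority see [two_group_split()]
#'   and [normalize_probe()].
#' @param reference_scales optional named numeric vector (by probe) of
#'   raw-scale low-to-high spans used on the single-group paths.
#' @param pooled_medians optional named list (by probe) of
#'   `list(low =, high =)` pooled raw group medians for unlabelled cohorts.
#' @param cohort_id identifier stamped into the report.
#' @return `cohort_report` with additional elements `probes` (per-probe
#'   provenance and cut), `normalized` (panel-probe normalized matrix) and
#'   `evidence` (samples-by-probes 0/1 score matrix).
#' @export
classify_cohort <- function(matrix, annotation = NULL,
                            panel = default_marker_panel(),
                            level = 0.999, cut_mode = c("cohort", "panel"),
                            min_group = 2L, sep_min = 3,
                            single_sex_majority = 0.9,
                            reference_scales = NULL, pooled_medians = NULL,
                            cohort_id = "cohort") {
  cut_mode <- match.arg(cut_mode)
  validate_expression_matrix(matrix)
  panel <- validate_marker_panel(panel)
  present <- panel$probe_id[panel$probe_id %in% rownames(matrix)]
  if (length(present) == 0) {
    abort("no marker panel probe found in the matrix; expected any of: %s",
          paste(panel$probe_id, collapse = ", "))
  }
  absent <- setdiff(panel$probe_id, present)
  if (length(absent)) {
    warnf("marker probe(s) absent from platform, dropped: %s",
          paste(absent, collapse = ", "))
  }

  samples <- colnames(matrix)
  labels <- if (is.character(annotation)) {
    stats::setNames(annotation[samples], samples)
  } else {
    annotation_for(samples, annotation)
  }
  labels[is.na(labels)] <- "unknown"

  evidence <- matrix(0L, nrow = length(samples), ncol = length(present),
                     dimnames = list(samples, present))
  normalized <- matrix(NA_real_, nrow = length(present), ncol = length(samples),
                       dimnames = list(present, samples))
  probe_rows <- vector("list", length(present))
  for (i in seq_along(present)) {
    p <- present[i]
    marker <- panel[panel$probe_id == p, , drop = FALSE]
    pe <- probe_evidence(
      matrix[p, ], marker, labels, level, min_group, sep_min,
      single_sex_majority,
      reference_scale = if (!is.null(reference_scales)) reference_scales[[p]],
      pooled_medians = if (!is.null(pooled_medians)) pooled_medians[[p]],
      cut_mode = cut_mode
    )
    evidence[, i] <- pe$scores
    normalized[i, ] <- pe$normalized$values
    probe_rows[[i]] <- data.frame(
      probe_id = p, gene = marker$gene, evidence_sex = marker$evidence_sex,
      provenance = pe$normalized$provenance, cut = pe$cut$cut,
      level = pe$cut$level, informative = pe$cut$informative,
      stringsAsFactors = FALSE
    )
  }
  probes <- do.call(rbind, probe_rows)

  f_probes <- present[panel$evidence_sex[match(present, panel$probe_id)] == "female"]
  m_probes <- present[panel$evidence_sex[match(present, panel$probe_id)] == "male"]
  predicted <- vapply(samples, function(s) {
    combine_evidence(evidence[s, f_probes], evidence[s, m_probes])
  }, character(1))

  verdicts <- data.frame(
    sample_id = samples,
    annotated_sex = unname(labels),
    predicted_sex = unname(predicted),
    category = verdict_category(unname(predicted), unname(labels)),
    stringsAsFactors = FALSE
  )
  report <- new_cohort_report(cohort_id, verdicts)
  report$probes <- probes
  report$normalized <- normalized
  report$evidence <- evidence
  report
}

#' Classify a collection of cohorts with pooled normalization references
#'
#' Two passes over the collection: the first fits the two-group split of
#' every marker probe in every cohort and pools, per probe, the raw-scale
#' low-to-high spans and group medians of the bimodal cohorts (medians
#' across cohorts). The second pass classifies each cohort, handing the
#' pooled values to the single-group and unlabelled normalization paths.
#'
#' @param cohorts named list; each element a list with `matrix` and
#'   optionally `annotation` (data.frame or named label vector).
#' @param panel marker panel.
#' @param ... further arguments passed to [classify_cohort()].
#' @param min_group,sep_min as in [two_group_split()] (needed in both
#'   passes, hence explicit).
#' @return object of class `cohort_report_set`: list with `reports` (named
#'   list of `cohort_report`), `summary` (per-cohort data.frame), `totals`
#'   (counts over all samples), `percentages`, `mislabel_directions`,
#'   `reference_scales`, `pooled_medians`.
#' @export
classify_cohorts <- function(cohorts, panel = default_marker_panel(),
                             min_group = 2L, sep_min = 3, ...) {
  stopifnot(length(cohorts) >= 1)
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  panel <- validate_marker_panel(panel)

  spans <- stats::setNames(vector("list", nrow(panel)), panel$probe_id)
  meds_lo <- spans; meds_hi <- spans
  for (co in cohorts) {
    for (p in intersect(panel$probe_id, rownames(co$matrix))) {
      v <- co$matrix[p, ]
      if (sum(!is.na(v)) < 2) next
      sp <- two_group_split(v, min_group = min_group, sep_min = sep_min)
      if (sp$bimodal) {
        spans[[p]] <- c(spans[[p]], sp$median_high - sp$median_low)
        meds_lo[[p]] <- c(meds_lo[[p]], sp$median_low)
        meds_hi[[p]] <- c(meds_hi[[p]], sp$median_high)
      }
    }
  }
  reference_scales <- vapply(panel$probe_id, function(p) {
    if (length(spans[[p]])) stats::median(spans[[p]]) else NA_real_
  }, numeric(1))
  pooled_medians <- lapply(stats::setNames(panel$probe_id, panel$probe_id),
    function(p) {
      list(low = if (length(meds_lo[[p]])) stats::median(meds_lo[[p]]) else NA_real_,
           high = if (length(meds_hi[[p]])) stats::median(meds_hi[[p]]) else NA_real_)
    })

  reports <- lapply(names(cohorts), function(id) {
    co <- cohorts[[id]]
    classify_cohort(co$matrix, co$annotation, panel = panel,
                    min_group = min_group, sep_min = sep_min,
                    reference_scales = reference_scales,
                    pooled_medians = pooled_medians, cohort_id = id, ...)
  })
  names(reports) <- names(cohorts)

  summary_df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(cohort_id = r$cohort_id, n_samples = r$n_samples,
               t(r$counts), t(r$mislabel_directions),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  totals <- Reduce(`+`, lapply(reports, `[[`, "counts"))
  n_total <- sum(summary_df$n_samples)
  structure(list(
    reports = reports, summary = summary_df,
    n_samples = n_total, totals = totals,
    percentages = vapply(totals, pct_of, numeric(1), total = n_total),
    mislabel_directions = Reduce(`+`, lapply(reports, `[[`, "mislabel_directions")),
    reference_scales = reference_scales, pooled_medians = pooled_medians
  ), class = "cohort_report_set")
}

#' @export
print.cohort_report_set <- function(x, ...) {
  cat(sprintf("%d cohorts, %d samples\n", length(x$reports), x$n_samples))
  for (cat_ in report_categories) {
    cat(sprintf("  %-13s %5d (%.1f%%)\n", cat_, x$totals[[cat_]],
                x$percentages[[cat_]]))
  }
  flagged <- sum(x$summary$misclassified > 0)
  cat(sprintf("  cohorts with >=1 misclassified: %d of %d (%.1f%%)\n",
              flagged, nrow(x$summary), pct_of(flagged, nrow(x$summary))))
  invisible(x)
}

#' Write a cohort report to TSV or JSON
#'
#' Both formats are round-trippable via [read_cohort_report()] and print
#' percentages with one decimal. The TSV variant carries the summary in
#' `#key value` header lines above the per-sample verdict table.
#'
#' @param report a `cohort_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_cohort_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "cohort_report"))
  if (format == "json") {
    payload <- list(
      cohort_id = report$cohort_id,
      n_samples = report$n_samples,
      counts = as.list(report$counts),
      percentages = as.list(report$percentages),
      mislabel_directions = as.list(report$mislabel_directions),
      verdicts = report$verdicts
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    con <- try(file(path, "w"), silent = TRUE)
    if (inherits(con, "try-error")) abort("cannot write to %s", path)
    on.exit(close(con))
    writeLines(c(
      sprintf("#cohort_id\t%s", report$cohort_id),
      sprintf("#n_samples\t%d", report$n_samples),
      sprintf("#count_%s\t%d", report_categories, report$counts),
      sprintf("#pct_%s\t%.1f", report_categories, report$percentages),
      sprintf("#mislabel_%s\t%d", names(report$mislabel_directions),
              report$mislabel_directions)
    ), con)
    utils::write.table(report$verdicts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort report written by [write_cohort_report()]
#' @param path input path.
#' @param format `"tsv"` or `"json"`.
#' @return a `cohort_report` (summary fields recomputed from the verdict
#'   table and checked against the stored counts).
#' @export
read_cohort_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    verdicts <- as.data.frame(payload$verdicts, stringsAsFactors = FALSE)
    report <- new_cohort_report(payload$cohort_id, verdicts)
    stored <- unlist(payload$counts)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t", fixed = TRUE))
    meta <- stats::setNames(kv[, 2], kv[, 1])
    verdicts <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                                  stringsAsFactors = FALSE)
    report <- new_cohort_report(meta[["cohort_id"]], verdicts)
    stored <- as.integer(meta[paste0("count_", report_categories)])
    names(stored) <- report_categories
  }
  if (!identical(as.integer(stored[report_categories]),
                 as.integer(report$counts[report_categories]))) {
    abort("cohort report %s: stored counts disagree with verdict table", path)
  }
  report
}

#' Scatter coordinates of the per-sample sex evidence
#'
#' One row per sample with the mean normalized value of the
#' female-evidence (X chromosome) probes on x and of the male-evidence
#' (Y chromosome) probes on y, plus the verdict category. Females cluster
#' near (1, 0), males near (0, 1); misclassified samples sit in the wrong
#' cloud. A probe missing for a sample is dropped from that sample's mean;
#' a sample missing every marker gets missing coordinates and is reported
#' unconfident.
#'
#' @param report a `cohort_report` from [classify_cohort()] (needs the
#'   `normalized` and `probes` elements).
#' @param path optional TSV output path.
#' @return data.frame with columns `sample_id`, `x`, `y`, `category`.
#' @export
export_sex_scatter <- function(report, path = NULL) {
  stopifnot(inherits(report, "cohort_report"), !is.null(report$normalized))
  probes <- report$probes
  fm <- report$normalized[probes$probe_id[probes$evidence_sex == "female"], ,
                          drop = FALSE]
  mm <- report$normalized[probes$probe_id[probes$evidence_sex == "male"], ,
                          drop = FALSE]
  mean_or_na <- function(m) {
    if (nrow(m) == 0) return(rep(NA_real_, ncol(m)))
    out <- colMeans(m, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  coords <- data.frame(
    sample_id = colnames(report$normalized),
    x = unname(mean_or_na(fm)), y = unname(mean_or_na(mm)),
    category = report$verdicts$category[
      match(colnames(report$normalized), report$verdicts$sample_id)],
    stringsAsFactors = FALSE
  )
  coords$category[is.na(coords$x) & is.na(coords$y)] <- "unconfident"
  if (!is.null(path)) {
    utils::write.table(coords, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  coords
}
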