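#' Read a probe-by-sample expression matrix from a tab-delimited file
#'
#' Expression values are expected on a log-like scale (as distributed in
#' processed public repositories); the package never re-summarizes raw
#' intensities. The first column holds probe IDs, the header row sample
#' IDs. Two dialects are supported:
#'
#' * `plain`: a regular TSV.
#' * `series_matrix`: the GEO series-matrix distribution format. Lines
#'   starting with `!` are metadata and are ignored; the expression table
#'   is delimited by `!series_matrix_table_begin` / `!series_matrix_table_end`
#'   guard lines when present. Quoted identifiers are unquoted.
#'
#' Non-numeric cells become `NA` (explicit missing, never silently 0).
#'
#' @param path path to the file.
#' @param dialect `"plain"` or `"series_matrix"`.
#' @return numeric matrix with unique probe row names and unique sample
#'   column names.
#' @export
read_expression_tsv <- function(path, dialect = c("plain", "series_matrix")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("expression file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) >= 1 && length(end) >= 1) {
      lines <- lines[(begin[1] + 1L):(end[1] - 1L)]
    }
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("expression table in %s is empty", path)

  df <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                          quote = "\"", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) abort("expression table in %s has no sample columns", path)
  probe_ids <- trimws(df[[1]])
  sample_ids <- trimws(colnames(df)[-1])
  dup_p <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup_p)) {
    abort("duplicate probe ID(s): %s", paste(dup_p, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    abort("duplicate sample ID(s): %s", paste(dup_s, collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(probe_ids, sample_ids))
  validate_expression_matrix(vals)
}

#' Validate an expression matrix
#'
#' Checks the container contract: a numeric matrix with unique, non-empty
#' probe row names and sample column names; all non-missing values finite.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly unchanged, or a hard error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("expression matrix must be a numeric matrix")
  if (nrow(x) == 0 || ncol(x) == 0) abort("expression matrix is empty")
  pn <- rownames(x); sn <- colnames(x)
  if (is.null(pn) || anyNA(pn) || any(!nzchar(pn))) abort("probe IDs missing or empty")
  if (is.null(sn) || anyNA(sn) || any(!nzchar(sn))) abort("sample IDs missing or empty")
  if (anyDuplicated(pn)) abort("duplicate probe ID(s): %s",
                               paste(unique(pn[duplicated(pn)]), collapse = ", "))
  if (anyDuplicated(sn)) abort("duplicate sample ID(s): %s",
                               paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (any(is.infinite(x))) abort("expression matrix contains non-finite values")
  x
}

#' Write an expression matrix as plain TSV
#'
#' Values are formatted with 15 significant digits so a write/read
#' round trip reproduces them to double precision.
#'
#' @param x numeric matrix with probe row names and sample column names.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression_matrix(x)
  fmt <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  fmt[is.na(x)] <- "NA"
  df <- data.frame(ID_REF = rownames(x), fmt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample annotation table
#'
#' Expects tab-delimited columns `sample_id` and `sex`; optional `time`
#' and `event` columns carry right-censored survival data. Sex labels are
#' case-normalized through a synonym map; anything unrecognized becomes
#' `unknown` with a warning (the package never guesses a sex label).
#'
#' @param path path to the TSV file.
#' @param synonyms named character vector mapping lower-cased raw labels to
#'   canonical labels; see [default_sex_synonyms()].
#' @return data.frame with columns `sample_id`, `sex` and, when present in
#'   the file, numeric `time` and integer `event`.
#' @export
read_annotation_tsv <- function(path, synonyms = default_sex_synonyms()) {
  if (!file.exists(path)) abort("annotation file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  if (!"sample_id" %in% names(df)) {
    abort("annotation file %s lacks a 'sample_id' column", path)
  }
  if (!"sex" %in% names(df)) abort("annotation file %s lacks a 'sex' column", path)
  out <- data.frame(
    sample_id = trimws(as.character(df$sample_id)),
    sex = normalize_sex_labels(df$sex, synonyms),
    stringsAsFactors = FALSE
  )
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup)) abort("duplicate sample ID(s) in annotation: %s",
                         paste(dup, collapse = ", "))
  if ("time" %in% names(df)) out$time <- as.numeric(df$time)
  if ("event" %in% names(df)) out$event <- as.integer(df$event)
  out
}

#' Sex labels for a given sample set
#'
#' Pairs an annotation table with the samples of a matrix. Samples absent
#' from the annotation get `unknown`. If the annotation is non-empty but
#' shares no IDs with the samples at all, that is almost certainly a
#' pairing mistake and raises an error listing the difference.
#'
#' @param sample_ids character vector of sample IDs (matrix columns).
#' @param annotation data.frame as from [read_annotation_tsv()], or `NULL`.
#' @return named character vector over `sample_ids` with values in
#'   `sex_levels()`.
#' @export
annotation_for <- function(sample_ids, annotation = NULL) {
  labels <- stats::setNames(rep("unknown", length(sample_ids)), sample_ids)
  if (is.null(annotation) || nrow(annotation) == 0) return(labels)
  hit <- intersect(annotation$sample_id, sample_ids)
  if (length(hit) == 0) {
    abort(paste0(
      "annotation and expression matrix share no sample IDs; ",
      "annotation-only: %s; matrix-only: %s"),
      paste(utils::head(annotation$sample_id, 5), collapse = ", "),
      paste(utils::head(sample_ids, 5), collapse = ", "))
  }
  m <- match(sample_ids, annotation$sample_id)
  labels[!is.na(m)] <- annotation$sex[m[!is.na(m)]]
  labels
}

#' Default marker panel for the male-female classifier
#'
#' Four Affymetrix HG-U133 probe sets: two for XIST (X chromosome, high in
#' females, female evidence) and one each for RPS4Y1 and DDX3Y
#' (Y chromosome, expressed in males only, male evidence). `default_cut`
#' holds fixed deployment-mode cut points on the normalized scale, used
#' only when [classify_cohort()] is told not to derive cohort-specific
#' cuts.
#'
#' @return data.frame with columns `probe_id`, `gene`, `chromosome`,
#'   `evidence_sex`, `default_cut`.
#' @export
default_marker_panel <- function() {
  panel <- data.frame(
    probe_id = c("221728_x_at", "214218_s_at", "201909_at", "205000_at"),
    gene = c("XIST", "XIST", "RPS4Y1", "DDX3Y"),
    chromosome = c("X", "X", "Y", "Y"),
    evidence_sex = c("female", "female", "male", "male"),
    default_cut = c(0.389, 0.385, 0.431, 0.276),
    stringsAsFactors = FALSE
  )
  validate_marker_panel(panel)
}

#' Validate a marker panel
#' @param panel data.frame with columns `probe_id`, `gene`, `chromosome`,
#'   `evidence_sex`, and optionally `default_cut`.
#' @return the panel, or a hard error.
#' @export
validate_marker_panel <- function(panel) {
  need <- c("probe_id", "gene", "chromosome", "evidence_sex")
  miss <- setdiff(need, names(panel))
  if (length(miss)) abort("marker panel lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(panel$probe_id)) abort("duplicate probe ID(s) in marker panel")
  if (!all(panel$chromosome %in% c("X", "Y"))) abort("marker chromosome must be X or Y")
  if (!all(panel$evidence_sex %in% c("female", "male"))) {
    abort("marker evidence_sex must be 'female' or 'male'")
  }
  if (!"default_cut" %in% names(panel)) panel$default_cut <- NA_real_
  panel
}

#' Read a marker panel from TSV
#' @param path tab-delimited file with the columns of [default_marker_panel()].
#' @return validated marker panel data.frame.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) abort("marker panel file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_marker_panel(df)
}

#' Benchmark cohort composition by cancer type
#'
#' Sample counts of the 45-cohort reference collection, aggregated into
#' seven tissue/disease groups (the scale at which the published totals
#' are reported): 4913 patients, 3034 females, 1879 males.
#'
#' @return data.frame with columns `type`, `n_cohorts`, `n_samples`,
#'   `n_female`, `n_male`.
#' @export
cohort_type_summary <- function() {
  data.frame(
    type = c("NSCLC", "Colon cancer", "Other cancer", "Non-cancer",
             "Breast cancer", "Ovarian cancer", "Prostate cancer"),
    n_cohorts = c(10L, 7L, 5L, 7L, 8L, 4L, 4L),
    n_samples = c(1338L, 769L, 200L, 408L, 1373L, 426L, 399L),
    n_female = c(594L, 358L, 64L, 219L, 1373L, 426L, 0L),
    n_male = c(744L, 411L, 136L, 189L, 0L, 0L, 399L),
    stringsAsFactors = FALSE
  )
}

#' Per-cohort composition of the 45-cohort reference collection
#'
#' Detailed female/male sample counts per cohort, used by
#' [benchmark_cohort_configs()] to simulate a collection with a realistic
#' mix of mixed-sex, all-female and all-male cohorts (10 NSCLC, 7
#' colorectal, 5 other-cancer, 7 non-cancer, 8 breast, 4 ovarian, 4
#' prostate). Per-type totals in this table differ slightly from
#' [cohort_type_summary()] (which carries the published group totals);
#' only the mix of cohort sizes and sex ratios matters for simulation.
#'
#' @return data.frame with columns `cohort_id`, `type`, `n_female`, `n_male`.
#' @export
cohort_table <- function() {
  tab <- rbind(
    c("GSE37745", "NSCLC", 89, 107), c("Shedden", "NSCLC", 220, 223),
    c("GSE31547", "NSCLC", 36, 14), c("GSE29013", "NSCLC", 17, 38),
    c("GSE14814", "NSCLC", 23, 67), c("GSE4573", "NSCLC", 47, 82),
    c("GSE31210", "NSCLC", 109, 95), c("GSE19188", "NSCLC", 23, 59),
    c("GSE31546", "NSCLC", 14, 3), c("GSE10445", "NSCLC", 16, 56),
    c("GSE4107", "Colon cancer", 12, 10), c("GSE33113", "Colon cancer", 48, 42),
    c("GSE31595", "Colon cancer", 22, 15), c("GSE12945", "Colon cancer", 28, 34),
    c("GSE14333", "Colon cancer", 106, 120), c("GSE17536", "Colon cancer", 81, 96),
    c("GSE17537", "Colon cancer", 29, 26),
    c("GSE4271", "Other cancer", 32, 68), c("GSE31684", "Other cancer", 25, 68),
    c("GSE34111", "Other cancer", 6, 24), c("GSE5720", "Other cancer", 24, 30),
    c("GSE42952", "Other cancer", 9, 14),
    c("GSE19027", "Non-cancer", 11, 48), c("GSE17913", "Non-cancer", 38, 40),
    c("GSE23343", "Non-cancer", 7, 10), c("GSE25462", "Non-cancer", 28, 22),
    c("GSE7821", "Non-cancer", 28, 12), c("GSE20950", "Non-cancer", 27, 12),
    c("GSE24427", "Non-cancer", 80, 45),
    c("GSE11121", "Breast cancer", 200, 0), c("GSE2034", "Breast cancer", 286, 0),
    c("TRANSBIG", "Breast cancer", 280, 0), c("GSE16446", "Breast cancer", 114, 0),
    c("GSE20194", "Breast cancer", 247, 0), c("GSE20271", "Breast cancer", 139, 0),
    c("GSE22093", "Breast cancer", 47, 0), c("GSE23988", "Breast cancer", 60, 0),
    c("Bild", "Ovarian cancer", 133, 0), c("GSE14764", "Ovarian cancer", 80, 0),
    c("GSE19829", "Ovarian cancer", 28, 0), c("GSE26712", "Ovarian cancer", 185, 0),
    c("GSE17951", "Prostate cancer", 0, 153), c("GSE25136", "Prostate cancer", 0, 79),
    c("GSE3325", "Prostate cancer", 0, 19), c("GSE8218", "Prostate cancer", 0, 148)
  )
  data.frame(
    cohort_id = tab[, 1], type = tab[, 2],
    n_female = as.integer(tab[, 3]), n_male = as.integer(tab[, 4]),
    stringsAsFactors = FALSE
  )
}
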