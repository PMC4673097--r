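#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Report-style rounding: 0.05 at the last kept digit always rounds up
#' (base R's `round()` rounds half to even, which would print 16.65 as 16.6).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half-up to one decimal
#' @param count,total non-negative integers; `total = 0` yields 0.
#' @return numeric scalar in `[0, 100]`.
#' @keywords internal
pct_of <- function(count, total, digits = 1) {
  if (total == 0) return(0)
  round_half_up(100 * count / total, digits)
}

# stop() with sprintf-style formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Canonical sex labels
#'
#' The three-valued label set used throughout: `female`, `male`, `unknown`.
#' @return character vector of the three labels.
#' @export
sex_levels <- function() c("female", "male", "unknown")

#' Default synonym map for sex labels
#'
#' Maps common annotation spellings onto the canonical labels. Matching is
#' case-insensitive and anything not covered becomes `unknown` (never a
#' guess). Extend or replace via the `synonyms` argument of
#' [read_annotation_tsv()].
#'
#' @return named character vector: names are lower-cased raw labels, values
#'   canonical labels.
#' @export
default_sex_synonyms <- function() {
  map <- c(
    "f" = "female", "female" = "female", "fem" = "female", "w" = "female",
    "woman" = "female", "girl" = "female",
    "m" = "male", "male" = "male", "man" = "male", "boy" = "male",
    "unknown" = "unknown", "na" = "unknown", "n/a" = "unknown",
    "none" = "unknown", "unk" = "unknown", "u" = "unknown"
  )
  c(map, stats::setNames("unknown", "")) # empty cell is also 'unknown'
}

normalize_sex_labels <- function(x, synonyms = default_sex_synonyms(),
                                 warn = TRUE) {
  key <- tolower(trimws(as.character(x)))
  key[is.na(x)] <- "na"
  out <- unname(synonyms[key])
  bad <- is.na(out)
  if (any(bad) && warn) {
    warnf("unrecognized sex label(s) set to 'unknown': %s",
          paste(unique(key[bad]), collapse = ", "))
  }
  out[bad] <- "unknown"
  out
}
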