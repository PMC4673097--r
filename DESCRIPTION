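Package: swapqc
Title: Sex-Label and Duplicate-Sample Quality Control for Gene Expression Cohorts
Version: 0.1.0
Authors@R:
    person("swapqc", "maintainers", email = "swapqc@example.org", role = c("aut", "cre"))
Description: Flags sex-misannotated samples in microarray or RNA-seq style
    expression cohorts with a robust male-female classifier built on a small
    panel of sex-specific transcripts (XIST for female evidence, RPS4Y1 and
    DDX3Y for male evidence), after a per-probe, per-cohort linear
    normalization that makes evidence scores comparable across studies.
    Also detects samples measured more than once via pairwise Pearson
    correlation of high-variance probes with largest-gap thresholding, and
    quantifies the downstream impact of flagged samples on univariate Cox
    survival screens (significance churn). Includes a synthetic-cohort
    generator with known ground truth for mislabels, duplicates and
    prognostic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
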