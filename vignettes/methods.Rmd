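---
title: "Auditing sex annotations and duplicate measurements in expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing sex annotations and duplicate measurements in expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapqc)
```

## The problem

Large transcriptomic collections accumulate annotation errors: tubes get
swapped between patients, the same mRNA is measured twice and filed under two
different IDs, clinical tables get shifted by a row. Most of these errors are
invisible after the fact — but a sample's transcriptome encodes its donor's
sex very reliably. XIST (expressed from the inactive X chromosome) is high in
females and silent in males; RPS4Y1 and DDX3Y (Y chromosome) are expressed in
males only. A sample whose marker profile contradicts its sex label is, with
high probability, annotated with another patient's record. Roughly half of
all identity swaps in a sex-balanced cohort cross sexes, so the rate of
flagged samples is a lower bound — the true mix-up rate is at least about
twice as high.

`swapqc` implements this audit as three cooperating analyses:

1. a **male–female classifier** over a four-probe marker panel, built on
   robust statistics so that the very outliers it hunts cannot distort its
   fit;
2. a **duplicate detector** that correlates all sample pairs over
   high-variance probes and splits the ordered correlations at the largest
   admissible gap;
3. an **impact analysis** that quantifies how much a univariate Cox survival
   screen changes when flagged samples are removed ("significance churn").

## The classifier, step by step

### Robust primitives

For each marker probe in each cohort, expression values are split into a low
and a high group by an exhaustive scan of the $n-1$ thresholds between
consecutive sorted values, minimizing the pooled within-group sum of squares
(optimal two-means in one dimension; deterministic, no seed). Each group gets
a robust location (median) and scale — the Rousseeuw–Croux $Q_n$, the $k$-th
smallest pairwise absolute difference with $k = \binom{h}{2}$,
$h = \lfloor n/2\rfloor + 1$, scaled by the asymptotic normal-consistency
constant 2.2219. No finite-sample correction is applied; at the group sizes
the pipeline sees (tens to hundreds) the correction is a few percent on a
quantity that only sets a far-tail threshold, and omitting it keeps the
estimator bit-for-bit checkable against its order-statistic definition. The
split counts as *bimodal* when the separation
$(\mathrm{med}_{hi}-\mathrm{med}_{lo})/(Q_{n,lo}+Q_{n,hi}+\varepsilon)$
reaches `sep_min` (default 3; $\varepsilon = 10^{-12}\max(1,|\mathrm{med}_{hi}|)$
keeps the ratio defined for zero-scale groups). Both groups must hold at
least `min_group = 2` samples — small enough to resolve a two-sample
minority, large enough that a single outlier can never found its own group.

### Normalization

Absolute intensities shift substantially between studies, so evidence
thresholds are only meaningful after normalization. For a bimodal probe the
affine map $y = a x + b$ with $a = 1/(\mathrm{med}_{hi}-\mathrm{med}_{lo})$,
$b = -a\,\mathrm{med}_{lo}$ places the group medians exactly at 0 and 1.
Single-sex cohorts (breast, ovarian, prostate collections) have no second
group; there the probe's expected side is known from its evidence direction —
a Y marker in an all-female cohort *is* the low group, an X marker there the
high group — and the lone group's median is anchored at 0 or 1 with slope
$1/\text{reference scale}$ (pooled from the bimodal cohorts of the run, else
1). Annotated sex orients the group as a whole (requiring a
`single_sex_majority` of 90% so a few mislabels cannot flip the
orientation); it never scores individual samples.

A cohort with *no* labels and a unimodal probe can only be oriented by
comparing its raw median to the pooled group medians of other cohorts. That
comparison is inherently not invariant to cohort-level affine shifts — the
very artefact normalization exists to remove — so this last-resort path is
restricted to completely unlabelled cohorts and documented as best-effort. A
*labelled* cohort that fails both the bimodality and the single-sex test
contributes no evidence for that probe ("failed" provenance) rather than
guessing; this choice is what makes the end-to-end pipeline exactly
invariant under per-cohort transforms $x \mapsto ax+b$, $a>0$, a property
the test suite asserts verbatim.

### Evidence and verdicts

A normal distribution is fitted to the low group (median, $Q_n$) and the
probe's cut point is its `level` = 0.999 quantile. A sample whose normalized
value lies *strictly* above the cut is inconsistent with the low group: its
evidence score for that marker is 1. Ties at the cut and missing values give
0 — absence of evidence. A zero $Q_n$ makes the cut non-informative and
disables the probe in that cohort. (The published deployment table prints
thresholds at the "99% quantile" while the accompanying text says 99.9%;
the level is a single configurable parameter, defaulting to 0.999, and the
fixed published thresholds are available via `cut_mode = "panel"`.) When the
lone group of a single-sex cohort is the *high* group there is no low group
to fit; the mirrored lower-tail bound
$\mathrm{med}_{hi} - z(\mathrm{level})\,Q_{n,hi}$ is used instead, so typical
members score 1 and low outliers (the wrong-sex intruders) score 0. This
mirror keeps the evidence affine-invariant, which a fixed external threshold
cannot.

The combination rule over (two female, two male) evidence scores: **male**
iff at least one male score and no female score; **female** by symmetry;
everything else — conflict or silence — **unconfident**. Of the 16 score
combinations, 3 map to male, 3 to female, 10 to unconfident. Against the
annotation, each sample becomes *correct*, *misclassified*, *unconfident*,
or *unannotated* (a confident prediction with no label to contradict — an
extension, since the published categories assume labels exist).

## Duplicate detection

Duplicates are found on raw values, before any normalization: the 1000
highest-variance probes (sample variance, $n-1$ denominator; probes with any
missing value excluded) are correlated between all sample pairs (Pearson),
and the descending correlations are split at the largest gap. The naked
largest-gap rule fires on every cohort, including clean ones, so two guards
make a split admissible: the upper block must lie entirely at or above
`r_min` (default 0.95 — observed duplicates exceed 0.99 while technical
re-runs of *distinct* samples stay at or below about 0.987) and may hold at
most `max_frac` (default 10%) of all pairs, except that the single top pair
is always size-admissible. Setting `r_min = -1`, `max_frac = 1` recovers the
literal rule. Pairs are the primary output (a triplicate is three pairs);
connected components are reported as a convenience.

## Impact on survival screens

Per probe, a univariate Cox proportional-hazards model (expression as the
single covariate, Efron tie handling, Wald p-value) is fitted before and
after removing flagged samples; the screen uses an unadjusted threshold
(default $p < 0.01$, no FDR correction — deliberately, to match how such
per-gene screens are usually summarized). `churn()` reports the percentage
of originally significant probes that lost significance and the percentage
newly significant, both relative to the original significant set. Probes
that are skipped (zero variance) or fail to converge are excluded from both
sets symmetrically.

## What the generator emulates — and what it does not

`simulate_cohort()` produces the world the method assumes: marker probes
with bimodal sex-specific expression — Normal(10, 0.4²) in the expressing
sex, Normal(6, 0.4²) otherwise, a plausible log2 intensity range for
strongly sex-specific array probes, giving a 10-$Q_n$-unit separation —
background probes i.i.d. N(0,1), and a cohort-level affine transform
(benchmark: shifts uniform on [−3, 3], scales on [0.8, 1.25], the order of
inter-study shifts seen in public collections). Annotation errors are
injected as exactly `round(rate * n)` cross-sex label flips (default
benchmark rate 1%, the order of magnitude reported for public cohorts);
duplicates as a copy of an existing sample's measured profile plus
N(0, 0.01²) technical noise, filed under a new ID carrying a randomly
chosen *other* patient's label. The 45-cohort benchmark reproduces the
reference collection's mix of cohort sizes and sex ratios, including the
all-female and all-male cohorts that exercise the single-group paths.

Survival times are exponential with log hazard linear in designated
prognostic probes (effects in log-hazard-ratio per SD of expression);
mislabeled and duplicate samples draw their survival from another random
sample's linear predictor, because an annotation swap attaches the clinical
record of a *different* patient — this is the mechanism that makes flagged
samples disproportionately damaging to a survival screen. The churn
experiment fixes n = 150, 5% mislabels, 25 prognostic probes at
$|\log HR| = 1$ per SD, 30% censoring: a small cohort with a realistic
(upper-range) error load, sized so twenty paired replicates run in seconds.

The generator does *not* emulate: probe-level correlation structure
(background probes are independent, so duplicate correlations are cleaner
than on real arrays); intermediate or skewed marker distributions (XIST in
tumors with X-chromosome aberrations can be genuinely ambiguous);
platform-specific missingness patterns; or same-sex swaps' effect on sex
markers (by construction invisible — the suite asserts this, which is the
formal content of the "at least twice as high" caveat). A green test
therefore establishes correctness of the algorithms under their stated
assumptions, not field performance on any particular platform.

## Numerical choices

- $Q_n$ is computed exactly (bit-identical to brute-force enumeration of
  pairwise differences) at every n; beyond n = 1500 a value-axis bisection
  with a two-pointer pair count replaces the O(n²) difference matrix.
- The two-group split scans thresholds only between *distinct* consecutive
  values, so tie blocks are never cut; ties in the objective resolve to the
  smallest admissible split index.
- Report percentages round half *away from zero* to one decimal (base R's
  round-half-even would print 9/54 as 16.6%, not the conventional 16.7%).
- Expression TSVs are written with 15 significant digits; write/read round
  trips are exact to double precision. Non-numeric cells parse to `NA`,
  never 0.
- Sex labels pass through a configurable synonym map; anything unrecognized
  becomes `unknown` with a warning — the package never guesses.

## Known limitations

- Inputs are assumed to be summarized, log-scale expression matrices (the
  usual form of processed public data); raw intensity preprocessing is out
  of scope, and no re-summarization is attempted.
- Cohorts of fewer than ~6 samples per sex stress the bimodality test; a
  two-sample minority is resolvable, a singleton is not (by design:
  `min_group = 2`).
- Completely unlabelled unimodal cohorts are oriented by raw-scale proximity
  to pooled references and are the one path without an affine-invariance
  guarantee.
- The duplicate screen assumes duplicates are rarer than `max_frac` of all
  pairs; a cohort that is mostly duplicates would defeat the gap guard.
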