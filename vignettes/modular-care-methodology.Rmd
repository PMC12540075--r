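---
title: "From demand assessment to modular service bundles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From demand assessment to modular service bundles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carebundles)
```

`carebundles` operationalizes a demand-driven modular model of community
home-based older adult care. This vignette documents the statistical
procedure, the assumptions behind it, the design choices made where the
methodology leaves the details open, and what the package's simulation-based
tests do and do not establish.

## The instrument and its data model

Demand is measured by a 19-item questionnaire on a 5-point Likert scale
(1 = not needed at all … 5 = strongly needed), grouped into five dimensions
that map one-to-one onto the model's service modules: life assistance
(5 items), medical care (6), spiritual/cultural engagement (3), rights
protection (3) and age-friendly modifications (2). A survey record is one
row: eight demographic factors plus the 19 item scores
(`item_01`–`item_19`, layout in `item_dimension_map()`).

A person's **dimension score** is the unweighted mean of the dimension's
items. This aggregation is implied by the granularity of typical reported
medians (values like 19/6 and 10/3 only arise from unweighted 6- and 3-item
means); item weighting within a dimension is deliberately out of scope.
The **score rate**, `100 × mean score / 5`, expresses a cohort's aggregate
demand as a percentage of the scale maximum. Field reports often print
score rates without defining them; the mean-over-maximum convention is
documented here precisely because it is a convention, and it is the only
place the package turns scores into percentages.

## The synthetic cohort generator

No raw respondent data are distributable, so the package generates cohorts
that emulate the study conditions: the demographic marginals of a
provincial survey of 331 community-dwelling older adults (e.g. 17.22%
living alone, 19.64% disabled, 71.00% with chronic disease, age bands at
32.63/22.36/33.23/11.78%) and a latent demand structure whose true effects
are the packaged reference coefficients (`care_coefficients()`).

The latent model: for respondent *i* and dimension *d*,

* latent(d) = intercept(d) + Σ effects of the non-reference categories the
  respondent carries + N(0, `noise_sd`),
* each item adds independent N(0, `noise_sd`) to its dimension's latent,
* the item score is the latent rounded **half away from zero** and clamped
  to [1, 5].

Design choices, fixed once:

* **Independent factors.** Only marginal prevalences are known, so factors
  are drawn independently. One joint-structure override exists
  (`p_living_alone_no_spouse`) for the plausible no-spouse × living-alone
  association; it is off by default.
* **`noise_sd = 0.6`.** No inter-item correlations or score variances are
  reported anywhere, so the noise level is a free parameter. 0.6 was chosen
  a priori as giving dimension medians/IQRs with spread comparable to the
  reference descriptives (medians near 3–3.5, IQR widths near 1); it is
  configurable and all calibration-sensitive tests state it explicitly.
* **Shared dimension latent + per-item noise.** Items within a dimension
  share the dimension latent, so dimension means are less noisy than
  single items — mirroring the multi-item design of the instrument.
* **Rounding half away from zero.** Base R's round-half-to-even would bias
  the discretized score distribution at the .5 boundaries; the convention
  is stated because it changes parameter-recovery behaviour.
* **Reproducible substreams.** Respondent *i* draws from a substream
  seeded `seed + i` (8 uniforms for the profile, then 24 normals for the
  scores, in fixed order). Cohorts are therefore byte-identical under a
  seed, and the first *m* rows of a size-*n* cohort equal the size-*m*
  cohort — partial regeneration cannot silently change existing records.

What the generator does **not** emulate: item-level correlation structure
beyond the shared latent, ordinal response styles (extreme/acquiescent
responding), convenience-sampling selection effects, and any joint
demographic structure beyond the single override. Tests that pass on these
cohorts therefore establish the correctness and calibration of the
*machinery* under the stated data-generating process, not the field
validity of the survey results.

## Screening and regression

The association analysis reproduces a conventional survey-statistics plan:

1. **Univariate screen.** Dimension scores are compared across each
   factor's groups with the Mann–Whitney test (two groups; Z statistic
   from mid-ranks with tie-corrected variance and a two-sided normal p)
   or the Kruskal–Wallis test (≥ 3 groups; tie-corrected H,
   χ² on k − 1 df, via `stats::kruskal.test()`). The normal approximation
   is used at all sample sizes because that is what the reported Z values
   correspond to; an exact enumeration path
   (`mann_whitney_exact_p()`) exists for small samples and as a test
   oracle. Factors pass the screen when *p* is **strictly** below α = 0.05;
   no multiple-testing correction is applied, faithfully reproducing the
   per-test α of the source methodology.
2. **Enter-method regression.** Each dimension score is regressed by OLS on
   the screened factors, all entered simultaneously as 0/1 dummies against
   fixed reference categories (age 60–65, low education, with spouse, ≤ 1
   child, not living alone, fully independent, no chronic disease, income
   0–1500). Reference rows are emitted with B = 0. A rank-deficient design
   is an error that names the collinear columns.
3. **Diagnostics.** Tolerance and VIF are computed per dummy column from
   auxiliary regressions (`VIF_j = 1/(1 − R²_j)`), matching how
   survey software reports collinearity for dummy-coded models (per-factor
   generalized VIFs would not be comparable to the reference table).
   Perfect collinearity yields an infinite, flagged VIF rather than an
   error. The Durbin–Watson statistic is computed over residuals in input
   row order — the methodology does not define an ordering, so the row
   order of the data is the documented choice. Diagnostics are reported,
   not gated: no fit is rejected automatically.

Two-group Kruskal–Wallis requests are refused (use the Mann–Whitney path);
the classical identity H = Z² for two tie-free groups is verified in the
test suite through an independent route.

## The bundle engine

* **Activation.** `α = 1` iff the dimension score is ≥ the module's
  threshold; equality activates. Thresholds are the cohort P75 of each
  dimension, computed with the **(n + 1)p position rule** with linear
  interpolation (type 6 in `stats::quantile()`), the convention of the
  statistics environment behind the reference results. This rule is not
  exactly invariant under duplicating a cohort (the interpolation fractions
  at positions 0.75(n + 1) and 0.75(2n + 1) differ unless they align);
  the property holds exactly when n is divisible by 4, which is how the
  suite tests it. The rule name is stored in the threshold provenance so
  alternates can be swapped.
* **Weighting.** `β` sums the **unstandardized B** coefficients of the
  module's significant predictors (p < 0.05) possessed by the person.
  Standardized Betas are carried in the coefficient table but do not enter
  β: the reference worked-example sums (1.277, 1.418, 1.021) are sums of B
  values, which fixes the reading. Reference categories and non-significant
  predictors contribute 0; unstated attributes default to reference.
* **Full rule vs. explicit sets.** Applied to a full profile, the stated
  rule includes *every* significant possessed coefficient — e.g. a chronic
  disease adds its life-assistance B (0.170) — whereas published worked
  examples sometimes enumerate a narrower predictor set. `build_bundles()`
  applies the full rule; `bundle_from_scores()` and the `predictor_sets`
  argument accept explicit sets so stated examples reproduce exactly.
* **The bundle is a weighted set, not a number.** `Sᵢ = Σ α·β·Mₖ` is
  symbolic: summing weights across unlike modules has no interpretation,
  so the engine returns per-module (α, β) rows rather than a scalar.
* **Tiers.** Tier-1 priority = age ≥ 71 **or** living alone **or**
  disabled. The criteria are listed as a group of priority populations, so
  the union reading is used; the triggering attributes are reported per
  person so any stricter conjunction can be recovered downstream.

## Monitoring with the matching index

`DSMI = (actual coverage / expected coverage) × satisfaction`. The three
operands are not defined operationally in the source methodology; the
package fixes them as fractions in [0, 1] — delivered over planned service
units across activated modules, the planned demand-coverage target, and
mean 5-point satisfaction divided by 5 — and documents them as
conventions. DSMI is not clamped above 1: over-delivery with high
satisfaction can exceed 1 and only the low side matters. The trigger is
inclusive at the boundary: DSMI ≤ 0.8 recombines, 0.8 + ε does not.

`run_monitor_cycle()` processes a delivery stream period by period (at most
`max_iter` periods), invoking a re-bundling hook on every triggered period
— typically a closure over `build_bundles()` with refreshed scores and
thresholds. If the cap is reached while still triggering, the decision is
flagged unresolved rather than looping further. Escalation policies beyond
re-bundling (provider capacity, cost) are out of scope. Whether the index
is tracked per person, per module or per community is likewise unspecified
upstream; the package evaluates it per record, which supports any of the
three by grouping.

## Numerical conventions and degenerate inputs

* Reported percentages (score rates, response rates) round half away from
  zero to 2 decimals.
* Percentile positions are clamped to [1, n]; a single-respondent cohort
  returns its own scores as thresholds.
* Empty cohorts, empty test groups, unknown dimensions or predictors, and
  `expected_coverage = 0` are errors, not NAs.
* All-tied samples give Z = 0 / H = 0 with p = 1 (no evidence of shift).
* The screen at exactly p = α excludes (strict inequality).

## Problem sizes used by the verification suite

The test suite sizes its simulations as follows (all seeded):

* **Parameter recovery**: one cohort of n = 20,000 with the reference
  effects and `noise_sd = 0.6`; every coefficient fitted on the latent
  dimension scores must lie within ±0.05 of truth, with VIF < 5 and
  tolerance > 0.1 throughout — at this size the Monte-Carlo standard error
  of the rarest dummy's coefficient is ≈ 0.013, so ±0.05 is a ≈ 4σ band.
* **Type-I error**: 10,000 null cohorts (all effects zero) of n = 100;
  Mann–Whitney on the chronic-disease split and Kruskal–Wallis over the
  four age bands must reject at 0.05 ± 0.01. n = 100 with the default
  marginals gives expected group sizes (29/71 and 33/22/33/12) large
  enough for the tie-corrected normal/χ² approximations to hold their
  level on 21-point discrete dimension scores.
* **Exact-oracle equivalence**: enumeration over all rank assignments for
  combined n ≤ 8; H = Z² verified at n ≥ 30 per group without ties.

## Known limitations

* The reference coefficient table is transcribed at printed precision
  (3 decimals); its tolerance/VIF pairs are reciprocal only to that
  precision, and downstream β sums inherit the printed rounding.
* Subgroup test statistics and score rates of the original survey are not
  reproducible without its raw records; the package verifies the machinery
  on synthetic cohorts with known truth instead.
* The generator's independence assumptions understate real demographic
  clustering; collinearity among dummies (and hence VIF) is milder in
  synthetic cohorts than in field data.
* The DSMI operands are conventions; deployments with different delivery
  accounting should redefine them consistently before comparing values to
  the 0.8 trigger.
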