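---
title: "Stratified metabolite signatures and classification consistency: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified metabolite signatures and classification consistency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosig)
```

## The problem

Plasma lysophosphatidylcholine (lysoPC) and phosphatidylcholine (PC)
concentrations differ between patients with advanced knee osteoarthritis
(OA) and healthy volunteers (HV), but individual effects are small
(univariate AUCs around 0.6--0.75) and confounded by age, sex and BMI.
`metabosig` implements a workflow for this setting: stratify the cohort
demographically, select per-stratum metabolite *signatures* by a bootstrap
criterion that rewards out-of-sample consistency rather than in-sample fit,
and then choose among multivariate classifiers by how little they overfit —
the gap between bootstrap training and test AUCs — rather than by the
training AUC itself.

The pipeline (`run_pipeline()`) runs: batch adjustment and log(x+1)
transformation; a multivariate dispersion homogeneity check used to justify
stratification; per-stratum univariate bootstrap selection; classifier
comparison on signature and lipid-class-aggregate inputs; and signature set
algebra across strata.

## Preprocessing

Concentrations are adjusted for batch effects and then log(x+1)
transformed.  The batch method is `median-ratio` by default: per
metabolite, each batch is rescaled multiplicatively so its within-batch
median equals the cohort median.  A multiplicative model on the raw scale
is additive on the log scale, matches how the simulator injects batch
shifts, is robust to outliers, and preserves positivity.  A `log-center`
alternative (per-batch mean-centering on the log(x+1) scale) is provided
for cohorts whose batch structure is additive after transformation; both
orders of operations are defensible and the univariate AUC machinery is
invariant to any monotone per-metabolite transform, so the choice matters
mainly for the multivariate models.

The natural logarithm is used; since AUC-based quantities depend only on
ranks, the base is immaterial.

Strata are conjunctions of age (> 50 strictly, or <= 50), obesity
(BMI >= 30 inclusive — the WHO threshold — or < 30) and sex.  Age 50
belongs to the younger stratum and BMI 30.0 to the obese stratum;
`stratify()` pins these boundaries and the test suite asserts them.

## Dispersion homogeneity

`group_dispersion()` computes each participant's Euclidean distance to its
group centroid in log-metabolite space, the construction underlying
homogeneity-of-multivariate-dispersion (PERMDISP2-style) testing, and
`tukey_dispersion_test()` compares group mean distances by one-way ANOVA
with Tukey's honestly-significant-difference adjustment.  Distances to the
*centroid* (not the spatial median) are the default because the centroid
version has closed-form behaviour that the unit tests exploit (translation
invariance, exact scaling, equality with `vegan::betadisper`); the spatial
median variant is available via `center = "spatial-median"`.  Permutation
p-values are deliberately not the default: significance here is assessed
parametrically through the Tukey procedure on distances.

## Univariate bootstrap selection

For each metabolite within a stratum of size N, `bootstrap_oob_auc()` draws
N participants with replacement (B = 1000 replicates by default), fits a
univariate logistic regression to the draw, scores the out-of-bag (OOB)
participants — those never drawn, on average `(1 - 1/N)^N` of the cohort,
about 37% — by the fitted linear predictor, and records the OOB AUC
(Mann--Whitney with midrank ties).  Replicates in which the training draw
or the OOB set lacks one of the classes are discarded and counted, not
redrawn: redrawing would condition the resampling distribution on a
class-balance event and bias the quantiles; the discard counts are reported
for audit.

A metabolite enters the stratum's signature when the 2.5% quantile of its
OOB AUC distribution exceeds 0.5 (`selection_rule()`); the reported
signature AUC is the bootstrap median `q50`.  The rule is strict (`>`) by
default, with a switch for `>=`.  Quantiles are always the type-7
(linear-interpolation) estimator: selection is threshold-sensitive, so one
fixed estimator is used everywhere and tested against a sort-based oracle.

Each metabolite's bootstrap is seeded by `derive_seed(master, stratum,
metabolite)`, so results are independent of panel ordering and any single
metabolite's distribution can be recomputed in isolation.

The plain (unstratified) bootstrap is used — draws are not balanced within
case/control groups — matching the selection procedure the pipeline is
designed around.

## Classifiers and consistency

Three families are compared on the fixed signature (selection is *not*
re-run inside the model bootstrap; the optimism this sequential design
retains is a property of the workflow itself and is visible in the
consistency grid):

* `logistic` — unpenalized multivariate logistic regression (IRLS, cap 100
  iterations, deviance tolerance 1e-8).  Complete separation is flagged,
  not treated as an error: the diverged direction still ranks participants,
  so training AUC 1.0 is reported honestly.
* `pcr` — principal component scores of the centered, unit-variance-scaled
  features fed to logistic regression.  Axis signs are fixed
  deterministically (largest-magnitude loading positive); the sign is
  absorbed by the logistic coefficients in any case.
* `pls` — univariate-response NIPALS partial least squares on standardized
  features with 0/1-coded centered labels, deflating between components;
  the first weight vector is proportional to the per-feature correlations
  with the outcome.  Scores feed the same logistic step.

Features are standardized before PCA/PLS because metabolite variances span
orders of magnitude; an unscaled PCA would load almost entirely on the
most abundant lipids.  Scoring new data always reuses the training centers
and scales — never test-set statistics — which the tests assert directly.

`bootstrap_model_auc()` repeats the resample-refit-evaluate cycle B times
and summarizes train and test AUCs at the 2.5/50/97.5% quantiles.
`consistency_table()` assembles the per-(model, quantile, stratum) grid
with `difference = train - test`, mean absolute difference per quantile
across strata, and an overall per-model mean across all cells (for six
strata and three quantiles, 18 cells).  `select_components()` picks the
component count minimizing the |mean train - mean test| gap, with ties
broken toward fewer components; one component is typically selected, and
the packaged consistency grid reproduces the ranking pcr < pls < log.

Lipid-class aggregates (`aggregate_by_class()`) sum raw concentrations over
all measured panel members within lysoPC, PCaa and PCae and then apply
log(x+1) — the same transform order as for individual metabolites.

ROC bands (`roc_band_export()`) average replicate test (or training) ROC
curves vertically on an FPR grid with linear interpolation between ROC
vertices, plus 2.5/97.5% envelopes.  A caveat the package's tests make
explicit: refitting a model on resamples of a single finite null cohort is
not a null classifier — the fit aligns with the cohort's accidental
direction, so its mean OOB ROC sits slightly above the diagonal.  Only
scores generated independently of the labels average to the diagonal.

## The synthetic cohort generator

The study's raw cohort is not publicly deposited, so `simulate_cohort()`
generates cohorts with the structure the analysis assumes, and every
downstream stage is tested against it.

* **Demographics.** `default_study_config()` reproduces the published
  stratum table exactly: the printed marginals pin down the full
  group x sex x age-band x obesity cell table (346 participants, 152 OA /
  194 HV, 159 male / 187 female, 250 over age 50 of whom 122 male, 172
  obese), and cell counts are matched without residual randomness.  Ages
  and BMI are truncated normals honoring band boundaries with the printed
  per-stratum means and SDs; the means of the small age <= 50 bands are
  derived from the printed mixture moments.
* **Concentrations.** Log-concentrations are multivariate normal with an
  exchangeable correlation block per lipid class (`rho_within_class`,
  default 0.5) and independence across classes — the minimal structure
  consistent with "metabolites are correlated within class", and
  configurable.  Case means are shifted by `auc_to_effect(target) * SD` on
  the log scale, where `auc_to_effect(a) = sqrt(2) * qnorm(a)` inverts the
  binormal identity `AUC = pnorm(d / sqrt(2))`; because exponentiation is
  monotone, the empirical univariate AUC of the natural-scale
  concentrations converges exactly to the configured target (verified at
  n = 5000 per group within 0.01).  Default targets give the tabulated
  older-male signature metabolites their published median AUCs, attenuated
  by 0.5 below age 50 and 0.6 in older females, concentrating signal in
  older males as observed.
* **Batches.** Additive per-(batch, metabolite) log-scale shifts with SD
  `batch_sd` (default 0.2, 4 near-balanced batches) — exactly the structure
  `adjust_batch()` removes.
* **Scale.** Baseline log-concentration location/scale default to 4 and
  0.4 (median concentration ~55 on the measurement scale).  These are
  arbitrary — the published tables carry no concentration scales — and all
  AUC-based results are invariant to them; they are exposed in the
  configuration and documented as arbitrary.
* **Diabetes.** An optional prevalence flag and per-metabolite DM shifts
  support the sensitivity screen (`dm_sensitivity()`), which Welch-tests DM
  vs non-DM within OA and HV separately and removes flagged metabolites
  from a signature before refitting.

What the generator does *not* emulate: measurement error and limits of
detection, missingness, non-normal concentration distributions, realistic
cross-class correlation, or confounding of metabolite levels with age/BMI
within a stratum.  Passing tests therefore demonstrate that the algorithms
are implemented correctly and behave as designed under the stated model —
not that the published effect sizes would replicate in new cohorts.

## Demographic comparisons

`sex_ratio_chisq()` is the 2x2 chi-square with Yates continuity
correction, which reproduces the published stratum p-values (0.312, 1.000,
0.586) from the printed counts; the uncorrected Pearson variant is
available (`correct = FALSE`, giving 0.263 for the full cohort).  On these
tables the corrected p bounds the Fisher exact p from above and the
uncorrected p bounds it from below — the correction overshoots the exact
conditional test by up to ~0.13 in the near-degenerate strata, which is
why both variants are exposed.  Continuous comparisons use Welch's
unequal-variance t-test, computable from summary moments
(`welch_t_from_summary()`) because published tables print only means and
SDs; checks against printed bound-level p-values are necessarily
bound-level, as the printed moments are rounded.

The DM screen uses unadjusted p < 0.05 per metabolite by default; the
screen is a sensitivity analysis (flag-and-refit), not an inferential
claim, so multiplicity correction is intentionally left to the caller.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere.
* Bootstrap stages error when fewer than half the replicates are valid.
* `adjust_batch` refuses batches with non-positive medians (undefined
  multiplicative scale) and requires two participants per batch.
* Empty strata and empty signatures are valid results (warned, not
  errors): two published strata legitimately select no metabolites.
* Zero-variance features are dropped with a warning by `fit_logistic` and
  are an error for PCA/PLS standardization.
* All RNG flows from explicit seeds; simulation and bootstrap functions
  save and restore the caller's RNG state.

## Problem sizes in the test suite

The packaged tests run the full workflow at reduced bootstrap depth
(B = 100--500, with B = 1000 reserved for the selection-calibration
checks), cohorts of 122--2000, and 2--10 seeds per property; these sizes
give the suite stable verdicts for the properties asserted while keeping a
complete run in the low minutes on one CPU.  The acceptance script
(`scripts/acceptance.R`) recomputes every in-table quantity exactly and the
synthetic-pipeline quantities at B = 300--500.

## Known limitations

* The published signature tables report one AUC per selected metabolite;
  which bootstrap summary it is (the package assumes the median) is not
  stated, so fixture-based comparisons treat the printed values as `q50`.
* The overall consistency grid means recompute the published pls and log
  values exactly and pcr to within one rounding unit (0.0185 vs 0.018),
  an artifact of rounding in the printed cells.
* The sequential design (select, then model) retains selection optimism by
  construction; consistency comparisons between models are unaffected, but
  absolute test AUCs should be read with this in mind.
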