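---
title: "In silico multifactorial intervention on urinary peptide profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico multifactorial intervention on urinary peptide profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptrisk)
```

## The problem

Several drug classes (mineralocorticoid receptor antagonists, SGLT2
inhibitors, GLP-1 receptor agonists, angiotensin receptor blockers) and
non-drug interventions (olive-oil-rich diet, exercise) slow the progression
of chronic kidney disease, but no patient should receive all of them: the
question is which combination helps *this* patient most. Each intervention
leaves a reproducible multiplicative signature on the urinary peptidome —
per-peptide fold changes measured in before/after treatment studies — and a
urinary peptide classifier (CKD273-like: a weighted combination of a few
hundred peptide abundances) summarises a patient's molecular risk of a major
adverse kidney event (MAKE, a ≥ 40% eGFR decline or kidney failure).

`peptrisk` implements the full in silico pipeline: apply candidate
interventions to a patient's measured peptide profile by multiplying
intensities with fold changes, rescore the treated profile, search all
non-empty combinations of the available interventions (63 regimens for six
interventions) for the score-minimising one, and translate score changes
into clinically interpretable risk quantities.

## The model, step by step

**Scoring.** A profile is a non-negative intensity vector with missing
values where the signal fell below the detection limit. Missing entries are
imputed as exact zeros (`impute_missing_as_zero()`), and the score is the
linear form `bias + sum(w_j * f(x_j))`. The production classifier behind
the original analysis is an SVM inside proprietary software; its kernel and
preprocessing are not public, so this package fixes a deterministic linear
decision function behind a stable contract — the downstream procedure needs
only a profile → score map, and the classifier is a replaceable component
(`classifier_model()`, serialisable as JSON). The default elementwise
transform is `log1p` rather than `log` so that the imputation value 0 stays
in-domain.

**Intervention.** A fold-change table maps peptide id to the ratio of mean
abundance after over before treatment; peptides not listed have fold change
1, and a zero intensity stays zero (below detection remains below
detection). Combinations multiply fold changes per peptide, treating
intervention effects as independent; combining then applying is identical
to applying sequentially, which the tests verify as an invariant.

**Optimisation.** All `2^k - 1` non-empty subsets are enumerated in a
canonical order (by size, then lexicographically by joined name) and scored;
the per-patient optimum is the minimum score. Ties — which occur exactly,
e.g. with identity tables — are broken toward fewer interventions, then
lexicographically. Parsimony is a deliberate design choice: when two
regimens achieve the same molecular effect, the one with less drug burden
carries less risk of adverse interactions and cost.

**Risk transformation.** The empirical bridge from score to outcome is the
100-nearest-neighbour person-time estimator
(`time_to_half_risk_empirical()`): for a target score, take the 50 nearest
subjects above and 50 at-or-below (nearest 100 overall at the extremes,
where the paper-described construction is undefined; distance ties are
resolved by patient order so results are reproducible), divide the summed
observation time by the number of events in the window, and halve it —
under linear risk accrual this is the time at which half of a cohort at
that score has had an event. Regressing `log10(t50)` on score gives the
log-linear risk model; the published coefficients are

```
log10(days to 50% risk of MAKE) = 4.1446 - 0.9498 * score
```

available as `published_risk_model()`. The logarithm is base 10: the
natural-log reading would put the time to 50% risk at score 0 near 63 days,
irreconcilable with the observed event rates, while base 10 reproduces the
reported incidence rates exactly. An incidence rate per 100 person-years
follows as `50 / t50_years` (50 events per 100 subjects accrued over the
time to 50% risk), with `days_per_year = 365.25`; this conversion
reproduces the reported medians (4.5 at score 0.565, 1.43 at 0.039) at
their printed precision:

```{r}
round(incidence_rate(0.565), 1)
round(incidence_rate(0.039), 2)
```

**Recalibration.** Short peptidomic follow-up studies overestimate what a
multi-year trial delivers, so raw fold changes are recalibrated per
intervention: the ratio `r = observed / predicted` between the
trial-observed percentage change in time to MAKE and the model-predicted
percentage change in time to 50% risk is applied to the table. The original
description does not give the functional form of "applying" the ratio; this
package uses power scaling `fc^r`, i.e. linear scaling of log fold changes.
The alternative linear form `1 + r*(fc - 1)` can produce non-positive fold
changes and does not commute with multiplicative combination, so it was
rejected. Because the predicted effect is nonlinear in `r`, one correction
pass does not land exactly on the observed value; both the literal
single-pass mode (default) and a fixed-point iterative mode
(`max_iter > 1`, tolerance in percentage points) are provided without
claiming either is the original procedure. The predicted effect summarises
per-patient percentage changes by the cohort median (robust; the mean is
available).

## The synthetic cohort generator

No peptide data are deposited with the original study, so the generator is
a first-class module producing cohorts with the statistical structure the
analysis assumes. Its defaults are the study conditions: 935 patients, a
273-peptide classifier, baseline scores with median 0.565 and standard
deviation 0.45 (matching the reported IQR of roughly 0.19–0.81), ~1.5-year
median follow-up, and the published risk coefficients as generative truth.
Specifics and the reasoning behind the open choices:

* **Peptide universe.** The total number of profiled peptides is not part
  of the analysis contract; the default of 2,000 keeps a full cohort matrix
  comfortably in memory while leaving the classifier a small subset of the
  universe, as in real CE-MS peptidomics.
* **Intensities** are log-normal per peptide; a latent per-patient severity
  raises up-regulated classifier markers and lowers down-regulated ones.
  Classifier weights are drawn with mixed signs and L1-normalised
  (`sum |w| = 10`) so effect sizes are comparable across seeds.
* **Missingness** is independent per cell at rate 0.3. Zero-imputed missing
  classifier markers contribute Bernoulli noise to the score; when the
  requested `score_scale` is below that noise floor (small classifiers),
  the generator takes the closest achievable spread rather than failing. A
  left-censoring (intensity-dependent) missingness mechanism is out of
  scope.
* **Calibration.** The classifier-marker log-intensities are scaled by an
  exponent solved so the score standard deviation matches `score_scale`,
  then shifted multiplicatively (up-markers by `alpha`, down-markers by
  `1/alpha`; the score is monotone in `alpha`, so `uniroot()` applies) to
  put the median at `score_location`. Reported scores are exactly the
  classifier scores of the generated profiles.
* **Outcomes.** Event times are exponential with mean `2 * t50(score)`
  days: "linear development" pins down only that t50 is half the average
  time to event, and the exponential is the simplest law consistent with
  the person-time estimator, which makes parameter recovery a well-posed
  test (the round trip through `estimate_risk_curve()` +
  `fit_risk_regression()` recovers the coefficients within ±0.15 at
  n = 10,000). Censoring is uniform administrative on
  `(0, followup_max_years)` with a 3-year default, giving a 1.5-year median
  follow-up; the original follow-up law is unstated, so uniform is an
  assumption, not a claim.
* **Fold-change tables** cover each classifier peptide with probability
  0.35 plus 50 non-classifier peptides; log fold changes are normal
  (sd 0.2) with a mean biased toward reversing each peptide's weight sign,
  scaled by a per-intervention potency drawn in (0.5, 1.5). The beneficial
  bias reflects that the source trials were efficacious; setting
  `benefit_bias = 0` yields null tables and adverse interventions can be
  simulated with a negative bias.

What passing tests on these cohorts do **not** show: batch effects,
migration-time drift, correlated missingness, non-linear classifier
behaviour, or the empirical dependence of treatment benefit on baseline
score. In particular the reported negative rank correlation between
baseline score and score change, the specific optimal-regimen frequency
table, and the high-vs-low tertile hazard ratio of 4.26 are properties of
the study's own cohort; on synthetic data the package asserts only their
structural counterparts (a significant downward score shift, count
conservation, an elevated hazard with a confidence interval excluding 1).

## Numerical and degenerate-input choices

* Scoring a profile with missing values is an error, never silent
  imputation; `impute_missing_as_zero()` must be explicit.
* Imputation happens once, on the baseline profile; interventions then act
  multiplicatively on the zeros and cannot resurrect a below-detection
  peptide. Whether the original study re-imputed after intervention is
  unknown; carrying zeros forward is the only reading consistent with
  multiplicative effects.
* Identity fold-change tables cannot be calibrated (predicted effect 0);
  this raises an informative error rather than returning an infinite
  correction factor.
* Tertile cut points are the 1/3 and 2/3 empirical quantiles with ties
  assigned to the lower stratum; all-equal scores land everyone in `low`.
* The high-vs-low hazard ratio is a single-covariate Cox model with Breslow
  tie handling and a Wald interval (the original software is named but not
  its method; this is the standard reading). The paired Wilcoxon test uses
  the exact signed-rank distribution up to 25 informative pairs and the
  continuity-corrected normal approximation beyond.
* All generator randomness flows from one root seed with fixed per-stage
  offsets, so cohorts, outcomes and tables are individually reproducible.

## Problem sizes used in the test-suite

Unit fixtures use cohorts of 80–300 patients with 150–600-peptide
universes; calibration and parameter-recovery checks use up to 10,000
patients with a single-peptide universe (only scores and outcomes matter
there); the cohort-scale property checks run one 935-patient cohort with a
100-peptide classifier over all 63 regimens. These sizes were chosen so
that estimator noise is well below the asserted tolerances.

## Worked run

```{r, message = FALSE}
spec <- cohort_spec(n_patients = 300, n_peptides = 500,
                    n_classifier_peptides = 80, seed = 42)
report <- run_pipeline(run_config(synthetic = spec), quiet = TRUE)
report
glance(report)
head(report$regimen_freq)
```

```{r, fig.width = 5, fig.height = 3.5}
plot_score_shift(report)
```

## Limitations

The linear classifier is a stand-in, not the proprietary 273-peptide SVM;
absolute score values are comparable only within one classifier. Trial
effect sizes are user-supplied percentages — the package performs no
meta-analysis of the underlying trials. The incidence-rate conversion
assumes linear risk accrual up to the 50% horizon, which overstates
long-horizon rates for low-risk patients. Intervention effects are treated
as molecularly independent; pharmacological interactions are not modelled.
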