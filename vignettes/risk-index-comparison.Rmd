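---
title: "Comparing point-based dementia risk indices: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing point-based dementia risk indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(demrisk)
```

# The problem

Several published dementia risk indices — ANU-ADRI, CAIDE, CogDrisk, LIBRA
and its extension LIBRA2 — summarize a person's risk-factor profile as an
additive point score: each categorical factor level (obesity, hypertension,
current smoking, ...) carries a published weight, and the score is the sum
of matched weights. The indices differ in which factors they cover, in
their weighting scales, and in whether non-modifiable demographics (age,
sex, education) are part of the score. `demrisk` implements all five
calculators over one harmonized factor vocabulary and the statistical
machinery needed to compare their ability to discriminate incident
dementia in an aging cohort: z-standardized logistic models, rank-based
AUCs with DeLong covariance, a gated global-then-pairwise comparison
procedure, stratified analyses, and multiple-imputation sensitivity
analyses. Because the cohort data such comparisons are run on are
access-restricted, the package also ships a synthetic-cohort generator
calibrated to a realistic elderly population, so the entire pipeline is
exercised end-to-end by code anyone can run.

# The score model

A weight table is a declarative set of entries
`(index, factor, level, points, condition)`. Scoring a participant means
matching each covered factor's level (resolving sex- and age-banded
conditions on baseline sex and attained whole years of age) and summing
points. Two properties follow and are enforced:

* **Additive separability.** The theoretical score range is the sum of
  per-factor extremes, scanned over sexes where entries are
  sex-conditioned (`theoretical_range()`); tests verify it against
  brute-force enumeration of level combinations.
* **Exact arithmetic.** All published weights have at most two decimals,
  so sums run internally on integer points scaled by 100; results are
  independent of summation order, and equality tests against the
  brute-force oracle are exact.

Demographic entries (sex, age, education) are flagged in the tables, and
every analysis runs in two variants: scores with and without them. The
LIBRA family is lifestyle-only by construction; its demographic entries are
borrowed from the ANU-ADRI scoring convention and marked as such.

Two scoring conventions come from the comparison design rather than the
indices themselves: former smokers carry the ANU-ADRI ex-smoker weight but
score as never-smokers in every other index, and CogDrisk's diabetes weight
is sex-specific.

## Transcription notes on the weight tables

The weight tables live in YAML files under `inst/extdata/weights/`, one per
index, each entry carrying the verbatim cell text it was transcribed from.
Three cells in the source table reproduce ambiguously, and the shipped
reading was chosen on internal-consistency grounds:

* The cognitive-activity column runs cells together; the only reading in
  which each index's gradient is coherent and all LIBRA2 weights stay
  non-negative is ANU-ADRI 0/−6/−7, CogDrisk 0/−4/−5, LIBRA 0/0/−3.2,
  LIBRA2 9.4/0/0. This reading also reproduces the printed observed score
  minima exactly: LIBRA −5.9 = (−1) + (−1.7) + (−3.2) and CogDrisk
  −8.25 = (−0.25) + (−5) + (−3), which the test suite asserts.
* A dash inside a factor an index otherwise covers (the underweight BMI
  row; the heart-disease "No" row in the LIBRA family) is transcribed as an
  explicit zero so that level-coverage validation can be strict.
* The ANU-ADRI education and social-activity gradients, and the LIBRA2
  social-contact gradient, are transcribed exactly as printed even though
  their direction looks inverted relative to the source indices' usual
  orientation. `load_weight_table(overrides = ...)` provides a per-cell
  override for users who want to correct individual cells without editing
  the shipped files.

Pesticide exposure and chronic kidney disease are omitted entirely,
matching the comparison design.

# Harmonization

`harmonize_cohort()` maps raw survey, clinical and registry measurements to
the factor vocabulary of `factor_levels()`, with one provenance tag per
factor (`survey`, `earlier_wave`, `registry`, `derived`). The precedence is
survey-first: a survey-derived value is never overwritten; positive reports
from earlier waves carry forward for hearing loss and stroke; positive
registry diagnoses (three-digit ICD-10, window 2007–2009 by default,
configurable) fill remaining gaps for depression (F32–F33), diabetes
(E10–E14), hypertension (I10, I15), heart disease (I11, I20–I25, I50–I51),
stroke (I60–I69) and head injury (S06–S07, S09). Registry codes that
contradict a survey "no" are logged, not applied.

Thresholds follow the conventional definitions: BMI bands at 18.5/25/30
(boundary up); HADS depression at ≥ 8; non-fasting glucose ≥ 9 mmol/L or a
self-report for diabetes; total cholesterol ≥ 6.5 mmol/L; hypertension as
the mean of the second and third systolic readings ≥ 140 mm Hg (mean of
whatever readings exist when one is missing, logged); sleep disturbance as
any of three insomnia items occurring several times a week; carrier status
as at least one APOE ε4 allele.

Decisions the package had to make where the conventions underdetermine the
rule:

* **Alcohol boundary.** The printed bands ("1–14" and "≥ 14" units/week)
  overlap at exactly 14. The default assigns 14 to the high band — the more
  specific risk condition — and `harmonize_config(alcohol_boundary =
  "low_moderate")` flips it.
* **Education banding.** Two bandings circulate (< 8 / 8–11 / > 11 and
  < 8 / 8–12 / > 12 years); the default is the one that carries the index
  weights, the other is a config switch.
* **CAIDE activity binary.** "At least 30 minutes at least twice per week"
  is implemented as sessions/week ≥ 2 *and* mean minutes per session ≥ 30,
  so 40 minutes once a week is inactive.
* **Quantile engine.** Cognitive and social activity are cohort-relative
  composites: each component is z-scored on the analytic cohort (equal
  weights — the aggregation rule is not specified more precisely anywhere)
  and the sum is cut at midrank-based empirical tertiles/quartiles with
  ties assigned to the lower group. This rule is deterministic, rank-only,
  and stable under monotone transforms; with distinct composites the group
  sizes differ by at most one. The cut points and z-parameters form a
  reusable `context`, so single records and strata are categorized on the
  cohort's scale rather than their own.

# The synthetic cohort

`cohort_spec()`/`generate_cohort()` produce raw participant records with
the statistical structure the analysis assumes:

* **Dependent categoricals by Gaussian copula.** One latent normal per
  factor plus one for age, correlated by a configurable matrix (defaults:
  modest, sign-plausible pairs such as age–hypertension 0.30, age–hearing
  0.45, depression–loneliness 0.35). Categories arise by thresholding each
  latent at the quantiles implied by the factor prevalences. The latent-
  normal choice deliberately matches the imputation stage's joint-normal
  model, so generator and imputer share assumptions.
* **Calibrated defaults.** Default prevalences are transcribed from the
  analytic-sample level counts of the calibration table shipped under
  `inst/extdata/cohort/` (5247 participants, 52.8% women, baseline age
  66.6 ± 5.8, dementia prevalence 10.8% with 58% AD among cases). They are
  defaults, not constants: every piece is overridable per spec.
* **Back-filling guarantees the round trip.** Raw continuous values are
  drawn uniformly inside the assigned category's numeric interval
  (unbounded intervals truncated at physiologic limits, e.g. hypertensive
  mean systolic pressure within [140, 210] mm Hg), so harmonizing a
  generated record
  recovers the assigned category for every factor and every record,
  exactly — a property the test suite asserts.
* **Outcome model.** Dementia is Bernoulli from a logistic model on
  baseline age (log-odds 0.148/year by default), ordered education, and any
  subset of factors; the intercept may be given directly or calibrated by
  root-finding so the realized prevalence hits a target. Outcomes are
  simulated on baseline covariates only — no time-to-event structure and no
  competing mortality, matching the binary-logistic framing of the
  analysis this package supports.
* **MAR missingness.** `inject_missingness()` blanks raw variables with
  per-variable logistic probabilities depending only on age, sex and
  education — exactly the predictors the imputation stage conditions on —
  with defaults that make missing participants older, more often female
  and less educated. Outcome and id are never blanked.

Two generator constructions deserve a caveat because they are *more*
regular than real data, and passing round-trip tests should be read
accordingly. First, composite components (cognitive/social items) are
back-filled as strictly monotone transforms of one latent, i.e. perfectly
rank-correlated, which guarantees tertile/quartile recoverability; real
item batteries carry item-specific noise. Second, the Mediterranean-diet
category is thresholded conditionally on the fish band (a diet score of 10
cannot be reached in the lowest fish band), using an empirical quantile
within the eligible subset so the marginal prevalence is preserved; this
induces a positive diet–fish association by construction.

# Evaluation

All indices are z-standardized (mean 0, SD 1, denominator *n* − 1) before
modelling, so odds ratios are per SD and comparable across the indices'
very different scales; standardization parameters are estimated on the
full analytic sample and reused inside strata (keeping per-SD ORs
comparable across strata; a per-stratum alternative sits behind
`z_policy`). The analytic sample is the complete-case set across *all*
indices, so every AUC is computed on identical participants — a
precondition the DeLong machinery enforces rather than silently fixing.

The reference model is demographics-only: logistic on age (years) and
education (ordered numeric level; a single OR, hence not dummy-coded —
switchable). AD analyses relabel the outcome as AD vs no dementia and drop
non-AD dementia cases.

`delong_compare()` estimates the joint covariance of all models' AUCs from
placement values (structural components), then applies the gate: a global
chi-square test of AUC equality (contrasts against one curve, rank-aware
inverse) must reach p ≤ 0.05 before any pairwise z-tests are reported.
Contrasts against the reference model are reported regardless of the gate,
starred at 0.05/0.005/0.001. AUCs carry the standard interpretation bands
(0.5–0.6 fail, 0.6–0.7 poor, 0.7–0.8 moderate, 0.8–0.9 good). Confidence
intervals are Wald on the AUC scale from the DeLong variance, and Wald on
the log-odds scale for ORs; no multiplicity correction is applied beyond
the gate. Whether the global test spans the reference curve as well as the
indices is genuinely ambiguous in the procedure this package mirrors; the
default includes it (`global_models = "all"`), and `"non_reference"`
restricts to the indices.

The stratification age boundary is another printed ambiguity (≤ 65 vs the
table labels ≤ 64/≥ 65): the package adopts under-65 vs 65-plus and
exposes `age_cut`.

Numerical edges: quasi-complete separation in a logistic fit is detected
(diverging coefficients or fitted probabilities at machine bounds), warned
about, and optionally replaced by a small-ridge IWLS refit; strata with a
single outcome class are skipped with a warning; a comparison of a model
with itself returns a zero statistic and p = 1 rather than a 0/0.

# Multiple imputation

`mvn_impute()` implements joint multivariate-normal imputation: harmonized
factors are mapped to ordered level scores, modelled jointly with the
always-complete predictors (age, sex, education, dementia status — the
predictor set is fixed and never imputed), and missing cells are drawn from
the conditional normal. Parameters come from bootstrap EM — one
pattern-grouped EM fit per bootstrap resample — giving proper
between-imputation variability without a burn-in schedule to tune; the
engine choice is recorded in the output metadata. Draws are rounded to the
nearest legal level (adaptive rounding was considered and rejected for
determinism and simplicity); observed cells are never altered; a fixed
seed reproduces every imputation. The default is m = 100 imputations;
tests and the bundled pipeline run scaled down (m = 10–20), which the
output flags via its metadata.

Pooling follows Rubin's rules: total variance `ubar + (1 + 1/m) b`,
relative variance increase `(1 + 1/m) b / ubar`, and fraction of missing
information reported as the large-sample fraction `(1 + 1/m) b / t`, which
is 0 when the imputations agree exactly; Barnard–Rubin adjusted degrees of
freedom drive the t-intervals when a complete-data df is supplied. The
no-missingness limit degenerates to the complete-case analysis exactly
(b = 0 throughout), and the test suite verifies that under ~30%
outcome-and-age-linked MAR missingness the pooled estimates are less
biased than complete-case ones.

The default imputes harmonized factors and then rescores, rather than
imputing the index scores themselves; score-level imputation would discard
the constraint that scores are deterministic functions of factors.

# The pipeline and problem sizes

`run_all()` chains simulate → inject missingness → harmonize → score →
evaluate (+ strata) → impute, derives every stage seed from one master
seed, checks that every reported percentage re-derives from the counts in
the same report, and writes TSV/JSON artifacts on request. Identical
configuration gives byte-identical tables.

Default problem sizes were chosen as the smallest at which each property
is comfortably testable: cohorts of 2,000–5,247 for pipeline runs, m = 20
imputations in the bundled sensitivity stage, 100–500 replicates for
simulation-based checks (null rejection rates, CI coverage, MAR recovery),
and 50,000 per group for the binormal AUC limit. The planted-ordering
experiment in the acceptance suite drives the outcome through
index-exclusive factors only — loneliness and stroke (CogDrisk), hearing
(LIBRA2), APOE ε4 (CAIDE) — because the LIBRA index shares every factor it
covers with other indices, so a five-way exclusive planting does not
exist; nuisance factors are pinned near their zero-weight levels so each
index's score variance is dominated by its drivers, and the recovered
ordering CogDrisk > LIBRA2 > CAIDE (with the driverless ANU-ADRI and LIBRA
below LIBRA2) is asserted across 100 seeds.

# Known limitations

* The generator emulates marginal prevalences and a plausible correlation
  structure, not the full joint distribution of a real cohort; effect
  sizes estimated on synthetic data characterize the machinery, not any
  population.
* Scores are compared on discrimination (AUC) only; calibration metrics,
  time-to-event structure, competing mortality and inverse-probability
  weighting are out of scope.
* Registry harmonization accepts three-digit ICD-10 codes only; free-text
  or other vocabularies are not mapped.
* The exact quantile engine behind the published composite tertiles, the
  composite component weights, and several weight-table cells are
  underdetermined by the sources; the package's choices are documented
  above and overridable, but they remain choices.
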