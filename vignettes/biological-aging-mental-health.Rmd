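---
title: "Methods: blood-chemistry biological aging and depression/anxiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-chemistry biological aging and depression/anxiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented by `bioagemh`, the
assumptions behind them, the choices made where the methodology was
genuinely open, and what the synthetic cohort generator does and does not
emulate.

## The two clocks

### KDM-BA

The Klemera–Doubal estimator treats each biomarker as a noisy linear readout
of age. Training (`fit_kdm()`) regresses each of nine biomarkers on
chronological age, separately by sex, in a reference population of adults
aged 30–75, giving intercept `q_i`, slope `k_i` and RMSE `s_i` per
biomarker. Prediction (`kdm_ba()`) combines the per-biomarker age estimates
`(x_i − q_i)/k_i`, weighted by their precisions `(k_i/s_i)²`, with
chronological age weighted by `1/s_BA²`. Two conventions deserve comment:

- **Regression direction.** Descriptions of this algorithm sometimes say
  "chronological age regressed on the biomarker", but the estimator's units
  only cohere when each biomarker is regressed **on** age
  (`x = q + k·CA + ε`): `q` is in biomarker units, `k` in units/year, and
  `(x − q)/k` is then an age. We implement biomarker-on-age, the canonical
  Klemera–Doubal convention used by the established reference
  implementations.
- **The scaling factor `s_BA`.** We define `s_BA²` as the variance in
  chronological age explained by the biomarker set: `R²·Var(CA)` from the
  multivariable OLS of age on the nine biomarkers within the sex stratum,
  with the population (divide-by-n) variance so that duplicating reference
  rows is a no-op. The original Klemera–Doubal corrected estimator — the
  dispersion of the biomarker-only age estimate around chronological age
  minus its expected estimation noise — is available via
  `fit_kdm(..., sba_method = "kd")`; which variant a published analysis
  used is usually not determinable from its text, so both are provided and
  the default follows the verbal definition.

CRP enters both clocks as `ln(CRP)`; its distribution is right-skewed and
log-linear in age, and the PhenoAge coefficient is defined on the log scale.
A useful identity, tested to 1e-9: a panel lying exactly on the trained mean
trajectory at age `a` (every `x_i = q_i + k_i·a`) yields `KDM-BA = a`
regardless of the parameter values, because every per-biomarker estimate and
the CA term all equal `a`.

### PhenoAge

PhenoAge maps nine blood chemistries plus chronological age through a
Gompertz mortality model: linear predictor `xb` (fixed published weights),
120-month mortality risk `1 − exp(−exp(xb)·(exp(120γ) − 1)/γ)` with
`γ = 0.0076927`, and back-transformation to the age scale,
`141.50225 + ln(0.00553·(−ln(1 − risk)))/0.090165`. Algebraically PhenoAge
is affine in `xb` with slope `1/0.090165 ≈ 11.09` years per unit; the
implementation evaluates the risk path as written and the test suite checks
agreement with the closed form to 1e-9. Two printed-source issues are
resolved the only way that reproduces the published algorithm: the albumin
term is `−0.0336 × albumin` (a typeset `+` between coefficient and variable),
and the mortality-risk exponent is the Gompertz cumulative hazard over a
120-month horizon. The published weights are meaningful only in the original
unit system (albumin g/L, creatinine µmol/L, glucose mmol/L, CRP ln mg/dL,
ALP U/L, MCV fL, RDW %, WBC 10³/µL, lymphocytes %); the panel stores
conventional clinical units (albumin g/dL, creatinine mg/dL, glucose mg/dL)
and `phenoage()` converts internally (×10, ×88.4017, ÷18.016). In double
precision the risk saturates to 1 once the cumulative hazard exceeds ~36
(`xb ≳ −1.7`), far above the physiological range (midlife panels give
`xb ≈ −9`); the strictly-in-(0,1) property is therefore asserted on the
resolvable range.

## Age acceleration

`compute_aa()` regresses biological age on chronological age by OLS *within
the analysis cohort* (not the reference) and takes residuals, which are then
standardized to mean 0/SD 1 and cut at the empirical quartiles. Choices:

- Residualization is pooled across sexes, with sex handled as a model
  covariate downstream; sex-stratified residualization is a plausible
  alternative but changes the estimand of "per SD" effects across sexes.
- Quartile ties go to the lower quartile (values equal to a cut-point);
  with continuous clocks ties are measure-zero, so this only matters for
  degenerate inputs.
- If the residual SD is numerically zero (e.g. BA ≡ CA) the standardized AA
  is undefined; the function warns and returns `NA` rather than dividing by
  zero.

## Case definitions and scoring

All scorers are pure functions. PHQ-4: total ≥ 6 positive for either
disorder, items 1+2 ≥ 3 for depression, items 3+4 ≥ 3 for anxiety; the
baseline "either" definition is the union of the total-score rule, the
subscale rules and the hospital-record flags, with every component exposed
so either narrower reading is computable. PHQ-9/GAD-7: total ≥ 10 positive;
any item ≥ 1 flags that symptom. ICD matching is by prefix on uppercase,
undotted codes (depression 311/F32/F33, anxiety 300/F40/F41), so sub-codes
such as F32.1 or 300.0 match their range. Childhood adversity follows the
published dichotomization verbatim — including its asymmetric response sets
(physical neglect counts "often true" as adversity; emotional neglect does
not) — summing five indicators to 0–5. Follow-up for incidence ends at the
earliest of the incident hospital record, the follow-up survey, and
administrative censoring (2018-12-31); survey-detected cases are dated at
survey completion, and when both channels fire the earlier date wins.
Incidence is undefined (NA) for participants prevalent at baseline, and
subtype analyses (depression, anxiety, co-incident both) carry their own
event times: an anxiety-only event does not terminate depression follow-up.

## Association models

The covariate ladder is Model 1 (age, sex), Model 2 (+ BMI category, race,
smoking, healthy alcohol, healthy activity), Model 3 (+ Townsend index,
hypertension, CHD, diabetes). Continuous exposures are per SD of AA;
quartile exposures contrast Q2–Q4 with Q1, quartiles computed in the
analysis subset (configurable; the alternative is the full-cohort cut).
Dose–response uses a hand-implemented restricted cubic spline
(truncated-power natural spline, knots at the 5th/50th/95th percentiles;
with 3 knots there is one nonlinear basis column). Model mechanics:

- Score and prevalence models use lme4 with the examination center as a
  random intercept; `center = "fixed"` is available as a fallback. The
  logistic mixed models default to `nAGQ = 0` (penalized-least-squares
  step only): with ~22 centers and small center variance the fixed-effect
  difference from adaptive quadrature is far below Monte-Carlo error, and it
  keeps 50,000-row fits to seconds. p-values are Wald.
- Cox models use `survival::coxph` with the center as a **stratification
  factor** by default (a gamma shared-frailty option exists); "random
  effect" in a proportional-hazards context is mechanism-ambiguous, and
  stratification is the more conservative choice. CIs are Wald on the log
  scale; no multiple-testing adjustment (deliberately, matching the
  analysis plan this mirrors); α = 0.05, two-sided.
- Same-day events are guarded with a half-day floor on time at risk.
- Sensitivity variants: exclusion of ≤ 2 years of follow-up; AA×age and
  AA×sex interactions; additional adjustment for incident chronic disease
  (diabetes, cardiovascular disease, cancer — the mediation contrast);
  additional adjustment for childhood adversity (skipped with a warning if
  the items are absent).
- Joint genetic-risk analysis: a multiplicative AA×PRS term, and — in the
  additive case — 8 joint categories (AA quartile × median-split PRS,
  reference Q1/low) fitted by logistic (baseline) and Cox (incidence).

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the *structure* of a large midlife biobank:
truncated-normal age 56.47 ± 8.07 (37–73), 46.2% male, the baseline
covariate prevalences (54% hypertension, 5.5% CHD, 4.9% diabetes, BMI and
smoking mixtures, Townsend −1.43 ± 3.02), 22 examination centers with a
small random intercept (SD 0.05 on each linear predictor), sex-specific
biomarker-on-age trajectories whose means at age 56.5 match the cohort's
characteristics table, ~1/3 follow-up-survey participation (2016–2017),
recruitment 2008-06–2010-12 with administrative censoring at 2018-12-31
(median potential follow-up 8.7 years), 12.9% baseline prevalence, and an
exponential incident-event process calibrated to a 4.47% incident fraction.
A single latent aging factor loads on every biomarker's noise
(`lambda_shared`, default 0.221) and is calibrated so the two standardized
AAs correlate ≈ 0.23; the marginal noise SD of each biomarker is held
constant as the loading varies. The four clock-shared biomarkers (albumin,
creatinine, CRP, ALP) are given small age slopes — as clinically observed —
which keeps the AA correlation induced by shared measurement noise below
0.03 when the latent factor is switched off.

The **two-pass design** is the load-bearing choice: biomarkers are generated
first, the clocks and residualization are run with the real estimators, and
outcomes are then simulated from the *computed* standardized AA. The
injected `beta` is therefore exactly the estimand of the downstream model,
immunizing recovery tests against clock nonlinearity or calibration error.
One cohort carries the injected effect through one chosen exposure
(`exposure = "aa_kdm_std"` or `"aa_pheno_std"`); because the two AAs
correlate 0.23, recovering both published marginal effects requires two
separately generated cohorts. Baseline PHQ-4 has two generative modes:
`"logistic"` draws binary status from a logistic model and rejection-samples
items consistent with it (used for odds-ratio recovery); `"linear_score"`
draws the PHQ-4 total as Binomial(12, p) with exactly linear conditional
mean in AA and splits it uniformly into items (used for recovering the
published linear coefficient without discretization attenuation — the
binomial mean is linear by construction, and scoring the split items
returns the total exactly).

Deliberate non-realism, which recovery tests inherit: covariates have zero
true effect on outcomes by default (so conditional and marginal effects
coincide; real confounding is absent), survey participation is independent
Bernoulli rather than self-selected, incident onsets generate hospital
records with probability 1 by default (`prob_hospital_record` lowers it, at
the cost of detection-lag attenuation), event subtypes are a fixed
multinomial mixture, the PRS is standard normal and independent of AA, and
there is no mortality or attrition. Passing recovery tests therefore shows
the *pipeline* is consistent for its estimands, not that those estimands
are unconfounded in real data. Missingness is optional uniform
(`missing_rate`); incomplete records are excluded, as in the motivating
analysis.

Calibration constants (`lambda_shared = 0.221`, `baseline_hazard =
0.00512`/yr, the recruitment window) were fixed once against the generator's
own targets (AA correlation 0.23, incident fraction 4.47%, median follow-up
8.7 years) at n = 1e5–2e5 and are not free parameters of the analyses.

## Problem sizes and numerical tolerances

The test suite runs recovery at n = 50,000 for the published continuous
effect sizes (hazard ratios 1.059/1.113, odds ratios 1.123/1.149, PHQ-4
coefficient 0.0516), asserting that the fitted 95% CI covers the injected
value; generator calibration at n = 20,000–50,000; a 20-replicate null
battery at n = 12,000 per replicate (all injected effects zero, CI coverage
of the null ≥ 18/20 per estimate); exhaustive scoring oracles (256 PHQ-4
vectors, 3,125 adversity grids, 1,000 random date triples); and exact
identities at 1e-9 (KDM trajectory identity, PhenoAge affine form) and
1e-10 (OLS residual orthogonality, spline basis values). Unit-level
injected-effect checks use a ±3 Monte-Carlo-SE band, the standard
single-replicate recovery criterion. A single-replicate 95% CI covers its
true value 95% of the time by construction, so CI-coverage assertions at a
fixed seed carry an irreducible 5% design risk; the suite accepts that for
the acceptance battery (where the coverage form is prescribed) and uses the
3-SE band elsewhere.

## Known limitations

- The mixed logistic default (`nAGQ = 0`) trades a negligible fixed-effect
  bias for speed; set `nagq = 1` for adaptive quadrature.
- lme4 may report singular fits when the center variance estimate hits
  zero (the generator's center effects are small); estimates remain valid.
- The KDM `"kd"` scaling-factor variant uses the characteristic correlation
  from the multivariable R², a simplification of the original's weighted
  biomarker-age correlation; it falls back to the explained-variance form
  if the noise correction turns the variance negative.
- `phenoage()` requires strictly positive CRP and errors otherwise; no
  imputation of missing biomarkers is offered anywhere, by design.
- Wald CIs and p-values throughout; no profile-likelihood or bootstrap
  intervals.
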