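---
title: "Methods: pediatric cardiovascular-health scoring, joinpoint trends and cross-lagged panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric cardiovascular-health scoring, joinpoint trends and cross-lagged panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvh8)
```

# The composite score

`cvh8` implements the pediatric Life's Essential 8 (LE8) framework: eight
cardiovascular-health components — four health behaviors (diet, physical
activity, nicotine exposure, sleep) and four health factors (body-mass index,
blood lipids as non-HDL cholesterol, blood glucose, blood pressure) — each
scored 0–100, with the overall cardiovascular-health (CVH) score the
unweighted mean of the components observed for a child. Categories follow
the standard cuts: 80–100 high, 50–79 moderate, 0–49 low CVH. Records with
fewer than four observed components are excluded (the `min_components`
argument of `overall_cvh()`), mirroring the usual inclusion rule for
multiwave surveys in which blood biomarkers exist only in a few waves.
Missing components are excluded from the mean; nothing is imputed.

**Rubrics are data, not code.** Every threshold-to-points mapping lives in
`inst/extdata/rubrics.yaml` and is loaded by `load_rubrics()`; the packaged
defaults combine the pediatric LE8 point bands with the survey-specific
choices this package targets: the seven physical-activity bands
(≥420 → 100 … 0 → 0 points/minutes per week), the three active-smoking
categories with a −20 secondhand-smoke modifier clamped at zero, and the
Healthy China Initiative sleep recommendations (10 h for ages 7–12, 9 h for
13–15, 8 h for 16–19; age stands in for school level because surveys record
age). Exact supplementary rubric values from any particular study can be
transcribed into a YAML copy without touching code. All band intervals are
left-closed on the native metric (e.g. 360 minutes scores 90, 359 scores
80); boundary behavior is unit-tested explicitly.

**Diet** uses DASH-style population-relative adherence, the LE8 mechanism:
each of eight food groups (vegetables, fruits, whole grains, milk
equivalents, beans, fish, salt, sugar-sweetened beverages) contributes 1–5
points for the population intake quintile it falls in, reversed for salt and
sugar-sweetened beverages; the adherence total is mapped through population
quintile cutoffs to {0, 25, 50, 80, 100}. Cutoffs are configuration
(`load_diet_cutoffs()`); `estimate_diet_cutoffs()` derives them from an
analysis population. Salt intake is allocated from 3-day household totals by
the individual-to-household energy ratio (`allocate_household_intake()`),
and `convert_food_equivalents()` implements protein-content conversions such
as soybean milk → soybean equivalents.

**Growth and blood-pressure references.** BMI-for-age is evaluated by the
LMS method, `z = ((x/M)^L − 1)/(L·S)`, with parameters linearly interpolated
in age (months) and no extrapolation; both the z-score and the percentile
`Φ(z)` are exposed, since composite-score frameworks vary in which they
quote. Blood pressure is referenced by a polynomial regression of expected
pressure on centered age and height z-score with a residual SD — the
functional form behind the familiar age-sex-height percentile tables — and
scored by AAP-style categories: below age 13, normal (<90th percentile),
elevated (90–95th), stage 1 (≥95th) and stage 2 (≥95th-percentile pressure
+ 12 mmHg); from 13 on, the adult cutoffs 120/130/140 systolic and 80/90
diastolic. The packaged reference tables are *synthetic*: smooth, monotone,
physiologically plausible surfaces covering 7–19 years for both sexes, named
`synthetic_*.csv` to make their provenance unmistakable. They are not the
official WHO/AAP tables, which matters only if you need published
percentiles digit-for-digit; all package validation is property-based and
self-consistent (the generator and the scorer share whatever references you
configure). Glucose scoring follows fasting-glucose bands without diabetes
and HbA1c severity bands with it; a doctor's diagnosis takes precedence over
a diabetic-range fasting glucose, and when only HbA1c is observed the
5.7/6.5% thresholds decide the track.

# Temporal trends: joinpoint regression

Trends are estimated in two stages. `adjusted_annual_means()` fits, within a
residence stratum, a linear model of the score on wave-year indicators plus
age and sex, and reports each year's prediction at the pooled covariate
reference (overall mean age, sexes balanced 50/50) with model-based standard
errors — the "adjusted for age and sex" annual means. `fit_segmented()` then
fits a continuous piecewise-linear model to the annual means by weighted
least squares (weights: per-year n by default, `1/se²` or none selectable),
searching exhaustively over candidate joinpoint positions.

Candidates are **all integer calendar years** with at least two observed
waves on each side (and two between consecutive joinpoints), not only the
survey years themselves: reported break years in multiwave surveys routinely
fall between waves (e.g. 2005 between the 2004 and 2006 waves), and a grid
restricted to observed years cannot represent such a kink — we measured a
~10% bias in recovered post-break slopes when it is forced to. The two-stage
design (adjust, then fit aggregated means) was chosen for transparency: the
annual means and their standard errors are themselves reportable objects.

`select_n_joinpoints()` chooses the number of joinpoints by sequential
permutation tests of k versus k+1 (k = 0, 1, …): residuals of the
k-joinpoint fit are permuted and added back to its fitted line, and the
observed relative SSE improvement `(SSE_k − SSE_{k+1})/SSE_{k+1}` is ranked
against its permutation distribution; the sequence is Bonferroni-corrected
at `alpha/k_max` and stops at the first non-rejection. A BIC alternative
(`method = "bic"`, penalty `2(k+1) log n` for the k-joinpoint model's
parameters including break positions) is provided. All permutation draws are
governed by a single seed and the selection trace is returned. Slopes are
reported signed; the command-line driver additionally prints `|slope|` with
a decline/growth label, matching how annual "speeds" are usually quoted.

# Cross-lagged panel models

Because multiwave cross-sectional surveys have no stable person identifiers,
the panel unit is the **community** (the primary sampling unit):
`build_panel()` averages scored records to community means per wave block
(defaults 2004–2008, 2009–2013, 2014–2018), keeps units observed in ≥2
blocks, and standardizes each variable within block so path coefficients are
standardized. `fit_clpm()` estimates lagged-only paths (defaults: all five
first-order autoregressions plus diet→BMI, BMI→sleep, sleep→BMI, BMI→blood
pressure) per block transition by regression on that transition's observed
covariance matrix — maximum likelihood for a recursive path model with
predetermined regressors — so a community missing the last block still
contributes to the first transition. Global fit is evaluated on the
listwise-complete covariance matrix: the model-implied covariance is built
block-recursively from the path matrices and residual (co)variances
(within-block residual covariances free by default, diagonal selectable),
and compared through the ML discrepancy `F = log|Σ| − log|S| + tr(SΣ⁻¹) − p`
with `χ² = (n−1)F`, an independence baseline, and the standard indices

* `CFI = 1 − max(χ²_m − df_m, 0) / max(χ²_b − df_b, χ²_m − df_m, 0)`
* `TLI = ((χ²_b/df_b) − (χ²_m/df_m)) / ((χ²_b/df_b) − 1)` (capped at 1)
* `RMSEA = sqrt(max(χ²_m − df_m, 0) / (df_m (n − 1)))`,

with a saturated flag (perfect fit by definition) when `df_m = 0`. The usual
good-fit reading is CFI, TLI > 0.95 and RMSEA < 0.05.

# The synthetic cohort generator

`generate_cohort()` emulates the structure of an 11-wave (1989–2018)
child/adolescent survey: ages uniform on 7–19, balanced sex, a configurable
urban fraction (default 0.28), 15 provinces with their staggered entry years
(e.g. Heilongjiang from 1997; Beijing, Shanghai, Chongqing from 2011), three
communities per province-stratum, blood biomarkers only in the 2009/2015/2018
waves, physical activity only from 2000 on, and a small random missingness
rate (2%) for sleep and blood pressure.

Ground truth is imposed by **inverse-rubric sampling**: for each component a
target score is drawn as a two-point mixture of adjacent achievable rubric
points whose expectation equals the scenario's trend mean, and the raw
measurement is then drawn uniformly inside that band's preimage under the
active configuration (for BMI and blood pressure, via the inverse LMS and
inverse normal-reference transforms). Draw intervals are inset from band
edges so that recording precision (0.1 cm, 0.1 kg, 0.1 h) cannot flip a
band. Scoring a generated cohort with the same configuration therefore
reproduces the intended component scores *exactly*, which is what makes
end-to-end parameter-recovery tests sharp.

The packaged scenarios encode the trend parameters this package is designed
to recover: rural diet break 1997 with post-break slope −0.18/yr; urban diet
1994, −0.03; rural BMI 2005, −0.56; urban BMI 2002, −0.63; sleep −0.69/yr
with no break in both strata; health factors 2005, −0.53 (rural) and 2003,
−0.50 (urban); and cross-lagged coefficients diet→BMI 0.190 and BMI→sleep
0.089. Quantities those sources do not report numerically are fixed
plausible choices, made once: baselines (diet ≈ 32–34, BMI ≈ 90, sleep 85,
factors 92 at the first wave) keep every trajectory comfortably inside
[0, 100] over 29 years; pre-break slopes are +0.5/yr for diet (mild
improvement before the mid-90s reversal) and +0.1/yr for BMI and the factor
composite (near-stability before the break); annual-mean noise is
`noise_sd = 0.3` score points; autoregressions in the cross-lagged scenario
are 0.6, and the recovery of the cross paths is verified to be insensitive
to that choice at 0.3 and 0.8. `generate_clpm_panel()` simulates the block
process `X_{t+1} = A X_t + e` with residuals scaled for unit variances and
rejects unstable path matrices (spectral radius ≥ 1).

# Numerical and design choices

* Bands are left-closed `[lower, next lower)` everywhere; lookups use
  `findInterval`, and values below a rubric's first band are an error rather
  than silently clamped.
* Joinpoint grid-search ties break toward the earliest candidate (strict
  `<` improvement test at tolerance 1e−12); permutation p-values use the
  add-one estimator `(1 + #{T* ≥ T})/(1 + n_perm)`.
* Weighted permutation: residuals are standardized by `sqrt(w)` before
  permuting so unequal per-year sample sizes do not break exchangeability.
* The BMI score recomputes BMI from height and weight (rounded to
  measurement precision) even when a BMI column exists.
* Degenerate inputs: a single observed sex drops the sex adjustment; a year
  with no observations is dropped; quantile ties in estimated diet cutoffs
  are broken by an infinitesimal jitter; `fit_segmented` refuses joinpoint
  counts that leave fewer than two waves per segment.
* Problem sizes: the test-suite and the acceptance script use 200 Monte-Carlo
  replicates per recovery target, 200 communities per simulated panel, and
  cohorts of a few hundred children per wave — sizes at which Monte-Carlo
  standard errors are a few thousandths of a score point per year.

# What passing tests do and do not show

The generator produces scores that are exact by construction and noise that
is Gaussian, independent across years and components; real survey data have
measurement error inside bands, correlated components, informative
missingness and design weights (out of scope here). Passing recovery tests
therefore demonstrate that the estimators are correct and calibrated under
the stated model, not that any particular real-world dataset satisfies that
model.

Known limitations worth stating plainly:

* Joinpoint selection is a post-model-selection procedure; the recovery
  suite itself measures a small upward bias of the post-break slope
  (~2% of the slope, ≈0.004 score points/yr for the rural-diet scenario,
  whose break sits early in the series where pre-break waves are sparse).
  This is inherent to break-point estimation at this noise level — we
  verified that continuous break refinement, segment-wise slope estimation
  and SSE-weighted model averaging all leave it in place — and is the reason
  one recovery assertion in the acceptance tests sits marginally outside its
  2-Monte-Carlo-SE band while all others pass.
* The CLPM is a classical cross-lagged model on community means: no
  random-intercept decomposition, no latent measurement model, listwise
  treatment for the global fit statistics.
* One-stage (individual-level) segmented regression is not implemented; the
  two-stage adjust-then-fit route is the supported design.
* An annual-percent-change (log-scale) parameterization is deliberately out
  of scope; slopes are in score points per year.
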