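---
title: "Methods: factor models and neighbor matching for path-mileage health prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factor models and neighbor matching for path-mileage health prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpphealth)
```

## The estimation problem

A city planner proposes adding path mileage to a census tract and wants the
expected change, in prevalence percentage points, of the tract's adverse
health outcomes several years later. No randomized experiment is available;
the only information is the city's own cross-section: tracts that already
differ in demographics, path infrastructure, and health. `bpphealth`
operationalizes the idea that *a tract's plausible future under added paths
is the present of tracts that are demographically similar but already have
those path habits*.

This requires (a) a low-dimensional, interpretable summary of "similar", and
(b) a guarantee that the summary separates demographic background from path
habits. Both come from an oblique three-factor measurement model — DBC
(demographics and background characteristics), health (adverse-outcome
burden), and BPH (bicycling and pedestrian habits) — fitted to
tract-by-year panels of ACS demographics, CDC-style prevalence estimates,
and mileage/use variables.

### Assumptions

1. Pairs of observed variables are approximately bivariate normal after
   standardization, so a linear factor model with ML estimation is
   appropriate.
2. The cross-sectional association between path habits and health reflects,
   at least in sign and rough magnitude, what a tract would experience over
   time if its path habits changed — the substitution of space for time that
   all matching estimators of this kind make.
3. Health outcomes are measured as prevalences in [0, 100] at the tract
   level; the mileage variable is the single lever a planner controls.

## Fitting pipeline

**Half split.** Tracts (never tract-years) are split at random; all years of
a tract stay together, so the confirmatory half is genuinely independent at
the unit of analysis. The EFA half takes the ceiling: a 77-tract city over
five years yields 195 EFA and 190 CFA tract-year rows.

**Iterative EFA.** Variables are z-standardized on the fitting half
(missing cells mean-imputed within year; variables missing in more than 20%
of tract-years dropped — complete-case analysis on a small city would be too
fragile). `stats::factanal` provides ML extraction with promax rotation.
Base R offers only ML extraction; a minimum-residual first stage, common in
dedicated factor-analysis packages, is not available, and ML is a standard
and defensible choice at these sample sizes. After each fit, a variable is
discarded when its absolute pattern loading is ≤ 0.5 on its assigned factor
(the argmax of absolute loadings) or ≥ 0.5 on any other factor. All
violators are discarded in one batch, and the loop repeats until a fixed
point; the discarded set grows monotonically, so at most one iteration per
candidate variable can occur. "Communality with respect to a factor" is read
as the absolute pattern loading: per-factor communality is not a standard
quantity, and the pattern loading is the coefficient actually tested by the
0.5 convention in the applied literature.

**Number of factors.** The smallest `m` in `3:max_factors` (default 6) whose
filtered solution converges and retains at least three variables per factor
wins. If a factor dissolves below three variables at some `m`, every
candidate re-enters the pool and the next `m` is tried. A panel with no
surviving three-factor solution (e.g. pure noise) raises a
requirements-unmet error rather than returning a degenerate model.

**Factor correlations.** The promax rotation matrix that `factanal` stores
is not guaranteed to share the column order of the loadings it returns, so
Φ is instead estimated by projecting the common part of the sample
correlation matrix onto the pattern matrix,
Φ = (ΛᵀΛ)⁻¹Λᵀ(R − Ψ)Λ(ΛᵀΛ)⁻¹, symmetrized and rescaled to unit diagonal.
On planted panels this recovers the generating correlations and yields
factor scores correlating above 0.9 with the truth (the scoring test
asserts this).

**Canonical orientation.** Each factor is flipped so its assigned variables
load positively; "high BPH" always means more path activity and "high
health" means a higher adverse burden. Without this, score signs would be
arbitrary across refits.

**Labeling.** Majority vote of the retained variables' category groups
(ACS → DBC, CDC prevalence → health, mileage/use → BPH), ties broken by the
larger mean absolute loading. The method's restrictions are then enforced:
all three labels present, a health-outcome variable in the health factor,
and the mileage variable in the BPH factor — otherwise the model is unusable
for prediction and an error says so.

**CFA.** No installed package provides confirmatory factor analysis, so the
estimator is written here: ML discrepancy
`F = log|Σ| + tr(SΣ⁻¹) − log|S| − p` with Σ = ΛΦΛᵀ + Ψ, simple-structure Λ
(off-assignments fixed at zero), Φ parameterized by a row-normalized
Cholesky factor (positive-definite with unit diagonal by construction), and
log-parameterized uniquenesses. Optimization is BFGS from the EFA solution;
a non-positive-definite Σ during line search returns a large penalty value
rather than failing. Fit indices are the standard CFI, TLI (capped at 1),
RMSEA, and SRMR against the independence baseline; default cutoffs
CFI ≥ 0.90, TLI ≥ 0.90, RMSEA ≤ 0.08, SRMR ≤ 0.08 are the conventional
"acceptable fit" values and are configurable. Confirmation additionally
requires every refitted loading to clear the 0.5 rule on the held-out half;
on confirmation the model's loadings are replaced by the CFA estimates.

**Scoring.** Regression (Thurstone) weights W = R⁻¹ΛΦ from the fitting
half. The package computes its own weights rather than using `factanal`'s
score option because frozen-model scoring is load-bearing downstream: the
variable centers/scales and the score mean/SD are stored in the model, and
`freeze_scoring()` pins them to the full city at the last fitted year.
Re-scoring one tract with hypothetical extra mileage then moves only that
tract. With `refit_standardization = TRUE` the constants are recomputed on
the scored set, which restores exact mean-0/SD-1 scores and makes scores
invariant to affine rescaling of any observed variable.

## The prediction algorithm

For query tract `q`, added miles Δ, and radius `x` (SD units, default 0.50):

1. add Δ to `q`'s mileage variable;
2. rescore `q` under the frozen model;
3. collect tracts within `x` of `q`'s DBC score;
4. collect tracts within `x` of `q`'s post-addition BPH score;
5. for each health outcome, the improvements are
   `{q's outcome − neighbor's outcome}` over the **intersection** of sets
   3 and 4, with negative values discarded; report min/mean/median/max/SD.

Three readings were genuinely open and are decided as follows:

- *Intersection vs union* of the two threshold sets: intersection. A
  counterfactual donor must be similar in background **and** in realized
  path habits; the union would admit tracts similar in only one dimension
  and is not conservative.
- *Sign of the difference*: query minus neighbor, so positive values mean
  the matched tract — similar except for path habits — carries a lower
  adverse-outcome prevalence. The discard rule exists to drop differences
  that would imply paths degrade health; that rationale only coheres with
  this orientation.
- *Boundary ties*: the comparison is a closed ball (`≤ x`), so a tract at
  exactly distance `x` is a neighbor. With continuous scores this almost
  never matters, but `x = 0` then cleanly yields an empty neighbor set.

An empty improvement list reports zero summaries with an `empty_flag` —
operationally, a tract where added paths are unlikely to be an effective
intervention — rather than `NA`s, so downstream aggregation never silently
drops tracts. The SD of a single improvement is reported as 0.

`sweep_increments()` evaluates the algorithm at every `step`-mile increment
(default 0.10) up to the requested total — the final partial increment is
always included so the full mileage is covered — and reports the maximum
median per outcome, encoding the assumption that more mileage is never
detrimental to the expected improvement. The maximum over a refined grid can
only grow, which the tests assert.

## Evaluation harness

For every intervened tract: the **ours** forecast is the intervention-year
observed outcome minus the sweep's best median (matching performed on the
last pre-intervention year, so the hypothetical addition is applied to a
panel that does not already contain it), clipped to [0, 100].
**Predict-no-change** is the tract's fit-window mean. The **regression
baseline** fits, per outcome, OLS of the fit-window change (last minus first
year) on an intercept and the DBC and BPH scores, and extrapolates the
fitted change to the horizon by linear time-rescaling (horizon/window
length) at the tract's post-addition scores. The training target for that
baseline is genuinely under-specified in the usual description of such
comparisons; window-start-to-end change with time rescaling is the simplest
member of the family and is stated here so results are reproducible.

MAE and RMSE are computed over tracts with a single prediction per tract;
their "mean (SD)" presentation is reconciled by reporting city-level
MAE/RMSE with nonparametric bootstrap SDs over tracts (default 1000
resamples, seeded — the SDs are deterministic given the seed). The paired
one-tailed t test uses per-tract `|error|` for the MAE comparison and
`error²` for the RMSE comparison, against the better alternative per
outcome. Zero-variance differences cannot support a t statistic: the p value
is 0 or 1 by the sign of the mean difference (1 when the approaches are
identical, so no significance is ever claimed from degenerate data) with a
degeneracy flag.

The horizon arithmetic takes the five-year lag literally: an intervention in
2016 with a 5-year lag realizes its effect in 2021, and the evaluation
compares forecasts against 2021 observations.

## The synthetic city

`generate_city()` draws tract-level factor scores and maps them to observed
variables by `z = Λf + u + e`, where `u` is the intrinsic uniqueness with
variance `1 − λᵀΦλ` (so communal variance is on the unit scale and a unit
loading with zero noise reproduces the factor exactly) and `e` is
measurement noise with SD `noise_sd`. Two same-factor variables with
loadings 0.9 and `noise_sd = 0.3` therefore correlate
0.81/(1 + 0.09) ≈ 0.74. Values are mapped affinely to each variable's
base/scale; prevalences are clipped to [0, 100]; the mileage variable is
drawn once per tract and held constant across years, since built
infrastructure persists.

Defaults define one coherent study world, chosen to mirror the data the
method targets and then left alone:

- **12 signal variables** (4 ACS on DBC, 4 CDC outcomes on health, mileage
  plus 3 use variables on BPH) with loadings 0.80–0.95. The CDC outcome
  loadings are highest (0.95) because real small-area prevalence estimates
  are model-based predictions from demographic inputs and carry little
  tract-idiosyncratic variance.
- **Factor correlations** corr(DBC, health) = −0.80,
  corr(health, BPH) = −0.60, corr(DBC, BPH) = 0.30: advantaged tracts are
  healthier and somewhat more active, and health is strongly — but not
  perfectly — determined by the other two factors, again reflecting how
  small-area estimates are constructed. Substantially stronger coupling
  makes the factors statistically inseparable and the EFA rightly fails.
- **Two distractors** cross-loading 0.45/0.45, both on the (DBC, BPH) pair —
  the factor pair whose dependence is linear throughout — so their planted
  sub-threshold pattern loadings are exactly interpretable. A 0.45 loading
  sits about 1.5 standard errors below the 0.5 filter at 200 tracts × 5
  years, so occasional retention of a distractor is statistically expected;
  recovery is therefore assessed as a rate over seeds, not as zero failures.
- **A DBC gate** at −0.75 true-score units, below which the BPH→health
  channel is severed in the cross-section, in the secular trend, and in the
  intervention response. This makes the "critical threshold" a property of
  the world rather than only of the intervention, which is what gives
  neighbor matching its advantage: below-gate queries are matched to
  below-gate donors whose outcomes carry no path benefit, while an ungated
  linear regression learns the above-gate trend and credits any mileage
  addition with improvement everywhere.
- **Dynamics**: AR(1) drift on outcomes (0.3 %-points/yr, φ = 0.7) so
  predict-no-change is not trivially perfect, plus a gated improvement trend
  of 0.08 variable-SD units per year per BPH SD for tracts above the gate.
- **Intervention**: saturating dose-response
  `max_drop · Δ/(Δ + half_sat)` with `max_drop = 3` %-points for the
  reference outcome, `half_sat = 0.5` miles, a 5-year lag, and small
  tract-by-outcome noise. Outcomes respond proportionally to their
  cross-sectional dispersion (a 1.2-SD stroke drop of 3 points would be
  absurd; dispersion-proportional drops keep the world consistent with the
  cross-section that the matching method reads). The default design adds
  0.3–2 miles to 40 of 195 tracts, about one mile per intervened tract.

**What passing tests show — and don't.** The recovery and baseline-beating
suites show the implementation is faithful to its specification in a world
where the method's assumptions hold by construction. They do not show that
real cities satisfy those assumptions: real panels have spatial
autocorrelation between adjacent tracts, nonuniform sampling bias in
app-derived use counts, measurement error correlated across years, and no
guarantee that cross-sectional gradients equal longitudinal responses. The
generator deliberately omits all of these.

## Numerical choices and degenerate inputs

- Problem sizes in the test and acceptance suites: recovery runs use 200
  tracts × 5 years over 20 seeds; evaluation replicates use 195 tracts with
  40 intervened over 10 seeds; the t-test calibration uses 2000 replicates
  of 31 paired observations. These complete in well under a minute each on a
  single CPU.
- Score standardization tolerances are 1e-8; oracle-equivalence comparisons
  are exact to 1e-12; the covariance rank check uses a 1e-8 relative
  eigenvalue threshold (double precision leaves residuals around 1e-9).
- `factanal` convergence failures at a given factor count are treated as
  "this m is not viable", not as fatal errors; only exhaustion of all m
  raises the requirements-unmet error.
- CSV round trips serialize numerics with 17 significant digits so panels
  survive write-then-read bit-exactly.
- The mile→km helper defaults to the international mile (1.609344 km/mi);
  `exact = FALSE` applies the 3-decimal planning approximation (1.609)
  found in municipal inventories, which is what published path-addition
  tables use.
- FIPS tract identifiers are opaque 11-character strings; no geometry is
  stored. GIS joining is assumed done upstream.

## Known limitations

- Only ML extraction is available for the EFA stage (base R constraint);
  minimum-residual or principal-axis extraction could retain slightly
  different variable sets near the 0.5 boundary.
- The CFA estimator handles the simple-structure, diagonal-uniqueness case
  this method needs; it is not a general SEM engine (no correlated errors,
  no equality constraints, normal-theory statistics only).
- Whether a real analysis should re-standardize all scores after a
  hypothetical mileage addition is debatable; this package freezes the
  model, which keeps the counterfactual local to the query tract and is the
  contract the predictor's tests rely on.
- The positive-part construction in step 5 (discarding negative
  differences) makes the improvement distribution an upper-leaning summary
  by design; the evaluation harness measures, rather than corrects, the
  consequences.
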