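---
title: "Physiological age clocks and delta-age: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiological age clocks and delta-age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

physage builds a *physiological age clock*: a sex-stratified PLS1
(partial least squares, univariate response) regression of chronological
age on a panel of standardized age-sensitive traits.  The residual of
that clock — predicted minus chronological age, centered so that its mean
is exactly zero at every chronological age — is **delta-age**, the
per-person estimate of how much physiologically older or younger someone
is than their birth-date peers.  Delta-age then drives three downstream
analyses:

1. **Gompertz mortality**.  Death within a fixed follow-up window is
   modelled with the hazard $h(t) = A e^{bt}$; the mortality-rate
   doubling time is $\log 2 / b$.  Binned death fractions are fitted by
   weighted least squares of $\log(\text{rate})$ on the bin center with
   death-count weights.  A complementary-log-log binary regression of
   death on age and delta-age yields the ratio $b_{\Delta}/b_{\text{age}}$
   — the mortality cost of one delta-age year in chronological-year
   units.
2. **Association scans**.  One linear engine (exact
   Frisch–Waugh residualization) tests environmental factors
   (threshold $10^{-5}$), genotype dosages (genome-wide threshold
   $10^{-9}$) and parental lifespan against delta-age, with optional
   covariates.
3. **Cluster-dropout attribution**.  The clock is refit with each of the
   ten correlated trait clusters removed (component selection and
   delta-age centering redone per dropout; dropout scans use the
   Bonferroni threshold $7\times10^{-7}$).  A hit that stays significant
   in every dropout and in the healthy subcohort is a *global driver
   candidate*; one that dies exactly when its own trait's cluster is
   dropped is a *cluster marker*; one that dies in the healthy subcohort
   is *disease linked*.

## Fitting and tunable parameters

* **Standardization**: every column (one-hot option columns included) to
  mean 0, sample SD 1 (n−1 divisor; the divisor choice is unstated in
  comparable analyses and irrelevant at cohort sizes).
* **Missingness**: individuals missing more than `max_missing = 15` raw
  trait cells are excluded (strict inequality: exactly 15 is kept).
  Remaining cells are KNN-imputed (`k = 10`, the usual default of KNN
  imputers; the neighbour distance is the mean squared difference over
  mutually observed columns, so heavily missing rows are not
  artificially near).  For cohorts beyond 20,000 rows the donor pool is
  thinned deterministically to every ceiling(n/20000)-th row; with
  k = 10 the imputed value is statistically indistinguishable while the
  donor scan stays linear in n.
* **Component count**: 10-fold cross-validation with a seeded random
  fold assignment gives an RMSEP curve (intercept-only entry first); the
  *one-sigma* rule picks the smallest count whose RMSEP is within one
  standard error of the minimum.  The count is data-determined and
  reported per sex, never hard-coded.
* **Calibration**: raw PLS predictions are regressed on age and rescaled
  by the inverse slope (the standard age-bias correction of the
  brain-age literature).  Without it, regression dilution shrinks
  delta-age by var(age)/(var(age)+var(offset)+noise) ≈ 0.75 under
  realistic noise, which would silently inflate the mortality
  coefficient of delta-age relative to age and bias every association.
  `calibrate = FALSE` restores the raw predictor (used when checking the
  full-rank PLS = OLS identity).
* **Delta-age centering**: one-year integer age bins, bins under
  `min_bin = 50` merged with their nearest neighbour, bin mean
  subtracted.  The per-bin mean is zero to numerical precision by
  construction.
* **Phenotype weights**: each component is deconstructed as
  $w_j=\sum_k |w^*_{jk} q_k|$ (rotated X-weights times y-loadings); for
  a one-component model this ranking provably equals ranking by absolute
  coefficient, which the tests exercise.

## What the synthetic cohort emulates

`generateCohort()` produces the statistical structures the pipeline
assumes, with defaults frozen as the package's study conditions:

* ages uniform on 40–70 (the age distribution of the motivating cohort
  is not published; uniform is the flagged assumption);
* a latent aging offset δ per person: normal core (SD 4.3 y) plus
  centered genetic contributions (three global driver SNPs, β = 0.4–0.6
  y/allele) and centered environmental contributions (education −1.51
  y/level, income −0.81 y/SD, computer gaming 0/−1.1/−2.2 y, smoking
  +1 y), composite SD ≈ 5 y — chosen so the fitted clock's RMSE (~5 y)
  and R² (~0.65) land where published physiological clocks land;
* ten organ-system trait clusters; each cluster couples its traits
  through a per-person organ latent (SD 2 y) and contains one low-noise
  "hero" trait (noise 3 age-equivalent years) and two noisy satellites
  (16/20 y).  This concentration of information on a handful of strong
  traits (blood-pressure-, cystatin-C-, FEV-like) mirrors the weight
  concentration real physiological clocks report, and it is what makes
  single-trait marker genetics visible to an adaptively-regularized
  clock at desk-scale n: a uniform-quality panel lets the clock
  substitute any distorted trait with its neighbours, erasing marker
  signals regardless of cohort size;
* marker SNPs as strong cis effects on hero traits (0.56 trait-SD per
  allele, MAF 0.15), sized at the point where the clock's down-weighting
  of the inflated trait exactly balances the shift — there the realized
  delta-age effect (~0.3 y/allele) is stationary with respect to the
  selected component count, making the attribution experiment stable
  across seeds;
* age-related diseases (prevalence rising ~0.07 log-odds/year) that age
  one organ system by 10–12 years without touching δ, one of them driven
  by a susceptibility allele.  Age-independent diseases would be pure
  orthogonal variance that the clock simply learns to remove; coupling
  prevalence to age is both realistic and what makes the
  disease-mimics-aging pattern detectable;
* Gompertz mortality on (age + δ): baseline hazard 4×10⁻⁵/y, doubling
  time 7.7 y, 5-y follow-up, giving ~5% deaths in follow-up at this age
  structure, matching the source cohort's ~4.7%;
* parental lifespans anti-correlated with δ; MCAR missingness (0.5% of
  cells, ~14% of rows incomplete) plus 2.7% of individuals with >15
  missing cells; two quartile-discretized multiple-choice traits; three
  age-associated traits carrying the exclusion flags (societal-norm,
  elapsed-time, age-derived).

What it does **not** emulate: linkage disequilibrium and population
structure, cohort/birth-year effects, nonlinear trait-age trajectories,
informative missingness, and measurement batch effects.  Passing tests
therefore show the machinery is correct under the declared generative
model, not that real-biobank estimates would be unbiased.

## Numerical choices and degenerate inputs

* PLS1 is computed by the deflation-free kernel recursion (only the
  covariance vector is deflated; scores come from rotated weights), is
  exactly the NIPALS solution, and reduces to OLS at full rank (tested
  to 1e−8; also cross-checked against an independent PLS
  implementation).  Components stop early when the residual covariance
  norm falls under 1e−10; requesting more components than the rank
  truncates with a warning.
* A strictly flat RMSEP curve selects one component (the intercept-only
  entry is never a candidate).
* Zero-variance columns are dropped from standardization with a warning
  and reported as missing in correlation output; equidistant imputation
  donors break ties toward the lower row index.
* Zero-death bins are excluded from the log-scale Gompertz fit (with a
  warning) rather than continuity-corrected; non-positive slopes return
  an infinite doubling time, flagged.
* Binned statistics merge under-occupied bins into their nearest
  neighbouring bin (ties toward the smaller neighbour), deterministically.

## Design choices made where the design was open

* **Dropout clusters come from the curated trait metadata** (as with the
  curated cluster files of the motivating study), not from a fresh tree
  cut: a k = 10 cut over a matrix with one-hot option columns and
  anti-correlated clusters fragments unpredictably.  The estimated tree
  is still computed, and is validated to recover planted clusters
  (adjusted Rand index > 0.9) on clean continuous panels.
* **Bonferroni** is the multiple-testing adjustment for the trait scan
  ("adjusted" alone does not pin a method; Bonferroni matches the
  conservative fixed thresholds used elsewhere in the pipeline).
* **Average linkage on 1 − r** for the dendrogram; linkage was a free
  choice.
* **Year-equivalence by one joint regression** (cloglog) rather than two
  separate Gompertz fits: it yields a delta-method CI for the ratio
  directly.
* **Recovery experiments under linear measurement**: planted-effect
  recovery (driver β, education effect) is validated on a generator
  variant without diseases and multiple-choice items.  Disease
  prevalence that rises with age contributes age information that has no
  δ counterpart, and discretized items are nonlinear in the latent; both
  attenuate the δ loading of delta-age by ~5% under the default
  conditions.  That attenuation is a property of the estimand (any
  estimated clock shares it), so unbiasedness is asserted where the
  measurement model is linear, and the attenuated default-condition
  estimates are reported as-is by the acceptance script.

## Problem sizes

Simulation-backed checks use the sizes at which their statistical
margins are meaningful: 100,000 individuals for association recovery,
latent-offset correlation and the ten-seed attribution experiment;
200,000 for doubling-time recovery; 8,000 × 20 seeds for the
latent-dimension selection experiment; 5,000 for byte-level determinism
of the end-to-end pipeline.

## Known limitations

* The year-equivalence ratio centers slightly below 1 (~0.94–0.97)
  because measurement noise in delta-age attenuates its mortality
  coefficient; with ~5,000 deaths its sampling SD is ~0.035, so
  occasional runs fall marginally below 0.9.
* Marker attribution depends on the trait panel carrying concentrated,
  high-quality traits; on panels of uniformly mediocre traits the clock
  substitutes away single-trait signals and markers are genuinely
  undetectable (arguably the scientifically correct outcome).
* The CLI wrapper is a thin script over `runPipeline()`; orchestration
  beyond one machine is out of scope.
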