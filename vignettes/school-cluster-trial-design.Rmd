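---
title: "Designing school-based cluster trials for children's physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing school-based cluster trials for children's physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `papower`, the
meaning, units and defaults of its parameters, how the synthetic-data
generator is calibrated, and the numerical choices that determine its
answers. It is a methods reference; the README shows the corresponding
worked examples.

## 1. The planning problem

School-based interventions for children's physical activity are evaluated
by randomising schools, not pupils. Accelerometer outcomes — here, minutes
per day of moderate-to-vigorous physical activity (MVPA) or sedentary time,
averaged over valid wear days and split into weekday and weekend values —
cluster within schools. The key design inputs are:

- **ICC** (intra-cluster correlation, `icc`, dimensionless in (0, 1)): the
  share of outcome variance attributable to schools. Doubling a plausible
  ICC can raise the required number of schools by tens of clusters, and
  under-stating it silently converts a nominally 80%-powered trial into a
  much weaker one.
- **CAC** (cluster autocorrelation, `cac`): the correlation of a school's
  *underlying mean* between two measurement waves. It governs how much a
  longitudinal design (stepped wedge, ANCOVA) can learn from repeated
  measurement of the same schools.
- **IAC** (individual autocorrelation, `iac`): the correlation of a
  *pupil's underlying level* between two waves; it matters only when the
  same pupils are measured repeatedly (cohort designs, baseline
  adjustment).
- **Total SD** (`sd_total`, minutes/day): the square root of
  σ²~school~ + σ²~pupil~ + σ²~resid~ for the population and outcome being
  planned.
- `m`: pupils measured per school per period; `delta`: the target
  difference in minutes/day.

## 2. Outcome model

For pupil *j* in school *k* of study *s* at wave *t*:

Y~skjt~ = μ + **x**′β + u~s~ + v~skt~ + w~skjt~ + e~skjt~

- u~s~ ~ N(0, σ²~study~): between-study heterogeneity (different cohorts,
  instruments, regions). It is *excluded* from the ICC denominator by
  default, because a trial is run within one study-like setting; the
  planning-relevant ICC is the within-study school share. Set
  `include_study = TRUE` in `icc_from_components()` to include it.
- v~skt~: the school effect at wave *t*, with Var = σ²~school~ and
  Corr(v~skt~, v~skt′~) = π (the latent CAC), implemented as
  √π·A~sk~ + √(1 − π)·B~skt~ with independent standard-normal parts, i.e.
  exchangeable across waves.
- w~skjt~: the pupil effect, Var = σ²~pupil~, exchangeable across waves
  with correlation τ (the latent IAC).
- e~skjt~ ~ N(0, σ²~resid~): occasion-level measurement noise
  (wear-time variation, weather, device error), independent across waves.

Fixed effects **x** comprise year group (with defaults giving younger
year groups higher MVPA), gender (default +8 min/day for boys), and
registered wear time in minutes (centred; default mean 780, SD 60).

### Estimation

`fit_variance_components()` fits this model by REML with `lme4`:
random intercepts for study, school and (when any pupil has repeated
measurements) pupil. With a single study the study intercept is dropped —
one draw cannot identify a variance — and σ²~study~ is reported as 0 with
a warning. Per-year-group school variances use independent school-level
slopes on year-group indicators (`(0 + yg1 + ... || school_id)`), with a
per-year-group subset refit as fallback if that model fails.

`lme4` does not expose a covariance matrix for variance components, which
the delta-method interval needs. The package computes it as 2 × the
inverse of the numerical Hessian (via `pracma::hessian`) of the profiled
REML criterion `lme4::devfun2` on the standard-deviation scale, then maps
it to the variance scale with the Jacobian diag(2·sd). Non-positive
curvature (boundary fits) falls back to a pseudo-inverse, or to an `NA`
covariance with a one-sided interval when the ICC itself is at 0.

### Confidence intervals on the logit scale

A Wald interval for a small ICC easily crosses 0. The package instead
applies the delta method twice: var-component covariance → se(ICC) →
se(logit ICC) = se(ICC) / [ICC·(1 − ICC)], builds the normal interval on
the logit scale and back-transforms, guaranteeing an interval inside
(0, 1). At ICC exactly 0 or 1 the logit is undefined and
`logit_delta_ci()` refuses; `icc_from_components()` then reports a
one-sided raw-scale bound.

### Baseline adjustment

`baseline_adjusted_icc()` pairs each pupil's measurement with their own
previous-wave value and refits the model with that baseline as a fixed
covariate. When pupils track over time (IAC > 0) this removes predictable
variation, shrinking both the residual SD and, typically, the ICC — the
inputs `required_schools_ancova()` expects.

## 3. Autocorrelation estimation

`empirical_cac()` correlates school-level means between two waves, using
only schools with at least `min_pupils = 5` measured pupils in *both*
waves, and only pupils who are recorded in the *same* school at both waves
(movers would mix two schools' means). `empirical_iac()` correlates
individual pupils' values between waves; movers are retained there, since
the pupil is the unit. Either estimator requires at least 4 qualifying
units for a correlation worth reporting.

`estimate_autocorrelations()` sweeps all wave pairs within each study;
`pool_correlations()` transforms each r to Fisher's z = atanh(r) with
variance 1/(n − 3) and pools by DerSimonian–Laird random-effects
meta-analysis (`metafor::rma`, method `"DL"`; `"FE"` available),
optionally binned by follow-up length (under 1 year vs whole years), and
back-transforms the pooled z and its interval with tanh.

## 4. Design calculations

### Two-arm parallel cluster RCT

With k schools per arm and m pupils per school, the difference in arm
means has variance 2σ²·DE/(km), DE = 1 + (m − 1)ρ. Because k is small,
the package uses the *t* distribution with 2(k − 1) degrees of freedom:
power = P(T > t~crit~) for noncentral T with ncp = δ/se, t~crit~ the
two-sided α critical value. `required_schools_crct()` iterates k upward
from 2 until power ≥ target — no normal-approximation shortcut, which at
these sizes can differ by several schools. `required_schools_ancova()`
is the same calculation run on baseline-adjusted SD and ICC.

### Stepped wedge

A complete stepped wedge with S steps has S sequences and T = S + 1
periods; sequence *s* switches to intervention from period *s* + 1. The
cluster-period mean has between- and within-cluster variance

- v~b~ = π·ρ·σ² + [cohort]·τ·(1 − ρ)·σ²/m
- v~w~ = (1 − π)·ρ·σ² + (1 − [cohort]·τ)·(1 − ρ)·σ²/m

where the τ terms appear only for cohort designs (same pupils each
period); cross-sectional designs draw fresh pupils, so only the school
effect persists. These feed the closed-form Hussey–Hughes GLS variance of
the treatment effect,

Var(θ̂) = I·v~w~·(v~w~ + T·v~b~) / [(IU − W)·v~w~ + (U² + ITU − TW − IV)·v~b~]

with I clusters, U = ΣX, W = Σ~t~(Σ~i~X~it~)², V = Σ~i~(Σ~t~X~it~)².
Power uses the normal approximation (GLS estimator, many cluster-periods):
power = Φ(δ/√Var − z~1−α/2~). `required_schools_sw()` searches total
school counts that are multiples of S (equal sequences), returning the
smallest reaching the target. S ≥ 2 is required: with one sequence the
treatment indicator is collinear with the period effects and the GLS
variance is undefined.

The test suite validates the closed form against a brute-force
block-matrix GLS inversion on randomized designs to 1e-8.

### Mis-specification

`achieved_power(..., true_icc = )` re-evaluates a sized design's power
under a different true ICC. This is how the package quantifies the cost of
under-estimated clustering, e.g. sizing at ICC 0.04 versus a true 0.08.

## 5. The synthetic-data generator

`sim_config()` assembles a generator configuration with two phase
presets:

| parameter | primary | secondary | units / note |
|---|---|---|---|
| grand mean | 55.8 | 54.7 | min/day weekday MVPA |
| ICC | 0.08 | 0.05 | school share of within-study variance |
| total SD | 23.2 | 27.5 | min/day |
| pupils/school | 25 | 50 | per wave |
| latent CAC | 0.6729 | 0.6571 | see calibration below |
| latent IAC | 0.5 | 0.5 | |
| σ²~study~ | 57.5 | 10 | between-study spread |
| year-group effects | +1/0/−4 | +4/+1/−3 | Y1–4/Y5/Y6 and Y7/Y8–9/Y10–11 |

All defaults can be overridden. Outcomes are drawn as Gaussian sums of the
components above, clamped at zero (minutes cannot be negative), with MCAR
missingness per outcome cell (`missing_rate`, default 0.15), a valid-day
count per pupil-wave, and companion outcomes (weekly MVPA, sedentary time)
derived from the same latent pupil level so they correlate realistically.
Pupils crossing the Y6→Y7 boundary between waves are reassigned to a
secondary `school_id`. `filter_valid()` applies the standard
at-least-2-valid-days inclusion rule. `write_observations()` /
`read_observations()` round-trip the fixed 14-column CSV layout.

### Calibration of latent vs observable autocorrelations

The empirical CAC is computed from *school means of m pupils*, which
contain pupil and residual noise, so it is an attenuated version of the
latent π:

corr(ȳ~t~, ȳ~t′~) = (π·σ²~s~ + τ·σ²~p~/m) / (σ²~s~ + (σ²~p~ + σ²~e~)/m)

and the pupil-level correlation is (π·σ²~s~ + τ·σ²~p~)/σ². The default
components were chosen **once, by closed-form inversion before any
estimation test was run**, so that these *observable* correlations equal
0.60 (school) and 0.46 (pupil) at the phase defaults — e.g. for the
primary phase, fixing τ = 0.5 and solving gives π = 0.6729,
σ²~p~ = 437.23, σ²~e~ = 57.95 alongside σ²~s~ = 43.06.
`theoretical_moments()` returns both the latent (`cac`, `iac`) and
observable (`cac_observed`, `iac_observed`) values, and the recovery
tests target the observable ones — the honest oracle for what the
estimators can see.

### What the generator does not emulate

Real accelerometer data are right-skewed with floor effects beyond simple
zero-clamping; wear-time and missingness are informative (less active
children wear devices less), not MCAR; school effects drift rather than
staying exchangeable across many waves; and pupils move schools for many
reasons besides the primary–secondary transition. The generator is a
*calibration target* for the estimators and design formulas, not a
population microsimulation. Zero-clamping also shaves the marginal SD
slightly below the Gaussian components' implied value (about 1% at the
primary defaults), which the calibration tests' tolerances cover.

## 6. Numerical choices, in one place

- cRCT sizing: noncentral-*t* with 2(k − 1) df, iterative minimal k;
  stepped wedge: normal approximation, minimal multiple of S.
- ICC denominator excludes σ²~study~ by default.
- Intervals: delta method on the logit scale; boundary ICC of 0 →
  one-sided raw bound; non-invertible Hessians → pseudo-inverse or NA.
- CAC: ≥5 pupils per school per wave, same-school pupils only, ≥4
  schools; IAC: ≥4 pupils, movers retained.
- Pooling: Fisher z, variance 1/(n − 3), DerSimonian–Laird by default.
- Stepped wedge requires S ≥ 2 and total schools divisible by S.

Test problem sizes (e.g. 200 replicates of 50 schools × 25 pupils for the
ICC bias check, 150 replicates of 500 schools for interval coverage, 5
studies × 30 schools × 50 pupils × 2 waves for autocorrelation recovery)
are the package's own choices, balancing Monte-Carlo error against a
single-CPU test-suite budget.

## 7. Limitations

- The stepped-wedge power uses a normal approximation; with very few
  clusters a small-sample correction (as used for the cRCT) would be
  conservative but is not implemented for that design.
- Exchangeable (compound-symmetric) correlation across waves; no
  decaying-autocorrelation structures.
- Complete stepped wedge designs only (equal sequences, one crossover per
  step, no transition periods).
- Gaussian outcome model; counts or bounded scores need transformation
  before the variance decomposition applies.
- The CAC/IAC estimators are pairwise Pearson correlations, not a joint
  longitudinal model; with many waves a joint model would be more
  efficient.
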