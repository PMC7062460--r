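---
title: "Move-to-hold integration: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Move-to-hold integration: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movehold)
```

## The model

When a limb movement ends, motor output does not fall back to its starting
level: muscles and hand forces settle on a new hold level appropriate to the
new posture. The serial integrator hypothesis holds that the hold command is
produced by time-integrating the move command, as the oculomotor system does
for gaze. Writing the measured output of one effector channel (a muscle's
normalized EMG, or the lateral channel-trial force) as `u(t)`, the model
decomposes it into a transient move command `m(t)` and a sustained hold
command `h(t)`:

    u(t) = m(t) + h(t),
    h(t) = u(h1) + k * integral from t0 to t of m(tau) dtau,

where `u(h1)` is the hold level before movement and `k` (units 1/s) is the
integration gain. Because `k` is not known a priori, the testable prediction
replaces `m` with the hold1-subtracted signal and absorbs the resulting
systematic error into an offset `a`:

    u(h2) - u(h1) ~ k * integral from t0 to T of [u(tau) - u(h1)] dtau + a.

`fit_integration()` estimates `k` and `a` by ordinary least squares across
trials; `decompose_move_hold()` solves the first pair of equations forward
in time for `m(t)` given an assumed `k`.

Around the hold posture, the package models the field of restoring forces as
a two-dimensional linear spring, `F = K (p - p_null)` with symmetric `K`
(N/cm): `fit_spring_model()` estimates the five parameters from probe
forces, `field_orientation()` and `field_stiffness()` summarize `K` by its
leading eigenvector and Frobenius norm, and `estimate_null_point()` locates
the zero crossing of along-probe forces. Perturbation analyses use the curl
field `f = b * R90 * v` and the two-parabola position field whose spatial
integral cancels when its components oppose.

## Window conventions and preprocessing

All hold windows are half-open `[start, start + duration)` in seconds, with
0-based sample indexing; the presets in `window_preset()` store the
conventions used throughout:

| preset | h1 (re onset) | h2 (re offset) | lead | cutoff |
|---|---|---|---|---|
| `monkey_reach_out` | [-700, -350] ms | [+300, +450] ms | 140 ms | 850 ms |
| `monkey_reach_back` | [-300, -200] ms | [+300, +450] ms | 140 ms | 850 ms |
| `monkey_finger` | 400 ms from -1000 ms | 200 ms from +700 ms | 150 ms | none |
| `human_force` | 100 ms from -500 ms | 100 ms from +900 ms | none | none |

The integration lead starts the move integral before kinematic onset to
capture command changes that precede movement. Movement events come from
speed thresholds (1 cm/s onset, 3.5 cm/s offset). Because transient
re-crossings near movement end are not otherwise specified, the offset
requires the speed to stay below threshold for a 50 ms dwell — a design
choice of this package, configurable in `detect_onset_offset()`.

EMG preprocessing rectifies and smooths with a Gaussian kernel (SD 20 ms for
reach EMG, 200 ms for slow finger tracking), truncated at ±4 SD and
renormalized to unit sum. Edge handling is by kernel renormalization over
the available samples rather than padding (another choice this package
makes explicit): constants pass through exactly and interior signal mass is
conserved to better than 1e-6. Baseline forces are the onset-aligned mean
over null-period channel trials, truncated to the shortest trace before
averaging.

## Numerical choices

* **Quadrature.** All integrals are trapezoidal on the sampled grid, with
  linear interpolation at window bounds. Deterministic and second-order
  accurate, which is what sampled data supports.
* **Decomposition recursion.** In `decompose_move_hold()` the current
  sample's `m` appears inside its own trapezoid term; the implicit step is
  solved in closed form, so the recursion is bit-reproducible and the
  reconstruction `m + h = u` holds to machine precision for any `k >= 0`.
* **Spring fit.** For a fixed null point the three stiffness parameters are
  linear, so they are profiled out by closed-form normal equations and the
  search reduces to a seeded 8-restart Nelder-Mead over the null point
  alone. This replaces a stochastic global search with a deterministic
  equivalent at the same summed-squared-force objective. Only samples
  inside the elliptical mask (half-axes 2.25 cm in x, 1.5 cm in y around
  the terminal hand position) enter the fit.
* **Exponential null-point fit.** The three-parameter form `A exp(B d) + C`
  is fitted by profiling: `A` and `C` are linear given `B`, leaving a 1-D
  optimization over `B` in [-4, 4] per cm, centred on the mean displacement
  for numerical range. When the optimal `|B|` falls below 1e-3 per cm the
  exponential is indistinguishable from a line and a linear fit supplies
  the intercept; on exactly linear data the intercept is recovered to
  better than 0.01 cm.
* **Probe ramps.** The probe's entry and exit ramps are quintic
  polynomials with boundary conditions: start at rest with zero
  acceleration, end at the plateau speed with zero acceleration after
  covering the ramp displacement. A classical minimum-jerk segment ends at
  rest, which a ramp into a constant-velocity phase cannot; the boundary
  set used here is the natural generalization and reproduces the printed
  phase timings exactly (7.67 s, 11.67 s, 15.03 s totals for the 2.5, 4
  and 5 cm probes; 5.87 s constant phase for 2.5 cm). Infeasible boundary
  combinations (those forcing a velocity reversal) raise an error.
* **Ratio gain guard.** `integration_gain(method = "ratio")` refuses when
  the median move integral is below 0.05 N·s, directing to the regression
  estimator — the null-period regime where the ratio is undefined in
  practice.
* **R-squared.** Reported as the squared correlation of fitted and
  observed values, which equals the coefficient of determination for these
  simple regressions. Where published values are phrased as "correlation
  coefficients" in percent, `restricted_hold1_filter()` reports both `r`
  and `r^2` so either reading can be checked.

## What the simulator emulates — and what it does not

`simulate_channel_trial()` and its cohort wrappers implement the serial
architecture directly: a move-force burst (bell, triangular, or biphasic
with zero integral) whose trapezoidal integral, scaled by `k_true` plus the
offset `a_true`, sets the hold-force plateau. Onset/offset events are
embedded exactly, and the hold force rises smoothly over 0.3 s after
movement offset — strictly after the integration window, so at zero noise
every downstream estimator is exact (the master consistency test). Hold
plateaus are constant by default, consistent with holding forces that are
sustained for several seconds; no decay term is included.

Defaults describe a human channel-trial experiment: 200 Hz sampling, 0.5 s
reaches, burst amplitude 4 ± 1.2 N across trials, hold-step noise 0.3 N and
sensor noise 0.05 N. The hold noise was set so the within-trial integration
statistic explains about half the hold-force variance, matching the range
reported for null-field and adaptation cohorts; at those levels the gain is
recovered from 150 trials with a relative SE near 0.09.

The trial-to-trial learner in `simulate_adaptation_experiment()` is a
single-state linear model (retention `A`, error sensitivity `B`) and the
optional gain-adaptation rule is a simple error-proportional decrement.
Both are testing scaffolding: they generate the gradual force growth the
schedules induce so the pipeline can be exercised end to end, and make no
claim about how humans adapt. Likewise the cosine directional tuning in
`simulate_emg_cohort()` is the minimal structure producing
direction-dependent bursts and suppressions; real muscles are not cosine
tuned, real EMG noise is not Gaussian, and real hold plateaus drift.
Passing recovery tests on these cohorts validates the estimators under the
model's own assumptions, not the biological claim.

## Problem sizes used by the test-suite experiments

The validation experiments are sized to run on one CPU in a few minutes:
parameter recovery uses 50 cohorts of 150 trials; spring-field recovery
uses 100 sessions of 12 rays with force noise at 10% of the largest probe
force; bootstrap coverage uses 200 cohorts of 19 subjects with 400
bootstrap replicates each (the estimator default is 2000); the noise-
scaling check uses 30 cohorts of 60 trials per noise level.

## Known limitations

* The percentile bootstrap interval that `estimate_null_point()` reports —
  the interval the original analysis used — undercovers slightly at small
  cohort sizes: at 19 subjects, measured coverage of the nominal 95%
  interval is 91-93% across realistic noise structures. This is the
  familiar small-sample behaviour of percentile intervals for nonlinear
  functionals; users who need calibrated small-n intervals should treat
  the reported CI as approximate.
* With the within-trial variance explained near its realistic value
  (~40-50%), the gain's relative standard error at 150 trials is
  0.08-0.10, so individual cohorts occasionally miss the gain by more than
  20%; recovery statements in that regime are distributional, not
  per-cohort guarantees.
* The spring model is linear by construction; curvature or asymmetry of
  real postural fields is absorbed into the residual and lowers the fit's
  R-squared rather than biasing the reported null point in any controlled
  way.
* `cross_predictor_regressions(mode = "position")` requires hold-period
  positions recorded per trial and regresses within condition only;
  pooling across hold conditions inflates the position R-squared through
  between-condition separation and is deliberately not offered.

## Reading published source tables

`read_source_table()` maps spreadsheet headers onto the package's logical
fields through schemas in `source_schemas()`. Header matching is
case-insensitive and punctuation-free, unmapped columns are dropped with a
notice, and a workbook's readme tab, when present, is attached to the
result so the mapping can be verified against the file's own documentation.
The shipped schemas are provisional defaults in exactly that sense.
`reproduce()` recomputes each built-in check from its declared source and
reports `skipped: data unavailable` — not failure — for file-backed checks
whose spreadsheet is not present locally.
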