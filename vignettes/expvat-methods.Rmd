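---
title: "Objective VAT estimation from exponential fits of ramp CPX data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective VAT estimation from exponential fits of ramp CPX data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expvat)
```

## The problem

During incremental (ramp) exercise, CO2 output and ventilation accelerate
relative to O2 uptake once buffering of lactic acid begins. The exercise
intensity at which this happens — the ventilatory anaerobic threshold (VAT),
expressed as a VO2 in mL/min — is a clinically useful submaximal index of
exercise tolerance, but its classical determination is visual: a reader
inspects the V-slope (VCO2 plotted against VO2) and marks where the curve
breaks away from the pre-threshold segment. That makes VAT ultimately
subjective and hard to blind.

This package computes two *objective* VAT estimates from closed-form tangent
constructions on exponential fits of the ramp data, together with the oxygen
uptake efficiency slope (OUES), quality control, agreement statistics,
truncation sensitivity analyses, and a simulator with known true thresholds
for validation.

## The model and the two estimators

Ramp-phase breaths (resting, warm-up and recovery breaths are excluded) are
fitted with a single exponential in VO2,

$$y = b\,a^{x},$$

where $x$ is VO2 in mL/min and $y$ is either VCO2 (mL/min) or VE (L/min).
Because $x$ is in mL/min, the base $a$ is numerically close to 1 (fitted
values are typically 1.0010–1.0020); $a$ summarises the steepness of the
whole curve, with a smaller $a$ (slower rise) corresponding to a higher
threshold.

Two tangent constructions then give the estimates in closed form:

* **expVAT(VCO2).** On the V-slope, the respiratory exchange ratio
  R = VCO2/VO2 equals 1 along a line of slope 1. The VO2 at which the
  tangent to the fitted curve is parallel to that line — i.e. where the
  instantaneous dVCO2/dVO2 is exactly 1 — solves
  $b\,a^{x}\ln a = 1$, giving
  $$x_0 = \frac{\ln\!\big(1/(b \ln a)\big)}{\ln a}.$$

* **expVAT(VE).** On the VO2–VE plot, the ventilatory equivalent VE/VO2 is
  the slope of the chord from the origin. The VO2 at which the tangent to
  the fitted curve passes through the origin is
  $$x_0 = \frac{1}{\ln a},$$
  independent of $b$, and is exactly the minimiser (nadir) of the fitted
  VE/VO2 — the point where the ventilatory equivalent turns from falling to
  rising, which is itself a recognised threshold criterion.

Both constructions are undefined when $a \le 1$ (the fitted curve never
steepens) and expVAT(VCO2) additionally requires $b\ln a < 1$ (otherwise the
tangent point lies at non-positive VO2). In those cases the estimate is
returned as missing with an explanatory flag rather than an error, because
batch cohort work needs per-subject missingness bookkeeping.

```{r tangent}
fit <- fit_exponential(seq(500, 2000, 50), 300 * 1.0015^seq(500, 2000, 50))
x0 <- expvat_vco2(fit)
c(expvat = x0, slope_at_x0 = fit$b * fit$a^x0 * log(fit$a))
```

### OUES

The oxygen uptake efficiency slope is the OLS slope of VO2 (mL/min) on
log10(VE); the analogous VCO2 variant log-transforms VCO2 instead. The
logarithm base is not universal in older literature; base 10 is used here,
the convention of the OUES literature, so slopes are in mL/min per decade.
Rescaling the channel only shifts its logarithm, so the slope is invariant
to the channel's unit — VE is nevertheless fixed at L/min for cross-study
comparability of intercepts.

## Fitting choices

The default fit is **log-linear**: OLS of ln(y) on x, with
$a = e^{\text{slope}}$, $b = e^{\text{intercept}}$. This is what spreadsheet
exponential-trend fitting computes, which is how such fits are typically
produced in clinical practice; a true nonlinear least-squares refinement
(Levenberg–Marquardt, initialised from the log-linear solution) is available
via `method = "nonlinear"` and coincides with it on noise-free data. Fit
quality `r_fit` is the Pearson correlation between observed and fitted
values on the *original* scale, not the log scale, since that is the scale
on which the fit is judged. Breaths are unweighted, and no breath averaging
or interpolation is applied before fitting by default — whether vendor
systems time-average before export varies, and the raw-breath default keeps
the estimator's input explicit. `highest_values()` likewise defaults to the
raw last-highest-value convention (rolling window of 1 breath), appropriate
for submaximal protocols; a wider window gives conventional peak averaging.

## Quality control

* **Pre-threshold slope validity.** If a test never crossed the threshold,
  an exponential can still be fitted and a (meaningless) expVAT computed.
  The guard is the linear slope of the whole-test V-slope: the
  pre-threshold segment has slope ≈ 0.90 with SD ≈ 0.10 across subjects, so
  a whole-test linear slope below mean + 2 SD = **1.105** indicates the
  threshold was likely never reached and the estimates are flagged
  (`pre_vat_slope_below_threshold`).
* **Fit-outlier screening.** Across a cohort, poor fits (hyperventilation
  artifacts, too few breaths) depress the fit-quality r. `grubbs_screen()`
  applies the Smirnov–Grubbs test iteratively (default α = 0.001, lower
  tail, one exclusion per step, repeated until none exceeds the critical
  value from the t distribution); `batch_estimates()` flags excluded
  subjects `poor_fit_outlier`.
* **Sanity bound.** Estimates above 1.5 × the highest observed VO2 are
  extrapolations well past the data and are flagged (not erased); fitting
  problems concentrate in subjects with high exercise tolerance.

## Agreement statistics

`bland_altman()` reports the mean difference, the SD of differences (n−1
denominator) and the limits-of-agreement half-width 1.96 × SD.
`williams_test()` compares two dependent correlations sharing a variable
(e.g. is expVAT better correlated with VO2peak than with the visual VAT?)
with the standard t statistic on n − 3 degrees of freedom.
`correlation_matrix()` is pairwise-complete — visual thresholds go
undetected in a meaningful fraction of submaximal tests, and listwise
deletion would shrink every estimator's n to the visual method's — and
reports the per-pair n alongside every cell.

## Truncation sensitivity

Because the estimators summarise the whole curve, they depend on how far
past the threshold the test was carried. `truncate_cpx()` shortens a test
either to the first fraction of ramp breaths (count-based cut, the default
reading of "first 75% of data points"; a time-based cut is available via
`mode = "fraction_of_time"` and coincides with it for near-uniform breath
intervals) or to a VO2 ceiling such as the visual threshold + 100 mL/min.
The ceiling crossing is located on an 8-breath rolling mean because raw
breath VO2 is non-monotone. `truncation_effect()` recomputes all estimates
and reports percent changes; `paired_change_report()` joins pre/post visits
by subject id and applies paired t-tests per index (delegated to
`stats::t.test`).

## The simulator

`simulate_subject()` generates a ramp test from explicit physiology:
linear VO2 rise through the ramp; a **two-segment linear** V-slope with
pre-threshold slope `s1` (default 0.90, matching the observed pre-threshold
slope distribution), post-threshold slope `s2` (default 1.40), continuous at
the true threshold; ventilation driven off VCO2 with a positive intercept
(`ve = 4 + 28·VCO2` in L/min), which is sufficient to give VE/VO2 a nadir at
the threshold; a linear HR rise; breaths every ~3 s with ±20% jitter; and
multiplicative lognormal noise per channel (default CV 4%, the scale of
breath-to-breath variability).

The generative V-slope is deliberately *not* exponential: the estimators are
meant to summarise threshold-shaped data with an exponential, and a
generator drawn from the fitted model would make their validation
self-fulfilling. Default cohort heterogeneity places true thresholds
uniformly over 450–1400 mL/min at ~57% of peak VO2 (SD 6%), spanning
cardiac-to-healthy exercise tolerance.

What the simulator does **not** model: the respiratory compensation point
above the threshold, dead-space/tidal-volume dynamics in early exercise,
hyperventilation artifacts, athlete or pediatric physiology, and
autocorrelated breath noise. Passing recovery tests on simulated cohorts
therefore shows the estimators invert the generative threshold geometry
accurately under realistic noise — it does not certify accuracy on real
patients, where the agreement with visual reading (LoA of roughly
±270 mL/min in the original cohort) is the relevant yardstick.

### A property the simulation surfaced

Raw RMSE of expVAT(VCO2) against the true threshold is *not* monotone in
breath noise: the exponential-summary bias is slightly negative on
noise-free piecewise data (≈ −58 mL/min under default settings) and
multiplicative noise drifts it upward through zero (near CV ≈ 0.10) before
accuracy collapses at gross noise. The test suite therefore checks the
noise-attributable component — the scatter of the estimate over noise
realizations of a fixed subject, which is strictly monotone (≈5/15/49
mL/min at CV 0.02/0.06/0.15) — plus an outright degradation check at
CV 0.25.

## Numerical choices and degenerate inputs

* Units are fixed at the I/O boundary (VO2/VCO2 mL/min, VE L/min); the
  reader maps vendor columns but does not guess units.
* Strictly increasing timestamps and positive gas values are enforced at
  construction; phase labels must follow protocol order.
* Grubbs with zero spread excludes nothing by construction; correlations of
  zero-variance vectors are reported as missing rather than NaN.
* Exponential fitting requires ≥ 10 ramp breaths, all y > 0 and non-zero
  x variance; violations raise classed errors
  (`expvat_insufficient_data`, `expvat_domain_error`, `expvat_fit_error`).
* Tangency identities hold to ≤ 1e−10 relative error and the log-linear fit
  recovers noise-free exponentials to ≤ 1e−9; these bounds are asserted in
  the test suite.

## Validation problem sizes

The test suite validates parameter recovery on seeded cohorts of 50
subjects (Pearson r between true and estimated threshold ≥ 0.9, mean
relative bias within ±15%), truncation asymmetry on 50 subjects at the 75%
cut, nadir equivalence on 1,000 random fitted curves against a 1 mL/min
brute-force grid, Grubbs null behaviour on 1,000 replicates of n = 100, and
noise monotonicity on 60 replicates per noise level. These sizes give
stable statistics for the properties tested while keeping the suite quick
to run.

## Worked example

```{r example}
test <- simulate_subject(sim_params(seed = 1))
est <- vat_estimates(test)
est

# sensitivity of the estimates to stopping the test earlier
eff <- truncation_effect(test, truncation_spec(fraction = 0.75))
round(eff$percent_change, 2)
```

## Limitations

The closed forms are exact given the fit, but the exponential is a summary
of the whole curve, not a breakpoint detector: the estimates are midway
points toward peak VO2 and correlate more tightly with VO2peak than with
visually read thresholds. They depend on test duration (expVAT(VCO2) more
than expVAT(VE)), carry a structural bias on threshold-shaped data, and
degrade when the fit is poor — which is exactly what the QC flags are for.
For individual clinical decisions the visual reading remains the
reference; the objective estimates are intended for blinded group
comparisons and pre/post intervention analyses.
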