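#' @title Seeded breath-by-breath ramp-test simulator
#'
#' @description
#' Generates CPX test records with a known true metabolic threshold, for
#' validating the estimators. The generative V-slope is deliberately
#' two-segment linear (slope `s1` < 1 below the threshold, `s2` > 1 above,
#' continuous at the knot), not exponential: the estimators are exercised on
#' threshold-shaped data the way they are used in practice, not on data
#' drawn from their own model. Ventilation is driven off VCO2 with a
#' positive intercept, which suffices to give the ventilatory equivalent
#' VE/VO2 a nadir at the threshold. Breath-to-breath variability is
#' multiplicative lognormal per channel.
#'
#' @name synth_cpx
NULL

#' Simulation parameters for one ramp test
#'
#' Defaults describe a healthy adult on a ~15 W/min cycle ramp: resting VO2
#' 300 mL/min rising 185 mL/min per minute for 560 s (peak ~2000 mL/min),
#' threshold at 1050 mL/min, pre/post-threshold V-slope 0.90 / 1.40,
#' ventilation VE = 4 + 28 x VCO2(L/min), breaths every ~3 s, 4%
#' coefficient of variation per channel.
#'
#' @param vo2_rest Resting VO2, mL/min.
#' @param vo2_rise_rate Ramp VO2 rise, mL/min per minute of ramp.
#' @param ramp_duration,warmup_duration,rest_duration Phase durations, s.
#' @param true_vat True metabolic threshold, mL/min (must lie strictly
#'   inside the ramp VO2 range).
#' @param s1,s2 Pre-/post-threshold V-slope, dimensionless, 0 < s1 < 1 < s2.
#' @param vco2_intercept V-slope intercept, mL/min.
#' @param ve_intercept Ventilation intercept, L/min (positive, creating the
#'   VE/VO2 nadir).
#' @param ve_per_vco2 Ventilatory response slope, L/min per L/min of VCO2.
#' @param hr_rest,hr_slope Heart-rate model: rest value (beats/min) and rise
#'   per L/min of VO2.
#' @param ramp_rate Work-rate ramp, W/min (metadata only).
#' @param breath_interval_mean Mean breath spacing, s (+/-20% uniform jitter).
#' @param noise_cv Per-channel multiplicative coefficient of variation.
#' @param seed Integer seed; identical seeds give identical tests.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(vo2_rest = 300, vo2_rise_rate = 185,
                       ramp_duration = 560, warmup_duration = 120,
                       rest_duration = 60, true_vat = 1050,
                       s1 = 0.90, s2 = 1.40, vco2_intercept = -30,
                       ve_intercept = 4, ve_per_vco2 = 28,
                       hr_rest = 70, hr_slope = 45,
                       ramp_rate = 15, breath_interval_mean = 3,
                       noise_cv = 0.04, seed = 1L) {
  p <- list(vo2_rest = vo2_rest, vo2_rise_rate = vo2_rise_rate,
            ramp_duration = ramp_duration, warmup_duration = warmup_duration,
            rest_duration = rest_duration, true_vat = true_vat,
            s1 = s1, s2 = s2, vco2_intercept = vco2_intercept,
            ve_intercept = ve_intercept, ve_per_vco2 = ve_per_vco2,
            hr_rest = hr_rest, hr_slope = hr_slope, ramp_rate = ramp_rate,
            breath_interval_mean = breath_interval_mean,
            noise_cv = noise_cv, seed = as.integer(seed))
  problems <- character(0)
  if (!(p$s1 > 0 && p$s1 < 1)) problems <- c(problems, "s1 must satisfy 0 < s1 < 1")
  if (p$s2 <= 1) problems <- c(problems, "s2 must be > 1")
  vo2_peak <- p$vo2_rest + p$vo2_rise_rate * p$ramp_duration / 60
  if (!(p$true_vat > p$vo2_rest && p$true_vat < vo2_peak))
    problems <- c(problems, sprintf(
      "true_vat must lie in the ramp VO2 range (%g, %g)", p$vo2_rest, vo2_peak))
  if (p$noise_cv < 0) problems <- c(problems, "noise_cv must be >= 0")
  if (p$breath_interval_mean <= 0)
    problems <- c(problems, "breath_interval_mean must be > 0")
  for (f in c("vo2_rest", "vo2_rise_rate", "ramp_duration"))
    if (p[[f]] <= 0) problems <- c(problems, sprintf("%s must be > 0", f))
  if (length(problems))
    stop_domain("invalid simulation parameters:\n  - %s",
                paste(problems, collapse = "\n  - "))
  structure(p, class = "sim_params")
}

# noise-free channel values at given ramp VO2 (vectorized over vo2)
model_channels <- function(p, vo2) {
  vco2 <- p$vco2_intercept + p$s1 * pmin(vo2, p$true_vat) +
    p$s2 * pmax(0, vo2 - p$true_vat)
  ve <- p$ve_intercept + p$ve_per_vco2 * vco2 / 1000
  hr <- p$hr_rest + p$hr_slope * (vo2 - p$vo2_rest) / 1000
  list(vco2 = vco2, ve = ve, hr = hr)
}

lognoise <- function(x, cv) {
  if (cv <= 0) return(x)
  sg <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), mean = -sg^2 / 2, sd = sg)) # unit mean
}

#' Simulate one breath-by-breath ramp test
#'
#' @param params A [sim_params()] object.
#' @param meta Optional [subject_meta()] to attach (defaults to a synthetic
#'   id derived from the seed).
#' @return A [cpx_test()] object. The true threshold is carried in
#'   `attr(, "true_vat")`; no estimator reads it.
#' @export
simulate_subject <- function(params = sim_params(), meta = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  total <- params$rest_duration + params$warmup_duration + params$ramp_duration
  n_est <- ceiling(total / params$breath_interval_mean * 1.6) + 8L
  iv <- params$breath_interval_mean * stats::runif(n_est, 0.8, 1.2)
  t <- cumsum(iv)
  t <- t[t <= total]
  ramp_start <- params$rest_duration + params$warmup_duration
  phase <- ifelse(t <= params$rest_duration, "rest",
           ifelse(t <= ramp_start, "warmup", "ramp"))
  ramp_t <- pmax(0, t - ramp_start)
  vo2 <- params$vo2_rest + params$vo2_rise_rate * ramp_t / 60
  ch <- model_channels(params, vo2)
  work <- ifelse(phase == "ramp", params$ramp_rate * ramp_t / 60, 0)
  samples <- data.frame(
    t = t,
    vo2 = lognoise(vo2, params$noise_cv),
    vco2 = lognoise(ch$vco2, params$noise_cv),
    ve = lognoise(ch$ve, params$noise_cv),
    hr = lognoise(ch$hr, params$noise_cv / 2),
    work_rate = work,
    phase = phase)
  if (is.null(meta))
    meta <- subject_meta(subject_id = sprintf("sim-%d", params$seed),
                         age = 50, weight = 65)
  test <- cpx_test(samples, meta = meta,
                   protocol = list(ramp_rate = params$ramp_rate,
                                   warmup_s = ramp_start))
  attr(test, "true_vat") <- params$true_vat
  test
}

#' Per-subject heterogeneity for cohort simulation
#'
#' @param true_vat_range Uniform range of true thresholds, mL/min.
#' @param vat_frac_mean,vat_frac_sd Normal draw (clipped to
#'   `vat_frac_range`) of the threshold as a fraction of peak VO2; the ramp
#'   rise rate is scaled per subject so the threshold sits at that fraction.
#' @param vat_frac_range Clip bounds for the fraction.
#' @param s1_sd,s2_sd,noise_cv_sd Normal jitter SDs around the base values
#'   (s1 clipped to (0.70, 0.98), s2 to (1.05, 2.0), noise to >= 0.005).
#' @return An object of class `cohort_spread`.
#' @export
cohort_spread <- function(true_vat_range = c(450, 1400),
                          vat_frac_mean = 0.57, vat_frac_sd = 0.06,
                          vat_frac_range = c(0.40, 0.75),
                          s1_sd = 0.05, s2_sd = 0.10, noise_cv_sd = 0.01) {
  if (diff(true_vat_range) < 0 || any(true_vat_range <= 0))
    stop_domain("true_vat_range must be positive and non-decreasing")
  for (v in c(vat_frac_sd, s1_sd, s2_sd, noise_cv_sd))
    if (v < 0) stop_domain("spread widths must be >= 0")
  structure(list(true_vat_range = true_vat_range,
                 vat_frac_mean = vat_frac_mean, vat_frac_sd = vat_frac_sd,
                 vat_frac_range = vat_frac_range,
                 s1_sd = s1_sd, s2_sd = s2_sd, noise_cv_sd = noise_cv_sd),
            class = "cohort_spread")
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a cohort of ramp tests with known thresholds
#'
#' Draws per-subject parameters around `base`: the true threshold uniform
#' over `spread$true_vat_range`, the threshold-to-peak fraction, the two
#' V-slope segments and the noise level jittered as configured. Reproducible
#' for a fixed seed.
#'
#' @param n Number of subjects.
#' @param base A [sim_params()] object of base values.
#' @param spread A [cohort_spread()] object.
#' @param seed Integer cohort seed.
#' @return List of length `n`; each element has `test` (a [cpx_test()]) and
#'   `true_vat` (mL/min).
#' @export
simulate_cohort <- function(n, base = sim_params(), spread = cohort_spread(),
                            seed = 1L) {
  stopifnot(n >= 1, inherits(base, "sim_params"), inherits(spread, "cohort_spread"))
  set.seed(seed)
  tv <- stats::runif(n, spread$true_vat_range[1], spread$true_vat_range[2])
  frac <- clip(stats::rnorm(n, spread$vat_frac_mean, spread$vat_frac_sd),
               spread$vat_frac_range[1], spread$vat_frac_range[2])
  s1 <- clip(stats::rnorm(n, base$s1, spread$s1_sd), 0.70, 0.98)
  s2 <- clip(stats::rnorm(n, base$s2, spread$s2_sd), 1.05, 2.0)
  cv <- pmax(stats::rnorm(n, base$noise_cv, spread$noise_cv_sd), 0.005)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    peak <- tv[i] / frac[i]
    rise <- (peak - base$vo2_rest) / (base$ramp_duration / 60)
    p <- sim_params(vo2_rest = base$vo2_rest, vo2_rise_rate = rise,
                    ramp_duration = base$ramp_duration,
                    warmup_duration = base$warmup_duration,
                    rest_duration = base$rest_duration,
                    true_vat = tv[i], s1 = s1[i], s2 = s2[i],
                    vco2_intercept = base$vco2_intercept,
                    ve_intercept = base$ve_intercept,
                    ve_per_vco2 = base$ve_per_vco2,
                    hr_rest = base$hr_rest, hr_slope = base$hr_slope,
                    ramp_rate = base$ramp_rate,
                    breath_interval_mean = base$breath_interval_mean,
                    noise_cv = cv[i], seed = seeds[i])
    meta <- subject_meta(subject_id = sprintf("sim-%03d", i), age = 50, weight = 65)
    list(test = simulate_subject(p, meta = meta), true_vat = tv[i])
  })
}
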