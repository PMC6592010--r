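#' @title Closed-form threshold estimators and slope indices
#'
#' @description
#' From the exponential fit y = b * a^x of a gas channel on VO2, two tangent
#' constructions yield closed-form estimates of the ventilatory anaerobic
#' threshold:
#'
#' * expVAT(VCO2): the VO2 at which the tangent to the fitted V-slope is
#'   parallel to the R = 1 line, i.e. where the instantaneous dVCO2/dVO2
#'   equals 1. Setting the derivative b * a^x * ln(a) = 1 gives
#'   x0 = ln(1 / (b * ln a)) / ln a.
#' * expVAT(VE): the VO2 at which the tangent to the fitted VO2-VE curve
#'   passes through the origin. The tangency condition gives x0 = 1 / ln(a),
#'   independent of b; this point is also the minimizer of the fitted
#'   ventilatory equivalent VE/VO2 (its nadir).
#'
#' A smaller base `a` (slower exponential rise) yields a larger threshold.
#' Both estimators are undefined when a <= 1 and are then reported as missing
#' with an explanatory flag rather than an error, mirroring per-subject
#' non-detection bookkeeping in batch work.
#'
#' @name estimators
NULL

flagged_na <- function(flag) structure(NA_real_, flag = flag)

#' expVAT from the V-slope (VCO2 vs VO2) exponential fit
#'
#' @param fit An [fit_exponential()] result for VCO2 (mL/min) on VO2 (mL/min).
#' @return The threshold in mL/min, or `NA` carrying a `flag` attribute
#'   (`"a_not_gt_1"` or `"tangent_nonpositive"`) when the tangent
#'   construction is undefined.
#' @export
expvat_vco2 <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (!is.finite(fit$a) || fit$a <= 1) return(flagged_na("a_not_gt_1"))
  lna <- log(fit$a)
  if (fit$b * lna >= 1) return(flagged_na("tangent_nonpositive"))
  x0 <- log(1 / (fit$b * lna)) / lna
  if (!is.finite(x0) || x0 <= 0) return(flagged_na("tangent_nonpositive"))
  x0
}

#' expVAT from the VO2-VE exponential fit
#'
#' @param fit An [fit_exponential()] result for VE (L/min) on VO2 (mL/min).
#' @return The threshold in mL/min (`1 / ln(a)`), or flagged `NA` when
#'   a <= 1.
#' @export
expvat_ve <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (!is.finite(fit$a) || fit$a <= 1) return(flagged_na("a_not_gt_1"))
  1 / log(fit$a)
}

#' Oxygen uptake efficiency slope
#'
#' OLS slope of VO2 (mL/min, response) on the base-10 logarithm of the
#' chosen channel. The conventional OUES uses VE (L/min); the VCO2 variant
#' log-transforms VCO2 instead. Because rescaling the channel only shifts
#' its logarithm, the slope is invariant to the channel's unit scale.
#'
#' @param samples Data frame of ramp samples.
#' @param channel `"ve"` or `"vco2"`.
#' @return Slope in mL/min per decade of the channel.
#' @export
oues <- function(samples, channel = c("ve", "vco2")) {
  channel <- match.arg(channel)
  y <- samples[[channel]]
  if (nrow(samples) < MIN_FIT_N)
    stop_insufficient("OUES needs >= %d ramp samples, got %d", MIN_FIT_N, nrow(samples))
  if (any(y <= 0)) stop_domain("non-positive %s; log undefined", channel)
  fit_linear(log10(y), samples$vo2)$slope
}

#' Full per-test estimate set
#'
#' Fits the V-slope (VCO2 on VO2) and the VO2-VE relation on the ramp
#' samples, evaluates both closed-form thresholds and both OUES variants,
#' applies the quality-control rules, and completes the summary metrics.
#'
#' QC flags collected in `qc_flags`:
#' * `a_not_gt_1`, `tangent_nonpositive` - a threshold formula was undefined;
#' * `pre_vat_slope_below_threshold` - the whole-test linear V-slope is below
#'   the validity threshold (default 1.105), indicating the metabolic
#'   threshold was likely never reached, so expVATs should not be trusted;
#' * `expvat_above_sanity_bound` - an extrapolated estimate exceeds 1.5 x the
#'   highest observed VO2 (flagged, not erased);
#' * `insufficient_data` - fewer than 10 ramp breaths.
#'
#' @param test A [cpx_test()] object.
#' @param method Fitting method, see [fit_exponential()].
#' @param slope_threshold Pre-threshold slope validity cutoff, see
#'   [pre_vat_slope_check()].
#' @param window Rolling-mean window for [highest_values()].
#' @return An object of class `vat_estimates`.
#' @export
vat_estimates <- function(test, method = "log-linear",
                          slope_threshold = 1.105, window = 1) {
  stopifnot(inherits(test, "cpx_test"))
  flags <- character(0)
  ramp <- select_ramp(test)
  if (nrow(ramp) < MIN_FIT_N) {
    est <- empty_estimates(test)
    est$qc_flags <- "insufficient_data"
    return(est)
  }
  fit_v <- fit_exponential(ramp$vo2, ramp$vco2, method = method, y_name = "vco2")
  fit_e <- fit_exponential(ramp$vo2, ramp$ve, method = method, y_name = "ve")

  xv <- expvat_vco2(fit_v)
  xe <- expvat_ve(fit_e)
  flags <- c(flags, attr(xv, "flag"), attr(xe, "flag"))

  slope_chk <- pre_vat_slope_check(ramp, threshold = slope_threshold)
  if (!slope_chk$valid) flags <- c(flags, "pre_vat_slope_below_threshold")

  hv <- highest_values(test, window = window)
  bound <- 1.5 * hv$highest_vo2
  if ((is.finite(xv) && xv > bound) || (is.finite(xe) && xe > bound))
    flags <- c(flags, "expvat_above_sanity_bound")

  est <- structure(list(
    subject_id = test$meta$subject_id,
    expvat_vco2 = as.numeric(xv), expvat_ve = as.numeric(xe),
    a_vslope = fit_v$a, b_vslope = fit_v$b, r_vslope = fit_v$r_fit,
    a_ve = fit_e$a, b_ve = fit_e$b, r_ve = fit_e$r_fit,
    oues_ve = oues(ramp, "ve"), oues_vco2 = oues(ramp, "vco2"),
    pre_vat_slope = slope_chk$slope,
    highest_vo2 = hv$highest_vo2, highest_hr = hv$highest_hr,
    highest_r = hv$highest_r,
    relative_vat_vco2_pct = NA_real_, relative_vat_ve_pct = NA_real_,
    pct_predicted_hr = NA_real_,
    expvat_vco2_kg = NA_real_, expvat_ve_kg = NA_real_,
    highest_vo2_kg = hv$highest_vo2_kg,
    qc_flags = unique(flags)
  ), class = "vat_estimates")
  summary_metrics(est, test)
}

empty_estimates <- function(test) {
  structure(list(
    subject_id = test$meta$subject_id,
    expvat_vco2 = NA_real_, expvat_ve = NA_real_,
    a_vslope = NA_real_, b_vslope = NA_real_, r_vslope = NA_real_,
    a_ve = NA_real_, b_ve = NA_real_, r_ve = NA_real_,
    oues_ve = NA_real_, oues_vco2 = NA_real_,
    pre_vat_slope = NA_real_,
    highest_vo2 = NA_real_, highest_hr = NA_real_, highest_r = NA_real_,
    relative_vat_vco2_pct = NA_real_, relative_vat_ve_pct = NA_real_,
    pct_predicted_hr = NA_real_,
    expvat_vco2_kg = NA_real_, expvat_ve_kg = NA_real_,
    highest_vo2_kg = NA_real_,
    qc_flags = character(0)
  ), class = "vat_estimates")
}

#' Complete the relative and per-kg summary metrics
#'
#' Relative VAT (%) is 100 * expVAT / highest VO2 per estimator;
#' %predicted HR is 100 * highest HR / (220 - age); per-kg values divide by
#' body weight. Fields whose inputs (age, weight, HR) are unknown stay
#' missing.
#'
#' @param est A `vat_estimates` object.
#' @param test The [cpx_test()] it came from (for age and weight).
#' @return The completed `vat_estimates`.
#' @export
summary_metrics <- function(est, test) {
  stopifnot(inherits(est, "vat_estimates"), inherits(test, "cpx_test"))
  if (is.finite(est$highest_vo2) && est$highest_vo2 > 0) {
    if (is.finite(est$expvat_vco2))
      est$relative_vat_vco2_pct <- 100 * est$expvat_vco2 / est$highest_vo2
    if (is.finite(est$expvat_ve))
      est$relative_vat_ve_pct <- 100 * est$expvat_ve / est$highest_vo2
  }
  age <- test$meta$age
  if (is.finite(age) && is.finite(est$highest_hr))
    est$pct_predicted_hr <- 100 * est$highest_hr / (220 - age)
  w <- test$meta$weight
  if (is.finite(w)) {
    if (is.finite(est$expvat_vco2)) est$expvat_vco2_kg <- est$expvat_vco2 / w
    if (is.finite(est$expvat_ve)) est$expvat_ve_kg <- est$expvat_ve / w
  }
  est
}

#' @export
print.vat_estimates <- function(x, ...) {
  cat(sprintf("<vat_estimates> subject '%s'\n", x$subject_id))
  cat(sprintf("  expVAT(VCO2) = %.0f mL/min (a = %.6f, r = %.4f)\n",
              x$expvat_vco2, x$a_vslope, x$r_vslope))
  cat(sprintf("  expVAT(VE)   = %.0f mL/min (a = %.6f, r = %.4f)\n",
              x$expvat_ve, x$a_ve, x$r_ve))
  cat(sprintf("  OUES(VE) = %.0f, OUES(VCO2) = %.0f mL/min per decade\n",
              x$oues_ve, x$oues_vco2))
  if (length(x$qc_flags))
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.vat_estimates <- function(x, ...) {
  num <- x[setdiff(names(x), c("qc_flags", "subject_id"))]
  df <- as.data.frame(num, stringsAsFactors = FALSE)
  df <- cbind(data.frame(subject_id = x$subject_id, stringsAsFactors = FALSE), df)
  df$qc_flags <- paste(x$qc_flags, collapse = ";")
  df
}
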