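#' @title Truncation sensitivity and paired-change analyses
#'
#' @description
#' The exponential threshold estimators summarise the whole ramp, so they
#' depend on how far past the metabolic threshold the test was carried.
#' Truncation analyses quantify that dependence by recomputing every
#' estimate on a shortened copy of the test: either the first fraction of
#' ramp breaths, or all breaths up to a VO2 ceiling (e.g. the visual
#' threshold plus 100 mL/min).
#'
#' @name sensitivity
NULL

#' Specify a truncation rule
#'
#' @param fraction Keep the first `ceiling(fraction * n)` ramp breaths
#'   (0 < fraction <= 1). Mutually exclusive with `vo2_limit`.
#' @param vo2_limit Keep ramp breaths strictly before the first breath at
#'   which a rolling mean of VO2 exceeds this ceiling (mL/min).
#' @param mode `"fraction_of_ramp"` (count-based cut, default when
#'   `fraction` is given), `"fraction_of_time"` (cut at that fraction of
#'   ramp elapsed time) or `"vo2_ceiling"`.
#' @param window Rolling-mean window (breaths) used to locate the VO2
#'   ceiling crossing; raw breath VO2 is non-monotone, so a smoothed scan is
#'   used (default 8 breaths).
#' @return An object of class `truncation_spec`.
#' @export
truncation_spec <- function(fraction = NULL, vo2_limit = NULL, mode = NULL,
                            window = 8) {
  if (is.null(mode)) {
    if (!is.null(fraction) && is.null(vo2_limit)) mode <- "fraction_of_ramp"
    else if (is.null(fraction) && !is.null(vo2_limit)) mode <- "vo2_ceiling"
    else stop_domain("give exactly one of fraction or vo2_limit")
  }
  mode <- match.arg(mode, c("fraction_of_ramp", "fraction_of_time", "vo2_ceiling"))
  if (mode %in% c("fraction_of_ramp", "fraction_of_time")) {
    if (is.null(fraction) || fraction <= 0 || fraction > 1)
      stop_domain("fraction must be in (0, 1]")
  } else {
    if (is.null(vo2_limit) || vo2_limit <= 0)
      stop_domain("vo2_limit must be > 0")
  }
  structure(list(mode = mode, fraction = fraction, vo2_limit = vo2_limit,
                 window = window),
            class = "truncation_spec")
}

#' Truncate a CPX test
#'
#' A pure sample filter: retained breaths are never altered, and rest /
#' warm-up samples are kept unchanged.
#'
#' @param test A [cpx_test()] object.
#' @param spec A [truncation_spec()].
#' @return A new [cpx_test()] with the ramp shortened per `spec`.
#' @export
truncate_cpx <- function(test, spec) {
  stopifnot(inherits(test, "cpx_test"), inherits(spec, "truncation_spec"))
  ramp_idx <- which(test$samples$phase == "ramp")
  n <- length(ramp_idx)
  keep_n <- switch(spec$mode,
    fraction_of_ramp = ceiling(spec$fraction * n),
    fraction_of_time = {
      t <- test$samples$t[ramp_idx]
      cutoff <- t[1] + spec$fraction * (t[n] - t[1])
      sum(t <= cutoff)
    },
    vo2_ceiling = {
      sm <- rolling_mean(test$samples$vo2[ramp_idx], spec$window)
      over <- which(sm > spec$vo2_limit)
      if (length(over) == 0) n else over[1] - 1L
    })
  if (keep_n < MIN_FIT_N)
    stop_insufficient("truncation leaves %d ramp samples (< %d)", keep_n, MIN_FIT_N)
  drop_idx <- ramp_idx[seq_len(n) > keep_n]
  samples <- if (length(drop_idx)) test$samples[-drop_idx, , drop = FALSE]
             else test$samples
  # recovery samples after a shortened ramp would break phase order; drop them
  samples <- samples[samples$phase != "recovery" | length(drop_idx) == 0, , drop = FALSE]
  cpx_test(samples, meta = test$meta, protocol = test$protocol)
}

#' Effect of truncation on every estimate
#'
#' Recomputes the full estimate set on the truncated test and reports the
#' percent change 100 * (truncated - full) / full per estimator. QC flags
#' from either fit propagate into the respective estimate set.
#'
#' @param test A [cpx_test()] object.
#' @param spec A [truncation_spec()].
#' @param ... Passed to [vat_estimates()].
#' @return List with `full`, `truncated` (both `vat_estimates`) and
#'   `percent_change` (named numeric vector over the main indices).
#' @export
truncation_effect <- function(test, spec, ...) {
  full <- vat_estimates(test, ...)
  trunc <- vat_estimates(truncate_cpx(test, spec), ...)
  indices <- c("expvat_vco2", "expvat_ve", "oues_ve", "oues_vco2")
  pct <- vapply(indices, function(k) {
    f <- full[[k]]; tr <- trunc[[k]]
    if (is.finite(f) && is.finite(tr) && f != 0) 100 * (tr - f) / f else NA_real_
  }, numeric(1))
  list(full = full, truncated = trunc, percent_change = pct)
}

#' Paired pre/post change report
#'
#' Matches estimate sets by subject id and reports, per index, the mean
#' before, mean after, mean paired difference, two-sided paired t-test p and
#' the number of complete pairs. Pairs with a missing member are dropped per
#' index.
#'
#' @param pre,post Lists of `vat_estimates` (e.g. before and after a
#'   rehabilitation program).
#' @param indices Which estimate fields to report.
#' @return Data frame with one row per index.
#' @export
paired_change_report <- function(pre, post,
                                 indices = c("expvat_vco2", "expvat_ve",
                                             "oues_ve", "oues_vco2",
                                             "a_vslope", "a_ve")) {
  pre_ids <- vapply(pre, `[[`, character(1), "subject_id")
  post_ids <- vapply(post, `[[`, character(1), "subject_id")
  common <- intersect(pre_ids, post_ids)
  if (length(common) == 0) stop_insufficient("no matching subject ids")
  rows <- lapply(indices, function(k) {
    a <- vapply(common, function(id) pre[[match(id, pre_ids)]][[k]], numeric(1))
    b <- vapply(common, function(id) post[[match(id, post_ids)]][[k]], numeric(1))
    keep <- is.finite(a) & is.finite(b)
    n <- sum(keep)
    if (n == 0)
      return(data.frame(index = k, mean_pre = NA_real_, mean_post = NA_real_,
                        mean_diff = NA_real_, p = NA_real_, n = 0L))
    a <- a[keep]; b <- b[keep]
    p <- if (n >= 2 && stats::sd(b - a) > 0)
      stats::t.test(b, a, paired = TRUE)$p.value else NA_real_
    data.frame(index = k, mean_pre = mean(a), mean_post = mean(b),
               mean_diff = mean(b - a), p = p, n = n)
  })
  do.call(rbind, rows)
}
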