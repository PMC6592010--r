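#' @title Quality control and method-agreement statistics
#' @name qc_stats
NULL

grubbs_crit <- function(n, alpha, sides) {
  # one exclusion step: critical G from the t distribution
  p <- alpha / (sides * n)
  tq <- stats::qt(p, df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative Grubbs (Smirnov-Grubbs) outlier screening
#'
#' Repeatedly tests the most extreme value on the chosen tail and removes it
#' while its G statistic exceeds the critical value from the t distribution,
#' \eqn{G_{crit} = \frac{N-1}{\sqrt N}\sqrt{t^2_{\alpha/N,\,N-2} /
#' (N-2+t^2_{\alpha/N,\,N-2})}}. The default tail is `lower` because the
#' screened quantity is typically a fit-quality correlation r, which poor
#' fits depress. Zero spread means no outliers by construction.
#'
#' @param values Numeric vector (e.g. per-subject fit r values), n >= 3.
#' @param alpha Significance level per step (default 0.001).
#' @param side `"lower"`, `"upper"` or `"two-sided"`.
#' @return An object of class `grubbs_result`: `excluded_indices` (into the
#'   original vector, in exclusion order), `g_statistics`, `g_critical`,
#'   `alpha`, `side`, `kept` (logical mask).
#' @export
grubbs_screen <- function(values, alpha = 0.001,
                          side = c("lower", "upper", "two-sided")) {
  side <- match.arg(side)
  if (length(values) < 3) stop_insufficient("Grubbs screening needs n >= 3")
  if (any(!is.finite(values))) stop_domain("values must be finite")
  sides <- if (side == "two-sided") 2 else 1
  idx <- seq_along(values)
  excluded <- integer(0); gs <- numeric(0); gcrits <- numeric(0)
  repeat {
    n <- length(idx)
    if (n < 3) break
    v <- values[idx]
    s <- stats::sd(v)
    if (s == 0) break
    m <- mean(v)
    cand <- switch(side,
      lower = which.min(v),
      upper = which.max(v),
      `two-sided` = which.max(abs(v - m)))
    g <- abs(v[cand] - m) / s
    crit <- grubbs_crit(n, alpha, sides)
    if (g <= crit) break
    excluded <- c(excluded, idx[cand])
    gs <- c(gs, g); gcrits <- c(gcrits, crit)
    idx <- idx[-cand]
  }
  structure(list(excluded_indices = excluded, g_statistics = gs,
                 g_critical = gcrits, alpha = alpha, side = side,
                 kept = !(seq_along(values) %in% excluded)),
            class = "grubbs_result")
}

#' Pre-threshold V-slope validity check
#'
#' Fits a straight line to VCO2 on VO2 over the supplied range. A whole-test
#' linear slope below the validity threshold indicates the metabolic
#' threshold was likely never reached during the test, in which case the
#' exponential threshold estimates should not be calculated. The default
#' threshold 1.105 is the upper 95% bound of the pre-threshold slope
#' distribution (mean 0.901 + 2 x SD 0.102).
#'
#' @param samples Data frame of ramp V-slope samples (>= 10 points).
#' @param threshold Dimensionless slope cutoff.
#' @return List with `slope` and `valid` (slope >= threshold).
#' @export
pre_vat_slope_check <- function(samples, threshold = 1.105) {
  if (nrow(samples) < MIN_FIT_N)
    stop_insufficient("slope check needs >= %d points, got %d",
                      MIN_FIT_N, nrow(samples))
  slope <- fit_linear(samples$vo2, samples$vco2)$slope
  list(slope = slope, valid = slope >= threshold)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences are d = x - y; the limits of agreement half-width is
#' 1.96 x SD(d) with the sample (n-1) standard deviation. Pairs with a
#' missing member are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return An object of class `agreement_report`: `n`, `mean_diff`,
#'   `sd_diff`, `loa_half_width`, `pearson_r`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_insufficient("agreement needs >= 3 complete pairs, got %d", n)
  d <- x - y
  sd_d <- stats::sd(d)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(n = n, mean_diff = mean(d), sd_diff = sd_d,
                 loa_half_width = 1.96 * sd_d, pearson_r = r),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement> n = %d: mean diff %.3g, LoA +/- %.3g (r = %.3f)\n",
              x$n, x$mean_diff, x$loa_half_width, x$pearson_r))
  invisible(x)
}

#' Williams's test for two dependent correlations sharing a variable
#'
#' Compares r12 and r13 measured on the same n subjects, given r23, with
#' \deqn{t = (r_{12}-r_{13})\sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}},}
#' where \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 +
#' 2 r_{12} r_{13} r_{23}} and \eqn{\bar r = (r_{12}+r_{13})/2}; p is
#' two-sided from the t distribution with n - 3 degrees of freedom.
#'
#' @param r12,r13 The two correlations being compared (share variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (>= 5).
#' @return List with `t`, `p`, `df`.
#' @export
williams_test <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23))
    if (!is.finite(r) || abs(r) >= 1) stop_domain("correlations must lie in (-1, 1)")
  if (n < 5) stop_insufficient("Williams's test needs n >= 5")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < 0) stop_domain("correlation triplet is not positive semi-definite")
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  list(t = t, p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE), df = df)
}

#' Pairwise-complete correlation matrix with per-pair n
#'
#' Missing values (e.g. undetected visual thresholds) are handled pairwise
#' so each estimator keeps its maximal n; the n used for every cell is
#' reported alongside. Cells with fewer than 3 complete pairs are `NA`.
#'
#' @param columns Named list (or data frame) of numeric vectors of equal
#'   length, possibly with `NA`s.
#' @return List with matrices `r` and `n`.
#' @export
correlation_matrix <- function(columns) {
  columns <- as.data.frame(columns)
  if (ncol(columns) < 2) stop_insufficient("need >= 2 columns")
  k <- ncol(columns)
  nm <- names(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  nmat <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    keep <- is.finite(columns[[i]]) & is.finite(columns[[j]])
    nmat[i, j] <- sum(keep)
    if (nmat[i, j] >= 3)
      r[i, j] <- stats::cor(columns[[i]][keep], columns[[j]][keep])
  }
  list(r = r, n = nmat)
}
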