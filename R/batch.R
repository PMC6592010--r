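#' @title Cohort batch processing and structured reports
#' @name batch
NULL

#' Estimate a cohort of tests with fit-outlier screening
#'
#' Runs [vat_estimates()] on every test, then screens the fit-quality r of
#' each exponential fit across the cohort with iterative Grubbs on the lower
#' tail; subjects excluded on either channel gain the `poor_fit_outlier`
#' flag in the returned table.
#'
#' @param tests List of [cpx_test()] objects (or of `list(test = ...)`
#'   elements as produced by [simulate_cohort()]).
#' @param grubbs_alpha Significance level per Grubbs step.
#' @param ... Passed to [vat_estimates()].
#' @return List with `table` (one row per subject), `estimates` (list of
#'   `vat_estimates`), `grubbs_vslope`, `grubbs_ve`.
#' @export
batch_estimates <- function(tests, grubbs_alpha = 0.001, ...) {
  tests <- lapply(tests, function(x) if (inherits(x, "cpx_test")) x else x$test)
  ests <- lapply(tests, vat_estimates, ...)
  tab <- do.call(rbind, lapply(ests, as.data.frame))
  gv <- ge <- NULL
  ok_v <- is.finite(tab$r_vslope); ok_e <- is.finite(tab$r_ve)
  if (sum(ok_v) >= 3) gv <- grubbs_screen(tab$r_vslope[ok_v], alpha = grubbs_alpha)
  if (sum(ok_e) >= 3) ge <- grubbs_screen(tab$r_ve[ok_e], alpha = grubbs_alpha)
  out_rows <- unique(c(which(ok_v)[gv$excluded_indices],
                       which(ok_e)[ge$excluded_indices]))
  if (length(out_rows)) {
    tab$qc_flags[out_rows] <- ifelse(
      tab$qc_flags[out_rows] == "", "poor_fit_outlier",
      paste(tab$qc_flags[out_rows], "poor_fit_outlier", sep = ";"))
  }
  list(table = tab, estimates = ests, grubbs_vslope = gv, grubbs_ve = ge)
}

#' Serialize an estimate set (or batch table) as JSON
#'
#' @param x A `vat_estimates` object, `agreement_report`, or data frame.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "vat_estimates") || inherits(x, "agreement_report"))
    unclass(x) else x
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
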