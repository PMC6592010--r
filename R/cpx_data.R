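#' @title Breath-by-breath CPX test records
#'
#' @description
#' A CPX test is an ordered breath-by-breath record of gas exchange during a
#' ramp exercise protocol: time `t` (seconds from test start), oxygen uptake
#' `vo2` (mL/min, STPD), carbon-dioxide output `vco2` (mL/min, STPD), minute
#' ventilation `ve` (L/min, BTPS), and optionally heart rate `hr` (beats/min),
#' `work_rate` (W) and a `phase` label in `rest`, `warmup`, `ramp`,
#' `recovery`. Units are fixed at this boundary: every downstream formula
#' assumes mL/min for the gas channels and L/min for ventilation.
#'
#' @name cpx_data
NULL

PHASES <- c("rest", "warmup", "ramp", "recovery")
REQUIRED_COLS <- c("t", "vo2", "vco2", "ve")

#' Subject metadata for a CPX test
#'
#' @param subject_id Opaque identifier string.
#' @param age Age in years (`NA` if unknown).
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param weight Body weight in kg (`NA` if unknown).
#' @param group Free-text cohort label.
#' @param vvat Externally (visually) determined ventilatory anaerobic
#'   threshold in mL/min, if available. Visual reading is a human procedure;
#'   this package only consumes the value.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id = "", age = NA_real_, sex = "unknown",
                         weight = NA_real_, group = "", vvat = NA_real_) {
  sex <- match.arg(sex, c("male", "female", "unknown"))
  if (!is.na(age) && age <= 0) stop_domain("age must be > 0, got %g", age)
  if (!is.na(weight) && weight <= 0) stop_domain("weight must be > 0, got %g", weight)
  if (!is.na(vvat) && vvat <= 0) stop_domain("vvat must be > 0, got %g", vvat)
  structure(list(subject_id = as.character(subject_id), age = as.numeric(age),
                 sex = sex, weight = as.numeric(weight),
                 group = as.character(group), vvat = as.numeric(vvat)),
            class = "subject_meta")
}

#' Construct and validate a CPX test record
#'
#' Validates the sample table (required columns, strictly increasing times,
#' positive gas values) and the phase sequence, which must follow protocol
#' order rest -> warmup -> ramp -> recovery (phases may be absent but never
#' interleaved out of order).
#'
#' @param samples Data frame with columns `t`, `vo2`, `vco2`, `ve` and
#'   optionally `hr`, `work_rate`, `phase`. If `phase` is missing it is
#'   inferred from `protocol$warmup_s`: samples at `t < warmup_s` are labelled
#'   `warmup`, the rest `ramp`.
#' @param meta A [subject_meta()] object.
#' @param protocol List with `ramp_rate` (W/min) and `warmup_s` (seconds).
#' @return An object of class `cpx_test` with elements `meta`, `protocol`,
#'   `samples`.
#' @export
cpx_test <- function(samples, meta = subject_meta(),
                     protocol = list(ramp_rate = 10, warmup_s = 120)) {
  if (!is.data.frame(samples)) stop_format("samples must be a data frame")
  missing_cols <- setdiff(REQUIRED_COLS, names(samples))
  if (length(missing_cols) > 0)
    stop_format("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (!inherits(meta, "subject_meta")) stop_format("meta must be a subject_meta object")

  samples <- samples[order(samples$t), , drop = FALSE]
  rownames(samples) <- NULL
  for (col in REQUIRED_COLS) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad) > 0)
      stop_data("non-finite %s at row(s) %s", col,
                paste(utils::head(bad, 5), collapse = ", "))
  }
  dt <- diff(samples$t)
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop_data("sample times not strictly increasing at row %d (t = %g)",
              row, samples$t[row])
  }
  for (col in c("vo2", "vco2", "ve")) {
    bad <- which(samples[[col]] <= 0)
    if (length(bad) > 0)
      stop_data("non-positive %s at row(s) %s", col,
                paste(utils::head(bad, 5), collapse = ", "))
  }

  if (is.null(samples$phase)) {
    samples$phase <- ifelse(samples$t < protocol$warmup_s, "warmup", "ramp")
  } else {
    samples$phase <- as.character(samples$phase)
    bad <- setdiff(unique(samples$phase), PHASES)
    if (length(bad) > 0)
      stop_data("unknown phase label(s): %s", paste(bad, collapse = ", "))
    idx <- match(samples$phase, PHASES)
    if (any(diff(idx) < 0)) {
      row <- which(diff(idx) < 0)[1] + 1L
      stop_data("phases out of protocol order at row %d ('%s' after '%s')",
                row, samples$phase[row], samples$phase[row - 1L])
    }
  }
  structure(list(meta = meta, protocol = protocol, samples = samples),
            class = "cpx_test")
}

#' @export
print.cpx_test <- function(x, ...) {
  n_ramp <- sum(x$samples$phase == "ramp")
  cat(sprintf("<cpx_test> subject '%s': %d breaths (%d ramp), t %.0f-%.0f s\n",
              x$meta$subject_id, nrow(x$samples), n_ramp,
              min(x$samples$t), max(x$samples$t)))
  invisible(x)
}

#' Read a breath-by-breath CPX table
#'
#' Reads a comma-separated, UTF-8 breath table with one header row and
#' canonical lower-case column names (`t`, `vo2`, `vco2`, `ve`, `hr`,
#' `work_rate`, `phase`). Vendor exports with different headers are
#' accommodated through `col_map`. Unknown columns are preserved in the
#' sample table as annotations.
#'
#' @param path Path to the CSV file.
#' @param meta Optional [subject_meta()]; defaults to an anonymous subject
#'   whose id is the file stem.
#' @param protocol Protocol list, see [cpx_test()].
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(vo2 = "VO2_mlmin")`.
#' @return A [cpx_test()] object.
#' @export
read_cpx_table <- function(path, meta = NULL,
                           protocol = list(ramp_rate = 10, warmup_s = 120),
                           col_map = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) stop_format("mapped column '%s' not in file", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  num_cols <- intersect(c("t", "vo2", "vco2", "ve", "hr", "work_rate"), names(raw))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad) > 0)
      stop_data("%s: column '%s' fails numeric parsing at row(s) %s",
                path, col, paste(utils::head(bad, 5), collapse = ", "))
    raw[[col]] <- v
  }
  if (is.null(meta))
    meta <- subject_meta(subject_id = sub("\\.[^.]*$", "", basename(path)))
  cpx_test(raw, meta = meta, protocol = protocol)
}

#' Write a CPX test as a breath table
#'
#' Writes the sample table as CSV with enough digits (17 significant) that
#' reading it back reproduces every double exactly.
#'
#' @param test A [cpx_test()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cpx_table <- function(test, path) {
  stopifnot(inherits(test, "cpx_test"))
  out <- test$samples
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- format(out[[col]], digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the ramp-phase samples of a test
#'
#' Fitting operations use ramp exercise data only, excluding resting and
#' warm-up (and recovery) breaths.
#'
#' @param test A [cpx_test()] object.
#' @return Data frame of ramp-phase samples, order preserved.
#' @export
select_ramp <- function(test) {
  stopifnot(inherits(test, "cpx_test"))
  ramp <- test$samples[test$samples$phase == "ramp", , drop = FALSE]
  if (nrow(ramp) == 0)
    stop_insufficient("test '%s' has no ramp-phase samples", test$meta$subject_id)
  rownames(ramp) <- NULL
  ramp
}

#' Per-breath gas-exchange ratios
#'
#' Computes the respiratory exchange ratio R = VCO2/VO2 and the ventilatory
#' equivalents of O2 and CO2. VE is converted from L/min to mL/min so the
#' equivalents are dimensionless; consequently `ve_vo2 / ve_vco2 == R`
#' identically.
#'
#' @param samples Data frame of breath samples with `vo2`, `vco2`, `ve`.
#' @return Data frame with columns `R`, `ve_vo2`, `ve_vco2`.
#' @export
derive_ratios <- function(samples) {
  for (col in c("vo2", "vco2", "ve"))
    if (any(samples[[col]] <= 0))
      stop_domain("non-positive %s; ratios undefined", col)
  data.frame(R = samples$vco2 / samples$vo2,
             ve_vo2 = samples$ve * 1000 / samples$vo2,
             ve_vco2 = samples$ve * 1000 / samples$vco2)
}

rolling_mean <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(x)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out
}

#' Highest observed values over the ramp
#'
#' Returns the maximum over ramp samples of a rolling mean (default window 1
#' breath, i.e. the raw last-highest value convention used for submaximal
#' protocols) for VO2, HR and R, with per-kg variants when weight is known.
#'
#' @param test A [cpx_test()] object.
#' @param window Rolling-mean window in breaths; 1 means no averaging.
#' @return List with `highest_vo2`, `highest_hr`, `highest_r`,
#'   `highest_vo2_kg`.
#' @export
highest_values <- function(test, window = 1) {
  ramp <- select_ramp(test)
  ratios <- derive_ratios(ramp)
  res <- list(
    highest_vo2 = max(rolling_mean(ramp$vo2, window)),
    highest_hr = if (!is.null(ramp$hr) && any(is.finite(ramp$hr)))
      max(rolling_mean(ramp$hr[is.finite(ramp$hr)], window)) else NA_real_,
    highest_r = max(rolling_mean(ratios$R, window))
  )
  w <- test$meta$weight
  res$highest_vo2_kg <- if (is.finite(w)) res$highest_vo2 / w else NA_real_
  res
}
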