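make_fit <- function(a, b) {
  structure(list(a = a, b = b, r_fit = 1, n = 100, method = "log-linear",
                 x_name = "vo2", y_name = "y"), class = "exp_fit")
}

test_that("expVAT(VCO2) sits exactly where the fitted slope equals 1", {
  x0 <- expvat_vco2(make_fit(1.0020, 154.3))
  expect_equal(x0, 589, tolerance = 1e-3)  # log(1/(154.3*log(1.002)))/log(1.002)
  expect_equal(154.3 * 1.0020^x0 * log(1.0020), 1, tolerance = 1e-10)

  set.seed(21)
  for (i in 1:200) {
    a <- runif(1, 1.0003, 1.01)
    b <- runif(1, 50, 0.9 / log(a))  # keep tangent point positive
    x0 <- expvat_vco2(make_fit(a, b))
    expect_equal(b * a^x0 * log(a), 1, tolerance = 1e-10)
  }
})

test_that("expVAT(VE) equals 1/ln(a), independent of b, at the VE/VO2 nadir", {
  expect_equal(expvat_ve(make_fit(1.0015, 4)), 667.2, tolerance = 1e-3)
  expect_equal(expvat_ve(make_fit(1.0015, 4)),
               expvat_ve(make_fit(1.0015, 400)))

  # origin-tangency: chord slope from (0,0) equals the derivative there
  a <- 1.0012; b <- 7
  x0 <- expvat_ve(make_fit(a, b))
  expect_equal((b * a^x0) / x0, b * a^x0 * log(a), tolerance = 1e-10)

  # brute-force nadir of fitted VE/VO2 on a 1 mL/min grid
  set.seed(22)
  for (i in 1:50) {
    a <- runif(1, 1.0005, 1.005)
    b <- runif(1, 2, 20)
    x0 <- expvat_ve(make_fit(a, b))
    grid <- seq(1, 5 / log(a), by = 1)
    expect_lte(abs(grid[which.min(b * a^grid / grid)] - x0), 1)
  }
})

test_that("undefined tangent constructions are flagged missing, not errors", {
  for (f in list(expvat_vco2, expvat_ve)) {
    res <- f(make_fit(1.0, 300))
    expect_true(is.na(res))
    expect_equal(attr(res, "flag"), "a_not_gt_1")
  }
  res <- expvat_vco2(make_fit(1.5, 300))  # b*ln(a) >= 1: tangent at x <= 0
  expect_true(is.na(res))
  expect_equal(attr(res, "flag"), "tangent_nonpositive")
})

test_that("both thresholds strictly decrease as the base a increases", {
  as <- seq(1.0008, 1.004, length.out = 25)
  xv <- vapply(as, function(a) expvat_vco2(make_fit(a, 150)), numeric(1))
  xe <- vapply(as, function(a) expvat_ve(make_fit(a, 5)), numeric(1))
  expect_true(all(diff(xv) < 0))
  expect_true(all(diff(xe) < 0))
})

test_that("OUES recovers an exact log-linear relation and ignores units", {
  ve <- seq(8, 90, length.out = 60)
  samples <- data.frame(vo2 = 2000 * log10(ve) - 500, ve = ve,
                        vco2 = ve * 35)
  expect_equal(oues(samples, "ve"), 2000, tolerance = 1e-9)

  # rescaling the channel shifts only the intercept
  ml <- oues(samples, "vco2")
  samples$vco2 <- samples$vco2 / 1000
  expect_equal(oues(samples, "vco2"), ml, tolerance = 1e-9)

  expect_error(oues(samples[1:5, ], "ve"), class = "expvat_insufficient_data")
  samples$ve[1] <- 0
  expect_error(oues(samples, "ve"), class = "expvat_domain_error")
})

test_that("summary metrics complete relative, %predicted and per-kg fields", {
  test <- toy_test()  # age 60, weight 70
  test$samples$hr <- seq(80, 160, length.out = nrow(test$samples))
  est <- vat_estimates(test)
  expect_equal(est$pct_predicted_hr, 100 * est$highest_hr / 160)
  expect_equal(est$relative_vat_vco2_pct,
               100 * est$expvat_vco2 / est$highest_vo2)
  expect_equal(est$expvat_vco2_kg, est$expvat_vco2 / 70)

  est2 <- est
  est2$expvat_vco2 <- 500; est2$highest_vo2 <- 1000
  est2 <- summary_metrics(est2, test)
  expect_equal(est2$relative_vat_vco2_pct, 50)

  # missing age/weight -> fields stay missing, no error
  test$meta$age <- NA_real_; test$meta$weight <- NA_real_
  est3 <- vat_estimates(test)
  expect_true(is.na(est3$pct_predicted_hr))
  expect_true(is.na(est3$expvat_vco2_kg))
})

test_that("vat_estimates collects QC flags for invalid inputs", {
  # pre-threshold-only segment: slope ~0.9, below validity cutoff
  pre_only <- toy_test(vo2 = seq(400, 950, length.out = 80), vat = 1000)
  est <- vat_estimates(pre_only)
  expect_true("pre_vat_slope_below_threshold" %in% est$qc_flags)

  short <- toy_test(n = 12)
  short$samples <- short$samples[1:8, ]
  short <- cpx_test(short$samples, meta = short$meta, protocol = short$protocol)
  est <- vat_estimates(short)
  expect_equal(est$qc_flags, "insufficient_data")
  expect_true(is.na(est$expvat_vco2))
})

test_that("batch estimation flags cohort-level fit outliers", {
  co <- simulate_cohort(12, seed = 31)
  b <- batch_estimates(co)
  expect_equal(nrow(b$table), 12)
  expect_true(all(is.finite(b$table$expvat_vco2)))

  # corrupt one subject's ramp so its fit r collapses
  bad <- co[[1]]$test
  set.seed(32)
  idx <- bad$samples$phase == "ramp"
  bad$samples$vco2[idx] <- bad$samples$vco2[idx] * exp(rnorm(sum(idx), 0, 0.8))
  co[[1]]$test <- cpx_test(bad$samples, meta = bad$meta, protocol = bad$protocol)
  b2 <- batch_estimates(co)
  expect_match(b2$table$qc_flags[1], "poor_fit_outlier")
})
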