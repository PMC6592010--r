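# independent critical-value oracle for one Grubbs step (one-sided)
grubbs_crit_oracle <- function(n, alpha) {
  t2 <- qt(1 - alpha / n, n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

test_that("Grubbs screening excludes a single gross low outlier", {
  set.seed(41)
  vals <- c(0.99 + rnorm(19, 0, 0.002), 0.70)
  res <- grubbs_screen(vals, alpha = 0.001, side = "lower")
  expect_equal(res$excluded_indices, 20L)
  # the recorded G exceeds the independently computed critical value
  g_hand <- (mean(vals) - min(vals)) / sd(vals)
  expect_equal(res$g_statistics[1], g_hand, tolerance = 1e-12)
  expect_gt(res$g_statistics[1], grubbs_crit_oracle(20, 0.001))
  expect_true(all(res$kept[-20]))
})

test_that("Grubbs iterates: several spread-out low outliers all go", {
  set.seed(42)
  vals <- c(0.99 + rnorm(30, 0, 0.002), 0.85, 0.70, 0.55)
  res <- grubbs_screen(vals, alpha = 0.001, side = "lower")
  expect_setequal(res$excluded_indices, 31:33)
  # exclusions ordered most-extreme first
  expect_equal(res$excluded_indices[1], 33L)
})

test_that("Grubbs degenerate and monotonicity properties hold", {
  expect_equal(grubbs_screen(rep(0.9, 10))$excluded_indices, integer(0))
  expect_error(grubbs_screen(c(1, 2)), class = "expvat_insufficient_data")
  expect_error(grubbs_screen(c(1, 2, NA)), class = "expvat_domain_error")

  # excluded count is non-increasing as alpha shrinks
  set.seed(43)
  for (i in 1:20) {
    vals <- c(rnorm(25, 0.97, 0.01), runif(3, 0.5, 0.9))
    n_ex <- vapply(c(0.1, 0.01, 0.001), function(a)
      length(grubbs_screen(vals, alpha = a)$excluded_indices), numeric(1))
    expect_true(all(diff(n_ex) <= 0))
  }
})

test_that("pre-threshold slope validity uses the mean + 2 SD cutoff", {
  # the default cutoff is the 95% upper bound of the pre-threshold slope
  expect_equal(0.901 + 2 * 0.102, 1.105)

  # segment wholly below the threshold: slope ~0.9, invalid
  seg <- select_ramp(toy_test(vo2 = seq(400, 950, length.out = 50), vat = 1000))
  chk <- pre_vat_slope_check(seg)
  expect_equal(chk$slope, 0.9, tolerance = 1e-9)
  expect_false(chk$valid)

  # full ramp crossing the threshold at midrange: mixture slope exceeds it
  full <- select_ramp(toy_test(vo2 = seq(400, 1600, length.out = 100),
                               vat = 1000, s2 = 1.4))
  chk <- pre_vat_slope_check(full)
  o <- ols_oracle(full$vo2, full$vco2)
  expect_equal(chk$slope, o$slope, tolerance = 1e-12)
  expect_true(chk$valid)

  expect_error(pre_vat_slope_check(seg[1:5, ]), class = "expvat_insufficient_data")
})

test_that("Bland-Altman agreement matches direct computation", {
  x <- c(10, 20, 30)
  r <- bland_altman(x, x)
  expect_equal(r$mean_diff, 0)
  expect_equal(r$loa_half_width, 0)

  # differences constructed with sample SD exactly 140.8
  y <- x - c(-140.8, 0, 140.8)
  r <- bland_altman(x, y)
  expect_equal(r$sd_diff, 140.8)
  expect_equal(r$loa_half_width, 1.96 * 140.8)  # 275.97, prints as +/-276
  expect_equal(r$loa_half_width, 275.968)

  set.seed(44)
  a <- rnorm(80, 1000, 300); b <- a + rnorm(80, -20, 140)
  r <- bland_altman(a, b)
  d <- a - b
  expect_equal(r$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(r$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(r$loa_half_width, 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(r$pearson_r, cor(a, b), tolerance = 1e-12)

  # LoA scales linearly with the inputs
  r10 <- bland_altman(10 * a, 10 * b)
  expect_equal(r10$loa_half_width, 10 * r$loa_half_width, tolerance = 1e-9)
  expect_error(bland_altman(1:2, 1:2), class = "expvat_insufficient_data")
})

test_that("Williams's test behaves per its closed form", {
  # equal correlations -> no evidence either way
  w <- williams_test(0.9, 0.9, 0.8, 50)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_equal(w$df, 47)

  # antisymmetric in the compared pair
  w1 <- williams_test(0.95, 0.90, 0.85, 60)
  w2 <- williams_test(0.90, 0.95, 0.85, 60)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)

  # matches an independent re-derivation on random PSD triplets
  oracle <- function(r12, r13, r23, n) {
    detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
    rbar <- (r12 + r13) / 2
    (r12 - r13) * sqrt((n - 1) * (1 + r23) /
      (2 * (n - 1) / (n - 3) * detR + rbar^2 * (1 - r23)^3))
  }
  set.seed(45)
  tested <- 0
  while (tested < 50) {
    r <- runif(3, -0.9, 0.9)
    det <- 1 - sum(r^2) + 2 * prod(r)
    if (det <= 0) next
    n <- sample(10:200, 1)
    w <- williams_test(r[1], r[2], r[3], n)
    expect_equal(w$t, oracle(r[1], r[2], r[3], n), tolerance = 1e-12)
    expect_equal(w$p, 2 * pt(abs(w$t), n - 3, lower.tail = FALSE),
                 tolerance = 1e-12)
    tested <- tested + 1
  }

  expect_error(williams_test(1, 0.5, 0.5, 20), class = "expvat_domain_error")
  expect_error(williams_test(0.9, -0.9, 0.9, 20), class = "expvat_domain_error")
  expect_error(williams_test(0.5, 0.4, 0.3, 4), class = "expvat_insufficient_data")
})

test_that("correlation matrix is pairwise-complete with per-pair n", {
  set.seed(46)
  n <- 40
  cols <- list(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  cols$b2 <- 3 * cols$b + 1           # exactly proportional
  cols$a[sample(n, 12)] <- NA          # mimic undetected visual thresholds
  cm <- correlation_matrix(cols)

  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_equal(cm$r["b", "b2"], 1, tolerance = 1e-12)
  expect_equal(cm$n["a", "b"], sum(is.finite(cols$a)))

  keep <- is.finite(cols$a)
  expect_equal(cm$r["a", "c"], cor(cols$a[keep], cols$c[keep]),
               tolerance = 1e-12)
  expect_true(isSymmetric(cm$r))

  sparse <- list(a = c(1, 2, NA, NA, NA), b = c(NA, NA, 3, 4, 5))
  cm2 <- correlation_matrix(sparse)
  expect_true(is.na(cm2$r["a", "b"]))
  expect_error(correlation_matrix(list(a = 1:5)),
               class = "expvat_insufficient_data")
})
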