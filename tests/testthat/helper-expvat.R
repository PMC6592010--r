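# Shared fixtures and independent oracles.

# noise-free exponential channel on a VO2 grid
exact_exp_data <- function(a = 1.0015, b = 300, x = seq(500, 2000, by = 50)) {
  list(x = x, y = b * a^x, a = a, b = b)
}

# two-pass closed-form OLS oracle (textbook sums, independent of lm)
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

# minimal valid hand-built test: linear VO2 ramp, piecewise V-slope
toy_test <- function(n = 100, phase = NULL, s1 = 0.9, s2 = 1.4,
                     vat = 1000, vo2 = seq(400, 1800, length.out = n)) {
  n <- length(vo2)
  vco2 <- -30 + s1 * pmin(vo2, vat) + s2 * pmax(0, vo2 - vat)
  ve <- 4 + 28 * vco2 / 1000
  if (is.null(phase)) phase <- rep("ramp", n)
  cpx_test(data.frame(t = seq_len(n) * 3, vo2 = vo2, vco2 = vco2,
                      ve = ve, phase = phase),
           meta = subject_meta(subject_id = "toy", age = 60, weight = 70))
}
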