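test_that("fluctuations remove the circular mean with minimal-image deviations", {
  # alternating +179/-179: circular mean 180, deviations -/+1, variance 1
  f <- fluctuations(series_of(rep(c(179, -179), 10)))
  expect_equal(f$mean_deg, 180)
  expect_equal(f$dev_deg[1:2], c(-1, 1))
  expect_equal(f$var_deg2, 1)

  f2 <- fluctuations(series_of(rep(c(0, 90), 8)))
  expect_equal(f2$mean_deg, 45)
  expect_equal(sort(unique(f2$dev_deg)), c(-45, 45))

  expect_error(fluctuations(series_of(rep(42, 20))), class = "tdcf_zero_variance")

  # unwrap policy: a branch-hopping drift keeps deviations continuous
  drift <- wrap_angle(170 + seq(0, 40, length.out = 50))
  fu <- fluctuations(series_of(drift), policy = "unwrap")
  expect_lt(max(abs(diff(fu$dev_deg))), 2)   # no 360-degree jumps
})

test_that("the TDCF estimator matches its definition (naive sums) and pins C(0)", {
  set.seed(21)
  x <- series_of(rnorm(60, sd = 12)); y <- series_of(rnorm(60, sd = 9), res = 2L)
  fx <- fluctuations(x); fy <- fluctuations(y)
  cu <- tdcf_estimate(fx, fy, max_lag_ns = 2, min_count = 5)
  # naive double-loop oracle
  L <- length(cu$lag_ns) - 1L
  naive <- sapply(0:L, function(l) {
    n <- length(fx$dev_deg) - l
    sum(fx$dev_deg[1:n] * fy$dev_deg[(1 + l):(n + l)]) /
      (n * sqrt(fx$var_deg2 * fy$var_deg2))
  })
  expect_equal(cu$C, naive, tolerance = 1e-10)
  expect_equal(cu$N_l, length(fx$dev_deg) - 0:L)

  # zero-lag normalization is exact
  expect_equal(tdcf_estimate(fx, fx, max_lag_ns = 1)$C[1], 1)
  fneg <- fx; fneg$dev_deg <- -fx$dev_deg
  expect_equal(tdcf_estimate(fx, fneg, max_lag_ns = 1)$C[1], -1)
  expect_equal(tdcf_pearson(fx, fy), cu$C[1])

  # mismatched grids rejected
  expect_error(tdcf_estimate(fx, fluctuations(series_of(rnorm(61)))),
               class = "tdcf_alignment")

  # per-window normalization also pins C(0) = 1 on itself
  expect_equal(tdcf_estimate(fx, fx, max_lag_ns = 1,
                             normalization = "per-window")$C[1], 1)
})

test_that("independent white-noise series stay inside the null envelope", {
  set.seed(77)
  n <- 2000L
  fx <- fluctuations(series_of(rnorm(n, sd = 15)))
  fy <- fluctuations(series_of(rnorm(n, sd = 15), res = 2L))
  cu <- tdcf_estimate(fx, fy, max_lag_ns = 40)    # 400 lags
  frac_out <- mean(abs(cu$C) > 3 / sqrt(n))
  expect_lt(frac_out, 0.02)
})

test_that("TDCF convergence saturates with trajectory length and flags regime shifts", {
  sys <- oscillator_from_times(2, 3, alpha = 0.25, beta = 0.05)
  ser <- simulate_oscillators(sys, n_steps = 40000, dt_ns = 0.05, seed = 5)
  cv <- convergence_check(ser[[1]], ser[[2]], fractions = c(0.5, 0.9, 1),
                          max_lag_ns = 15)
  expect_lt(cv$sup_diff["0.9", "1"], cv$sup_diff["0.5", "1"])
  expect_equal(convergence_check(ser[[1]], ser[[2]], fractions = c(1, 1),
                                 max_lag_ns = 15)$sup_diff[1, 2], 0)
  # regime switch mid-series (coupling sign reverses): prefix curves diverge
  dev <- fluctuations(ser[[1]])$dev_deg
  dev[20001:40000] <- -dev[20001:40000]
  sh <- series_of(wrap_angle(dev), dt_ns = 0.05)
  cv2 <- convergence_check(sh, ser[[2]], fractions = c(0.5, 1), max_lag_ns = 15)
  expect_gt(cv2$sup_diff["0.5", "1"], 3 * cv$sup_diff["0.5", "1"])
  expect_warning(convergence_check(ser[[1]], ser[[2]], fractions = c(0.001, 1),
                                   max_lag_ns = 15),
                 "too short")
})

test_that("the numerical Laplace transform reproduces closed-form pairs and is linear", {
  lag <- seq(0, 40, by = 0.01)
  a <- 0.5; b <- 2
  s <- logspace(0.1, 10, 60)
  lc1 <- laplace_transform(fake_curve(lag, exp(-a * lag)), s_grid = s)
  expect_lt(max(abs(lc1$F_s - 1 / (s + a)) / (1 / (s + a))), 0.01)

  lc2 <- laplace_transform(fake_curve(lag, exp(-a * lag) * cos(b * lag)), s_grid = s)
  ref <- (s + a) / ((s + a)^2 + b^2)
  expect_lt(max(abs(lc2$F_s - ref) / abs(ref)), 0.01)

  expect_equal(laplace_transform(fake_curve(lag, rep(0, length(lag))),
                                 s_grid = s)$F_s,
               rep(0, length(s)))

  # linearity to quadrature precision
  mix <- laplace_transform(fake_curve(lag, 2 * exp(-a * lag) -
                                        0.5 * exp(-a * lag) * cos(b * lag)),
                           s_grid = s)
  expect_equal(mix$F_s, 2 * lc1$F_s - 0.5 * lc2$F_s, tolerance = 1e-12)

  expect_error(laplace_transform(fake_curve(lag, exp(-lag)), s_grid = c(-1, 1)),
               class = "tdcf_domain")

  # F at s -> 0 approaches the trapezoid estimate of the integral of C
  tiny <- laplace_transform(fake_curve(lag, exp(-a * lag)), s_grid = c(1e-8, 1e-7))
  expect_equal(tiny$F_s[1], trapz(lag, exp(-a * lag)), tolerance = 1e-6)
})

test_that("Laplace extrema distinguish interior peaks, boundaries and sign", {
  s <- logspace(1e-3, 10, 120)
  a <- 0.1; b <- 1
  mk <- function(F_s) structure(list(s = s, F_s = F_s, trunc_bias = rep(0, length(s)),
                                     dt_ns = 1e-3), class = "laplace_curve")
  ex <- laplace_extremum(mk((s + a) / ((s + a)^2 + b^2)))
  expect_false(ex$boundary)
  expect_equal(ex$s_peak, sqrt(a^2 + b^2) - a, tolerance = 0.05)

  ex2 <- laplace_extremum(mk(1 / (s + a)))
  expect_true(ex2$boundary)
  expect_equal(ex2$s_peak, s[1])

  ex3 <- laplace_extremum(mk(-(s + a) / ((s + a)^2 + b^2)))
  expect_equal(ex3$F_ext, -ex$F_ext)
  expect_equal(ex3$s_peak, ex$s_peak)
})

test_that("tail exponents recover the algebraic decay of closed forms", {
  # F = 1/(s+a): kappa -> 1 from below over a high-s decade; the estimator
  # must match the least-squares slope of the closed form on the same window
  lag <- seq(0, 60, by = 0.005)
  a <- 0.5
  lc <- laplace_transform(fake_curve(lag, exp(-a * lag)), n_s = 200L)
  ta <- tail_exponent(lc, window = c(10 * a, 100 * a))
  in_win <- lc$s >= 10 * a & lc$s <= 100 * a
  oracle <- -unname(coef(lm(log(1 / (lc$s[in_win] + a)) ~ log(lc$s[in_win])))[2])
  expect_equal(ta$kappa, oracle, tolerance = 0.02)
  expect_lt(abs(ta$kappa - 1), 0.06)

  # C(0) = 0 (C = t exp(-t)): leading Watson term 1/s^2, kappa near 2
  lc2 <- laplace_transform(fake_curve(lag, lag * exp(-lag)), n_s = 200L)
  ta2 <- tail_exponent(lc2, window = c(20, 90))
  in2 <- lc2$s >= 20 & lc2$s <= 90
  oracle2 <- -unname(coef(lm(log(1 / (lc2$s[in2] + 1)^2) ~ log(lc2$s[in2])))[2])
  expect_equal(ta2$kappa, oracle2, tolerance = 0.03)
  expect_gt(ta2$kappa, 1.8)

  # default window stays below the quadrature cap
  ta3 <- tail_exponent(lc)
  expect_lte(ta3$window[2], 0.5 / lc$dt_ns + 1e-9)
  expect_gt(ta3$n_points, 5)
})
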