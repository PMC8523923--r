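# SNR, the run-of-2 threshold rule, the weighted smoothing spline, the
# median-slope metric, regression statistics, low-frequency aggregation.

series_with_snr <- function(snr, levels = seq(10, by = 5,
                                              length.out = length(snr))) {
  level_series(480, levels, response = snr, noise_floor = rep(0, length(snr)))
}

test_that("SNR arithmetic per measurement kind", {
  s <- level_series(480, c(10, 20), c(10, 4), noise_floor = c(4, 4))
  expect_equal(compute_snr(s)$snr, c(6, 0))
  s2 <- level_series(4000, c(10, 20), c(10, 1), noise_floor = c(1, 1),
                     kind = "cap_p2p")
  expect_equal(compute_snr(s2)$snr, c(20, 0))
  s3 <- level_series(480, c(10, 20), c(1, 2), kind = "anow_phase_delay")
  expect_error(compute_snr(s3), "delay")
})

test_that("run-of-2 threshold rule", {
  expect_identical(estimate_threshold(series_with_snr(c(-2, 3, 8, 12, 20))),
                   20)
  expect_identical(estimate_threshold(series_with_snr(c(1, 2, 3, 4, 5))),
                   NA_real_)
  # isolated single-level excursions never qualify
  expect_identical(estimate_threshold(series_with_snr(c(2, 8, 3, 9, 4))),
                   NA_real_)
  # criterion is configurable
  expect_identical(estimate_threshold(series_with_snr(c(-2, 3, 8, 12, 20)),
                                      criterion = 10), 25)
})

test_that("the spline reproduces affine data exactly for any p and weights", {
  L <- seq(10, 80, 5)
  y <- -4 + 0.37 * L
  s <- level_series(480, L, y, noise_floor = rep(-100, length(L)))
  for (p in c(0.005, 0.3, 0.9)) {
    set.seed(p * 1000)
    w <- runif(length(L), 6.5, 40)
    fit <- fit_growth_spline(s, smoothing = p, snr_override = w)
    expect_equal(fit$fitted, -4 + 0.37 * fit$grid, tolerance = 1e-9)
    expect_equal(fit$derivative, rep(0.37, length(fit$grid)),
                 tolerance = 1e-9)
  }
})

test_that("grid spacing is exactly 1 dB and spans the tested levels", {
  L <- seq(10, 80, 5)
  s <- level_series(480, L, 0.5 * L, noise_floor = rep(0, length(L)))
  fit <- fit_growth_spline(s)
  expect_identical(fit$grid, seq(10, 80, by = 1))
  expect_identical(unique(diff(fit$grid)), 1)
})

test_that("sub-criterion points are provably inert", {
  L <- seq(10, 80, 5)
  y <- 0.5 * L
  snr <- y - 0; snr[1] <- 2          # below the 6 dB criterion
  s1 <- level_series(480, L, y, noise_floor = y - snr)
  y2 <- y; y2[1] <- 999
  s2 <- level_series(480, L, y2, noise_floor = y2 - snr)
  f1 <- fit_growth_spline(s1)
  f2 <- fit_growth_spline(s2)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$derivative, f2$derivative)
  expect_error(fit_growth_spline(series_with_snr(c(2, 3, 8, 9, 10))),
               "nonzero weight")
})

test_that("median slope counts grid points above threshold correctly", {
  fake <- structure(
    list(grid = 0:29, fitted = rep(0, 30),
         derivative = c(rep(2, 10), rep(0.5, 20)), smoothing = 0.005,
         weights_used = rep(1, 30), frequency = 480, label = "500",
         kind = "anow_magnitude"),
    class = "growth_fit")
  sl <- median_slope(fake, 0)
  expect_equal(sl$median_slope, 0.5)
  expect_identical(sl$n_grid_points_used, 30L)
  # even-count midpoint convention
  fake$derivative <- c(1, 2, 3, 4); fake$grid <- 1:4
  expect_equal(median_slope(fake, 1)$median_slope, 2.5)
  # absence propagates
  expect_true(is.na(median_slope(fake, NA_real_)$median_slope))
  expect_true(is.na(median_slope(fake, 99)$median_slope))
})

test_that("noiseless linear growth recovers the generating slope through the pipeline", {
  scen <- scenario_config(
    neural_amplitude_fn = function(l) db_amplitude(0.75 * l - 50),
    noise_sigma = 0, seed = 1)
  s <- gen_growth_series(scen, seq(10, 80, 5), frequency = 480)
  fit <- fit_growth_spline(s)
  th <- estimate_threshold(s)
  sl <- median_slope(fit, th)
  expect_equal(sl$median_slope, 0.75, tolerance = 1e-6)
})

test_that("OLS statistics: exact fit and closed-form agreement", {
  suppressWarnings(
    r <- regress_slope_vs_threshold(data.frame(threshold = c(0, 10, 20),
                                               median_slope = c(0, 1, 2))))
  expect_equal(r$slope, 0.1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)

  set.seed(14)
  x <- c(12, 18, 25, 33, 41)
  y <- 0.3 + 0.02 * x + rnorm(5, 0, 0.05)
  r2 <- regress_slope_vs_threshold(data.frame(threshold = x,
                                              median_slope = y))
  o <- ols_oracle(x, y)
  expect_equal(r2$slope, o$slope, tolerance = 1e-8)
  expect_equal(r2$intercept, o$intercept, tolerance = 1e-8)
  expect_equal(r2$r_squared, o$r_squared, tolerance = 1e-8)
  expect_equal(r2$p_value, o$p_value, tolerance = 1e-8)
  expect_equal(r2$conf_int, o$conf_int, tolerance = 1e-8)
  expect_true(r2$conf_int[1] < r2$slope && r2$slope < r2$conf_int[2])

  expect_error(regress_slope_vs_threshold(
    data.frame(threshold = c(5, 5, 5), median_slope = 1:3)), "degenerate")
  # NA rows are excluded, never silently regressed
  r3 <- regress_slope_vs_threshold(
    data.frame(threshold = c(x, NA), median_slope = c(y, 1)))
  expect_identical(r3$n, 5L)
  expect_error(regress_slope_vs_threshold(
    data.frame(threshold = c(1, 2, NA), median_slope = c(1, NA, 3))),
    "at least 3")
})

test_that("low-frequency aggregation averages qualifying frequencies", {
  df <- data.frame(frequency = c(300, 480, 720, 1020),
                   median_slope = c(0.3, 0.5, 0.7, 0.9),
                   threshold = c(20, 25, 30, 35))
  a <- aggregate_low_freq(df, control_reference = 15)
  expect_equal(a$mean_slope, 0.6)
  expect_equal(a$mean_threshold, 27.5)
  expect_equal(a$threshold_shift, 12.5)
  expect_identical(a$n_frequencies, 4L)
  # single qualifying frequency is the identity; high frequencies excluded
  df2 <- data.frame(frequency = c(720, 8000),
                    median_slope = c(0.4, 1.2), threshold = c(30, 10))
  a2 <- aggregate_low_freq(df2)
  expect_equal(a2$mean_slope, 0.4)
  # absence propagates
  df3 <- data.frame(frequency = 300, median_slope = NA_real_,
                    threshold = NA_real_)
  expect_true(is.na(aggregate_low_freq(df3)$mean_slope))
})

test_that("the fit agrees with an independent penalized-spline oracle", {
  skip_if_not_installed("Matrix")
  L <- seq(10, 80, 5)
  for (k in 1:5) {
    set.seed(30 + k)
    y <- 0.02 * L^2 + rnorm(length(L), 0, 1)
    s <- level_series(480, L, y, noise_floor = rep(0, length(L)))
    fit <- fit_growth_spline(s)
    snr <- y
    w <- pmax(snr, 0); w[snr < 6] <- 0
    keep <- w > 0
    orac <- oracle_penalized_spline(L[keep], y[keep], w[keep], 0.005,
                                    step = 0.25)
    inside <- fit$grid >= min(L[keep]) & fit$grid <= max(L[keep])
    expect_lt(max(abs(fit$fitted[inside] - orac$at(fit$grid[inside]))),
              0.05)
  }
})
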