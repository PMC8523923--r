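# Growth-function analysis: SNR weighting, the run-of-2 threshold rule,
# SNR-weighted smoothing-spline fits of response-vs-level series on a 1-dB
# grid, the median-derivative recruitment slope, and the downstream
# slope-versus-threshold regression statistics.

#' Per-level response series for one frequency of one ear
#'
#' @param frequency actual stimulus frequency, Hz.
#' @param levels strictly ascending stimulus levels, dB SPL.
#' @param response per-level response: ANOW RMS magnitude in dB re 1 uV
#'   (`anow_magnitude`), CAP peak-to-peak in uV (`cap_p2p`), or a delay in
#'   ms (`*_delay` kinds).
#' @param noise_floor per-level noise floor on the same scale (dB or uV);
#'   not used by delay kinds.
#' @param kind measurement kind.
#' @param label display label (the conventional nominal frequency, e.g.
#'   "500" for a 480 Hz stimulus); defaults to the actual frequency.
#' @param snr optional per-level SNR in dB (computed by [compute_snr()]
#'   for magnitude kinds, inherited from the paired magnitude series for
#'   delay kinds).
#' @return an object of class `level_series`.
#' @export
level_series <- function(frequency, levels, response, noise_floor = NULL,
                         kind = c("anow_magnitude", "cap_p2p",
                                  "anow_phase_delay", "cap_peak_delay"),
                         label = NULL, snr = NULL) {
  kind <- match.arg(kind)
  check_scalar(frequency, "frequency", positive = TRUE)
  if (is.unsorted(levels, strictly = TRUE))
    abort_field("levels", "must be strictly ascending")
  n <- length(levels)
  if (length(response) != n)
    abort_field("response", "must match levels in length")
  if (!is.null(noise_floor) && length(noise_floor) != n)
    abort_field("noise_floor", "must match levels in length")
  if (!is.null(snr) && length(snr) != n)
    abort_field("snr", "must match levels in length")
  structure(
    list(frequency = frequency,
         label = if (is.null(label)) format(frequency) else label,
         levels = as.numeric(levels), response = as.numeric(response),
         noise_floor = if (is.null(noise_floor)) NULL
                       else as.numeric(noise_floor),
         snr = if (is.null(snr)) NULL else as.numeric(snr), kind = kind),
    class = "level_series")
}

#' @export
print.level_series <- function(x, ...) {
  cat(sprintf("<level_series> %s at %s Hz (%s): %d levels %g-%g dB SPL\n",
              x$kind, x$label, format(x$frequency), length(x$levels),
              min(x$levels), max(x$levels)))
  invisible(x)
}

#' Signal-to-noise ratio of a magnitude series
#'
#' For dB-valued responses (`anow_magnitude`) the SNR is the plain dB
#' difference `response - noise_floor`; for linear responses (`cap_p2p`)
#' both are first expressed in dB.  Delay series carry no own SNR and are
#' an error here (their SNR is inherited from the paired magnitude
#' series).
#'
#' @param series a [level_series()] with noise floors.
#' @return the series with `$snr` (dB) filled in.
#' @export
compute_snr <- function(series) {
  stopifnot(inherits(series, "level_series"))
  if (series$kind %in% c("anow_phase_delay", "cap_peak_delay"))
    stop("delay series have no own SNR; inherit it from the paired magnitude series",
         call. = FALSE)
  if (is.null(series$noise_floor))
    stop("series carries no noise floors", call. = FALSE)
  series$snr <- if (series$kind == "anow_magnitude")
    series$response - series$noise_floor
  else
    20 * log10(series$response / series$noise_floor)
  series
}

#' Threshold by the run-of-2 SNR rule
#'
#' The threshold is the lowest tested level whose SNR meets the criterion
#' (default 6 dB, the same criterion that zeroes spline weights) at that
#' level *and* at the next tested level; a single-level excursion does not
#' qualify.  Absence of such a level is a value (`NA`), not an error.
#'
#' @param series a [level_series()]; SNR is computed if missing.
#' @param criterion SNR criterion in dB.
#' @return threshold level in dB SPL, or `NA_real_` ("no threshold").
#' @export
estimate_threshold <- function(series, criterion = 6) {
  stopifnot(inherits(series, "level_series"))
  if (is.null(series$snr)) series <- compute_snr(series)
  ok <- series$snr >= criterion
  n <- length(ok)
  if (n < 2) return(NA_real_)
  run2 <- which(ok[-n] & ok[-1])
  if (length(run2) == 0) NA_real_ else series$levels[run2[1]]
}

# ---- smoothing-spline engine -------------------------------------------
# Natural cubic smoothing spline minimizing
#     p * sum_i w_i (y_i - g(x_i))^2 + (1 - p) * int g''(t)^2 dt
# via the Reinsch scheme (solve for interior second derivatives).  p -> 1
# interpolates, p -> 0 tends to the weighted least-squares line.

reinsch_fit <- function(x, y, w, p) {
  n <- length(x)
  h <- diff(x)
  lambda <- (1 - p) / p
  # Q: n x (n-2) second-difference operator, R: (n-2) x (n-2) tridiagonal
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in seq_len(n - 2)) {
    Q[j, j] <- 1 / h[j]
    Q[j + 1, j] <- -1 / h[j] - 1 / h[j + 1]
    Q[j + 2, j] <- 1 / h[j + 1]
    R[j, j] <- (h[j] + h[j + 1]) / 3
    if (j < n - 2) {
      R[j, j + 1] <- h[j + 1] / 6
      R[j + 1, j] <- h[j + 1] / 6
    }
  }
  A <- R + lambda * crossprod(Q, Q / w)
  gamma <- solve(A, crossprod(Q, y))
  yhat <- y - lambda * (Q %*% gamma) / w
  list(x = x, yhat = as.numeric(yhat), M = c(0, as.numeric(gamma), 0))
}

# evaluate the natural cubic spline and its derivative; linear
# extrapolation beyond the data range
spline_eval <- function(fit, xout) {
  x <- fit$x; yhat <- fit$yhat; M <- fit$M
  n <- length(x)
  xc <- pmin(pmax(xout, x[1]), x[n])
  i <- findInterval(xc, x, all.inside = TRUE)
  h <- x[i + 1] - x[i]
  dl <- x[i + 1] - xc
  dr <- xc - x[i]
  g <- M[i] * dl^3 / (6 * h) + M[i + 1] * dr^3 / (6 * h) +
    (yhat[i] / h - M[i] * h / 6) * dl +
    (yhat[i + 1] / h - M[i + 1] * h / 6) * dr
  gp <- -M[i] * dl^2 / (2 * h) + M[i + 1] * dr^2 / (2 * h) +
    (yhat[i + 1] - yhat[i]) / h - (M[i + 1] - M[i]) * h / 6
  out_lo <- xout < x[1]
  out_hi <- xout > x[n]
  if (any(out_lo) || any(out_hi)) {
    sl_lo <- spline_eval(fit, x[1])$derivative
    sl_hi <- spline_eval(fit, x[n])$derivative
    g[out_lo] <- yhat[1] + sl_lo * (xout[out_lo] - x[1])
    gp[out_lo] <- sl_lo
    g[out_hi] <- yhat[n] + sl_hi * (xout[out_hi] - x[n])
    gp[out_hi] <- sl_hi
  }
  list(fitted = g, derivative = gp)
}

#' SNR-weighted smoothing-spline fit of a growth function
#'
#' Fits the series with a natural cubic smoothing spline minimizing
#' `p * sum w_i (y_i - g(L_i))^2 + (1 - p) * int g''^2`, with
#' `p = smoothing` (default 0.005; `p -> 1` interpolates, `p -> 0`
#' approaches the weighted straight-line fit -- note other software inverts
#' this convention).  Weights are the per-level SNR in dB floored at zero,
#' and exactly zero below `snr_criterion` (6 dB), so sub-criterion points
#' are provably inert.  The fit and its analytic derivative are evaluated
#' on a 1-dB grid spanning the tested levels (natural-spline linear
#' extrapolation outside the weighted support).
#'
#' @param series a [level_series()]; SNR is computed if missing, or
#'   supplied via `snr_override` for delay series.
#' @param smoothing smoothing coefficient `p` in (0, 1).
#' @param snr_criterion SNR (dB) below which weights are set to zero.
#' @param snr_override optional SNR vector (dB) to use as weights, for
#'   delay series that inherit SNR from the paired magnitude series.
#' @return an object of class `growth_fit`: `grid` (dB SPL, 1-dB spacing),
#'   `fitted`, `derivative` (per dB), `smoothing`, `weights_used` (full
#'   length, zeros included), plus the fitted knots.
#' @export
fit_growth_spline <- function(series, smoothing = 0.005, snr_criterion = 6,
                              snr_override = NULL) {
  stopifnot(inherits(series, "level_series"))
  check_scalar(smoothing, "smoothing", positive = TRUE)
  if (smoothing >= 1) abort_field("smoothing", "must be in (0, 1)")
  if (!is.null(snr_override)) {
    if (length(snr_override) != length(series$levels))
      abort_field("snr_override", "must match levels in length")
    series$snr <- as.numeric(snr_override)
  } else if (is.null(series$snr)) {
    series <- compute_snr(series)
  }
  w <- pmax(series$snr, 0)
  w[series$snr < snr_criterion] <- 0
  keep <- w > 0
  if (sum(keep) < 4)
    stop(sprintf("only %d levels carry nonzero weight; need at least 4",
                 sum(keep)), call. = FALSE)
  fit <- reinsch_fit(series$levels[keep], series$response[keep], w[keep],
                     smoothing)
  grid <- seq(min(series$levels), max(series$levels), by = 1)
  ev <- spline_eval(fit, grid)
  structure(
    list(grid = grid, fitted = ev$fitted, derivative = ev$derivative,
         smoothing = smoothing, weights_used = w,
         knots = fit$x, knot_values = fit$yhat,
         frequency = series$frequency, label = series$label,
         kind = series$kind),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(paste0("<growth_fit> %s at %s Hz: grid %g-%g dB SPL, ",
                     "p = %g, %d weighted levels\n"),
              x$kind, x$label, min(x$grid), max(x$grid), x$smoothing,
              sum(x$weights_used > 0)))
  invisible(x)
}

#' Median-derivative recruitment slope
#'
#' The recruitment metric: the median of the spline derivative over grid
#' levels at and above threshold.  A missing threshold propagates to a
#' missing slope; it never silently becomes a number.
#'
#' @param fit a [fit_growth_spline()] result.
#' @param threshold threshold in dB SPL (possibly `NA`).
#' @return an object of class `recruit_slope`: `frequency`, `label`,
#'   `threshold`, `median_slope` (response units per dB),
#'   `n_grid_points_used`.
#' @export
median_slope <- function(fit, threshold) {
  stopifnot(inherits(fit, "growth_fit"))
  if (is.na(threshold)) {
    sl <- NA_real_; nuse <- 0L
  } else {
    sel <- fit$grid >= threshold - 1e-9
    if (!any(sel)) {
      sl <- NA_real_; nuse <- 0L
    } else {
      sl <- median(fit$derivative[sel]); nuse <- sum(sel)
    }
  }
  structure(
    list(frequency = fit$frequency, label = fit$label,
         threshold = threshold, median_slope = sl,
         n_grid_points_used = as.integer(nuse)),
    class = "recruit_slope")
}

#' @export
print.recruit_slope <- function(x, ...) {
  cat(sprintf("<recruit_slope> %s Hz: threshold %s dB SPL, median slope %s (%d grid points)\n",
              x$label, format(x$threshold), format(x$median_slope),
              x$n_grid_points_used))
  invisible(x)
}

#' Linear regression of recruitment slope on threshold
#'
#' Ordinary least squares of `median_slope ~ threshold` across ears at one
#' frequency, with the two-sided t-test p-value for a nonzero slope
#' coefficient and its t-based 95% confidence interval.  Rows with a
#' missing threshold or slope are excluded (absence never becomes a
#' point); at least 3 complete pairs are required.
#'
#' @param points data frame with columns `threshold` and `median_slope`
#'   (or any two-column numeric data frame / matrix, x then y).
#' @param conf_level confidence level for the slope interval.
#' @return an object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `conf_int` (length 2), `n`.
#' @export
regress_slope_vs_threshold <- function(points, conf_level = 0.95) {
  if (is.matrix(points)) points <- as.data.frame(points)
  if (all(c("threshold", "median_slope") %in% names(points))) {
    x <- points$threshold; y <- points$median_slope
  } else {
    x <- points[[1]]; y <- points[[2]]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop(sprintf("need at least 3 complete points, got %d", n),
         call. = FALSE)
  if (max(x) - min(x) == 0)
    stop("degenerate regressor: all thresholds are equal", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, "x", level = conf_level)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
         conf_int = as.numeric(ci), conf_level = conf_level, n = n),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(paste0("<regression_result> y = %.4gx + %.4g, R^2 = %.4f, ",
                     "p = %.4g, %g%% CI [%.4g, %.4g], n = %d\n"),
              x$slope, x$intercept, x$r_squared, x$p_value,
              100 * x$conf_level, x$conf_int[1], x$conf_int[2], x$n))
  invisible(x)
}

#' Aggregate recruitment metrics across low frequencies
#'
#' Unweighted means of the median slopes and thresholds over frequencies
#' at or below the cutoff (default 1 kHz), for one ear.  The threshold
#' shift is referenced to a caller-supplied control-cohort low-frequency
#' mean threshold.
#'
#' @param per_freq data frame with columns `frequency`, `median_slope`,
#'   `threshold` (one row per frequency of one ear).
#' @param cutoff include frequencies `<= cutoff` Hz.  The default 1020
#'   admits the 1,020 Hz stimulus conventionally labelled 1 kHz.
#' @param control_reference control-cohort mean low-frequency threshold
#'   (dB SPL), or `NULL` to skip the shift.
#' @return list with `mean_slope`, `mean_threshold`, `threshold_shift`
#'   (`NA` without a reference), `n_frequencies`; all-`NA` input at the
#'   qualifying frequencies yields `NA` values (absence propagates).
#' @export
aggregate_low_freq <- function(per_freq, cutoff = 1020,
                               control_reference = NULL) {
  stopifnot(is.data.frame(per_freq))
  sel <- per_freq$frequency <= cutoff &
    is.finite(per_freq$median_slope) & is.finite(per_freq$threshold)
  if (!any(sel))
    return(list(mean_slope = NA_real_, mean_threshold = NA_real_,
                threshold_shift = NA_real_, n_frequencies = 0L))
  ms <- mean(per_freq$median_slope[sel])
  mt <- mean(per_freq$threshold[sel])
  list(mean_slope = ms, mean_threshold = mt,
       threshold_shift = if (is.null(control_reference)) NA_real_
                         else mt - control_reference,
       n_frequencies = sum(sel))
}
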