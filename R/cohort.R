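# Cohort-level simulation and summaries: many ears, several frequencies,
# the recruitment contrast between hydropic and control growth.

#' Simulate a cohort of ears and extract recruitment metrics
#'
#' Generates per-ear, per-frequency level series with
#' [gen_growth_series()] and runs the growth analysis on each: SNR,
#' run-of-2 threshold, smoothing-spline fit, median slope.  Hydropic ears
#' draw a low-frequency threshold shift from a truncated normal; because
#' the generator forces hydropic growth to converge to the control
#' amplitude at 80 dB SPL, larger shifts imply steeper growth -- the
#' recruitment coupling.  High frequencies receive no shift in either
#' group (hydrops spares the cochlear base), providing the negative
#' control.
#'
#' @param seed integer seed for the whole cohort.
#' @param n_hydropic,n_control ear counts.
#' @param low_freqs ANOW frequencies (Hz), shifted in hydropic ears.
#' @param high_freqs CAP frequencies (Hz), never shifted.
#' @param levels tested levels, dB SPL.
#' @param shift_mean,shift_sd,shift_range hydropic threshold-shift
#'   distribution (dB): normal, truncated to `shift_range`.
#' @param noise_sigma measurement noise scale (see
#'   [scenario_config()]).
#' @param smoothing,snr_criterion growth-analysis settings.
#' @return data frame with one row per ear x frequency: `ear`, `group`,
#'   `frequency`, `band`, `true_shift`, `threshold`, `median_slope`.
#' @export
simulate_cohort <- function(seed = NULL, n_hydropic = 18, n_control = 8,
                            low_freqs = c(300, 480, 720, 1020),
                            high_freqs = c(8000, 12000),
                            levels = seq(10, 80, by = 5),
                            shift_mean = 22, shift_sd = 10,
                            shift_range = c(2, 42), noise_sigma = 1,
                            smoothing = 0.005, snr_criterion = 6) {
  with_seed(seed, {
    groups <- c(rep("hydropic", n_hydropic), rep("control", n_control))
    rows <- list()
    for (e in seq_along(groups)) {
      hyd <- groups[e] == "hydropic"
      shift <- if (hyd)
        pmin(pmax(rnorm(1, shift_mean, shift_sd), shift_range[1]),
             shift_range[2])
      else 0
      conv_jit <- rnorm(1, 0, 1.5)   # ear-to-ear ceiling variability, dB
      thr_jit <- rnorm(1, 0, 1.5)    # ear-to-ear sensitivity variability
      for (f in c(low_freqs, high_freqs)) {
        band <- if (f <= max(low_freqs)) "low" else "high"
        if (band == "low") {
          scen <- if (hyd)
            scenario_hydropic(threshold_shift = shift,
                              converge_db = 20 + conv_jit,
                              base_threshold = 5 + thr_jit,
                              noise_sigma = noise_sigma)
          else
            scenario_control(converge_db = 20 + conv_jit,
                             base_threshold = 5 + thr_jit,
                             noise_sigma = noise_sigma)
          series <- gen_growth_series(scen, levels, frequency = f,
                                      kind = "anow_magnitude")
        } else {
          # base of the cochlea: no shift in either group
          scen <- scenario_control(cap_threshold = 10 + 2.5 * thr_jit,
                                   cap_max_p2p = 30 + 4 * conv_jit,
                                   noise_sigma = noise_sigma)
          series <- gen_growth_series(scen, levels, frequency = f,
                                      kind = "cap_p2p")
        }
        th <- estimate_threshold(series, criterion = snr_criterion)
        sl <- NA_real_
        fit <- tryCatch(fit_growth_spline(series, smoothing = smoothing,
                                          snr_criterion = snr_criterion),
                        error = function(e) NULL)
        if (!is.null(fit)) sl <- median_slope(fit, th)$median_slope
        rows[[length(rows) + 1L]] <-
          data.frame(ear = e, group = groups[e], frequency = f,
                     band = band, true_shift = shift, threshold = th,
                     median_slope = sl)
      }
    }
    do.call(rbind, rows)
  })
}

#' Cohort-level recruitment statistics
#'
#' Per-frequency slope-versus-threshold regressions across the selected
#' ears, plus the low-frequency aggregation: per-ear mean slope and mean
#' threshold over frequencies at or below the cutoff, threshold shifts
#' referenced to the control-ear mean, and the regression of aggregated
#' slope on aggregated shift.
#'
#' @param cohort data frame from [simulate_cohort()].
#' @param group ears entering the per-frequency regressions.
#' @param cutoff low-frequency cutoff, Hz.
#' @return list: `per_frequency` (named list of
#'   [regress_slope_vs_threshold()] results, `NULL` where degenerate),
#'   `low_freq` (per-ear aggregated data frame), `low_freq_regression`,
#'   `group_mean_slopes` (mean low-frequency median slope by group).
#' @export
cohort_statistics <- function(cohort, group = "hydropic", cutoff = 1020) {
  stopifnot(is.data.frame(cohort))
  per_frequency <- list()
  for (f in sort(unique(cohort$frequency))) {
    sub <- cohort[cohort$frequency == f & cohort$group %in% group, ]
    per_frequency[[format(f)]] <- tryCatch(
      regress_slope_vs_threshold(sub[, c("threshold", "median_slope")]),
      error = function(e) NULL)
  }
  ctrl <- cohort[cohort$group == "control" & cohort$frequency <= cutoff, ]
  ctrl_ref <- mean(ctrl$threshold, na.rm = TRUE)
  ears <- unique(cohort$ear)
  agg <- do.call(rbind, lapply(ears, function(e) {
    sub <- cohort[cohort$ear == e, ]
    a <- aggregate_low_freq(sub, cutoff = cutoff,
                            control_reference = ctrl_ref)
    data.frame(ear = e, group = sub$group[1], mean_slope = a$mean_slope,
               mean_threshold = a$mean_threshold,
               threshold_shift = a$threshold_shift)
  }))
  lf_reg <- tryCatch(
    regress_slope_vs_threshold(
      data.frame(threshold = agg$threshold_shift,
                 median_slope = agg$mean_slope)),
    error = function(e) NULL)
  gm <- tapply(cohort$median_slope[cohort$frequency <= cutoff],
               cohort$group[cohort$frequency <= cutoff],
               mean, na.rm = TRUE)
  list(per_frequency = per_frequency, low_freq = agg,
       low_freq_regression = lf_reg,
       group_mean_slopes = as.list(gm))
}
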