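# Synthetic round-window electrophysiology.  The generator is the study
# bench for the analysis chain: it produces epoch matrices containing a
# polarity-following cochlear microphonic, a polarity-invariant neural
# component at twice the stimulus frequency, Gaussian background noise and
# sparse high-amplitude transients, plus cohort-level growth scenarios with
# compressive (control) versus linearized, threshold-shifted (hydropic)
# shapes.

#' Scenario configuration for the synthetic generator
#'
#' Bundles the physiological "truth" used to synthesize recordings: the
#' cochlear microphonic amplitude, the level-dependent neural and CAP
#' amplitude functions, noise and artifact statistics, and the seed making
#' generation bit-reproducible.
#'
#' @param cm_amplitude cochlear microphonic amplitude at the stimulus
#'   frequency, uV.
#' @param neural_amplitude_fn function mapping level (dB SPL) to the neural
#'   component amplitude (uV) at twice the stimulus frequency; must be
#'   non-negative, zero below threshold.
#' @param cap_n1_amplitude_fn function mapping level to N1 amplitude (uV,
#'   returned positive; the lobe is negative-going).
#' @param cap_n1_latency_fn function mapping level to N1 latency (ms after
#'   onset), monotone non-increasing.
#' @param noise_sigma Gaussian background noise SD.  Interpreted at the
#'   generator's granularity: per-sample uV for epoch synthesis
#'   ([gen_anow_epochs()], [gen_cap_epochs()]) and per-pair complex
#'   coefficient SD per axis for series synthesis ([gen_growth_series()]).
#' @param artifact_rate fraction of samples displaced by transients,
#'   in `[0, 0.2)`.
#' @param artifact_scale transient size as a multiple of `noise_sigma`.
#' @param threshold_shift nominal threshold elevation (dB) this scenario
#'   encodes; informational, consumed by cohort summaries.
#' @param seed integer seed; identical configurations generate bit-identical
#'   output.  `NULL` draws from the current RNG stream.
#' @param neural_phase phase (radians) of the neural second-harmonic
#'   component at stimulus onset.
#' @param neural_mode `"sinusoid"` (pure component at 2f, the minimal
#'   faithful forward model since the analysis consumes only the second
#'   harmonic) or `"rectified"` (half-wave rectified stimulus-frequency
#'   drive, whose 2f Fourier component is scaled to the requested
#'   amplitude, for realism checks).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(cm_amplitude = 10,
                            neural_amplitude_fn = function(level) 0 * level,
                            cap_n1_amplitude_fn = function(level) 0 * level,
                            cap_n1_latency_fn = function(level)
                              pmax(4.5 - 0.025 * (level - 10), 2),
                            noise_sigma = 1,
                            artifact_rate = 0, artifact_scale = 50,
                            threshold_shift = 0, seed = NULL,
                            neural_phase = 0,
                            neural_mode = c("sinusoid", "rectified")) {
  check_scalar(cm_amplitude, "cm_amplitude", nonneg = TRUE)
  check_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_scalar(artifact_rate, "artifact_rate", nonneg = TRUE)
  if (artifact_rate >= 0.2)
    abort_field("artifact_rate", "must be < 0.2")
  check_scalar(artifact_scale, "artifact_scale", nonneg = TRUE)
  check_scalar(threshold_shift, "threshold_shift")
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  probe <- seq(0, 100, by = 5)
  for (fn_name in c("neural_amplitude_fn", "cap_n1_amplitude_fn")) {
    fn <- get(fn_name)
    if (!is.function(fn)) abort_field(fn_name, "must be a function")
    v <- vapply(probe, fn, numeric(1))
    if (any(!is.finite(v)) || any(v < 0))
      abort_field(fn_name, "must be finite and non-negative over 0-100 dB SPL")
  }
  if (!is.function(cap_n1_latency_fn))
    abort_field("cap_n1_latency_fn", "must be a function")
  lat <- vapply(probe, cap_n1_latency_fn, numeric(1))
  if (any(diff(lat) > 1e-9))
    abort_field("cap_n1_latency_fn", "must be monotone non-increasing in level")
  structure(
    list(cm_amplitude = cm_amplitude,
         neural_amplitude_fn = neural_amplitude_fn,
         cap_n1_amplitude_fn = cap_n1_amplitude_fn,
         cap_n1_latency_fn = cap_n1_latency_fn,
         noise_sigma = noise_sigma, artifact_rate = artifact_rate,
         artifact_scale = artifact_scale, threshold_shift = threshold_shift,
         seed = seed, neural_phase = neural_phase,
         neural_mode = match.arg(neural_mode)),
    class = "scenario_config")
}

# shared piecewise growth template: amplitude (uV) of the 2f neural
# component versus level, expressed in dB re 1 uV internally
control_growth_db <- function(level, converge_db = 20, compressive_slope = 1 / 3,
                              knee = 20, base_threshold = 5, low_slope = 1.5) {
  knee_db <- converge_db - compressive_slope * (80 - knee)
  ifelse(level < base_threshold, -Inf,
         ifelse(level < knee, knee_db - low_slope * (knee - level),
                converge_db - compressive_slope * (80 - level)))
}

#' Canonical cohort scenarios
#'
#' `scenario_control()` encodes compressive control-ear growth: the neural
#' component grows steeply just above threshold, then compressively
#' (default 0.33 dB/dB) above a 20 dB SPL knee, reaching `converge_db`
#' (dB re 1 uV amplitude) at 80 dB SPL.  `scenario_hydropic()` encodes the
#' linearized, threshold-shifted growth of a hydropic ear: the response
#' appears at `base_threshold + threshold_shift` and grows linearly so as
#' to converge to the control amplitude at 80 dB SPL; the growth slope is
#' therefore coupled to the threshold shift (larger shifts force steeper
#' growth), which is the generative structure behind recruitment.
#'
#' @param threshold_shift threshold elevation in dB (hydropic scenario).
#' @param converge_db common amplitude (dB re 1 uV) reached at 80 dB SPL.
#' @param base_threshold control-ear nominal threshold, dB SPL.
#' @param compressive_slope control growth slope (dB/dB) above the knee.
#' @param at_threshold_db response amplitude (dB re 1 uV) right at the
#'   hydropic threshold, anchoring the linearized segment.
#' @param cap_max_p2p,cap_threshold CAP peak-to-peak ceiling (uV) and
#'   threshold (dB SPL) for the CAP amplitude function.
#' @param ... passed to [scenario_config()] (e.g. `noise_sigma`, `seed`,
#'   `artifact_rate`).
#' @return a `scenario_config`.
#' @export
scenario_control <- function(converge_db = 20, base_threshold = 5,
                             compressive_slope = 1 / 3,
                             cap_max_p2p = 30, cap_threshold = 10, ...) {
  scenario_config(
    neural_amplitude_fn = function(level) {
      db <- control_growth_db(level, converge_db = converge_db,
                              compressive_slope = compressive_slope,
                              base_threshold = base_threshold)
      ifelse(is.finite(db), db_amplitude(db), 0)
    },
    cap_n1_amplitude_fn = cap_amplitude_template(cap_max_p2p, cap_threshold),
    threshold_shift = 0, ...)
}

#' @rdname scenario_control
#' @export
scenario_hydropic <- function(threshold_shift = 20, converge_db = 20,
                              base_threshold = 5, at_threshold_db = -10,
                              cap_max_p2p = 30, cap_threshold = 10, ...) {
  check_scalar(threshold_shift, "threshold_shift", nonneg = TRUE)
  thr <- base_threshold + threshold_shift
  if (thr >= 80) abort_field("threshold_shift", "threshold must stay below 80 dB SPL")
  slope <- (converge_db - at_threshold_db) / (80 - thr)
  scenario_config(
    neural_amplitude_fn = function(level)
      ifelse(level < thr, 0,
             db_amplitude(converge_db - slope * (80 - level))),
    cap_n1_amplitude_fn = cap_amplitude_template(cap_max_p2p,
                                                 cap_threshold + threshold_shift),
    threshold_shift = threshold_shift, ...)
}

# saturating CAP N1 amplitude (uV, positive) with a hard threshold; the
# dynamic span is fixed (70 dB) so threshold jitter translates the curve
# horizontally without changing its growth slope
cap_amplitude_template <- function(max_p2p = 30, threshold = 10,
                                   exponent = 0.7) {
  n1_max <- max_p2p / 1.8  # p2p = 1.8 * N1 with the default lobe shapes
  function(level)
    ifelse(level <= threshold, 0,
           n1_max * pmin((level - threshold) / 70, 1.1)^exponent)
}

#' Generate alternating-polarity low-frequency tone-burst epochs
#'
#' Each epoch is the sum of (i) a cochlear microphonic that follows the
#' stimulus and inverts with polarity, (ii) a polarity-invariant neural
#' component at twice the stimulus frequency, phase-locked to stimulus
#' onset and gated by the stimulus envelope, (iii) i.i.d. Gaussian noise,
#' and (iv) optional injected transient artifacts.
#'
#' @param spec a [tone_burst_spec()].
#' @param scenario a [scenario_config()].
#' @param pre_ms,post_ms silence padding before/after the burst, ms.
#' @return an `epoch_matrix`; if artifacts were injected the ground-truth
#'   locations are attached as the `artifact_truth` element (a data frame
#'   of 1-based `epoch`/`sample` indices).
#' @export
gen_anow_epochs <- function(spec, scenario, pre_ms = 8, post_ms = 8) {
  stopifnot(inherits(spec, "tone_burst_spec"),
            inherits(scenario, "scenario_config"))
  fs <- spec$sample_rate
  n_pre <- ms_to_samples(pre_ms, fs)
  n_burst <- ms_to_samples(spec$duration_ms, fs)
  n_post <- ms_to_samples(post_ms, fs)
  ns <- n_pre + n_burst + n_post
  n_ramp <- ms_to_samples(spec$rise_fall_ms, fs)
  env <- raised_cosine_envelope(n_burst, n_ramp)
  tt <- (seq_len(n_burst) - 1) / fs
  cm_wave <- scenario$cm_amplitude * env * sin(2 * pi * spec$frequency * tt)
  amp2f <- scenario$neural_amplitude_fn(spec$level)
  neural_wave <- if (scenario$neural_mode == "sinusoid") {
    amp2f * env * sin(2 * pi * 2 * spec$frequency * tt + scenario$neural_phase)
  } else {
    # half-wave rectified drive; its 2f Fourier amplitude is 2/(3*pi) of
    # the rectified peak, so rescale to deliver `amp2f` at 2f exactly
    hw <- pmax(sin(2 * pi * spec$frequency * tt + scenario$neural_phase / 2), 0)
    amp2f / (2 / (3 * pi)) * env * (hw - 1 / pi)
  }
  pol <- spec$polarity_start * rep_len(c(1L, -1L), spec$n_repetitions)
  burst_idx <- n_pre + seq_len(n_burst)
  with_seed(scenario$seed, {
    data <- matrix(rnorm(spec$n_repetitions * ns, 0, scenario$noise_sigma),
                   nrow = spec$n_repetitions)
    data[, burst_idx] <- data[, burst_idx] +
      outer(pol, cm_wave) + rep(neural_wave, each = spec$n_repetitions)
    em <- epoch_matrix(data, fs, pol, onset_sample = n_pre, stimulus = spec)
    maybe_inject(em, scenario)
  })
}

#' Generate alternating-polarity CAP tone-burst epochs
#'
#' Each epoch holds a stereotyped compound action potential: a
#' negative-going N1 lobe of amplitude `cap_n1_amplitude_fn(level)` at
#' latency `cap_n1_latency_fn(level)` followed by a positive P1 lobe, plus
#' a polarity-following microphonic during the burst, Gaussian noise, and
#' optional artifacts.  A silence interval is appended after the burst to
#' mirror the interleaved stimulation design; its length is a free
#' parameter (`silence_ms`).
#'
#' @inheritParams gen_anow_epochs
#' @param silence_ms appended silence after the burst, ms.
#' @param n1_width_ms,p1_offset_ms,p1_width_ms,p1_ratio Gaussian lobe
#'   geometry: N1 SD, P1 lag after N1, P1 SD, and P1/N1 amplitude ratio.
#' @return an `epoch_matrix` (see [gen_anow_epochs()] for artifact
#'   bookkeeping).
#' @export
gen_cap_epochs <- function(spec, scenario, pre_ms = 2, silence_ms = 13.9,
                           n1_width_ms = 0.25, p1_offset_ms = 1.5,
                           p1_width_ms = 0.4, p1_ratio = 0.8) {
  stopifnot(inherits(spec, "tone_burst_spec"),
            inherits(scenario, "scenario_config"))
  fs <- spec$sample_rate
  n_pre <- ms_to_samples(pre_ms, fs)
  n_burst <- ms_to_samples(spec$duration_ms, fs)
  ns <- n_pre + n_burst + ms_to_samples(silence_ms, fs)
  t_ms <- ((seq_len(ns) - 1) - n_pre) / fs * 1000
  amp <- scenario$cap_n1_amplitude_fn(spec$level)
  lat <- scenario$cap_n1_latency_fn(spec$level)
  cap_wave <- -amp * exp(-(t_ms - lat)^2 / (2 * n1_width_ms^2)) +
    p1_ratio * amp * exp(-(t_ms - lat - p1_offset_ms)^2 / (2 * p1_width_ms^2))
  env <- raised_cosine_envelope(n_burst, ms_to_samples(spec$rise_fall_ms, fs))
  tt <- (seq_len(n_burst) - 1) / fs
  cm_wave <- scenario$cm_amplitude * env * sin(2 * pi * spec$frequency * tt)
  pol <- spec$polarity_start * rep_len(c(1L, -1L), spec$n_repetitions)
  burst_idx <- n_pre + seq_len(n_burst)
  with_seed(scenario$seed, {
    data <- matrix(rnorm(spec$n_repetitions * ns, 0, scenario$noise_sigma),
                   nrow = spec$n_repetitions)
    data <- data + rep(cap_wave, each = spec$n_repetitions)
    data[, burst_idx] <- data[, burst_idx] + outer(pol, cm_wave)
    em <- epoch_matrix(data, fs, pol, onset_sample = n_pre, stimulus = spec)
    maybe_inject(em, scenario)
  })
}

maybe_inject <- function(em, scenario) {
  if (scenario$artifact_rate <= 0) return(em)
  inj <- displace_samples(em, scenario$artifact_rate, scenario$artifact_scale,
                          scenario$noise_sigma)
  em <- inj$epochs
  em$artifact_truth <- inj$locations
  em
}

# core displacement routine; uses the current RNG stream
displace_samples <- function(epochs, rate, scale, sigma) {
  n_total <- length(epochs$data)
  k <- floor(rate * n_total)
  if (k == 0)
    return(list(epochs = epochs,
                locations = data.frame(epoch = integer(0), sample = integer(0))))
  idx <- sample.int(n_total, k)
  signs <- sample(c(-1, 1), k, replace = TRUE)
  epochs$data[idx] <- epochs$data[idx] + signs * scale * sigma
  nr <- nrow(epochs$data)
  loc <- data.frame(epoch = ((idx - 1L) %% nr) + 1L,
                    sample = ((idx - 1L) %/% nr) + 1L)
  loc <- loc[order(loc$epoch, loc$sample), , drop = FALSE]
  rownames(loc) <- NULL
  list(epochs = epochs, locations = loc)
}

#' Inject transient artifacts into an epoch matrix
#'
#' Displaces uniformly random samples by `+/- scale * sigma` and returns
#' the ground-truth locations, for validating the quartile detector.
#'
#' @param epochs an [epoch_matrix()].
#' @param rate fraction of samples to displace, in `[0, 0.2)`.
#' @param scale displacement as a multiple of `sigma`.
#' @param seed integer seed (or `NULL` for the current stream).
#' @param sigma noise scale in uV that `scale` multiplies.
#' @return list with elements `epochs` (displaced copy) and `locations`
#'   (data frame of 1-based `epoch`, `sample` indices, sorted).
#' @export
inject_artifacts <- function(epochs, rate, scale, seed = NULL, sigma = 1) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  check_scalar(rate, "rate", nonneg = TRUE)
  if (rate >= 0.2) abort_field("rate", "must be < 0.2")
  check_scalar(scale, "scale", nonneg = TRUE)
  check_scalar(sigma, "sigma", nonneg = TRUE)
  with_seed(seed, displace_samples(epochs, rate, scale, sigma))
}

#' Generate a per-level response series for one frequency of one ear
#'
#' Simulates what the epoch pipeline would deliver, at the level-series
#' granularity: for the ANOW kind, `n_pairs` per-pair complex second
#' harmonic coefficients are drawn around the scenario's true amplitude
#' (per-axis SD `noise_sigma`) and aggregated exactly as
#' [aggregate_response()] aggregates measured coefficients, so magnitudes,
#' SEM noise floors and their repetition-count scaling are inherited rather
#' than re-modelled.  For the CAP kind the peak-to-peak amplitude is the
#' scenario truth plus Gaussian measurement error with SEM set by
#' `noise_sigma` and the repetition count.
#'
#' @param scenario a [scenario_config()].
#' @param levels ascending stimulus levels, dB SPL.
#' @param frequency actual stimulus frequency, Hz.
#' @param kind `"anow_magnitude"` (response in dB re 1 uV RMS) or
#'   `"cap_p2p"` (response in uV).
#' @param n_pairs number of overlapped pairs backing each ANOW point.
#' @param n_repetitions CAP repetition count backing each CAP point.
#' @param label display label for the frequency (defaults to the actual
#'   frequency).
#' @return a [level_series()] with SNR computed.
#' @export
gen_growth_series <- function(scenario, levels, frequency = 480,
                              kind = c("anow_magnitude", "cap_p2p"),
                              n_pairs = 46, n_repetitions = 128,
                              label = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  kind <- match.arg(kind)
  if (is.unsorted(levels, strictly = TRUE))
    abort_field("levels", "must be strictly ascending")
  with_seed(scenario$seed, {
    if (kind == "anow_magnitude") {
      resp <- floor_db <- numeric(length(levels))
      for (i in seq_along(levels)) {
        a <- scenario$neural_amplitude_fn(levels[i])
        coeffs <- complex(real = a + rnorm(n_pairs, 0, scenario$noise_sigma),
                          imaginary = rnorm(n_pairs, 0, scenario$noise_sigma))
        agg <- aggregate_response(coeffs, analysis_frequency = 2 * frequency)
        resp[i] <- agg$magnitude_db
        floor_db[i] <- agg$noise_floor_db
      }
      series <- level_series(frequency, levels, resp, noise_floor = floor_db,
                             kind = kind, label = label)
    } else {
      sem <- scenario$noise_sigma / sqrt(n_repetitions)
      truth <- 1.8 * scenario$cap_n1_amplitude_fn(levels)
      meas <- abs(truth + rnorm(length(levels), 0, 2 * sem))
      series <- level_series(frequency, levels, meas,
                             noise_floor = rep(2 * sem, length(levels)),
                             kind = kind, label = label)
    }
    compute_snr(series)
  })
}
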