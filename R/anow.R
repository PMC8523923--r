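# Auditory nerve overlapped waveform (ANOW): averaging alternating-polarity
# responses cancels the cochlear microphonic and overlaps phase-locked
# neural firing; the second harmonic of the overlapped response is then
# estimated by a weighted least-squares sinusoid fit, pair by pair, and
# aggregated with a standard-error noise floor.

#' Overlap alternating-polarity epoch pairs
#'
#' Waveform `i` is the mean of epochs `2i-1` and `2i`; any
#' polarity-following component (the cochlear microphonic) cancels exactly,
#' while polarity-invariant components (neural firing) remain.  Pair
#' weights are the logical AND of the member epochs' artifact weights.
#'
#' @param epochs an [epoch_matrix()] with strictly alternating polarity and
#'   an even epoch count.
#' @param weights optional 0/1 matrix shaped like `epochs$data` (from
#'   [detect_artifacts_quartile()]); defaults to all ones.
#' @return an object of class `overlapped_set`: `waveforms`
#'   (pairs x samples), `weights` (pairs x samples), `frequency`,
#'   `sample_rate`, `onset_sample`, `invalid_edge`, `stimulus`.
#' @export
overlap_pairs <- function(epochs, weights = NULL) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  n <- nrow(epochs$data)
  if (n %% 2 != 0)
    stop("epoch count must be even to form polarity pairs", call. = FALSE)
  if (any(diff(epochs$polarity) == 0))
    stop("epoch polarity must strictly alternate", call. = FALSE)
  if (is.null(weights)) {
    weights <- matrix(1, n, ncol(epochs$data))
  } else if (!identical(dim(weights), dim(epochs$data))) {
    stop("weights must be shaped like the epoch data", call. = FALSE)
  }
  odd <- seq(1, n, by = 2)
  even <- odd + 1
  structure(
    list(waveforms = (epochs$data[odd, , drop = FALSE] +
                        epochs$data[even, , drop = FALSE]) / 2,
         weights = weights[odd, , drop = FALSE] *
           weights[even, , drop = FALSE],
         frequency = if (!is.null(epochs$stimulus)) epochs$stimulus$frequency
                     else NA_real_,
         sample_rate = epochs$sample_rate,
         onset_sample = epochs$onset_sample,
         invalid_edge = epochs$invalid_edge,
         stimulus = epochs$stimulus),
    class = "overlapped_set")
}

#' @export
print.overlapped_set <- function(x, ...) {
  cat(sprintf("<overlapped_set> %d pair waveforms x %d samples @ %g Hz (f = %g Hz)\n",
              nrow(x$waveforms), ncol(x$waveforms), x$sample_rate,
              x$frequency))
  invisible(x)
}

# weighted LSQ fit of a single sinusoid at frequency `f_fit`:
# y(t) ~ a*cos(2*pi*f_fit*t) + b*(-sin(2*pi*f_fit*t)), time origin at the
# stimulus onset sample.  Returns complex(a, b).
sinusoid_fit <- function(waveform, f_fit, sample_rate, weights = NULL,
                         onset_sample = 0, min_cycles = 10) {
  if (is.null(weights)) weights <- rep(1, length(waveform))
  if (length(weights) != length(waveform))
    stop("weights must match the waveform length", call. = FALSE)
  eff_dur <- sum(weights > 0) / sample_rate
  if (eff_dur < min_cycles / f_fit)
    stop(sprintf(paste0("insufficient weighted support: effective duration ",
                        "%.4f ms < %g cycles of %g Hz (%.4f ms)"),
                 eff_dur * 1e3, min_cycles, f_fit,
                 min_cycles / f_fit * 1e3), call. = FALSE)
  t <- (seq_along(waveform) - 1 - onset_sample) / sample_rate
  x1 <- cos(2 * pi * f_fit * t)
  x2 <- -sin(2 * pi * f_fit * t)
  s11 <- sum(weights * x1 * x1)
  s12 <- sum(weights * x1 * x2)
  s22 <- sum(weights * x2 * x2)
  b1 <- sum(weights * x1 * waveform)
  b2 <- sum(weights * x2 * waveform)
  det <- s11 * s22 - s12 * s12
  a <- (s22 * b1 - s12 * b2) / det
  b <- (s11 * b2 - s12 * b1) / det
  complex(real = a, imaginary = b)
}

#' Weighted least-squares second-harmonic coefficient
#'
#' Fits `y(t) ~ a*cos(2*pi*2f*t) + b*(-sin(2*pi*2f*t))` by weighted least
#' squares with 0/1 sample weights, the time origin at the stimulus onset.
#' Zero-weighted samples simply drop out of the fit, which removes short,
#' infrequent artifacts without cutting the waveform and without spectral
#' splatter from edge discontinuities.  With uniform weights and an
#' integer number of cycles the result equals the scaled DFT bin.
#'
#' @param waveform numeric vector, one overlapped waveform (uV).
#' @param f stimulus frequency, Hz; the fit is at `2 * f`.
#' @param sample_rate sampling rate, Hz.
#' @param weights per-sample weights (0/1); `NULL` for all ones.
#' @param onset_sample 0-based stimulus onset index (time origin).
#' @param min_cycles minimum cycles of `2f` that must carry nonzero weight.
#' @return complex coefficient `a + bi` (uV).
#' @export
fit_second_harmonic <- function(waveform, f, sample_rate, weights = NULL,
                                onset_sample = 0, min_cycles = 10) {
  check_scalar(f, "f", positive = TRUE)
  sinusoid_fit(waveform, 2 * f, sample_rate, weights, onset_sample,
               min_cycles)
}

#' Aggregate per-pair coefficients into a response with a noise floor
#'
#' The complex mean of the stored coefficients is the signal; the noise
#' floor is the standard error of that mean, computed per axis and
#' combined as `sqrt(SEM_re^2 + SEM_im^2)` (SEM-of-magnitudes conventions
#' are biased at low SNR).  Magnitude is `sqrt(re^2 + im^2)`, phase the
#' four-quadrant arctangent.  dB conversion uses the RMS magnitude
#' (`magnitude/sqrt(2)`) when `rms = TRUE` (electrode responses re 1 uV)
#' and the amplitude itself otherwise (microphone components re 20 uPa).
#'
#' @param coeffs complex vector of per-pair (or per-frame) coefficients,
#'   length >= 2.
#' @param ref dB reference amplitude (1 for uV, 20e-6 for Pa).
#' @param rms convert to dB via the RMS magnitude?
#' @param min_floor_db clamp for the dB noise floor when the SEM underflows
#'   (identical coefficients).
#' @param analysis_frequency frequency the coefficients were fitted at, Hz.
#' @return an object of class `complex_response` with elements `real`,
#'   `imag`, `magnitude`, `phase`, `magnitude_db`, `noise_floor`,
#'   `noise_floor_db`, `snr_db`, `n_contributing`, `analysis_frequency`.
#' @export
aggregate_response <- function(coeffs, ref = 1, rms = TRUE,
                               min_floor_db = -40,
                               analysis_frequency = NA_real_) {
  if (length(coeffs) < 2)
    stop("need at least 2 coefficients (SEM undefined otherwise)",
         call. = FALSE)
  coeffs <- as.complex(coeffs)
  m <- mean(coeffs)
  n <- length(coeffs)
  sem_re <- sd(Re(coeffs)) / sqrt(n)
  sem_im <- sd(Im(coeffs)) / sqrt(n)
  floor_uv <- sqrt(sem_re^2 + sem_im^2)
  scale <- if (rms) sqrt(2) else 1
  mag <- Mod(m)
  structure(
    list(real = Re(m), imag = Im(m), magnitude = mag,
         phase = atan2(Im(m), Re(m)),
         magnitude_db = 20 * log10((mag / scale) / ref),
         noise_floor = floor_uv,
         noise_floor_db = max(20 * log10((floor_uv / scale) / ref),
                              min_floor_db),
         snr_db = 20 * log10(mag / floor_uv),
         n_contributing = n, analysis_frequency = analysis_frequency),
    class = "complex_response")
}

#' @export
print.complex_response <- function(x, ...) {
  cat(sprintf(paste0("<complex_response> |%.4g| dB (%.4g amp), phase %.3f rad, ",
                     "floor %.4g dB, n = %d, f = %g Hz\n"),
              x$magnitude_db, x$magnitude, x$phase, x$noise_floor_db,
              x$n_contributing, x$analysis_frequency))
  invisible(x)
}

#' Full ANOW extraction from an epoch matrix
#'
#' Chains the canonical pipeline: optional FIR band-limiting with
#' group-delay correction, quartile artifact detection, polarity-pair
#' overlap, per-pair weighted second-harmonic fits restricted to the
#' steady-state analysis window (stimulus ramps and filter-invalid edges
#' excluded), and SEM aggregation.
#'
#' @param epochs an [epoch_matrix()] with tone-burst stimulus metadata.
#' @param kernel optional `fir_kernel` (e.g. the 600-1600 Hz band); `NULL`
#'   skips filtering, appropriate when the noise background is already
#'   band-limited or white.
#' @param fence quartile fence for artifact detection; `NA` disables
#'   masking (all weights 1), giving the unmasked estimator.
#' @param window optional `c(start, end)` analysis window in seconds re
#'   onset; default is the steady-state portion of the burst.
#' @param min_floor_db,min_cycles passed through.
#' @return a `complex_response` at twice the stimulus frequency.
#' @export
anow_response <- function(epochs, kernel = NULL, fence = 3, window = NULL,
                          min_floor_db = -40, min_cycles = 10) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (is.null(epochs$stimulus))
    stop("epochs carry no stimulus metadata", call. = FALSE)
  if (!is.null(kernel)) epochs <- filter_epochs(epochs, kernel)
  weights <- if (is.na(fence)) NULL else
    detect_artifacts_quartile(epochs, fence)$weights
  ov <- overlap_pairs(epochs, weights)
  fs <- ov$sample_rate
  if (is.null(window)) {
    ramp <- epochs$stimulus$rise_fall_ms / 1e3
    window <- c(ramp, epochs$stimulus$duration_ms / 1e3 - ramp)
  }
  t <- (seq_len(ncol(ov$waveforms)) - 1 - ov$onset_sample) / fs
  in_window <- t >= window[1] & t <= window[2]
  if (ov$invalid_edge > 0) {
    ok <- seq_len(ncol(ov$waveforms)) > ov$invalid_edge &
      seq_len(ncol(ov$waveforms)) <= ncol(ov$waveforms) - ov$invalid_edge
    in_window <- in_window & ok
  }
  # vectorized per-pair weighted 2x2 normal equations (same math as
  # fit_second_harmonic, solved for all pairs at once)
  W <- sweep(ov$weights, 2, as.numeric(in_window), `*`)
  eff_dur <- rowSums(W > 0) / fs
  f2 <- 2 * ov$frequency
  short <- eff_dur < min_cycles / f2
  if (any(short))
    stop(sprintf(paste0("insufficient weighted support in pair %d: ",
                        "effective duration %.4f ms < %g cycles of %g Hz"),
                 which(short)[1], min(eff_dur) * 1e3, min_cycles, f2),
         call. = FALSE)
  x1 <- cos(2 * pi * f2 * t)
  x2 <- -sin(2 * pi * f2 * t)
  s11 <- W %*% (x1 * x1)
  s12 <- W %*% (x1 * x2)
  s22 <- W %*% (x2 * x2)
  WY <- W * ov$waveforms
  b1 <- WY %*% x1
  b2 <- WY %*% x2
  det <- s11 * s22 - s12 * s12
  coeffs <- complex(real = (s22 * b1 - s12 * b2) / det,
                    imaginary = (s11 * b2 - s12 * b1) / det)
  aggregate_response(coeffs, min_floor_db = min_floor_db,
                     analysis_frequency = f2)
}
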