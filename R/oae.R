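# Otoacoustic emission extraction: the double-evoked residual isolates the
# emission from the stimulus and system distortion; single-frequency
# components are estimated per frame with the same least-squares sinusoid
# estimator as the overlapped-waveform analysis and aggregated with SEM
# noise floors in dB SPL.

#' Microphone frame set
#'
#' @param data numeric matrix, repetitions x samples, pressure in Pa.
#' @param sample_rate sampling rate, Hz.
#' @param stimulus named list of stimulus descriptors; for DPOAE supply
#'   `f1`, `f2` (Hz) and optionally `l1`, `l2` (dB SPL); for SFOAE supply
#'   `f_probe`, `f_suppressor`, levels.
#' @return an object of class `oae_frame_set`.
#' @export
oae_frame_set <- function(data, sample_rate, stimulus = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    abort_field("data", "must be a numeric matrix (repetitions x samples)")
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  structure(list(data = data, sample_rate = sample_rate,
                 stimulus = stimulus),
            class = "oae_frame_set")
}

#' @export
print.oae_frame_set <- function(x, ...) {
  cat(sprintf("<oae_frame_set> %d frames x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sample_rate))
  invisible(x)
}

#' Double-evoked residual
#'
#' For probe-alone, suppressor-alone and both-together frame sets, the
#' residual is `probe + suppressor - both`, computed per repetition so the
#' repetition scatter (and hence the SEM noise floor) is retained.  Any
#' system that responds linearly in its stimuli cancels identically; what
#' survives is the nonlinear (emission) component suppressed by the second
#' tone.
#'
#' @param frames_probe,frames_suppressor,frames_both [oae_frame_set()]s
#'   with identical shapes and rates.
#' @return an `oae_frame_set` of per-repetition residual frames.
#' @export
double_evoked_residual <- function(frames_probe, frames_suppressor,
                                   frames_both) {
  for (f in list(frames_probe, frames_suppressor, frames_both))
    stopifnot(inherits(f, "oae_frame_set"))
  if (!identical(dim(frames_probe$data), dim(frames_suppressor$data)) ||
      !identical(dim(frames_probe$data), dim(frames_both$data)))
    stop("frame sets must have identical repetitions x samples shapes",
         call. = FALSE)
  if (!isTRUE(all.equal(frames_probe$sample_rate,
                        frames_suppressor$sample_rate)) ||
      !isTRUE(all.equal(frames_probe$sample_rate, frames_both$sample_rate)))
    stop("frame sets must share one sample rate", call. = FALSE)
  oae_frame_set(frames_probe$data + frames_suppressor$data -
                  frames_both$data,
                frames_probe$sample_rate,
                stimulus = frames_probe$stimulus)
}

#' Extract a single-frequency component with an SEM noise floor
#'
#' Fits `a*cos + b*(-sin)` at `f` to every frame (uniform weights, same
#' estimator as [fit_second_harmonic()]), then takes the complex mean as
#' the component and the standard error of the mean as the noise floor,
#' both converted to dB SPL re 20 uPa.
#'
#' @param frames an [oae_frame_set()] with at least 2 frames.
#' @param f analysis frequency, Hz; at least `min_cycles` cycles must fit
#'   in the analysed window.
#' @param discard_ms rise/fall portion discarded at each frame end before
#'   fitting (steady-state analysis), ms.
#' @param min_cycles minimum number of cycles of `f` in the window.
#' @param calibration optional function mapping frequency (Hz) to a
#'   multiplicative probe-microphone correction applied to the component.
#' @return a `complex_response` in Pa with dB fields re 20 uPa (component
#'   amplitude convention).
#' @export
extract_tone_component <- function(frames, f, discard_ms = 0,
                                   min_cycles = 2, calibration = NULL) {
  stopifnot(inherits(frames, "oae_frame_set"))
  check_scalar(f, "f", positive = TRUE)
  if (nrow(frames$data) < 2)
    stop("need at least 2 frames (SEM undefined otherwise)", call. = FALSE)
  fs <- frames$sample_rate
  ns <- ncol(frames$data)
  drop_n <- ms_to_samples(discard_ms, fs)
  sel <- seq_len(ns) > drop_n & seq_len(ns) <= ns - drop_n
  if (sum(sel) / fs < min_cycles / f)
    stop(sprintf("frequency %g Hz not resolvable in %.1f ms of frame",
                 f, sum(sel) / fs * 1e3), call. = FALSE)
  coeffs <- vapply(seq_len(nrow(frames$data)), function(i)
    sinusoid_fit(frames$data[i, sel], f, fs, onset_sample = 0,
                 min_cycles = min_cycles),
    complex(1))
  if (!is.null(calibration)) coeffs <- coeffs * calibration(f)
  aggregate_response(coeffs, ref = 20e-6, rms = FALSE, min_floor_db = -Inf,
                     analysis_frequency = f)
}

#' Distortion-product component at 2f1 - f2
#'
#' Reads `f1`/`f2` from the frame set's stimulus descriptors and delegates
#' to [extract_tone_component()] at `2*f1 - f2`.
#'
#' @inheritParams extract_tone_component
#' @return a `complex_response` at `2*f1 - f2`.
#' @export
dpoae_level <- function(frames, discard_ms = 0, calibration = NULL) {
  stopifnot(inherits(frames, "oae_frame_set"))
  f1 <- frames$stimulus$f1
  f2 <- frames$stimulus$f2
  if (is.null(f1) || is.null(f2))
    stop("frame set records no f1/f2 stimulus frequencies", call. = FALSE)
  fd <- 2 * f1 - f2
  if (fd <= 0)
    stop("2*f1 - f2 must be positive", call. = FALSE)
  extract_tone_component(frames, fd, discard_ms = discard_ms,
                         calibration = calibration)
}
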