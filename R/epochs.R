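# Epoch containers: repetitions x samples voltage matrices with alternating
# stimulus polarity, the raw unit of round-window recording.

#' Tone-burst stimulus description
#'
#' Describes the tone burst used to evoke one epoch set.  Defaults follow
#' the standard low-frequency neural protocol: 33.3 ms bursts, 92
#' alternating-polarity repetitions, 96 kHz sampling.
#'
#' @param frequency stimulus frequency in Hz (> 0).
#' @param level sound level in dB SPL.
#' @param duration_ms burst duration in ms.
#' @param rise_fall_ms raised-cosine on/off ramp duration in ms; must
#'   satisfy `2 * rise_fall_ms <= duration_ms`.
#' @param n_repetitions number of epochs; must be even so that polarity
#'   pairs are complete.
#' @param polarity_start polarity of the first epoch, `+1` or `-1`.
#' @param sample_rate sampling rate in Hz; must be at least `4 * frequency`.
#' @return an object of class `tone_burst_spec`.
#' @export
tone_burst_spec <- function(frequency, level,
                            duration_ms = 33.3, rise_fall_ms = 5,
                            n_repetitions = 92, polarity_start = 1L,
                            sample_rate = 96000) {
  check_scalar(frequency, "frequency", positive = TRUE)
  check_scalar(level, "level")
  check_scalar(duration_ms, "duration_ms", positive = TRUE)
  check_scalar(rise_fall_ms, "rise_fall_ms", nonneg = TRUE)
  if (2 * rise_fall_ms > duration_ms)
    abort_field("rise_fall_ms", "2 * rise_fall_ms must not exceed duration_ms")
  check_scalar(n_repetitions, "n_repetitions", positive = TRUE, integer = TRUE)
  if (n_repetitions %% 2 != 0)
    abort_field("n_repetitions", "must be even (alternating-polarity pairs)")
  if (!polarity_start %in% c(-1, 1))
    abort_field("polarity_start", "must be +1 or -1")
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (sample_rate < 4 * frequency)
    abort_field("sample_rate", "must be at least 4 * frequency")
  structure(
    list(frequency = frequency, level = level, duration_ms = duration_ms,
         rise_fall_ms = rise_fall_ms, n_repetitions = as.integer(n_repetitions),
         polarity_start = as.integer(polarity_start),
         sample_rate = sample_rate),
    class = "tone_burst_spec")
}

#' @rdname tone_burst_spec
#' @param ... further arguments passed to [tone_burst_spec()].
#' @export
anow_burst <- function(frequency, level, n_repetitions = 92, ...) {
  tone_burst_spec(frequency, level, duration_ms = 33.3, rise_fall_ms = 5,
                  n_repetitions = n_repetitions, ...)
}

#' @rdname tone_burst_spec
#' @export
cap_burst <- function(frequency, level, n_repetitions = 128, ...) {
  tone_burst_spec(frequency, level, duration_ms = 13.9, rise_fall_ms = 1,
                  n_repetitions = n_repetitions, ...)
}

#' Epoch matrix of repeated electrode recordings
#'
#' @param data numeric matrix, repetitions in rows, samples in columns,
#'   input-referred microvolts.
#' @param sample_rate sampling rate in Hz.
#' @param polarity integer vector of per-epoch stimulus polarity (+1/-1),
#'   strictly alternating.
#' @param onset_sample 0-based index of the stimulus onset within an epoch.
#' @param stimulus optional [tone_burst_spec()] metadata.
#' @param invalid_edge number of samples at each end rendered invalid by
#'   filtering (0 for raw epochs).
#' @return an object of class `epoch_matrix`.
#' @export
epoch_matrix <- function(data, sample_rate, polarity, onset_sample = 0L,
                         stimulus = NULL, invalid_edge = 0L) {
  if (!is.matrix(data) || !is.numeric(data))
    abort_field("data", "must be a numeric matrix (repetitions x samples)")
  n <- nrow(data)
  if (n < 2 || n %% 2 != 0)
    abort_field("data", "number of epochs must be even and >= 2")
  if (length(polarity) != n)
    abort_field("polarity", "must have one entry per epoch")
  if (!all(polarity %in% c(-1, 1)))
    abort_field("polarity", "entries must be +1 or -1")
  if (any(diff(polarity) == 0))
    abort_field("polarity", "must strictly alternate +,-,+,- ...")
  check_scalar(onset_sample, "onset_sample", nonneg = TRUE, integer = TRUE)
  if (onset_sample >= ncol(data))
    abort_field("onset_sample", "must lie within the epoch")
  structure(
    list(data = data, sample_rate = sample_rate,
         polarity = as.integer(polarity),
         onset_sample = as.integer(onset_sample),
         stimulus = stimulus, invalid_edge = as.integer(invalid_edge)),
    class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %d epochs x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sample_rate))
  if (!is.null(x$stimulus))
    cat(sprintf("  stimulus: %g Hz, %g dB SPL, %g ms\n",
                x$stimulus$frequency, x$stimulus$level,
                x$stimulus$duration_ms))
  cat(sprintf("  onset sample %d (0-based), invalid edge %d samples\n",
              x$onset_sample, x$invalid_edge))
  invisible(x)
}

# time axis (seconds re stimulus onset) for one epoch
epoch_time <- function(epochs) {
  (seq_len(ncol(epochs$data)) - 1 - epochs$onset_sample) / epochs$sample_rate
}
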