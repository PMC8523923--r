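# Epoch conditioning: linear-phase FIR band-limiting with group-delay
# correction, and quartile-fence detection of high-amplitude artifacts.

#' Design a linear-phase FIR bandpass kernel
#'
#' Kaiser-windowed design via [signal::fir1()].  Tap count may be given
#' explicitly or derived with [signal::kaiserord()] from the stopband
#' specification (stopband edges at `low/2` and `min(2*high, 0.9*Nyquist)`).
#' The realized frequency response is measured at design time: passband
#' ripple beyond `ripple_db` is an error (with a suggested tap count);
#' achieved stopband attenuation is stored on the kernel and enforced only
#' when `min_stopband_db` is supplied, because deep low-side stopbands can
#' demand kernels longer than an epoch.
#'
#' @param low,high passband edges, Hz (`0 < low < high < sample_rate/2`).
#' @param sample_rate sampling rate, Hz.
#' @param n_taps odd tap count, or `NULL` to derive from `stopband_db`.
#' @param stopband_db stopband attenuation target used for the Kaiser beta
#'   and the automatic tap count.
#' @param ripple_db allowed passband deviation from 0 dB.
#' @param min_stopband_db if non-`NULL`, error unless the measured stopband
#'   attenuation reaches this many dB.
#' @return an object of class `fir_kernel` with elements `taps`,
#'   `passband`, `sample_rate`, `group_delay` (samples), `stopband_edges`
#'   and `stopband_attenuation_db` (measured, dB, positive numbers).
#' @export
design_bandpass_fir <- function(low, high, sample_rate, n_taps = 1025,
                                stopband_db = 40, ripple_db = 1,
                                min_stopband_db = NULL) {
  check_scalar(low, "low", positive = TRUE)
  check_scalar(high, "high", positive = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  nyq <- sample_rate / 2
  if (!(low < high && high < nyq))
    abort_field("passband", "need 0 < low < high < sample_rate/2")
  stop_lo <- low / 2
  stop_hi <- min(2 * high, 0.9 * nyq)
  if (is.null(n_taps)) {
    # start from the Kaiser estimate, then grow until the measured
    # attenuation at the stopband edges actually meets the target
    n_taps <- suggest_taps(stop_lo, low, high, stop_hi, stopband_db,
                           ripple_db, sample_rate)
    trial <- NULL
    for (i in 1:6) {
      trial <- tryCatch(
        design_bandpass_fir(low, high, sample_rate, n_taps, stopband_db,
                            ripple_db),
        error = function(e) NULL)
      if (!is.null(trial) && all(trial$stopband_attenuation_db >= stopband_db))
        return(trial)
      n_taps <- 2 * ((n_taps * 1.35) %/% 2) + 1
    }
    if (is.null(trial))
      stop("FIR design infeasible for the requested band", call. = FALSE)
    return(trial)
  }
  check_scalar(n_taps, "n_taps", positive = TRUE, integer = TRUE)
  if (n_taps %% 2 == 0)
    abort_field("n_taps", "must be odd (integer group delay)")
  beta <- kaiser_beta(stopband_db)
  # fir1 places its -6 dB point at the cutoff; widen the cutoffs by the
  # Kaiser transition half-width so [low, high] falls in the flat region
  tw <- (stopband_db - 8) / (2.285 * (n_taps - 1)) * sample_rate / (2 * pi)
  cut_lo <- max(low - tw / 2, 1)
  cut_hi <- min(high + tw / 2, 0.99 * nyq)
  taps <- signal::fir1(n_taps - 1, c(cut_lo, cut_hi) / nyq, type = "pass",
                       window = signal::kaiser(n_taps, beta), scale = TRUE)
  taps <- as.numeric(taps)
  kernel <- structure(
    list(taps = taps, passband = c(low, high), sample_rate = sample_rate,
         n_taps = as.integer(n_taps), group_delay = (n_taps - 1L) %/% 2L,
         stopband_edges = c(stop_lo, stop_hi)),
    class = "fir_kernel")
  pass_freqs <- seq(low, high, length.out = 101)
  pass_db <- 20 * log10(Mod(fir_frequency_response(kernel, pass_freqs)))
  worst <- max(abs(pass_db))
  if (worst > ripple_db) {
    suggested <- suggest_taps(stop_lo, low, high, stop_hi, stopband_db,
                              ripple_db, sample_rate)
    if (suggested <= n_taps) suggested <- 2 * ((n_taps * 1.35) %/% 2) + 1
    stop(sprintf(paste0("FIR design infeasible for %d taps: passband ",
                        "deviation %.2f dB exceeds %.2f dB; try >= %d taps"),
                 n_taps, worst, ripple_db, suggested), call. = FALSE)
  }
  att <- -20 * log10(Mod(fir_frequency_response(kernel, c(stop_lo, stop_hi))))
  kernel$passband_ripple_db <- worst
  kernel$stopband_attenuation_db <- att
  if (!is.null(min_stopband_db) && any(att < min_stopband_db)) {
    suggested <- suggest_taps(stop_lo, low, high, stop_hi, min_stopband_db,
                              ripple_db, sample_rate)
    stop(sprintf(paste0("FIR design infeasible for %d taps: stopband ",
                        "attenuation %.1f dB below %.1f dB; try >= %d taps"),
                 n_taps, min(att), min_stopband_db, suggested), call. = FALSE)
  }
  kernel
}

kaiser_beta <- function(att_db) {
  if (att_db > 50) 0.1102 * (att_db - 8.7)
  else if (att_db > 21) 0.5842 * (att_db - 21)^0.4 + 0.07886 * (att_db - 21)
  else 0
}

suggest_taps <- function(stop_lo, low, high, stop_hi, stopband_db, ripple_db,
                         sample_rate) {
  dev <- c(10^(-stopband_db / 20), 10^(ripple_db / 20) - 1,
           10^(-stopband_db / 20))
  ord <- signal::kaiserord(c(stop_lo, low, high, stop_hi), c(0, 1, 0),
                           dev, sample_rate)
  n <- ord$n + 1
  if (n %% 2 == 0) n + 1 else n
}

#' Complex frequency response of an FIR kernel
#'
#' @param kernel a `fir_kernel`.
#' @param freqs frequencies in Hz.
#' @return complex response values (group delay included).
#' @export
fir_frequency_response <- function(kernel, freqs) {
  k <- seq_along(kernel$taps) - 1
  vapply(freqs, function(f)
    sum(kernel$taps * exp(-2i * pi * f * k / kernel$sample_rate)),
    complex(1))
}

#' @export
print.fir_kernel <- function(x, ...) {
  cat(sprintf(paste0("<fir_kernel> %d taps, passband %g-%g Hz @ %g Hz, ",
                     "ripple %.3f dB, stopband %.1f/%.1f dB at %g/%g Hz\n"),
              x$n_taps, x$passband[1], x$passband[2], x$sample_rate,
              x$passband_ripple_db, x$stopband_attenuation_db[1],
              x$stopband_attenuation_db[2], x$stopband_edges[1],
              x$stopband_edges[2]))
  invisible(x)
}

#' Filter epochs and correct for group delay
#'
#' Convolves every epoch with the kernel (FFT overlap-free convolution,
#' epochs treated as preceded/followed by silence) and advances the output
#' by the kernel group delay so filtered features stay aligned with the
#' input time axis.  The half-kernel at each end, where the convolution
#' reaches beyond the recorded epoch, is marked invalid in
#' `$invalid_edge`.
#'
#' @param epochs an [epoch_matrix()].
#' @param kernel a `fir_kernel` with matching sample rate.
#' @return a filtered `epoch_matrix`.
#' @export
filter_epochs <- function(epochs, kernel) {
  stopifnot(inherits(epochs, "epoch_matrix"), inherits(kernel, "fir_kernel"))
  if (!isTRUE(all.equal(epochs$sample_rate, kernel$sample_rate)))
    stop("kernel sample rate does not match epochs", call. = FALSE)
  ns <- ncol(epochs$data)
  nt <- kernel$n_taps
  L <- stats::nextn(ns + nt - 1, 2)
  X <- rbind(t(epochs$data), matrix(0, L - ns, nrow(epochs$data)))
  H <- fft(c(kernel$taps, rep(0, L - nt)))
  Y <- Re(stats::mvfft(stats::mvfft(X) * H, inverse = TRUE)) / L
  out <- t(Y[kernel$group_delay + seq_len(ns), , drop = FALSE])
  epochs$data <- out
  epochs$invalid_edge <- max(epochs$invalid_edge, kernel$group_delay)
  epochs
}

#' Quartile-fence detection of high-amplitude artifacts
#'
#' Computes a pointwise median waveform across epochs and the absolute
#' deviation of every sample from it; deviations are pooled, and samples
#' beyond `Q3 + fence * IQR` (a Tukey fence, default fence 3) are flagged.
#' With `by_polarity = TRUE` (default) the median is taken within each
#' epoch's own polarity class, so a polarity-following stimulus component
#' (the cochlear microphonic) does not inflate every deviation; for
#' polarity-balanced data without stimulus content the two settings agree.
#' Weights are 1 (clean) or 0 (artifact); an epoch is flagged whole when
#' more than `epoch_flag_frac` of its samples are flagged.  Artifact
#' locations are recorded; samples are never altered.
#'
#' @param epochs an [epoch_matrix()] with at least 4 epochs.
#' @param fence IQR multiplier of the upper fence.
#' @param epoch_flag_frac fraction of flagged samples above which the whole
#'   epoch is flagged.
#' @param by_polarity take the reference median within each polarity class?
#' @return an object of class `artifact_scan`: `weights` (0/1 matrix shaped
#'   like the data), `report` (data frame of flagged `epoch`/`sample`
#'   pairs), `threshold` (the fence in uV), `epoch_flagged` (logical per
#'   epoch), `epoch_counts` (flagged samples per epoch).
#' @export
detect_artifacts_quartile <- function(epochs, fence = 3,
                                      epoch_flag_frac = 0.10,
                                      by_polarity = TRUE) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  check_scalar(fence, "fence", nonneg = TRUE)
  if (nrow(epochs$data) < 4)
    stop("quartile artifact detection needs at least 4 epochs", call. = FALSE)
  dev <- matrix(0, nrow(epochs$data), ncol(epochs$data))
  groups <- if (by_polarity) epochs$polarity else rep(1L, nrow(epochs$data))
  for (g in unique(groups)) {
    rows <- groups == g
    med <- apply(epochs$data[rows, , drop = FALSE], 2, median)
    dev[rows, ] <- abs(sweep(epochs$data[rows, , drop = FALSE], 2, med))
  }
  qs <- quantile(dev, c(0.25, 0.75), names = FALSE)
  thr <- qs[2] + fence * (qs[2] - qs[1])
  flagged <- dev > thr
  weights <- 1 - flagged
  storage.mode(weights) <- "double"
  idx <- which(flagged, arr.ind = TRUE)
  report <- data.frame(epoch = as.integer(idx[, 1]),
                       sample = as.integer(idx[, 2]))
  report <- report[order(report$epoch, report$sample), , drop = FALSE]
  rownames(report) <- NULL
  counts <- rowSums(flagged)
  structure(
    list(weights = weights, report = report, threshold = thr,
         epoch_flagged = counts > epoch_flag_frac * ncol(epochs$data),
         epoch_counts = counts),
    class = "artifact_scan")
}

#' @export
print.artifact_scan <- function(x, ...) {
  cat(sprintf("<artifact_scan> %d flagged samples in %d epochs (fence %.4g uV); %d epochs flagged whole\n",
              nrow(x$report), length(x$epoch_flagged), x$threshold,
              sum(x$epoch_flagged)))
  invisible(x)
}
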