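# Compound action potential analysis: artifact-epoch rejection, grand
# averaging (polarity averaging cancels the microphonic), and automated
# N1/P1 peak picking.

#' Remove artifact-bearing epochs (with their polarity partners)
#'
#' Any epoch containing at least one flagged sample is removed, and so is
#' its polarity partner, keeping the +/- balance exact so the microphonic
#' still cancels in the average.
#'
#' @param epochs an [epoch_matrix()].
#' @param report either an `artifact_scan` from
#'   [detect_artifacts_quartile()] or its `report` data frame
#'   (`epoch`/`sample` columns).
#' @return the retained `epoch_matrix`, with attributes `retained` and
#'   `removed` (epoch counts).
#' @export
reject_artifact_epochs <- function(epochs, report) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (inherits(report, "artifact_scan")) report <- report$report
  n <- nrow(epochs$data)
  if (nrow(report) > 0 && max(report$epoch) > n)
    stop("artifact report is not aligned to these epochs", call. = FALSE)
  bad <- unique(report$epoch)
  pair_of <- function(i) ifelse(i %% 2 == 1, i + 1L, i - 1L)
  drop <- sort(unique(c(bad, pair_of(bad))))
  keep <- setdiff(seq_len(n), drop)
  if (length(keep) == 0)
    stop("all epochs contain artifacts; nothing retained", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[keep, , drop = FALSE]
  out$polarity <- epochs$polarity[keep]
  if (!is.null(out$artifact_truth)) out$artifact_truth <- NULL
  attr(out, "retained") <- length(keep)
  attr(out, "removed") <- length(drop)
  out
}

#' Grand-average CAP waveform
#'
#' Mean across all retained epochs; with balanced alternating polarity the
#' cochlear microphonic cancels, as in the overlapped-waveform analysis.
#'
#' @param epochs an [epoch_matrix()] with even, alternating epochs.
#' @return numeric waveform (uV) with attributes `sample_rate` and
#'   `onset_sample`.
#' @export
average_cap <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_matrix"))
  if (nrow(epochs$data) %% 2 != 0)
    stop("epoch count must be even for balanced polarity averaging",
         call. = FALSE)
  if (any(diff(epochs$polarity) == 0))
    stop("epoch polarity must strictly alternate", call. = FALSE)
  w <- colMeans(epochs$data)
  attr(w, "sample_rate") <- epochs$sample_rate
  attr(w, "onset_sample") <- epochs$onset_sample
  w
}

# strict local extrema; ties broken towards the earliest sample
local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] < y[i - 1] & y[i] <= y[i + 1]]
}

# 3-point parabolic refinement around sample i; returns (offset, value)
parabolic_refine <- function(y, i) {
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(c(0, y[i]))
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  c(delta, y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Automated N1/P1 peak picking
#'
#' N1 is the most negative local extremum inside the search window
#' (default 0.5-6 ms after stimulus onset); P1 is the most positive local
#' extremum within `p1_max_lag_ms` after N1.  Latencies are refined below
#' sample resolution by 3-point parabolic interpolation.  A flat or
#' extremum-free window yields a "no response" result (all-`NA` peaks,
#' `quality_flag = "no_response"`) rather than an error.  The quality flag
#' is `"low"` when |N1| is under `min_snr` times the pre-onset RMS.
#'
#' @param waveform averaged CAP waveform (uV); attributes from
#'   [average_cap()] are honoured, or pass `sample_rate`/`onset_sample`.
#' @param sample_rate sampling rate, Hz.
#' @param onset_sample 0-based stimulus onset index.
#' @param n1_window_ms `c(start, end)` N1 search window, ms re onset.
#' @param p1_max_lag_ms maximum P1 lag after N1, ms.
#' @param min_snr multiple of the pre-onset RMS below which quality is
#'   flagged low.
#' @return an object of class `cap_peaks`: `n1_latency_ms`,
#'   `n1_amplitude`, `p1_latency_ms`, `p1_amplitude`, `peak_to_peak`,
#'   `quality_flag` (`"ok"`, `"low"`, or `"no_response"`).
#' @export
pick_peaks <- function(waveform,
                       sample_rate = attr(waveform, "sample_rate"),
                       onset_sample = attr(waveform, "onset_sample"),
                       n1_window_ms = c(0.5, 6), p1_max_lag_ms = 5,
                       min_snr = 3) {
  if (is.null(sample_rate))
    stop("sample_rate must be supplied", call. = FALSE)
  if (is.null(onset_sample)) onset_sample <- 0L
  y <- as.numeric(waveform)
  t_ms <- (seq_along(y) - 1 - onset_sample) / sample_rate * 1000
  if (max(t_ms) < n1_window_ms[2])
    stop("waveform does not span the N1 search window", call. = FALSE)
  pre_rms <- if (any(t_ms < 0)) sqrt(mean(y[t_ms < 0]^2)) else NA_real_
  no_response <- structure(
    list(n1_latency_ms = NA_real_, n1_amplitude = NA_real_,
         p1_latency_ms = NA_real_, p1_amplitude = NA_real_,
         peak_to_peak = NA_real_, quality_flag = "no_response"),
    class = "cap_peaks")

  mins <- local_minima(y)
  mins <- mins[t_ms[mins] >= n1_window_ms[1] & t_ms[mins] <= n1_window_ms[2]]
  if (length(mins) == 0) return(no_response)
  i_n1 <- mins[which.min(y[mins])]          # earliest wins on exact ties
  r_n1 <- parabolic_refine(y, i_n1)
  n1_lat <- t_ms[i_n1] + r_n1[1] / sample_rate * 1000
  n1_amp <- r_n1[2]

  maxs <- local_minima(-y)
  maxs <- maxs[t_ms[maxs] > n1_lat &
                 t_ms[maxs] <= n1_lat + p1_max_lag_ms]
  if (length(maxs) == 0) return(no_response)
  i_p1 <- maxs[which.max(y[maxs])]
  r_p1 <- parabolic_refine(y, i_p1)
  p1_lat <- t_ms[i_p1] + r_p1[1] / sample_rate * 1000
  p1_amp <- r_p1[2]

  quality <- if (!is.na(pre_rms) && abs(n1_amp) < min_snr * pre_rms) "low"
             else "ok"
  structure(
    list(n1_latency_ms = n1_lat, n1_amplitude = n1_amp,
         p1_latency_ms = p1_lat, p1_amplitude = p1_amp,
         peak_to_peak = p1_amp - n1_amp, quality_flag = quality),
    class = "cap_peaks")
}

#' @export
print.cap_peaks <- function(x, ...) {
  if (x$quality_flag == "no_response") {
    cat("<cap_peaks> no response\n")
  } else {
    cat(sprintf(paste0("<cap_peaks> N1 %.3f ms / %.3f uV, P1 %.3f ms / ",
                       "%.3f uV, p2p %.3f uV [%s]\n"),
                x$n1_latency_ms, x$n1_amplitude, x$p1_latency_ms,
                x$p1_amplitude, x$peak_to_peak, x$quality_flag))
  }
  invisible(x)
}
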