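# Small shared helpers: unit conversions, validation, seeded RNG scope.

#' Convert a linear amplitude to decibels
#'
#' @param x linear amplitude (same units as `ref`).
#' @param ref reference amplitude; 1 for dB re 1 uV, 20e-6 for dB SPL.
#' @param floor_db values are clamped below at this dB value (default
#'   `-Inf`, no clamping) so that zero amplitudes stay finite when needed.
#' @return dB value `20*log10(x/ref)`.
#' @export
amplitude_db <- function(x, ref = 1, floor_db = -Inf) {
  pmax(20 * log10(x / ref), floor_db)
}

#' @rdname amplitude_db
#' @export
db_amplitude <- function(x, ref = 1) ref * 10^(x / 20)

# stop() with the calling function's name stripped from the message context
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) abort_field(field, "must be > 0")
  if (nonneg && x < 0) abort_field(field, "must be >= 0")
  if (integer && x != round(x)) abort_field(field, "must be an integer")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.  `seed = NULL` uses the current
# stream (and therefore does advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  check_scalar(seed, "seed", integer = TRUE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# raised-cosine on/off ramps applied to a gate of `n` samples
raised_cosine_envelope <- function(n, n_ramp) {
  env <- rep(1, n)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
    env[seq_len(n_ramp)] <- r
    env[n - n_ramp + seq_len(n_ramp)] <- rev(r)
  }
  env
}

ms_to_samples <- function(ms, sample_rate) round(ms * 1e-3 * sample_rate)
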