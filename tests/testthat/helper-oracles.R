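# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementation.

# Penalized-spline oracle: minimize
#   p * sum_i w_i (y_i - g(x_i))^2 + (1 - p) * int g''^2
# by discretizing g on a fine grid and solving the sparse quadratic
# program with second-difference curvature.  Independent of the Reinsch
# scheme used by the package.
oracle_penalized_spline <- function(x, y, w, p, step = 0.25) {
  stopifnot(requireNamespace("Matrix", quietly = TRUE))
  grid <- seq(min(x), max(x), by = step)
  m <- length(grid)
  ix <- match(round(x, 9), round(grid, 9))
  stopifnot(!anyNA(ix))
  A <- Matrix::sparseMatrix(i = seq_along(x), j = ix, x = 1,
                            dims = c(length(x), m))
  e <- rep(1, m - 2)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2, diagonals = list(e, -2 * e, e))
  Wd <- Matrix::Diagonal(x = w)
  M <- p * Matrix::t(A) %*% Wd %*% A +
    (1 - p) / step^3 * Matrix::t(D) %*% D
  rhs <- p * Matrix::t(A) %*% Wd %*% y
  g <- as.numeric(Matrix::solve(M, rhs))
  list(grid = grid, fitted = g,
       at = function(xq) approx(grid, g, xq, rule = 2)$y)
}

# Closed-form OLS with t statistics, written in scalar arithmetic (no lm)
ols_oracle <- function(x, y, conf = 0.95) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2); sst <- sum((y - my)^2)
  r2 <- 1 - sse / sst
  se <- sqrt(sse / (n - 2) / sxx)
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  tq <- qt(1 - (1 - conf) / 2, df = n - 2)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p,
       conf_int = c(slope - tq * se, slope + tq * se))
}

# amplitude of the component at frequency f in a waveform sampled at fs,
# via the DFT (f must land on a bin)
dft_amplitude <- function(wave, f, fs) {
  n <- length(wave)
  k <- round(f * n / fs)
  stopifnot(abs(f * n / fs - k) < 1e-9)
  2 * Mod(fft(wave)[k + 1]) / n
}

# standard ANOW test scenarios
test_anow_scenario <- function(seed, neural = 1, noise = 0.5, cm = 10,
                               rate = 0, scale = 50) {
  scenario_config(cm_amplitude = cm,
                  neural_amplitude_fn = function(l) rep(neural, length(l)),
                  noise_sigma = noise, seed = seed,
                  artifact_rate = rate, artifact_scale = scale)
}
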