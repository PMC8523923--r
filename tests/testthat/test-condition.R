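# FIR design/filtering contracts and the quartile artifact detector.

kernel_anow <- design_bandpass_fir(600, 1600, 96000, 1025)
kernel_cap <- design_bandpass_fir(150, 1500, 96000, 1025)

test_that("FIR kernels are linear phase with the advertised band behavior", {
  expect_identical(kernel_anow$n_taps %% 2L, 1L)
  expect_equal(kernel_anow$taps, rev(kernel_anow$taps))  # symmetric
  # passband: 1000 Hz within +/-1 dB of 0; stopband: 300 Hz at <= -40 dB
  h1000 <- 20 * log10(Mod(fir_frequency_response(kernel_anow, 1000)))
  expect_lt(abs(h1000), 1)
  h300 <- 20 * log10(Mod(fir_frequency_response(kernel_anow, 300)))
  expect_lt(h300, -40)
  h700 <- 20 * log10(Mod(fir_frequency_response(kernel_cap, 700)))
  expect_lt(abs(h700), 1)
})

test_that("infeasible designs fail with a suggested tap count", {
  expect_error(design_bandpass_fir(600, 1600, 96000, 31,
                                   min_stopband_db = 40), "try >=")
  expect_error(design_bandpass_fir(150, 1500, 96000, 1025,
                                   min_stopband_db = 40), "try >=")
  expect_error(design_bandpass_fir(600, 1600, 96000, 1024), "n_taps")
  expect_error(design_bandpass_fir(1600, 600, 96000), "passband")
})

make_epochs <- function(data, fs = 96000) {
  epoch_matrix(data, fs, rep_len(c(1L, -1L), nrow(data)))
}

test_that("group-delay-corrected filtering keeps passband tones aligned and in amplitude", {
  fs <- 96000
  n <- 9600
  t <- (0:(n - 1)) / fs
  tone <- cos(2 * pi * 1000 * t)
  em <- make_epochs(rbind(tone, tone))
  out <- filter_epochs(em, kernel_anow)
  mid <- (kernel_anow$group_delay + 1):(n - kernel_anow$group_delay)
  cf <- recruitpipe:::sinusoid_fit(out$data[1, mid], 1000, fs,
                                   onset_sample = -(mid[1] - 1))
  expect_lt(abs(20 * log10(Mod(cf))), 1)          # amplitude preserved
  expect_lt(abs(Arg(cf)), 0.02)                    # zero phase after correction
  expect_identical(out$invalid_edge, kernel_anow$group_delay)

  low <- cos(2 * pi * 100 * t)
  out2 <- filter_epochs(make_epochs(rbind(low, low)), kernel_anow)
  cf2 <- recruitpipe:::sinusoid_fit(out2$data[1, mid], 100, fs,
                                    onset_sample = -(mid[1] - 1),
                                    min_cycles = 5)
  expect_lt(20 * log10(Mod(cf2)), -40)             # stopband attenuation
})

test_that("an impulse returns to its original sample index after delay correction", {
  n <- 4096
  imp <- rep(0, n); imp[2000] <- 1
  out <- filter_epochs(make_epochs(rbind(imp, imp)), kernel_anow)
  expect_identical(which.max(abs(out$data[1, ])), 2000L)
})

test_that("filtering is linear and maps zero to zero", {
  set.seed(4)
  n <- 3000
  x <- rnorm(n); y <- rnorm(n)
  fx <- filter_epochs(make_epochs(rbind(x, x)), kernel_anow)$data[1, ]
  fy <- filter_epochs(make_epochs(rbind(y, y)), kernel_anow)$data[1, ]
  fxy <- filter_epochs(make_epochs(rbind(2 * x - 3 * y, 2 * x - 3 * y)),
                       kernel_anow)$data[1, ]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
  fz <- filter_epochs(make_epochs(matrix(0, 2, n)), kernel_anow)$data
  expect_identical(max(abs(fz)), 0)
  em_bad <- epoch_matrix(matrix(0, 2, n), 48000, c(1L, -1L))
  expect_error(filter_epochs(em_bad, kernel_anow), "sample rate")
})

test_that("identical noiseless epochs produce no artifact flags", {
  w <- sin(2 * pi * 960 * (0:2999) / 96000)
  em <- make_epochs(matrix(rep(w, 8), nrow = 8, byrow = TRUE))
  scan <- detect_artifacts_quartile(em)
  expect_identical(nrow(scan$report), 0L)
  expect_true(all(scan$weights == 1))
  expect_false(any(scan$epoch_flagged))
  expect_error(detect_artifacts_quartile(make_epochs(matrix(0, 2, 100))),
               "at least 4")
})

test_that("a gross outlier is flagged and the detector is scale-equivariant", {
  set.seed(7)
  data <- matrix(rnorm(16 * 2000), nrow = 16)
  data[5, 700] <- 100
  em <- make_epochs(data)
  scan <- detect_artifacts_quartile(em)
  expect_true(any(scan$report$epoch == 5 & scan$report$sample == 700))
  expect_identical(scan$weights[5, 700], 0)
  scan2 <- detect_artifacts_quartile(make_epochs(data * 37))
  expect_identical(scan$report, scan2$report)
})

test_that("Gaussian false-flag rate matches the Tukey-fence tail rate", {
  set.seed(12)
  data <- matrix(rnorm(64 * 4096), nrow = 64)
  scan <- detect_artifacts_quartile(make_epochs(data))
  rate <- nrow(scan$report) / length(data)
  # half-normal Q3 + 3*IQR fence is ~3.65 sigma: two-sided tail ~2.7e-4
  expect_gt(rate, 1e-4)
  expect_lt(rate, 6e-4)
})

test_that("detector recall on injected ground truth is at least 99%", {
  spec <- anow_burst(480, 60)
  scen <- test_anow_scenario(seed = 21, noise = 0.5, rate = 0.01, scale = 50)
  em <- gen_anow_epochs(spec, scen, pre_ms = 2, post_ms = 2)
  scan <- detect_artifacts_quartile(em)
  truth <- em$artifact_truth
  hit <- scan$weights[cbind(truth$epoch, truth$sample)] == 0
  expect_gte(mean(hit), 0.99)
  # flagged set equals report contents; weights are binary and exhaustive
  expect_identical(sum(scan$weights == 0), nrow(scan$report))
  expect_true(all(scan$weights %in% c(0, 1)))
})
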