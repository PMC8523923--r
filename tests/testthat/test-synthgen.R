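# Generator contracts: polarity structure, spectral content, determinism,
# artifact bookkeeping, growth-scenario geometry.

test_that("polarity-following microphonic cancels pairwise and epochs are pure sinusoids", {
  spec <- tone_burst_spec(480, 60, n_repetitions = 4)
  scen <- scenario_config(cm_amplitude = 10, noise_sigma = 0)
  em <- gen_anow_epochs(spec, scen, pre_ms = 2, post_ms = 2)
  expect_identical(em$polarity, c(1L, -1L, 1L, -1L))
  # consecutive pair means are identically zero (exact cancellation)
  expect_identical(max(abs(em$data[1, ] + em$data[2, ])), 0)
  expect_identical(max(abs(em$data[3, ] + em$data[4, ])), 0)
  # burst portion is the enveloped sinusoid, silence elsewhere
  n_pre <- recruitpipe:::ms_to_samples(2, 96000)
  n_burst <- recruitpipe:::ms_to_samples(33.3, 96000)
  tt <- (seq_len(n_burst) - 1) / 96000
  env <- recruitpipe:::raised_cosine_envelope(
    n_burst, recruitpipe:::ms_to_samples(5, 96000))
  expect_equal(em$data[1, n_pre + seq_len(n_burst)],
               10 * env * sin(2 * pi * 480 * tt))
  expect_identical(max(abs(em$data[, seq_len(n_pre)])), 0)
})

test_that("noiseless neural-only epochs are identical with a single spectral line at 2f", {
  spec <- tone_burst_spec(500, 60, duration_ms = 20, rise_fall_ms = 0,
                          n_repetitions = 4)
  scen <- scenario_config(cm_amplitude = 0,
                          neural_amplitude_fn = function(l) rep(1, length(l)),
                          noise_sigma = 0)
  em <- gen_anow_epochs(spec, scen, pre_ms = 0, post_ms = 0)
  expect_equal(em$data[1, ], em$data[2, ])
  expect_equal(em$data[1, ], em$data[4, ])
  expect_equal(dft_amplitude(em$data[1, ], 1000, 96000), 1, tolerance = 1e-12)
  # energy at every other bin is numerically zero
  sp <- Mod(fft(em$data[1, ]))
  n <- length(sp)
  k2f <- round(1000 * n / 96000) + 1
  sp[c(k2f, n - k2f + 2)] <- 0
  expect_lt(max(sp) / n, 1e-9)
})

test_that("noiseless CM+neural epochs contain energy only at f and 2f", {
  spec <- tone_burst_spec(500, 60, duration_ms = 20, rise_fall_ms = 0,
                          n_repetitions = 4)
  scen <- scenario_config(cm_amplitude = 10,
                          neural_amplitude_fn = function(l) rep(1, length(l)),
                          noise_sigma = 0)
  em <- gen_anow_epochs(spec, scen, pre_ms = 0, post_ms = 0)
  sp <- Mod(fft(em$data[1, ]))
  n <- length(sp)
  kf <- round(500 * n / 96000) + 1
  k2f <- round(1000 * n / 96000) + 1
  expect_equal(2 * sp[kf] / n, 10, tolerance = 1e-12)
  expect_equal(2 * sp[k2f] / n, 1, tolerance = 1e-12)
  sp[c(kf, k2f, n - kf + 2, n - k2f + 2)] <- 0
  expect_lt(max(sp) / n, 1e-9)
})

test_that("seeded generation is bit-reproducible and leaves the caller RNG alone", {
  spec <- cap_burst(4000, 60, n_repetitions = 8)
  scen <- scenario_config(cm_amplitude = 2, noise_sigma = 1, seed = 11,
                          cap_n1_amplitude_fn = function(l) rep(5, length(l)))
  set.seed(99)
  before <- rnorm(1)
  a <- gen_cap_epochs(spec, scen)
  b <- gen_cap_epochs(spec, scen)
  expect_identical(a$data, b$data)
  set.seed(99)
  expect_identical(before, rnorm(1))
  # ANOW path too
  scen2 <- test_anow_scenario(seed = 3)
  expect_identical(gen_anow_epochs(anow_burst(480, 60, 8), scen2)$data,
                   gen_anow_epochs(anow_burst(480, 60, 8), scen2)$data)
})

test_that("injected artifacts are exactly counted and exactly reported", {
  spec <- anow_burst(480, 60, n_repetitions = 8)
  em <- gen_anow_epochs(spec, test_anow_scenario(seed = 5, cm = 0, neural = 0,
                                                 noise = 1))
  none <- inject_artifacts(em, rate = 0, scale = 50, seed = 1)
  expect_identical(none$epochs$data, em$data)
  expect_identical(nrow(none$locations), 0L)

  inj <- inject_artifacts(em, rate = 0.01, scale = 50, seed = 2, sigma = 1)
  k_expected <- floor(0.01 * length(em$data))
  expect_identical(nrow(inj$locations), as.integer(k_expected))
  changed <- which(inj$epochs$data != em$data, arr.ind = TRUE)
  changed <- changed[order(changed[, 1], changed[, 2]), , drop = FALSE]
  expect_identical(as.integer(changed[, 1]), inj$locations$epoch)
  expect_identical(as.integer(changed[, 2]), inj$locations$sample)
  # every displacement has the advertised size
  expect_true(all(abs((inj$epochs$data - em$data)[changed]) == 50))
})

test_that("generator validation names the offending field", {
  expect_error(tone_burst_spec(480, 60, rise_fall_ms = 20, duration_ms = 30),
               "rise_fall_ms")
  expect_error(tone_burst_spec(480, 60, n_repetitions = 91), "n_repetitions")
  expect_error(tone_burst_spec(480, 60, sample_rate = 1000), "sample_rate")
  expect_error(scenario_config(artifact_rate = 0.25), "artifact_rate")
  expect_error(scenario_config(noise_sigma = -1), "noise_sigma")
  expect_error(scenario_config(neural_amplitude_fn = function(l) -l),
               "neural_amplitude_fn")
  expect_error(inject_artifacts(gen_anow_epochs(anow_burst(480, 60, 4),
                                                scenario_config()),
                                rate = 0.3, scale = 10), "rate")
})

test_that("noiseless linear growth produces an exactly linear level series", {
  scen <- scenario_config(
    neural_amplitude_fn = function(l) db_amplitude(l - 60),
    noise_sigma = 0, seed = 1)
  s <- gen_growth_series(scen, seq(20, 80, 5), frequency = 480)
  steps <- diff(s$response)
  expect_equal(steps, rep(5, length(steps)), tolerance = 1e-9)
})

test_that("hydropic and control scenarios converge at 80 dB SPL by construction", {
  ctrl <- scenario_control()
  hyd <- scenario_hydropic(threshold_shift = 20)
  expect_equal(ctrl$neural_amplitude_fn(80), hyd$neural_amplitude_fn(80),
               tolerance = 1e-12)
  # hydropic is silent below its shifted threshold and steeper above it
  expect_identical(hyd$neural_amplitude_fn(20), 0)
  sl_h <- diff(20 * log10(hyd$neural_amplitude_fn(c(40, 50)))) / 10
  sl_c <- diff(20 * log10(ctrl$neural_amplitude_fn(c(40, 50)))) / 10
  expect_gt(sl_h, sl_c)
})
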