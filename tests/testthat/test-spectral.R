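test_that("integer-frequency sine has a single unit component", {
  w <- normgrid_waveform(sin(2 * pi * 2 * grid_ms / 1000), "arterial")
  sp <- dft_components(w)
  expect_equal(sp$magnitude[sp$freq_hz == 2], 1, tolerance = 1e-10)
  expect_lt(max(sp$magnitude[sp$freq_hz != 2]), 1e-10)
})

test_that("constant waveforms have empty harmonic content", {
  sp <- dft_components(normgrid_waveform(rep(3, 100), "aqueduct"))
  expect_true(all(sp$magnitude < 1e-12))
  expect_equal(nrow(sp), 5)  # aqueductal reporting cutoff
})

test_that("magnitudes are phase-invariant and linear", {
  s1 <- dft_components(normgrid_waveform(sin(2 * pi * 3 * grid_ms / 1000)))
  s2 <- dft_components(normgrid_waveform(cos(2 * pi * 3 * grid_ms / 1000)))
  expect_equal(s1$magnitude, s2$magnitude, tolerance = 1e-12)
  set.seed(3)
  v <- rnorm(100)
  m1 <- dft_components(normgrid_waveform(v, "arterial"))$magnitude
  m3 <- dft_components(normgrid_waveform(3 * v, "arterial"))$magnitude
  expect_equal(m3, 3 * m1, tolerance = 1e-12)
})

test_that("Parseval's identity holds for band-limited cycles", {
  set.seed(11)
  for (i in 1:5) {
    amps <- runif(10, 0, 2)
    phs <- runif(10, 0, 2 * pi)
    v <- rep(runif(1, -1, 1), 100)
    for (k in 1:10)
      v <- v + amps[k] * cos(2 * pi * k * grid_ms / 1000 + phs[k])
    sp <- dft_components(normgrid_waveform(v, "arterial"))
    expect_equal(sum(sp$magnitude^2) / 2 + mean(v)^2, mean(v^2),
                 tolerance = 1e-10)
  }
})

test_that("un-normalized input is rejected", {
  w <- flow_waveform(seq(0, 790, 10), rnorm(80), 800)
  expect_error(dft_components(w), "time-normalized")
})

test_that("noise threshold is the maximum of one-fifth SDs", {
  cal <- calibrate_noise_threshold(list(spinal = c(0.5, 1.0, 0.8)))
  expect_equal(cal$threshold, 0.2)
  cal2 <- calibrate_noise_threshold(list(aqueduct = 0.05))
  expect_equal(cal2$threshold, 0.01)
  expect_error(calibrate_noise_threshold(list()), "non-empty")
  expect_error(calibrate_noise_threshold(list(spinal = numeric())), "empty")
})

test_that("adding a subject can only raise the threshold", {
  set.seed(5)
  sds <- runif(8, 0.1, 2)
  for (i in 3:8) {
    t_small <- calibrate_noise_threshold(list(x = sds[1:(i - 1)]))$threshold
    t_big <- calibrate_noise_threshold(list(x = sds[1:i]))$threshold
    expect_gte(t_big, t_small)
  }
})

test_that("detectability endpoints behave as expected", {
  res <- detectability_simulation(amplitude_grid = c(1, 0.9), n_trials = 30,
                                  seed = 1)
  expect_equal(res$table$detection_rate[1], 1)  # amplitude = SD: always found
  expect_error(detectability_simulation(n_trials = 5), "at least 20")
  expect_error(detectability_simulation(amplitude_grid = c(0.5, 0.9)),
               "descending")
})
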