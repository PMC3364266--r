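test_that("identity system is recovered with unit gain", {
  u <- normgrid_waveform(rich_input(), "arterial")
  tf <- identify_tf(u, u)
  bc <- bode(tf, seq(0.5, 5, 0.5))
  expect_true(all(abs(bc$gain - 1) < 1e-6))
  expect_true(all(abs(bc$phase) < 1e-6))
})

test_that("a known fifth-order system is refit essentially exactly", {
  poles <- c(0.7, 0.5 + 0.3i, 0.5 - 0.3i, 0.3 + 0.5i, 0.3 - 0.5i)
  a0 <- Re(rev(Reduce(function(p, r) c(p, 0) - c(0, p * r), poles, 1)))
  b0 <- c(0.05, 0.1, 0.08, 0.02, 0.01, 0.005)
  u <- rich_input()
  y <- circular_filter(u, b0, a0)
  tf <- identify_tf(normgrid_waveform(u, "arterial"),
                    normgrid_waveform(y, "spinal"))
  expect_gte(tf$vaf, 99.9)
})

test_that("a pure circular delay shows the delay phase law", {
  u <- rich_input()
  y <- circular_shift(u, 5)  # 50 ms delay
  tf <- identify_tf(normgrid_waveform(u, "arterial"),
                    normgrid_waveform(y, "spinal"))
  f <- seq(0.5, 5, 0.5)
  bc <- bode(tf, f)
  expect_equal(bc$phase, -2 * pi * f * 0.05, tolerance = 0.05)
  expect_true(all(abs(bc$gain - 1) < 0.01))
})

test_that("identified models are always stable and causal", {
  set.seed(19)
  for (i in 1:8) {
    u <- rich_input() + rnorm(100, 0, 0.05)
    y <- circular_filter(u, runif(3, -0.5, 0.5), c(1, runif(2, -0.4, 0.4))) +
      rnorm(100, 0, 0.02)
    tf <- identify_tf(normgrid_waveform(u, "arterial"),
                      normgrid_waveform(y, "spinal"))
    expect_true(all(Mod(tf_poles(tf)) < 1))
    expect_gte(tf$delay_ms, 0)
  }
})

test_that("constant input is rejected as unidentifiable", {
  u <- normgrid_waveform(rep(2, 100), "arterial")
  y <- normgrid_waveform(rnorm(100), "spinal")
  expect_error(identify_tf(u, y), "unidentifiable")
})

test_that("bode matches the closed-form single-pole response", {
  p <- 0.9
  model <- structure(list(b = c(1 - p, 0, 0, 0, 0, 0),
                          a = c(1, -p, 0, 0, 0, 0), dt_ms = 10, delay_ms = 0,
                          order = 5, vaf = 100, residual_variance = 0,
                          iterations = 0, converged = TRUE),
                     class = "tf_model")
  f <- c(0.5, 1, 2, 5, 10)
  bc <- bode(model, f)
  w <- 2 * pi * f * 0.01
  expect_equal(bc$gain, Mod((1 - p) / (1 - p * exp(-1i * w))),
               tolerance = 1e-10)
  expect_error(bode(model, 60), "frequencies must lie")
})

test_that("crossover frequency interpolates the downward unity crossing", {
  mk <- function(f, g) structure(tibble::tibble(freq_hz = f, gain = g,
                                                phase = 0),
                                 class = c("bode_curve", "tbl_df", "tbl",
                                           "data.frame"))
  f <- seq(0.1, 2, 0.1)
  curve <- mk(f, 1 + (0.8 - f) * 0.5)  # gain exactly 1 at 0.8, decreasing
  expect_equal(crossover_frequency(curve), 0.8, tolerance = 1e-9)
  expect_true(is.na(crossover_frequency(mk(f, rep(1, 20)))))
  expect_true(is.na(crossover_frequency(mk(f, rep(0.5, 20)))))
})

test_that("cross-correlation of shifted copies peaks at the shift", {
  u <- rich_input() - mean(rich_input())
  for (k in c(0, 5, 37)) {
    y <- circular_shift(u, k)
    cc <- cross_correlate(normgrid_waveform(u, "arterial"),
                          normgrid_waveform(y, "spinal"))
    expect_equal(cc$lag_ms[which.max(cc$r)], k * 10)
    expect_equal(max(cc$r), 1, tolerance = 1e-9)
  }
  cc0 <- cross_correlate(normgrid_waveform(u, "arterial"),
                         normgrid_waveform(-u, "spinal"))
  expect_equal(cc0$r[1], -1, tolerance = 1e-9)
})

test_that("zero-variance input is rejected", {
  u <- normgrid_waveform(rep(1, 100), "arterial")
  v <- normgrid_waveform(rich_input(), "spinal")
  expect_error(cross_correlate(u, v), "zero-variance")
})

test_that("transmission delay is exact for every on-grid lag", {
  u <- rich_input()
  art <- normgrid_waveform(u, "arterial")
  for (k in c(0, 3, 15, 50, 99)) {
    csf <- normgrid_waveform(-circular_shift(u, k), "spinal")
    d <- transmission_delay(art, csf)
    expect_equal(d$delay_ms, k * 10, tolerance = 1e-6)
  }
})

test_that("constructed coupled pairs recover their lag exactly", {
  subj <- generate_coupled_subject(
    coupling_spec("young", spinal_lag_ms = 50, aqueduct_lag_ms = 150),
    heart_period_ms = 1000,
    noise_sd_ml_s = c(arterial = 0, spinal = 0, aqueduct = 0))
  na <- normalize_time(normalize_amplitude(subj$arterial, "systolic_average"))
  ns <- normalize_time(normalize_amplitude(subj$spinal, "cc_average"))
  nq <- normalize_time(normalize_amplitude(subj$aqueduct, "cc_average"))
  expect_equal(transmission_delay(na, ns)$delay_ms, 50, tolerance = 1e-6)
  expect_equal(transmission_delay(na, nq)$delay_ms, 150, tolerance = 1e-6)

  # brute-force oracle: the grid argmax over all 100 lags equals the lag
  cc <- cross_correlate(na, normgrid_waveform(-ns$flow, "spinal"))
  expect_equal(cc$lag_ms[which.max(cc$r)], 50)
})
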