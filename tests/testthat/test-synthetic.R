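test_that("a single-harmonic template evaluates to the closed-form sine", {
  tpl <- structure(list(compartment = "aqueduct", group = "young",
                        baseline = 0, amplitude = 1, phase = -pi / 2,
                        systole_ms = 330, scale_ml_s = 1),
                   class = "waveform_template")
  w <- generate_waveform(tpl, 1000)
  expect_equal(max(w$flow), 1, tolerance = 1e-12)
  expect_equal(w$time_ms[which.max(w$flow)], 250)
  expect_equal(w$flow, sin(2 * pi * w$time_ms / 1000), tolerance = 1e-12)
})

test_that("an all-zero template generates an identically zero waveform", {
  tpl <- structure(list(compartment = "aqueduct", group = "young",
                        baseline = 0, amplitude = c(0, 0, 0), phase = c(0, 0, 0),
                        systole_ms = 330, scale_ml_s = 1),
                   class = "waveform_template")
  expect_true(all(generate_waveform(tpl, 900)$flow == 0))
  empty <- tpl; empty$amplitude <- numeric(); empty$phase <- numeric()
  expect_error(generate_waveform(empty, 900), "empty template")
})

test_that("systolic samples are invariant to heart period", {
  tpl <- waveform_template("aqueduct", "young")
  w850 <- generate_waveform(tpl, 850)
  w1000 <- generate_waveform(tpl, 1000)
  sys_idx <- which(w850$time_ms < tpl$systole_ms)
  expect_identical(w850$flow[sys_idx], w1000$flow[sys_idx])
  expect_error(generate_waveform(tpl, 300), "500")
})

test_that("generation is bit-identical under a fixed seed", {
  tpl <- waveform_template("spinal", "elderly")
  w1 <- generate_waveform(tpl, 830, noise_sd = 0.05, seed = 77)
  w2 <- generate_waveform(tpl, 830, noise_sd = 0.05, seed = 77)
  expect_identical(w1$flow, w2$flow)

  s1 <- generate_coupled_subject(coupling_spec("young"), 910, seed = 5)
  s2 <- generate_coupled_subject(coupling_spec("young"), 910, seed = 5)
  expect_identical(s1$arterial$flow, s2$arterial$flow)
  expect_identical(s1$spinal$flow, s2$spinal$flow)
  expect_identical(s1$aqueduct$flow, s2$aqueduct$flow)

  c1 <- simulate_cohort(cohort_spec("young", n_subjects = 3, seed = 12))
  c2 <- simulate_cohort(cohort_spec("young", n_subjects = 3, seed = 12))
  expect_identical(c1$heart_period_ms, c2$heart_period_ms)
  expect_identical(c1$spinal[[2]]$flow, c2$spinal[[2]]$flow)
})

test_that("coupled subjects record their construction provenance", {
  s <- generate_coupled_subject(coupling_spec("elderly"), 900, seed = 2)
  prov <- attr(s$spinal, "provenance")
  expect_equal(prov$spinal_lag_ms, 34)
  expect_equal(prov$aqueduct_lag_ms, 132)
  expect_equal(prov$spinal_crossover_hz, 3.0)
  expect_equal(prov$aqueduct_crossover_hz, 0.5)
})

test_that("delay recovery is exact for arbitrary on-grid lags", {
  for (lags in list(c(50, 150), c(20, 310), c(0, 700))) {
    subj <- generate_coupled_subject(
      coupling_spec("elderly", spinal_lag_ms = lags[1],
                    aqueduct_lag_ms = lags[2]),
      heart_period_ms = 1000,
      noise_sd_ml_s = c(arterial = 0, spinal = 0, aqueduct = 0))
    na <- normalize_time(normalize_amplitude(subj$arterial, "systolic_average"))
    ns <- normalize_time(normalize_amplitude(subj$spinal, "cc_average"))
    nq <- normalize_time(normalize_amplitude(subj$aqueduct, "cc_average"))
    expect_equal(transmission_delay(na, ns)$delay_ms, lags[1], tolerance = 1e-6)
    expect_equal(transmission_delay(na, nq)$delay_ms, lags[2], tolerance = 1e-6)
  }
})

test_that("phantom synthesis wraps velocities like a scanner", {
  # peak true velocity 130 cm/s at venc 100 is stored as -70 cm/s
  w <- flow_waveform(seq(0, 990, 10), rep(1, 100), 1000,
                     compartment = "arterial")
  g <- geometry_spec(c(16, 16), radius_px = 4, pixel_mm = c(1, 1),
                     venc_cm_s = 100)
  # choose flow so that the centre-pixel velocity is 130 cm/s:
  # v_max = q * 100 / (area * sum(prof)); compute sum(prof) first
  ser0 <- synthesize_velocity_series(w, g, 24)
  peak_px <- which.max(ser0$phase[, , 1])
  q130 <- 130 / max(ser0$phase[, , 1])  # flow scaled so the peak pixel is 130
  w2 <- flow_waveform(seq(0, 990, 10), rep(q130, 100), 1000,
                      compartment = "arterial")
  ser <- synthesize_velocity_series(w2, g, 24)
  expect_equal(ser$phase[, , 1][peak_px], -70, tolerance = 1e-9)
})

test_that("ideal-mask integration reproduces the input waveform exactly", {
  tpl <- waveform_template("arterial", "young")
  w <- generate_waveform(tpl, 1000)
  g <- geometry_spec(c(24, 24), radius_px = 6, pixel_mm = c(0.8, 0.7),
                     venc_cm_s = 200)        # high venc: no wrapping
  ser <- synthesize_velocity_series(w, g, 40)
  xs <- matrix(rep(0:23, 24), 24, 24); ys <- t(xs)
  lum <- (xs - 11.5)^2 + (ys - 11.5)^2 <= 36
  mask <- structure(list(mask = array(lum, c(24, 24, 1)), per_frame = FALSE,
                         compartment = "arterial"),
                    class = "segmentation_mask")
  got <- compute_flow(ser, mask, 1000)
  truth <- approx(c(w$time_ms, 1000), c(w$flow, w$flow[1]),
                  xout = got$time_ms)$y
  expect_lt(max(abs(got$flow - truth)), 1e-6)
})

test_that("a lumen-free reference region reads back the background ramp", {
  w <- flow_waveform(seq(0, 990, 10), rep(0.5, 100), 1000,
                     compartment = "aqueduct")
  g <- geometry_spec(c(20, 20), radius_px = 4, pixel_mm = c(0.4, 0.4),
                     venc_cm_s = 15, background_ramp = c(0.8, 0, 0))
  ser <- synthesize_velocity_series(w, g, 24)
  ref <- ser$phase[1:4, 1:4, ]
  expect_equal(mean(ref), 0.8, tolerance = 1e-9)
})

test_that("frame counts outside the acquisition range are rejected", {
  w <- sine_waveform()
  g <- geometry_spec()
  expect_error(synthesize_velocity_series(w, g, 10), "22")
  expect_error(synthesize_velocity_series(w, g, 80), "64")
})

test_that("templates respect their invariants", {
  for (grp in c("young", "elderly")) for (comp in c("arterial", "spinal", "aqueduct")) {
    tpl <- waveform_template(comp, grp)
    expect_true(all(is.finite(tpl$amplitude)))
    expect_true(all(tpl$amplitude >= 0))
    expect_lt(tpl$systole_ms, 1000)
  }
  # young templates carry more relative high-harmonic energy than elderly
  hy <- waveform_template("arterial", "young")
  he <- waveform_template("arterial", "elderly")
  hi_frac <- function(t) sum(t$amplitude[4:10]^2) / sum(t$amplitude^2)
  expect_gt(hi_frac(hy), hi_frac(he))
})
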