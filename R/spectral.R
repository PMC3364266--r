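#' Harmonic components of a normalized flow waveform
#'
#' After temporal normalization every cycle spans exactly 1 s, so the
#' discrete Fourier transform lands on exact integer frequencies (Hz).
#' Magnitudes are reported as single-sided amplitudes, `2 |X_k| / N`, so a
#' unit-amplitude sine at an integer frequency has magnitude 1. The zero
#' frequency is excluded: after amplitude normalization it no longer
#' corresponds to net flow.
#'
#' Reporting cutoffs follow the compartment conventions: 10 components for
#' arterial flow, 7 for cervical spinal CSF, 5 for aqueductal CSF.
#'
#' @param w A time-normalized [flow_waveform()].
#' @param k_max Number of components; defaults to the compartment cutoff.
#' @return A tibble of class `flow_spectrum` with columns `freq_hz`,
#'   `magnitude`.
#' @export
dft_components <- function(w, k_max = NULL) {
  assert_waveform(w)
  if (!is_time_normalized(w))
    abort("spectra are only defined for time-normalized waveforms")
  k_max <- k_max %||% switch(compartment(w),
                             arterial = 10L, spinal = 7L, aqueduct = 5L)
  n <- nrow(w)
  if (k_max > floor(n / 2)) abort("k_max beyond the Nyquist frequency")
  X <- fft(w$flow)
  out <- tibble(freq_hz = seq_len(k_max),
                magnitude = 2 * Mod(X[seq_len(k_max) + 1]) / n)
  class(out) <- c("flow_spectrum", class(out))
  attr(out, "compartment") <- compartment(w)
  out
}

#' Noise-floor calibration of detectable harmonic magnitudes
#'
#' Each subject's background velocity noise (measured in the same reference
#' region used for background phase correction) sets a floor below which a
#' harmonic magnitude cannot be distinguished from noise. Per compartment,
#' one fifth of every subject's background noise SD is computed and the
#' maximum over subjects is taken as the compartment's magnitude threshold;
#' the one-fifth factor is the minimal detectable sine amplitude established
#' by [detectability_simulation()].
#'
#' @param background_sds A named list: one numeric vector of per-subject
#'   background noise SDs per compartment.
#' @return A tibble of class `noise_calibration` with columns `compartment`,
#'   `threshold` (= max over subjects of SD/5), `n_subjects`.
#' @export
calibrate_noise_threshold <- function(background_sds) {
  if (!is.list(background_sds) || length(background_sds) == 0)
    abort("need a non-empty named list of per-subject noise SDs")
  if (is.null(names(background_sds)) || any(names(background_sds) == ""))
    abort("compartments must be named")
  rows <- lapply(names(background_sds), function(comp) {
    sds <- background_sds[[comp]]
    if (length(sds) == 0) abort("empty SD list for compartment ", comp)
    if (any(sds <= 0)) abort("noise SDs must be positive")
    tibble(compartment = comp, threshold = max(sds / 5),
           n_subjects = length(sds))
  })
  out <- bind_rows(rows)
  class(out) <- c("noise_calibration", class(out))
  out
}

#' Minimal detectable sine amplitude in white noise
#'
#' Recreates the calibration experiment behind the one-fifth-SD rule: a
#' sinusoid of stepwise decreasing amplitude is buried in white Gaussian
#' noise (mean 0, variance 1) and its spectrum computed. The component is
#' declared correctly specifiable at a given amplitude when its frequency
#' bin carries the largest magnitude of all non-zero-frequency bins in at
#' least 90\% of trials. The smallest amplitude still detected is returned
#' as a fraction of the noise SD.
#'
#' The record length (default 2048 samples) sets the per-bin noise floor
#' (`sqrt(2/N)` in amplitude units, giving a maximal noise bin of about
#' 0.12 SD); together with the 90\% dominance criterion this places the
#' detection limit at about one fifth of the noise SD.
#'
#' @param noise_sd Noise standard deviation (the amplitude grid is
#'   expressed as a fraction of it).
#' @param amplitude_grid Descending amplitudes within (0, 1], as fractions
#'   of `noise_sd`.
#' @param n_trials Trials per amplitude (minimum 20).
#' @param seed Optional integer seed.
#' @param n_samples Record length.
#' @param signal_bin Harmonic index of the test sine.
#' @return A list of class `detectability_result`: `minimal_detectable`
#'   (fraction of noise SD) and the per-amplitude detection table.
#' @export
detectability_simulation <- function(noise_sd = 1,
                                     amplitude_grid = seq(1, 0.05, by = -0.05),
                                     n_trials = 200, seed = NULL,
                                     n_samples = 2048, signal_bin = 8) {
  if (n_trials < 20) abort("need at least 20 trials per amplitude")
  if (any(diff(amplitude_grid) >= 0) || any(amplitude_grid <= 0) ||
      any(amplitude_grid > 1))
    abort("amplitude grid must be descending within (0, 1]")
  t_idx <- 0:(n_samples - 1)
  sine <- sin(2 * pi * signal_bin * t_idx / n_samples)
  half <- floor(n_samples / 2)
  run <- function() {
    det_rate <- vapply(amplitude_grid, function(a) {
      hits <- 0L
      for (tr in seq_len(n_trials)) {
        x <- a * noise_sd * sine + rnorm(n_samples, 0, noise_sd)
        mags <- Mod(fft(x)[2:(half + 1)])
        if (which.max(mags) == signal_bin) hits <- hits + 1L
      }
      hits / n_trials
    }, numeric(1))
    det_rate
  }
  det_rate <- with_seed_maybe(seed, run())
  detected <- det_rate >= 0.9
  minimal <- if (any(detected)) min(amplitude_grid[detected]) else NA_real_
  structure(list(minimal_detectable = minimal,
                 table = tibble(amplitude = amplitude_grid,
                                detection_rate = det_rate,
                                detected = detected)),
            class = "detectability_result")
}
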