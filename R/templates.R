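#' Packaged waveform templates and coupling calibration
#'
#' The generator is parameterized by group-specific canonical waveforms and
#' a coupling specification. The canonical arterial cycles are defined by
#' anchor points (feature-point style landmarks joined by a shape-preserving
#' cubic), one set per age group: the young template has a taller, narrower
#' systolic peak; the elderly template a more pronounced late systolic peak,
#' reflecting stiffer arterial walls. CSF templates are derived from the
#' arterial template of the same group through the packaged coupling (a
#' low-pass harmonic-gain profile, a transmission lag, and a baseline),
#' so that running the analysis pipeline on default synthetic cohorts
#' recovers the packaged coupling parameters.
#'
#' All template amplitudes are synthetic calibration constants chosen for
#' qualitative realism, not digitized measurements.
#'
#' @name templates
NULL

# Canonical arterial anchor points (dimensionless units; scaled to mL/s by
# `scale_ml_s`). Times in ms on the nominal 1 s cycle.
.arterial_anchors <- list(
  young = list(
    time_ms = c(0, 40, 120, 210, 260, 330, 420, 600, 800, 1000),
    value   = c(1.05, 1.00, 2.80, 1.45, 1.65, 1.10, 1.25, 1.15, 1.08, 1.05),
    systole_ms = 330),
  elderly = list(
    time_ms = c(0, 50, 130, 230, 290, 360, 460, 650, 850, 1000),
    value   = c(1.10, 1.06, 2.30, 1.55, 1.90, 1.15, 1.30, 1.20, 1.12, 1.10),
    systole_ms = 360)
)

# Physical amplitude scales (mL/s per dimensionless template unit).
.compartment_scale <- c(arterial = 12, spinal = 0.8, aqueduct = 0.07)

# Coupling calibration: transmission lags and transfer crossovers are the
# packaged group values; `cutoff_hz` and `ac_scale` are the synthesis-filter
# shape constants calibrated so that the full pipeline, run on default
# cohorts, reproduces the lag and crossover values.
.coupling_defaults <- list(
  young = list(
    spinal_lag_ms = 55, aqueduct_lag_ms = 160,
    spinal_crossover_hz = 0.5, aqueduct_crossover_hz = 0.8,
    filter_order = 2,
    shape = list(spinal   = list(cutoff_hz = 1.0, ac_scale = 0.0756),
                 aqueduct = list(cutoff_hz = 1.0, ac_scale = 0.1059))),
  elderly = list(
    spinal_lag_ms = 34, aqueduct_lag_ms = 132,
    spinal_crossover_hz = 3.0, aqueduct_crossover_hz = 0.5,
    filter_order = 2,
    shape = list(spinal   = list(cutoff_hz = 1.2, ac_scale = 0.4627),
                 aqueduct = list(cutoff_hz = 1.0, ac_scale = 0.0472)))
)

#' Default coupling specification for a group
#'
#' Returns the packaged arterial-to-CSF coupling parameters: transmission
#' lags (ms), transfer-function crossover frequencies (Hz), the synthesis
#' filter order and the calibrated filter shape constants.
#'
#' @param group `"young"` or `"elderly"`.
#' @param spinal_lag_ms,aqueduct_lag_ms Optional overrides of the lags (ms,
#'   within `[0, 1000)`).
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(group = c("young", "elderly"),
                          spinal_lag_ms = NULL, aqueduct_lag_ms = NULL) {
  group <- arg_match(group)
  cs <- .coupling_defaults[[group]]
  if (!is.null(spinal_lag_ms)) cs$spinal_lag_ms <- spinal_lag_ms
  if (!is.null(aqueduct_lag_ms)) cs$aqueduct_lag_ms <- aqueduct_lag_ms
  for (lag in c(cs$spinal_lag_ms, cs$aqueduct_lag_ms))
    if (lag < 0 || lag >= .NOMINAL_MS) abort("lags must lie in [0, cycle length)")
  if (cs$spinal_crossover_hz <= 0 || cs$aqueduct_crossover_hz <= 0)
    abort("crossover frequencies must be positive")
  cs$group <- group
  structure(cs, class = "coupling_spec")
}

#' Cohort specification for the synthetic generator
#'
#' @param group `"young"` or `"elderly"`.
#' @param n_subjects Number of subjects (default 11 per group, the study
#'   group size).
#' @param heart_period_mean_ms,heart_period_sd_ms Heart-period distribution
#'   (defaults 831 and 169 ms); draws are truncated to `[500, 1200]` ms.
#' @param noise_sd_ml_s Named measurement-noise SDs (mL/s) per compartment.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("young", "elderly"), n_subjects = 11,
                        heart_period_mean_ms = 831, heart_period_sd_ms = 169,
                        noise_sd_ml_s = c(arterial = 0.36, spinal = 0.016,
                                          aqueduct = 0.0014),
                        seed = 1L) {
  group <- arg_match(group)
  if (n_subjects < 1) abort("need at least one subject")
  stopifnot(all(c("arterial", "spinal", "aqueduct") %in% names(noise_sd_ml_s)))
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 heart_period_mean_ms = heart_period_mean_ms,
                 heart_period_sd_ms = heart_period_sd_ms,
                 noise_sd_ml_s = noise_sd_ml_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Canonical arterial cycle (dimensionless) on the nominal 10 ms grid.
canonical_arterial <- function(group) {
  a <- .arterial_anchors[[group]]
  grid <- seq(0, .NOMINAL_MS - .DT_MS, by = .DT_MS)
  pracma::pchip(a$time_ms, a$value, grid)
}

# Low-pass harmonic gain profile of the synthesis filter.
coupling_gain <- function(f_hz, cutoff_hz, order) {
  (1 + (f_hz / cutoff_hz)^(2 * order))^(-1 / 2)
}

# Apply the coupling to an arterial cycle sampled on its native uniform
# grid: per harmonic, scale by the gain profile at that frequency, delay the
# phase by lag_ms, and negate (peak caudal CSF flow aligns with the arterial
# peak under the cranial-positive sign convention). Returns the dimensionless
# CSF cycle: unit baseline plus the AC part scaled to RMS `ac_scale`.
couple_cycle <- function(arterial_norm, lag_ms, cutoff_hz, order, ac_scale,
                         k_max = 10L) {
  n <- length(arterial_norm)
  period_s <- n * .DT_MS / 1000
  X <- fft(arterial_norm)
  t_s <- (seq_len(n) - 1) * .DT_MS / 1000
  ac <- numeric(n)
  for (k in seq_len(min(k_max, floor((n - 1) / 2)))) {
    fk <- k / period_s
    amp <- 2 * Mod(X[k + 1]) / n
    ph <- Arg(X[k + 1])
    ac <- ac - coupling_gain(fk, cutoff_hz, order) * amp *
      cos(2 * pi * fk * t_s + ph - 2 * pi * fk * lag_ms / 1000)
  }
  rms <- sqrt(mean((ac - mean(ac))^2))
  if (rms == 0) abort("degenerate arterial cycle: no pulsatile content")
  1 + ac_scale * ac / rms
}

#' Build a waveform template
#'
#' A template holds the harmonic parameterization (amplitudes and phases of
#' the first `k_max` harmonics of the 1 Hz-normalized cycle, plus a baseline
#' offset), the systole duration and the group label. Arterial templates are
#' built from the packaged anchor curves; CSF templates are derived from the
#' same group's arterial template through the packaged coupling.
#'
#' @param compartment `"arterial"`, `"spinal"` or `"aqueduct"`.
#' @param group `"young"` or `"elderly"`.
#' @param k_max Number of harmonics retained (default 10).
#' @param coupling Optional [coupling_spec()] override for CSF templates.
#' @return A list of class `waveform_template` with fields `compartment`,
#'   `group`, `baseline`, `amplitude`, `phase`, `systole_ms`, `scale_ml_s`.
#' @export
waveform_template <- function(compartment = c("arterial", "spinal", "aqueduct"),
                              group = c("young", "elderly"),
                              k_max = 10L, coupling = NULL) {
  compartment <- arg_match(compartment)
  group <- arg_match(group)
  if (k_max < 1) abort("k_max must be >= 1")
  u <- canonical_arterial(group)
  sys_ms <- .arterial_anchors[[group]]$systole_ms
  if (compartment == "arterial") {
    cyc <- u
  } else {
    cs <- coupling %||% coupling_spec(group)
    sh <- cs$shape[[compartment]]
    lag <- if (compartment == "spinal") cs$spinal_lag_ms else cs$aqueduct_lag_ms
    un <- u / mean(abs(u[seq_len(sys_ms / .DT_MS)]))
    cyc <- couple_cycle(un, lag, sh$cutoff_hz, cs$filter_order, sh$ac_scale)
  }
  X <- fft(cyc); n <- length(cyc)
  ks <- seq_len(k_max)
  structure(list(
    compartment = compartment, group = group,
    baseline = mean(cyc),
    amplitude = 2 * Mod(X[ks + 1]) / n,
    phase = Arg(X[ks + 1]),
    systole_ms = sys_ms,
    scale_ml_s = unname(.compartment_scale[compartment])
  ), class = "waveform_template")
}

#' @export
print.waveform_template <- function(x, ...) {
  cat(sprintf("<waveform_template: %s %s, %d harmonics, systole %d ms>\n",
              x$group, x$compartment, length(x$amplitude), x$systole_ms))
  invisible(x)
}

# Evaluate a template's canonical (nominal 1 s) cycle on the 10 ms grid,
# in dimensionless template units.
template_cycle <- function(template) {
  t_s <- seq(0, .NOMINAL_MS - .DT_MS, by = .DT_MS) / 1000
  v <- rep(template$baseline, length(t_s))
  for (k in seq_along(template$amplitude))
    v <- v + template$amplitude[k] *
      cos(2 * pi * k * t_s + template$phase[k])
  v
}
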