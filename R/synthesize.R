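#' Generate a single flow waveform from a template
#'
#' Evaluates the template's canonical 1 s cycle and adapts it to the
#' requested heart period the same way the heart adapts: systole keeps its
#' duration and shape regardless of heart rate, and all rate variation is
#' absorbed by the diastolic tail. A cycle shorter than nominal truncates
#' end-diastole; a longer one extends diastole linearly back to the
#' beginning-of-cycle value. White Gaussian measurement noise is added on
#' top.
#'
#' @param template A [waveform_template()].
#' @param heart_period_ms Cycle length in ms, within `[500, 1200]`.
#' @param noise_sd Measurement noise SD in mL/s (applied after physical
#'   scaling).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   waveforms.
#' @return A [flow_waveform()] in mL/s, sampled every 10 ms.
#' @export
#' @examples
#' w <- generate_waveform(waveform_template("aqueduct", "young"), 850)
generate_waveform <- function(template, heart_period_ms, noise_sd = 0,
                              seed = NULL) {
  if (!inherits(template, "waveform_template")) abort("not a waveform_template")
  if (length(template$amplitude) == 0) abort("empty template")
  if (heart_period_ms < 500 || heart_period_ms > 1200)
    abort("heart period must lie within [500, 1200] ms")
  cyc <- template_cycle(template) * template$scale_ml_s
  v <- adapt_cycle_period(cyc, heart_period_ms)
  if (noise_sd > 0) {
    v <- v + with_seed_maybe(seed, rnorm(length(v), 0, noise_sd))
  } else if (!is.null(seed)) {
    # keep the RNG contract: same seed, same stream consumed
    invisible(with_seed_maybe(seed, NULL))
  }
  flow_waveform(seq(0, length(v) * .DT_MS - .DT_MS, by = .DT_MS), v,
                heart_period_ms = round(heart_period_ms / .DT_MS) * .DT_MS,
                systole_end_ms = template$systole_ms,
                compartment = template$compartment,
                provenance = list(group = template$group,
                                  heart_period_ms = heart_period_ms,
                                  noise_sd = noise_sd, seed = seed))
}

# Adapt a canonical nominal-length cycle (10 ms grid) to a heart period:
# truncate end-diastole or extend it linearly back to the first value.
adapt_cycle_period <- function(cyc, heart_period_ms) {
  n_nom <- length(cyc)
  n <- round(heart_period_ms / .DT_MS)
  if (n <= n_nom) return(cyc[seq_len(n)])
  t_extra <- seq(n_nom * .DT_MS, (n - 1) * .DT_MS, by = .DT_MS)
  t_last <- (n_nom - 1) * .DT_MS
  v_ext <- cyc[n_nom] + (cyc[1] - cyc[n_nom]) *
    (t_extra - t_last) / (n * .DT_MS - t_last)
  c(cyc, v_ext)
}

with_seed_maybe <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) return(eval.parent(expr))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   eval(expr, envir = parent.frame()))
}

#' Generate one subject's coupled arterial and CSF waveforms
#'
#' The arterial waveform is generated from the group's arterial template at
#' the subject's heart period. The spinal and aqueductal waveforms are then
#' built from that (noise-free) arterial cycle: each harmonic is scaled by a
#' stable low-pass gain profile with the coupling's crossover calibration,
#' circularly delayed by the coupling lag, negated into the cranial-positive
#' convention and placed on a unit baseline; compartment-specific amplitude
#' scaling and measurement noise are applied last. Construction parameters
#' are recorded in each waveform's provenance.
#'
#' @param coupling A [coupling_spec()].
#' @param heart_period_ms Cycle length (ms) within `[500, 1200]`.
#' @param noise_sd_ml_s Named vector of per-compartment noise SDs (mL/s).
#' @param seed Optional integer seed (same seed, identical triplet).
#' @param group Group label, defaults to the coupling's group.
#' @return A named list of three [flow_waveform()]s:
#'   `arterial`, `spinal`, `aqueduct`.
#' @export
generate_coupled_subject <- function(coupling = coupling_spec("young"),
                                     heart_period_ms = 831,
                                     noise_sd_ml_s = c(arterial = 0.36,
                                                       spinal = 0.016,
                                                       aqueduct = 0.0014),
                                     seed = NULL, group = NULL) {
  if (!inherits(coupling, "coupling_spec")) abort("not a coupling_spec")
  group <- group %||% coupling$group
  if (heart_period_ms < 500 || heart_period_ms > 1200)
    abort("heart period must lie within [500, 1200] ms")
  sys_ms <- .arterial_anchors[[group]]$systole_ms
  cyc <- canonical_arterial(group)
  art_clean <- adapt_cycle_period(cyc, heart_period_ms)
  n <- length(art_clean)
  un <- art_clean / mean(abs(art_clean[seq_len(min(n, sys_ms / .DT_MS))]))

  csf_clean <- lapply(c(spinal = "spinal", aqueduct = "aqueduct"), function(comp) {
    sh <- coupling$shape[[comp]]
    lag <- if (comp == "spinal") coupling$spinal_lag_ms else coupling$aqueduct_lag_ms
    couple_cycle(un, lag, sh$cutoff_hz, coupling$filter_order, sh$ac_scale)
  })

  noise <- with_seed_maybe(seed, list(
    arterial = rnorm(n, 0, noise_sd_ml_s[["arterial"]]),
    spinal = rnorm(n, 0, noise_sd_ml_s[["spinal"]]),
    aqueduct = rnorm(n, 0, noise_sd_ml_s[["aqueduct"]])))

  t_ms <- seq(0, (n - 1) * .DT_MS, by = .DT_MS)
  period <- round(heart_period_ms / .DT_MS) * .DT_MS
  prov <- list(group = group,
               spinal_lag_ms = coupling$spinal_lag_ms,
               aqueduct_lag_ms = coupling$aqueduct_lag_ms,
               spinal_crossover_hz = coupling$spinal_crossover_hz,
               aqueduct_crossover_hz = coupling$aqueduct_crossover_hz,
               heart_period_ms = heart_period_ms, seed = seed)

  list(
    arterial = flow_waveform(
      t_ms, art_clean * .compartment_scale[["arterial"]] + noise$arterial,
      period, sys_ms, "arterial", provenance = prov),
    spinal = flow_waveform(
      t_ms, csf_clean$spinal * .compartment_scale[["spinal"]] + noise$spinal,
      period, sys_ms, "spinal", provenance = prov),
    aqueduct = flow_waveform(
      t_ms, csf_clean$aqueduct * .compartment_scale[["aqueduct"]] + noise$aqueduct,
      period, sys_ms, "aqueduct", provenance = prov)
  )
}

#' Simulate a synthetic cohort
#'
#' Draws subject heart periods from the cohort's heart-period distribution
#' (truncated to `[500, 1200]` ms), assigns demographics, and generates the
#' coupled waveform triplet for every subject with the group's packaged
#' coupling.
#'
#' @param spec A [cohort_spec()].
#' @param coupling Optional [coupling_spec()] overriding the group default.
#' @return A tibble with one row per subject: `id`, `group`, `sex`, `age`,
#'   `heart_period_ms`, and list-columns `arterial`, `spinal`, `aqueduct`
#'   holding [flow_waveform()]s.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec("young", n_subjects = 2, seed = 7))
simulate_cohort <- function(spec = cohort_spec("young"), coupling = NULL) {
  if (!inherits(spec, "cohort_spec")) abort("not a cohort_spec")
  cs <- coupling %||% coupling_spec(spec$group)
  age_range <- if (spec$group == "young") c(21, 29) else c(64, 81)
  draws <- with_seed_maybe(spec$seed, list(
    hp = pmin(pmax(rnorm(spec$n_subjects, spec$heart_period_mean_ms,
                         spec$heart_period_sd_ms), 500), 1200),
    age = round(runif(spec$n_subjects, age_range[1], age_range[2])),
    sex = sample(rep_len(c("f", "m"), spec$n_subjects)),
    subseed = sample.int(.Machine$integer.max - 1L, spec$n_subjects)))
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    generate_coupled_subject(cs, draws$hp[i], spec$noise_sd_ml_s,
                             seed = draws$subseed[i]))
  tibble(
    id = sprintf("%s%02d", substr(spec$group, 1, 1), seq_len(spec$n_subjects)),
    group = spec$group,
    sex = draws$sex,
    age = draws$age,
    heart_period_ms = round(draws$hp / .DT_MS) * .DT_MS,
    arterial = lapply(subjects, `[[`, "arterial"),
    spinal = lapply(subjects, `[[`, "spinal"),
    aqueduct = lapply(subjects, `[[`, "aqueduct")
  )
}
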