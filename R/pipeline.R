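#' Pipeline configuration
#'
#' Collects the settings of the end-to-end analysis: the nominal cycle and
#' resampling interval of the temporal normalization, the transfer-function
#' order, encoding velocities per compartment, harmonic reporting cutoffs,
#' the Bode evaluation band per compartment (bounded by the noise-limit
#' frequencies), and the clinical reference thresholds for aqueductal
#' stroke volume (42 µL) and average flow rate (18 mL/min).
#'
#' @param nominal_ms Nominal cardiac-cycle length (ms).
#' @param dt_ms Resampling interval (ms); must divide `nominal_ms`.
#' @param tf_order Transfer-function model order.
#' @param venc_cm_s Encoding velocities per compartment.
#' @param n_components Harmonic reporting cutoffs per compartment.
#' @param noise_limit_hz Upper Bode evaluation frequency per CSF compartment.
#' @param stroke_volume_ul_threshold,avg_flow_ml_min_threshold Clinical
#'   reference thresholds.
#' @param seed Master seed for the simulation-backed stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(nominal_ms = 1000, dt_ms = 10, tf_order = 5,
                            venc_cm_s = c(arterial = 100, spinal = 12,
                                          aqueduct = 15),
                            n_components = c(arterial = 10, spinal = 7,
                                             aqueduct = 5),
                            noise_limit_hz = c(spinal = 7, aqueduct = 5),
                            stroke_volume_ul_threshold = 42,
                            avg_flow_ml_min_threshold = 18,
                            seed = 1L) {
  if (nominal_ms %% dt_ms != 0) abort("dt_ms must divide nominal_ms")
  if (tf_order < 1) abort("tf_order must be >= 1")
  structure(list(nominal_ms = nominal_ms, dt_ms = dt_ms, tf_order = tf_order,
                 venc_cm_s = venc_cm_s, n_components = n_components,
                 noise_limit_hz = noise_limit_hz,
                 stroke_volume_ul_threshold = stroke_volume_ul_threshold,
                 avg_flow_ml_min_threshold = avg_flow_ml_min_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-subject waveform analysis
#'
#' Runs the waveform stages for one subject: scalar metrics on the raw
#' cycles, amplitude normalization (systolic average for arterial,
#' cycle average for CSF), temporal normalization, spectra, transfer
#' functions, crossover frequencies and transmission delays.
#'
#' @param arterial,spinal,aqueduct [flow_waveform()]s of one subject.
#' @param config A [pipeline_config()].
#' @return A list with `metrics` (one-row tibble), `normalized` (list of
#'   the three normalized waveforms), `spectra`, `tf` (list of `tf_model`),
#'   `bode` curves, `crossover` and `delays` tibbles.
#' @export
analyze_subject <- function(arterial, spinal, aqueduct,
                            config = pipeline_config()) {
  metrics <- tibble(
    aqueduct_stroke_volume_ul = stroke_volume(aqueduct),
    aqueduct_avg_flow_ml_min = average_flow_rate(aqueduct),
    spinal_avg_flow_ml_min = average_flow_rate(spinal),
    arterial_avg_systolic_flow_ml_min =
      mean(abs(arterial$flow[arterial$time_ms < systole_end(arterial)])) * 60,
    heart_period_ms = heart_period(arterial))
  metrics$stroke_volume_above_threshold <-
    metrics$aqueduct_stroke_volume_ul > config$stroke_volume_ul_threshold
  metrics$avg_flow_above_threshold <-
    metrics$aqueduct_avg_flow_ml_min > config$avg_flow_ml_min_threshold

  norm <- list(
    arterial = normalize_time(normalize_amplitude(arterial, "systolic_average")),
    spinal = normalize_time(normalize_amplitude(spinal, "cc_average")),
    aqueduct = normalize_time(normalize_amplitude(aqueduct, "cc_average")))

  spectra <- lapply(norm, dft_components)

  tf <- list(
    spinal = identify_tf(norm$arterial, norm$spinal, config$tf_order),
    aqueduct = identify_tf(norm$arterial, norm$aqueduct, config$tf_order))
  bode_curves <- list(
    spinal = bode(tf$spinal,
                  seq(0.05, config$noise_limit_hz[["spinal"]], by = 0.05),
                  config$noise_limit_hz[["spinal"]]),
    aqueduct = bode(tf$aqueduct,
                    seq(0.05, config$noise_limit_hz[["aqueduct"]], by = 0.05),
                    config$noise_limit_hz[["aqueduct"]]))
  crossover <- tibble(
    compartment = c("spinal", "aqueduct"),
    crossover_hz = c(as.numeric(crossover_frequency(bode_curves$spinal)),
                     as.numeric(crossover_frequency(bode_curves$aqueduct))),
    tf_stable = c(all(Mod(tf_poles(tf$spinal)) < 1),
                  all(Mod(tf_poles(tf$aqueduct)) < 1)),
    tf_vaf = c(tf$spinal$vaf, tf$aqueduct$vaf))
  delays <- bind_rows(
    mutate(transmission_delay(norm$arterial, norm$spinal),
           compartment = "spinal"),
    mutate(transmission_delay(norm$arterial, norm$aqueduct),
           compartment = "aqueduct"))

  list(metrics = metrics, normalized = norm, spectra = spectra, tf = tf,
       bode = bode_curves, crossover = crossover, delays = delays)
}

#' Image-domain flow extraction for one compartment
#'
#' Runs the image stages on a velocity series: temporal unwrapping,
#' segmentation (per-frame magnitude thresholding for arteries, single
#' reference frame for the aqueduct, frequency-domain for the spinal
#' canal), rim-based quality control with iterative threshold refinement,
#' background phase correction, and flow integration.
#'
#' @param series A [velocity_series()].
#' @param roi A [roi_polygon()] around the lumen.
#' @param heart_period_ms Cycle length of the acquisition.
#' @param background_region Rectangle `c(x0, x1, y0, y1)` for background
#'   correction; contour mode is used when `NULL` (spinal convention).
#' @return A list: `waveform` ([flow_waveform()]), `mask`, `rim_report`,
#'   `background_offset_cm_s`.
#' @export
extract_flow <- function(series, roi, heart_period_ms,
                         background_region = NULL) {
  assert_series(series)
  series <- unwrap_velocity(series)
  comp <- series$compartment
  if (comp == "spinal") {
    # iterate the pulsatile-energy threshold under rim control, as for the
    # magnitude-based masks
    scale <- 1
    for (i in 1:10) {
      mask <- segment_spinal_frequency(series, roi, scale)
      rim <- rim_check(series, mask)
      if (all(rim$pass)) break
      scale <- scale * if (rim$suggestion[1] == "grow") 0.95 else 1.05
    }
  } else {
    mask <- switch(comp,
      arterial = refine_segmentation(series, roi, "per_frame"),
      aqueduct = refine_segmentation(series, roi, "single_frame"))
    rim <- attr(mask, "rim_report")
  }
  series <- correct_background(
    series, mask,
    reference = if (is.null(background_region)) "contour" else "rectangle",
    region = background_region)
  w <- compute_flow(series, mask, heart_period_ms)
  w <- wf_update_compartment(w, comp)
  list(waveform = w, mask = mask, rim_report = rim,
       background_offset_cm_s = attr(series, "background_offset_cm_s"))
}

# internal: retag compartment and systole marker after image extraction
wf_update_compartment <- function(w, comp, systole_ms = NULL) {
  flow_waveform(w$time_ms, w$flow, heart_period(w),
                systole_end_ms = systole_ms %||% systole_end(w),
                compartment = comp)
}

#' Run the end-to-end cohort pipeline
#'
#' Simulates (or accepts) young and elderly cohorts, optionally passes every
#' subject's waveforms through the image domain (phantom synthesis,
#' segmentation, flow integration), analyzes each subject, and aggregates
#' group-level results: mean transmission delays, group-average Bode gain
#' curves with their crossover frequencies, per-component spectra, clinical
#' flags, and between-group statistics. Group gain curves are the pointwise
#' median of the subject curves, which is robust to occasional poorly
#' conditioned subject fits.
#'
#' @param config A [pipeline_config()].
#' @param cohorts A named list of cohort tibbles from [simulate_cohort()];
#'   by default young and elderly cohorts of 11 subjects are simulated with
#'   the packaged calibration and the config seed.
#' @param through_images If `TRUE`, every waveform is first rendered into a
#'   phase-contrast phantom and re-extracted through segmentation and flow
#'   integration before analysis.
#' @param image_frames Number of cardiac phases for the phantom stage.
#' @return A list of class `csfpulse_report`: `subjects` (per-subject
#'   metrics tibble), `delays`, `crossovers`, `group_gain`, `spectra`,
#'   `stats`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohorts = NULL,
                         through_images = FALSE, image_frames = 32) {
  log <- list()
  note <- function(...) log[[length(log) + 1]] <<- sprintf(...)

  if (is.null(cohorts)) {
    cohorts <- list(
      young = simulate_cohort(cohort_spec("young", seed = config$seed)),
      elderly = simulate_cohort(cohort_spec("elderly", seed = config$seed + 1L)))
    note("simulated default cohorts (seed %d)", config$seed)
  }
  if (length(cohorts) == 0) abort("empty input set")

  subj_rows <- list(); delay_rows <- list(); cross_rows <- list()
  gain_curves <- list(); spectra_rows <- list()

  for (gname in names(cohorts)) {
    coh <- cohorts[[gname]]
    if (nrow(coh) == 0) abort("empty cohort: ", gname)
    for (i in seq_len(nrow(coh))) {
      wfs <- list(arterial = coh$arterial[[i]], spinal = coh$spinal[[i]],
                  aqueduct = coh$aqueduct[[i]])
      if (through_images) {
        wfs <- reextract_through_images(wfs, config, image_frames,
                                        seed = config$seed * 1000L + i)
        note("%s/%s: image-domain re-extraction done", gname, coh$id[i])
      }
      an <- analyze_subject(wfs$arterial, wfs$spinal, wfs$aqueduct, config)
      subj_rows[[length(subj_rows) + 1]] <-
        mutate(an$metrics, id = coh$id[i], group = gname, .before = 1)
      delay_rows[[length(delay_rows) + 1]] <-
        mutate(an$delays, id = coh$id[i], group = gname, .before = 1)
      cross_rows[[length(cross_rows) + 1]] <-
        mutate(an$crossover, id = coh$id[i], group = gname, .before = 1)
      for (comp in c("spinal", "aqueduct"))
        gain_curves[[length(gain_curves) + 1]] <-
          tibble(group = gname, id = coh$id[i], compartment = comp,
                 freq_hz = an$bode[[comp]]$freq_hz,
                 gain = an$bode[[comp]]$gain)
      for (comp in names(an$spectra))
        spectra_rows[[length(spectra_rows) + 1]] <-
          mutate(an$spectra[[comp]], id = coh$id[i], group = gname,
                 compartment = comp, .before = 1)
    }
    note("analyzed %d subjects in cohort %s", nrow(coh), gname)
  }

  subjects <- bind_rows(subj_rows)
  delays <- bind_rows(delay_rows)
  crossovers <- bind_rows(cross_rows)
  gains <- bind_rows(gain_curves)
  spectra <- bind_rows(spectra_rows)

  group_delays <- delays |>
    group_by(.data$group, .data$compartment) |>
    summarise(mean_delay_ms = mean(.data$delay_ms),
              sd_delay_ms = sd(.data$delay_ms), .groups = "drop")
  group_gain <- gains |>
    group_by(.data$group, .data$compartment, .data$freq_hz) |>
    summarise(gain = median(.data$gain), .groups = "drop")
  group_cross <- crossovers |>
    group_by(.data$group, .data$compartment) |>
    summarise(crossover_hz = mean(.data$crossover_hz, na.rm = TRUE),
              n_defined = sum(!is.na(.data$crossover_hz)), .groups = "drop")

  stats <- cohort_statistics(delays, spectra, names(cohorts))
  note("group statistics computed")

  structure(list(subjects = subjects, delays = delays,
                 group_delays = group_delays,
                 crossovers = crossovers, group_gain = group_gain,
                 group_crossover = group_cross, spectra = spectra,
                 stats = stats, config = config,
                 log = unlist(log)),
            class = "csfpulse_report")
}

# unity downward crossing of a gain curve given as vectors
crossing_of <- function(f, g) {
  for (i in seq_along(g)[-1])
    if (g[i - 1] >= 1 && g[i] < 1)
      return(f[i - 1] + (f[i] - f[i - 1]) * (g[i - 1] - 1) / (g[i - 1] - g[i]))
  NA_real_
}

# render waveforms into phantoms and re-extract them through the image stages
reextract_through_images <- function(wfs, config, image_frames, seed) {
  out <- list()
  geoms <- list(
    arterial = geometry_spec(c(28, 28), radius_px = 5, pixel_mm = c(0.8, 0.7),
                             venc_cm_s = config$venc_cm_s[["arterial"]],
                             background_ramp = c(0.4, 0, 0)),
    spinal = geometry_spec(c(28, 28), radius_px = 6, pixel_mm = c(0.8, 0.7),
                           venc_cm_s = config$venc_cm_s[["spinal"]],
                           background_ramp = c(0.05, 0, 0)),
    aqueduct = geometry_spec(c(28, 28), radius_px = 4, pixel_mm = c(0.4, 0.4),
                             venc_cm_s = config$venc_cm_s[["aqueduct"]],
                             background_ramp = c(0.1, 0, 0)))
  noise <- c(arterial = 0.5, spinal = 0.05, aqueduct = 0.05)
  for (comp in names(wfs)) {
    w <- wfs[[comp]]
    ser <- synthesize_velocity_series(w, geoms[[comp]], image_frames,
                                      noise_sd_cm_s = noise[[comp]],
                                      seed = seed + match(comp, names(wfs)))
    roi <- roi_polygon(c(6, 21, 21, 6), c(6, 6, 21, 21))
    ex <- extract_flow(ser, roi, heart_period(w),
                       background_region = if (comp != "spinal") c(0, 4, 0, 4))
    out[[comp]] <- wf_update_compartment(ex$waveform, comp,
                                         systole_ms = systole_end(w))
  }
  out
}

# between-group statistics on delays and spectra
cohort_statistics <- function(delays, spectra, group_names) {
  if (length(group_names) < 2) return(tibble())
  g1 <- group_names[1]; g2 <- group_names[2]
  rows <- list()
  for (comp in unique(delays$compartment)) {
    x <- delays$delay_ms[delays$group == g1 & delays$compartment == comp]
    y <- delays$delay_ms[delays$group == g2 & delays$compartment == comp]
    mw <- mann_whitney(x, y)
    rows[[length(rows) + 1]] <- mutate(mw, test = "mann_whitney",
                                       variable = paste0("delay_", comp),
                                       .before = 1)
  }
  for (comp in unique(spectra$compartment)) {
    sp <- spectra[spectra$compartment == comp, ]
    wide <- tidyr::pivot_wider(sp[, c("id", "group", "freq_hz", "magnitude")],
                               names_from = "freq_hz",
                               values_from = "magnitude")
    m <- as.matrix(wide[, -(1:2)])
    res <- rm_anova_gg(m, wide$group)
    rows[[length(rows) + 1]] <- tibble(
      test = "rm_anova_gg", variable = paste0("spectrum_", comp),
      statistic = res$statistic[res$effect == "measure:group"],
      p_value = res$p_value[res$effect == "measure:group"],
      method = sprintf("epsilon=%.3f", res$epsilon[2]),
      significant = res$significant[res$effect == "measure:group"])
  }
  bind_rows(rows)
}

#' @export
print.csfpulse_report <- function(x, ...) {
  cat("<csfpulse_report>\n")
  cat(sprintf("  subjects: %d\n", nrow(x$subjects)))
  cat("  group mean delays (ms):\n")
  print(as.data.frame(x$group_delays), row.names = FALSE)
  cat("  group crossover frequencies (Hz):\n")
  print(as.data.frame(x$group_crossover), row.names = FALSE)
  invisible(x)
}
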