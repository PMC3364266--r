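#' Read and write flow waveforms as delimited text
#'
#' Waveforms are stored as tab-separated tables with columns `time_ms` and
#' `flow_ml_s`, preceded by `#`-prefixed header lines carrying the
#' metadata (units, heart period, systole end, compartment, normalization
#' state). The round trip is lossless.
#'
#' @param w A [flow_waveform()].
#' @param path File path.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns the [flow_waveform()].
#' @export
write_waveform <- function(w, path) {
  assert_waveform(w)
  hdr <- c(
    "# csfpulse flow waveform",
    "# units: time_ms, flow_ml_s",
    sprintf("# heart_period_ms: %.10g", heart_period(w)),
    sprintf("# systole_end_ms: %s",
            if (is.null(systole_end(w))) "NA" else sprintf("%.10g", systole_end(w))),
    sprintf("# compartment: %s", compartment(w)),
    sprintf("# amp_norm: %s", amp_norm_state(w)),
    sprintf("# time_normalized: %s", is_time_normalized(w)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_ms\tflow_ml_s", con)
  writeLines(sprintf("%.17g\t%.17g", w$time_ms, w$flow), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(m)) abort(sprintf("malformed header: missing '%s'", key))
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  if (!any(grepl("^# units: time_ms, flow_ml_s", hdr)))
    abort("malformed header: missing units line (expected time_ms, flow_ml_s)")
  body <- lines[!grepl("^#", lines)]
  if (body[1] != "time_ms\tflow_ml_s") abort("malformed column header")
  dat <- utils::read.table(text = body[-1], sep = "\t",
                           col.names = c("time_ms", "flow_ml_s"))
  if (any(diff(dat$time_ms) <= 0))
    abort("time column is not strictly increasing")
  send <- get("systole_end_ms")
  flow_waveform(dat$time_ms, dat$flow_ml_s,
                heart_period_ms = as.numeric(get("heart_period_ms")),
                systole_end_ms = if (send == "NA") NULL else as.numeric(send),
                compartment = get("compartment"),
                amp_norm = get("amp_norm"),
                time_normalized = get("time_normalized") == "TRUE")
}

#' Read and write velocity image series (NIfTI + JSON sidecar)
#'
#' The phase and magnitude stacks are written as NIfTI volumes (frames
#' along the third axis) with a JSON sidecar holding `venc_cm_s`,
#' `pixel_mm`, `frame_times_ms` and `compartment`. `path_stem` is extended
#' with `_phase.nii`, `_mag.nii` and `.json`.
#'
#' @param series A [velocity_series()].
#' @param path_stem Path without extension.
#' @return `write_velocity_series()` returns `path_stem` invisibly;
#'   `read_velocity_series()` returns the [velocity_series()].
#' @export
write_velocity_series <- function(series, path_stem) {
  assert_series(series)
  RNifti::writeNifti(series$phase, paste0(path_stem, "_phase.nii"))
  RNifti::writeNifti(series$magnitude, paste0(path_stem, "_mag.nii"))
  sidecar <- list(venc_cm_s = series$venc_cm_s,
                  pixel_mm = series$pixel_mm,
                  frame_times_ms = series$frame_times_ms,
                  compartment = series$compartment)
  jsonlite::write_json(sidecar, paste0(path_stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_stem)
}

#' @rdname write_velocity_series
#' @export
read_velocity_series <- function(path_stem) {
  sc_path <- paste0(path_stem, ".json")
  if (!file.exists(sc_path)) abort("sidecar JSON not found")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (key in c("venc_cm_s", "pixel_mm", "frame_times_ms", "compartment"))
    if (is.null(sc[[key]])) abort(sprintf("sidecar missing '%s'", key))
  ph <- array(as.numeric(RNifti::readNifti(paste0(path_stem, "_phase.nii"))),
              dim = dim(RNifti::readNifti(paste0(path_stem, "_phase.nii"))))
  mg <- array(as.numeric(RNifti::readNifti(paste0(path_stem, "_mag.nii"))),
              dim = dim(RNifti::readNifti(paste0(path_stem, "_mag.nii"))))
  if (dim(ph)[3] != length(sc$frame_times_ms))
    abort("frame-count mismatch between stack and sidecar")
  velocity_series(ph, mg, sc$venc_cm_s, sc$pixel_mm, sc$frame_times_ms,
                  sc$compartment)
}

#' Write a provenance record
#'
#' @param x A list of construction parameters (as stored in a waveform's
#'   provenance attribute).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
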