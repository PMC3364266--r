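#' Velocity image series
#'
#' Container for a cardiac-gated 2D phase-contrast acquisition: a stack of
#' phase frames holding velocities (cm/s, within `(-venc, +venc]`) and the
#' corresponding magnitude frames, plus geometry and timing metadata.
#'
#' @param phase,magnitude Numeric arrays `nx x ny x n_frames`.
#' @param venc_cm_s Encoding velocity (cm/s): the velocity mapped to +/- pi
#'   of phase; true velocities beyond it wrap around.
#' @param pixel_mm Pixel dimensions `c(dx, dy)` in mm.
#' @param frame_times_ms Strictly increasing frame times (ms from R-wave).
#' @param compartment Compartment label.
#' @return A list of class `velocity_series`.
#' @export
velocity_series <- function(phase, magnitude, venc_cm_s, pixel_mm,
                            frame_times_ms,
                            compartment = c("arterial", "spinal", "aqueduct")) {
  compartment <- arg_match(compartment)
  if (!is.array(phase) || length(dim(phase)) != 3L)
    abort("`phase` must be an nx x ny x n_frames array")
  if (!identical(dim(phase), dim(magnitude)))
    abort("phase and magnitude stacks must have identical dimensions")
  if (dim(phase)[3] != length(frame_times_ms))
    abort("frame count and frame_times_ms length differ")
  if (any(diff(frame_times_ms) <= 0)) abort("frame times must be strictly increasing")
  if (is.null(venc_cm_s) || !is.finite(venc_cm_s) || venc_cm_s <= 0)
    abort("venc must be a positive number")
  if (any(pixel_mm <= 0)) abort("pixel dimensions must be positive")
  structure(list(phase = phase, magnitude = magnitude,
                 venc_cm_s = venc_cm_s, pixel_mm = as.numeric(pixel_mm),
                 frame_times_ms = as.numeric(frame_times_ms),
                 compartment = compartment),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<velocity_series: %s, %dx%d px, %d frames, venc %g cm/s>\n",
              x$compartment, d[1], d[2], d[3], x$venc_cm_s))
  invisible(x)
}

#' Acquisition geometry for the velocity phantom
#'
#' @param grid_size Image size in pixels `c(nx, ny)`.
#' @param center Lumen centre (pixels, 0-based, `c(x, y)`).
#' @param radius_px Lumen radius in pixels (scalar, or one per frame).
#' @param pixel_mm Pixel dimensions `c(dx, dy)` in mm.
#' @param venc_cm_s Encoding velocity (cm/s).
#' @param background_ramp Planar background velocity offset coefficients
#'   `c(c0, cx, cy)` (cm/s, cm/s per px): the offset at pixel `(x, y)` is
#'   `c0 + cx * x + cy * y`.
#' @param magnitude_levels Background and lumen magnitude intensity
#'   `c(background, lumen)`.
#' @return A list of class `geometry_spec`.
#' @export
geometry_spec <- function(grid_size = c(32, 32), center = NULL, radius_px = 6,
                          pixel_mm = c(0.8, 0.7), venc_cm_s = 100,
                          background_ramp = c(0, 0, 0),
                          magnitude_levels = c(60, 400)) {
  center <- center %||% (grid_size - 1) / 2
  if (any(pixel_mm <= 0)) abort("pixel dimensions must be positive")
  if (venc_cm_s <= 0) abort("venc must be positive")
  if (any(center - max(radius_px) < 0) ||
      any(center + max(radius_px) > grid_size - 1))
    abort("lumen must lie entirely inside the image grid")
  structure(list(grid_size = as.integer(grid_size), center = center,
                 radius_px = radius_px, pixel_mm = as.numeric(pixel_mm),
                 venc_cm_s = venc_cm_s, background_ramp = background_ramp,
                 magnitude_levels = magnitude_levels),
            class = "geometry_spec")
}

# wrap velocities into (-venc, venc]
wrap_velocity <- function(v, venc) {
  w <- (v + venc) %% (2 * venc) - venc
  w[w == -venc] <- venc
  w
}

#' Synthesize a phase-contrast velocity series from a flow waveform
#'
#' Builds a phantom acquisition: a circular lumen with a parabolic (fully
#' developed laminar) velocity profile whose mask-integrated flow equals the
#' waveform exactly at every frame, a planar background phase offset, white
#' velocity noise, and velocity wrapping into `(-venc, +venc]` exactly as a
#' scanner stores aliased velocities. Magnitude frames show lumen/background
#' contrast suitable for thresholding.
#'
#' @param waveform A [flow_waveform()] (mL/s).
#' @param geometry A [geometry_spec()].
#' @param n_frames Number of cardiac phases (22 to 64); the waveform is
#'   sampled at the frame times by linear interpolation.
#' @param noise_sd_cm_s Velocity noise SD (cm/s).
#' @param seed Optional integer seed.
#' @return A [velocity_series()].
#' @export
synthesize_velocity_series <- function(waveform, geometry, n_frames = 32,
                                       noise_sd_cm_s = 0, seed = NULL) {
  assert_waveform(waveform)
  if (!inherits(geometry, "geometry_spec")) abort("not a geometry_spec")
  if (n_frames < 22 || n_frames > 64)
    abort("n_frames must lie within [22, 64]")
  period <- heart_period(waveform)
  ft <- seq(0, period - period / n_frames, length.out = n_frames)
  q <- approx(c(waveform$time_ms, period), c(waveform$flow, waveform$flow[1]),
              xout = ft)$y                         # mL/s at frame times
  g <- geometry
  nx <- g$grid_size[1]; ny <- g$grid_size[2]
  xs <- matrix(rep(0:(nx - 1), ny), nx, ny)
  ys <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  radii <- rep_len(g$radius_px, n_frames)
  px_area_mm2 <- g$pixel_mm[1] * g$pixel_mm[2]
  ramp <- g$background_ramp[1] + g$background_ramp[2] * xs + g$background_ramp[3] * ys

  noise <- if (noise_sd_cm_s > 0)
    with_seed_maybe(seed, array(rnorm(nx * ny * n_frames, 0, noise_sd_cm_s),
                                dim = c(nx, ny, n_frames)))
  else array(0, dim = c(nx, ny, n_frames))

  phase <- array(0, dim = c(nx, ny, n_frames))
  mag <- array(g$magnitude_levels[1], dim = c(nx, ny, n_frames))
  for (i in seq_len(n_frames)) {
    r2 <- (xs - g$center[1])^2 + (ys - g$center[2])^2
    lum <- r2 <= radii[i]^2
    prof <- pmax(0, 1 - r2 / radii[i]^2) * lum     # parabolic weights
    wsum <- sum(prof)
    v <- matrix(0, nx, ny)
    if (wsum > 0) {
      # scale so that pixel-sum of velocity integrates exactly to q[i]:
      # flow [mL/s] = sum(v_cm_s) * 10 * px_area_mm2 / 1000
      v[lum] <- prof[lum] * (q[i] * 100 / (px_area_mm2 * wsum))
    }
    fr <- v + ramp + noise[, , i]
    phase[, , i] <- wrap_velocity(fr, g$venc_cm_s)
    m <- mag[, , i]; m[lum] <- g$magnitude_levels[2]
    mag[, , i] <- m
  }
  velocity_series(phase, mag, g$venc_cm_s, g$pixel_mm, ft,
                  compartment(waveform))
}
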