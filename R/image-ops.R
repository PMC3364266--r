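#' Temporal unwrapping of aliased velocities
#'
#' Velocities beyond the encoding velocity wrap around: a true velocity of
#' `venc + d` is stored as `-venc + d`. Treating `+/-venc` as `+/-pi`, each
#' pixel's velocity-versus-time sequence is phase-unwrapped with a jump
#' tolerance of pi: consecutive differences exceeding `venc` are corrected
#' by steps of `2 * venc`. Pixels that never alias are returned unchanged.
#'
#' @param series A [velocity_series()] with at least two frames.
#' @return The unwrapped [velocity_series()] (velocities may now exceed
#'   `venc`).
#' @export
unwrap_velocity <- function(series) {
  assert_series(series)
  venc <- series$venc_cm_s
  d <- dim(series$phase)
  if (d[3] < 2) abort("temporal unwrapping needs at least two frames")
  ph <- series$phase
  flat <- matrix(ph, d[1] * d[2], d[3])            # pixels x time
  dif <- flat[, -1, drop = FALSE] - flat[, -d[3], drop = FALSE]
  step <- -2 * venc * round(dif / (2 * venc))      # correction per jump
  corr <- cbind(0, t(apply(step, 1, cumsum)))
  out <- array(flat + corr, dim = d)
  series$phase <- out
  series
}

assert_series <- function(x, arg = caller_arg(x)) {
  if (!inherits(x, "velocity_series"))
    abort(sprintf("`%s` must be a velocity_series", arg))
  invisible(x)
}

#' Otsu threshold of a gray-level image
#'
#' Histogram shape-based thresholding: the image is binned into a 256-level
#' histogram and the level maximizing the between-class variance is
#' returned (in the image's own intensity units).
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @return The threshold level: values strictly above it form the
#'   foreground class.
#' @export
otsu_threshold <- function(image) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (length(x) < 2 || rng[1] == rng[2])
    abort("degenerate input: constant image has no threshold")
  nbin <- 256L
  edges <- seq(rng[1], rng[2], length.out = nbin + 1L)
  h <- tabulate(pmin(findInterval(x, edges, left.open = FALSE), nbin), nbin)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbin + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbin]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  between <- between[-nbin]
  # the optimum can be a plateau (empty bins between classes): take its middle
  plateau <- which(between >= max(between) * (1 - 1e-12))
  k <- plateau[ceiling(length(plateau) / 2)]
  edges[k + 1L]
}

#' Region of interest polygon
#'
#' @param x,y Vertex coordinates (pixels, 0-based), at least three vertices
#'   forming a simple polygon.
#' @return A tibble of class `roi_polygon`.
#' @export
roi_polygon <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort("a ROI polygon needs at least three vertices")
  out <- tibble(x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("roi_polygon", class(out))
  out
}

# boolean mask of pixels inside the ROI polygon (0-based pixel centres)
roi_mask <- function(roi, nx, ny) {
  xs <- rep(0:(nx - 1), ny)
  ys <- rep(0:(ny - 1), each = nx)
  inside <- pracma::inpolygon(xs, ys, roi$x, roi$y, boundary = TRUE)
  matrix(inside, nx, ny)
}

# largest 4-connected foreground component (EBImage labelling)
largest_component <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0) return(fg & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

dilate1 <- function(m) {
  k <- EBImage::makeBrush(3, shape = "box")
  EBImage::dilate(m * 1, k) > 0
}
erode1 <- function(m) {
  k <- EBImage::makeBrush(3, shape = "box")
  EBImage::erode(m * 1, k) > 0
}

#' Segment a vessel or aqueduct cross-section from magnitude contrast
#'
#' Applies Otsu thresholding to the magnitude image inside a region of
#' interest and keeps the largest connected foreground component. Arteries
#' change cross-section over the cycle and are segmented frame by frame
#' (`mode = "per_frame"`); the aqueduct varies only moderately and is
#' segmented on a single reference frame — by default the frame containing
#' the maximum velocities (`mode = "single_frame"`).
#'
#' @param series A [velocity_series()].
#' @param roi A [roi_polygon()] enclosing the target lumen.
#' @param mode `"per_frame"` or `"single_frame"`.
#' @param threshold_scale Multiplicative adjustment of the Otsu level
#'   (default 1); [rim_check()] failures suggest the direction in which to
#'   adjust it.
#' @param reference_frame Frame index for `single_frame` mode; defaults to
#'   the frame with the highest in-ROI absolute velocity.
#' @return A list of class `segmentation_mask` with fields `mask` (logical
#'   `nx x ny x n` array: one slice per frame, or a single slice),
#'   `per_frame`, `compartment`.
#' @export
segment_compartment <- function(series, roi,
                                mode = c("per_frame", "single_frame"),
                                threshold_scale = 1,
                                reference_frame = NULL) {
  assert_series(series)
  mode <- arg_match(mode)
  d <- dim(series$magnitude)
  rmask <- roi_mask(roi, d[1], d[2])
  if (!any(rmask)) abort("ROI does not intersect the image")

  seg_one <- function(frame_idx) {
    m <- series$magnitude[, , frame_idx]
    vals <- m[rmask]
    if (length(unique(vals)) < 2) abort("no contrast inside ROI")
    thr <- otsu_threshold(vals) * threshold_scale
    fg <- (m > thr) & rmask
    if (!any(fg)) abort("no foreground inside ROI")
    largest_component(fg)
  }
  if (mode == "per_frame") {
    mask <- vapply(seq_len(d[3]), seg_one, matrix(TRUE, d[1], d[2]))
    mask <- array(mask, dim = d)
    per_frame <- TRUE
  } else {
    if (is.null(reference_frame)) {
      vmax <- vapply(seq_len(d[3]), function(i)
        max(abs(series$phase[, , i][rmask])), numeric(1))
      reference_frame <- which.max(vmax)
    }
    mask <- array(seg_one(reference_frame), dim = c(d[1], d[2], 1L))
    per_frame <- FALSE
  }
  structure(list(mask = mask, per_frame = per_frame,
                 compartment = series$compartment,
                 reference_frame = if (!per_frame) reference_frame),
            class = "segmentation_mask")
}

#' Frequency-domain segmentation of the cervical spinal canal
#'
#' The spinal canal has poor magnitude contrast, but its CSF pulsates with
#' the cardiac cycle while the surrounding tissue does not. For every voxel
#' inside the ROI the temporal discrete Fourier transform of the velocity
#' series is computed and the energy at non-zero frequencies taken; voxels
#' whose pulsatile energy exceeds an automatically determined (Otsu)
#' threshold on the log-energy map form the mask. The mask is associated
#' with the frame of highest velocity content.
#'
#' @param series A [velocity_series()] with at least 8 frames.
#' @param roi A [roi_polygon()].
#' @param frequency_threshold_scale Multiplicative adjustment of the
#'   automatic energy threshold (applied on the log-energy scale).
#' @return A `segmentation_mask` (single frame).
#' @export
segment_spinal_frequency <- function(series, roi, frequency_threshold_scale = 1) {
  assert_series(series)
  d <- dim(series$phase)
  if (d[3] < 8) abort("frequency segmentation needs at least 8 frames")
  rmask <- roi_mask(roi, d[1], d[2])
  if (!any(rmask)) abort("ROI does not intersect the image")
  flat <- matrix(series$phase, d[1] * d[2], d[3])
  sp <- Mod(t(stats::mvfft(t(flat))))^2
  energy <- rowSums(sp[, 2:d[3], drop = FALSE])    # non-zero frequencies
  emap <- matrix(energy, d[1], d[2])
  vals <- log10(emap[rmask] + .Machine$double.xmin)
  if (length(unique(vals)) < 2) abort("no pulsatile contrast inside ROI")
  thr <- otsu_threshold(vals) * frequency_threshold_scale
  fg <- matrix(FALSE, d[1], d[2])
  fg[rmask] <- log10(emap[rmask] + .Machine$double.xmin) > thr
  if (!any(fg)) abort("no voxel exceeds the pulsatile-energy threshold")
  fg <- largest_component(fg)
  vmax <- vapply(seq_len(d[3]), function(i)
    max(abs(series$phase[, , i][fg])), numeric(1))
  structure(list(mask = array(fg, dim = c(d[1], d[2], 1L)),
                 per_frame = FALSE, compartment = series$compartment,
                 reference_frame = which.max(vmax)),
            class = "segmentation_mask")
}

mask_slice <- function(mask, i) {
  if (mask$per_frame) mask$mask[, , i] else mask$mask[, , 1]
}

#' Rim-based quality control of a segmentation
#'
#' Compares the velocity content of two one-pixel wide rims adjacent to the
#' outside and the inside of the segmented cross-section against the
#' velocity evaluated inside it. Signal in the outer rim indicates the mask
#' is too small (lumen signal is leaking out — grow it); an inner rim that
#' carries much less velocity than the mask interior indicates the mask is
#' too large (shrink it). The suggested adjustment direction drives the
#' iterative threshold refinement in [refine_segmentation()].
#'
#' @param series A [velocity_series()].
#' @param mask A `segmentation_mask`.
#' @param noise_sd_cm_s Background velocity noise SD; the outer rim fails
#'   when its mean absolute velocity exceeds `3 * noise_sd_cm_s`. Estimated
#'   from image corners when `NULL`.
#' @return A tibble of class `rim_report` with per-frame rows: `frame`,
#'   `outer_rim_mean`, `inner_rim_mean`, `roi_mean`, `pass`, `suggestion`
#'   (`"keep"`, `"grow"` or `"shrink"`).
#' @export
rim_check <- function(series, mask, noise_sd_cm_s = NULL) {
  assert_series(series)
  d <- dim(series$phase)
  n_frames <- d[3]
  if (is.null(noise_sd_cm_s)) {
    cx <- min(4, d[1]); cy <- min(4, d[2])
    corner <- series$phase[1:cx, 1:cy, , drop = FALSE]
    noise_sd_cm_s <- max(stats::sd(corner), 1e-6)
  }
  rows <- lapply(seq_len(n_frames), function(i) {
    m <- mask_slice(mask, i)
    if (!any(m)) abort("empty mask")
    inner_band <- m & !erode1(m)
    core <- m & !inner_band
    if (!any(core)) abort("mask too small to erode: inner rim undefined")
    outer_band <- dilate1(m) & !m
    v <- series$phase[, , i]
    outer <- mean(abs(v[outer_band]))
    inner <- mean(abs(v[inner_band]))
    roi_mean <- mean(abs(v[m]))
    tibble(frame = i, outer_rim_mean = outer, inner_rim_mean = inner,
           roi_mean = roi_mean)
  })
  out <- bind_rows(rows)
  # aggregate over the cycle: rims carry the whole cycle's velocity content
  outer_bad <- mean(out$outer_rim_mean) > 3 * noise_sd_cm_s
  inner_low <- mean(out$inner_rim_mean) < 0.2 * mean(out$roi_mean)
  out$pass <- !outer_bad & !inner_low
  out$suggestion <- if (outer_bad) "grow" else if (inner_low) "shrink" else "keep"
  class(out) <- c("rim_report", class(out))
  attr(out, "noise_sd_cm_s") <- noise_sd_cm_s
  out
}

#' Iterative threshold refinement driven by rim checks
#'
#' Repeats the semi-automatic segmentation with the Otsu threshold scaled
#' by +/-5% steps, up to `max_iter` times, until the rim check passes.
#'
#' @inheritParams segment_compartment
#' @param noise_sd_cm_s Passed to [rim_check()].
#' @param max_iter Maximum refinement iterations (default 10).
#' @return A `segmentation_mask` whose attribute `threshold_scale` records
#'   the accepted scale and `rim_report` the final report.
#' @export
refine_segmentation <- function(series, roi, mode = c("per_frame", "single_frame"),
                                noise_sd_cm_s = NULL, max_iter = 10,
                                reference_frame = NULL) {
  mode <- arg_match(mode)
  scale <- 1
  for (i in seq_len(max_iter)) {
    mask <- segment_compartment(series, roi, mode, scale, reference_frame)
    rep <- rim_check(series, mask, noise_sd_cm_s)
    if (all(rep$pass)) break
    scale <- scale * if (rep$suggestion[1] == "grow") 0.95 else 1.05
  }
  attr(mask, "threshold_scale") <- scale
  attr(mask, "rim_report") <- rep
  mask
}

#' Background phase-error correction
#'
#' Phase-contrast velocities carry a spatially slowly varying offset (eddy
#' currents, concomitant fields). The temporal-mean velocity of a static
#' reference region is subtracted from every pixel of every frame. The
#' reference is either a rectangle placed close to (but not overlapping)
#' the lumen, or the one-voxel wide contour adjacent to the mask (used for
#' the spinal canal where no clean rectangle exists).
#'
#' @param series A [velocity_series()].
#' @param mask A `segmentation_mask` (the region that must not contribute).
#' @param reference `"rectangle"` or `"contour"`.
#' @param region For `rectangle`: `c(x0, x1, y0, y1)` pixel bounds
#'   (0-based, inclusive).
#' @return The corrected [velocity_series()]; the subtracted offset is
#'   stored in attribute `background_offset_cm_s`.
#' @export
correct_background <- function(series, mask,
                               reference = c("rectangle", "contour"),
                               region = NULL) {
  assert_series(series)
  reference <- arg_match(reference)
  d <- dim(series$phase)
  any_mask <- apply(mask$mask, c(1, 2), any)
  if (reference == "rectangle") {
    if (is.null(region) || length(region) != 4)
      abort("rectangle reference needs region = c(x0, x1, y0, y1)")
    sel <- matrix(FALSE, d[1], d[2])
    sel[(region[1]:region[2]) + 1L, (region[3]:region[4]) + 1L] <- TRUE
    if (any(sel & any_mask)) abort("reference region overlaps the mask")
  } else {
    sel <- dilate1(any_mask) & !any_mask
  }
  if (!any(sel)) abort("empty reference region")
  offset <- mean(apply(series$phase, 3, function(fr) mean(fr[sel])))
  series$phase <- series$phase - offset
  attr(series, "background_offset_cm_s") <- offset
  series
}

#' Integrate volumetric flow over a segmentation mask
#'
#' Per frame, the flow is the sum over masked pixels of pixel area times
#' velocity, converted to mL/s. A single-frame mask is broadcast to all
#' frames.
#'
#' @param series A [velocity_series()] (background-corrected, unwrapped).
#' @param mask A `segmentation_mask`.
#' @param heart_period_ms Cycle length; defaults to the frame spacing
#'   extrapolated one frame past the last.
#' @return A [flow_waveform()] carrying the frame times.
#' @export
compute_flow <- function(series, mask, heart_period_ms = NULL) {
  assert_series(series)
  d <- dim(series$phase)
  px_area <- series$pixel_mm[1] * series$pixel_mm[2]
  q <- vapply(seq_len(d[3]), function(i) {
    m <- mask_slice(mask, i)
    if (!any(m)) abort("empty mask")
    sum(series$phase[, , i][m]) * px_area / 100    # cm/s * mm^2 -> mL/s
  }, numeric(1))
  ft <- series$frame_times_ms
  heart_period_ms <- heart_period_ms %||%
    (ft[length(ft)] + (ft[2] - ft[1]))
  flow_waveform(ft, q, heart_period_ms,
                compartment = series$compartment)
}
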