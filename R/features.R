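#' Detect characteristic waveform feature points
#'
#' Feature points are the landmarks used to compare waveform morphology
#' across subjects and groups. Arterial cycles carry six labels
#' (`ar1`..`ar6`): diastolic minimum, systolic maximum, late systolic local
#' minimum, late systolic peak, minimum at aortic valve closure, diastolic
#' maximum. Cervical spinal CSF cycles carry `sp1`..`sp6` (local maximum of
#' cranial flow, maximum caudal flow, inflection point, local maximum, local
#' minimum, maximum cranial flow) and aqueductal cycles `aq1`..`aq5`
#' (maximum cranial flow, maximum caudal flow, and three inflection points).
#'
#' Extrema are located as sign changes of the first difference and
#' inflections as sign changes of the second difference of a lightly
#' smoothed copy (3-point moving average); amplitudes are read from the
#' unsmoothed waveform. Labels are assigned in temporal order. Extremum
#' labels are required — if one cannot be found (e.g. on monotone input) an
#' error lists the missing labels; inflection labels are reported when
#' present.
#'
#' @param w A time-normalized [flow_waveform()].
#' @param compartment Compartment whose labelling scheme to use; defaults to
#'   the waveform's own label.
#' @return A tibble with columns `label`, `time_ms`, `amplitude` (class
#'   `feature_points`).
#' @export
detect_feature_points <- function(w, compartment = NULL) {
  assert_waveform(w)
  if (!is_time_normalized(w)) abort("feature detection expects a time-normalized waveform")
  comp <- compartment %||% compartment(w)
  comp <- arg_match0(comp, c("arterial", "spinal", "aqueduct"))
  v <- w$flow; t_ms <- w$time_ms; n <- length(v)

  sm <- (v + c(v[1], v[-n]) + c(v[-1], v[n])) / 3      # 3-point MA
  d1 <- diff(sm)                                       # n-1 forward differences
  is_max <- is_min <- is_infl <- rep(FALSE, n)
  # interior extrema: sign change of the first difference
  is_max[2:(n - 1)] <- d1[1:(n - 2)] > 0 & d1[2:(n - 1)] <= 0
  is_min[2:(n - 1)] <- d1[1:(n - 2)] < 0 & d1[2:(n - 1)] >= 0
  d2 <- diff(d1)                                       # n-2 second differences
  is_infl[3:(n - 1)] <- (d2[1:(n - 3)] > 0 & d2[2:(n - 2)] <= 0) |
                        (d2[1:(n - 3)] < 0 & d2[2:(n - 2)] >= 0)

  maxima <- which(is_max); minima <- which(is_min); infl <- which(is_infl)
  pts <- switch(comp,
    arterial = label_arterial(v, maxima, minima),
    spinal   = label_spinal(v, maxima, minima, infl),
    aqueduct = label_aqueduct(v, maxima, minima, infl))

  missing <- pts$required[!pts$required %in% pts$tbl$label]
  if (length(missing))
    abort(paste0("missing feature points: ", paste(missing, collapse = ", ")),
          class = "csfpulse_missing_feature")
  out <- tibble(label = pts$tbl$label,
                time_ms = t_ms[pts$tbl$idx],
                amplitude = v[pts$tbl$idx])
  out <- out[order(out$time_ms), ]
  class(out) <- c("feature_points", class(out))
  attr(out, "compartment") <- comp
  out
}

# next element of `set` strictly after idx (no wrap)
next_after <- function(set, idx) {
  s <- set[set > idx]
  if (length(s)) s[1] else NA_integer_
}
prev_before <- function(set, idx) {
  s <- set[set < idx]
  if (length(s)) s[length(s)] else NA_integer_
}

label_arterial <- function(v, maxima, minima) {
  tbl <- tibble(label = character(), idx = integer())
  add <- function(tbl, lab, idx) if (!is.na(idx)) bind_rows(tbl, tibble(label = lab, idx = idx)) else tbl
  if (length(maxima)) {
    ar2 <- maxima[which.max(v[maxima])]
    ar1 <- prev_before(minima, ar2)
    ar3 <- next_after(minima, ar2)
    ar4 <- if (!is.na(ar3)) next_after(maxima, ar3) else NA_integer_
    ar5 <- if (!is.na(ar4)) next_after(minima, ar4) else NA_integer_
    ar6 <- if (!is.na(ar5)) next_after(maxima, ar5) else NA_integer_
    tbl <- add(tbl, "ar1", ar1); tbl <- add(tbl, "ar2", ar2)
    tbl <- add(tbl, "ar3", ar3); tbl <- add(tbl, "ar4", ar4)
    tbl <- add(tbl, "ar5", ar5); tbl <- add(tbl, "ar6", ar6)
  }
  list(tbl = tbl, required = paste0("ar", 1:6))
}

label_spinal <- function(v, maxima, minima, infl) {
  tbl <- tibble(label = character(), idx = integer())
  add <- function(tbl, lab, idx) if (!is.na(idx)) bind_rows(tbl, tibble(label = lab, idx = idx)) else tbl
  if (length(minima) && length(maxima)) {
    sp2 <- minima[which.min(v[minima])]              # maximum caudal flow
    sp1 <- prev_before(maxima, sp2)
    sp3 <- next_after(infl, sp2)
    sp4 <- next_after(maxima, sp2)
    sp5 <- if (!is.na(sp4)) next_after(minima, sp4) else NA_integer_
    rest <- maxima[maxima > (if (!is.na(sp5)) sp5 else sp2)]
    sp6 <- if (length(rest)) rest[which.max(v[rest])] else NA_integer_
    tbl <- add(tbl, "sp1", sp1); tbl <- add(tbl, "sp2", sp2)
    tbl <- add(tbl, "sp3", sp3); tbl <- add(tbl, "sp4", sp4)
    tbl <- add(tbl, "sp5", sp5); tbl <- add(tbl, "sp6", sp6)
  }
  list(tbl = tbl, required = c("sp1", "sp2", "sp4", "sp5", "sp6"))
}

label_aqueduct <- function(v, maxima, minima, infl) {
  tbl <- tibble(label = character(), idx = integer())
  add <- function(tbl, lab, idx) if (!is.na(idx)) bind_rows(tbl, tibble(label = lab, idx = idx)) else tbl
  if (length(maxima) && length(minima)) {
    aq1 <- maxima[which.max(v[maxima])]              # maximum cranial flow
    aq2 <- minima[which.min(v[minima])]              # maximum caudal flow
    tbl <- add(tbl, "aq1", aq1); tbl <- add(tbl, "aq2", aq2)
    after <- infl[infl > aq2]
    for (k in seq_len(min(3L, length(after))))
      tbl <- add(tbl, paste0("aq", k + 2L), after[k])
  }
  list(tbl = tbl, required = c("aq1", "aq2"))
}

#' Shape-preserving piecewise cubic Hermite interpolation of feature points
#'
#' Fits the monotonicity-preserving piecewise cubic Hermite interpolating
#' polynomial (PCHIP) through a set of feature points and evaluates it on a
#' time grid. The interpolant passes through every point exactly and does
#' not overshoot beyond adjacent point values on monotone segments.
#'
#' @param points A `feature_points` tibble (or any data frame with
#'   `time_ms` and `amplitude`), at least two points with strictly
#'   increasing times.
#' @param grid Times (ms) at which to evaluate, within the node range.
#' @return A tibble with columns `time_ms` and `amplitude`.
#' @export
hermite_fit <- function(points, grid) {
  if (!all(c("time_ms", "amplitude") %in% names(points)))
    abort("`points` needs columns time_ms and amplitude")
  x <- as.numeric(points$time_ms); y <- as.numeric(points$amplitude)
  if (length(x) < 2) abort("need at least two feature points")
  if (anyDuplicated(x)) abort("duplicate feature-point times")
  o <- order(x); x <- x[o]; y <- y[o]
  fit <- if (length(x) == 2) approx(x, y, xout = grid)$y
         else pracma::pchip(x, y, grid)
  tibble(time_ms = grid, amplitude = fit)
}
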