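#' Amplitude normalization of flow waveforms
#'
#' CSF waveforms are normalized by the cycle-average of the absolute flow
#' rate (`mode = "cc_average"`), so that the normalized cycle has an average
#' flow rate of exactly one. Arterial waveforms are normalized by the average
#' absolute flow of the systolic phase only (`mode = "systolic_average"`):
#' systole has a nearly heart-rate-invariant duration, so a systolic
#' reference makes subjects with different heart rates comparable, while the
#' rate-dependent diastole is left out of the reference. Normalization
#' accentuates waveform shape; the physical amplitudes are retained in the
#' scalar metrics computed beforehand.
#'
#' @param w A [flow_waveform()], not yet amplitude-normalized.
#' @param mode `"cc_average"` or `"systolic_average"` (the latter requires a
#'   systole end marker).
#' @return The normalized `flow_waveform` (dimensionless).
#' @export
normalize_amplitude <- function(w, mode = c("cc_average", "systolic_average")) {
  assert_waveform(w)
  mode <- arg_match(mode)
  if (amp_norm_state(w) != "none")
    abort("waveform is already amplitude-normalized")
  if (mode == "systolic_average") {
    send <- systole_end(w)
    if (is.null(send)) abort("systolic_average normalization needs a systole end marker")
    sel <- w$time_ms < send
    if (!any(sel)) abort("no samples within the systolic phase")
    ref <- mean(abs(w$flow[sel]))
  } else {
    ref <- cycle_mean(w$time_ms, abs(w$flow), heart_period(w))
  }
  if (ref <= 0) abort("zero average flow: normalization undefined")
  wf_update(w, flow = w$flow / ref, amp_norm = mode)
}

#' Temporal normalization to the nominal 1 s cardiac cycle
#'
#' Cycle lengths differ between subjects, which makes harmonic frequencies
#' incommensurable across a cohort. Stretching or compressing the waveform
#' would distort systole, whose duration is nearly heart-rate-invariant, so
#' the cycle is instead brought to a nominal length by adjusting only the
#' diastolic tail: a cycle shorter than nominal is extended by a straight
#' line from the last data point back to the value of the first point
#' (reaching it at the nominal length); a longer cycle has its end-diastolic
#' part cut at the nominal length. The result is resampled by linear
#' interpolation onto the uniform 10 ms grid (100 samples at 0, ..., 990 ms),
#' with systolic timing untouched.
#'
#' @param w A [flow_waveform()] with known heart period.
#' @param nominal_ms Nominal cycle length (default 1000 ms).
#' @param dt_ms Resampling interval (default 10 ms).
#' @return A time-normalized `flow_waveform` (100 samples).
#' @export
normalize_time <- function(w, nominal_ms = 1000, dt_ms = 10) {
  assert_waveform(w)
  if (nominal_ms != .NOMINAL_MS || dt_ms != .DT_MS)
    abort("the analysis grid is fixed at a 1000 ms cycle sampled every 10 ms")
  period <- heart_period(w)
  if (is.null(period)) abort("heart period unknown")
  send <- systole_end(w)
  if (!is.null(send) && period < send) abort("heart period shorter than systole")
  t_in <- w$time_ms; v_in <- w$flow
  if (is_time_normalized(w)) return(w)

  if (period < nominal_ms) {
    # extend diastole: the last data value holds to the end of the native
    # cycle, then rises/falls linearly back to the first value at nominal
    n <- length(v_in)
    if (t_in[n] < period) { t_in <- c(t_in, period); v_in <- c(v_in, v_in[n]) }
    t_in <- c(t_in, nominal_ms)
    v_in <- c(v_in, v_in[1])
  } else if (period > nominal_ms) {
    keep <- t_in < nominal_ms
    t_in <- t_in[keep]; v_in <- v_in[keep]
  }
  # periodic closure at t = nominal for interpolation of the last interval
  if (t_in[length(t_in)] < nominal_ms) {
    t_in <- c(t_in, nominal_ms); v_in <- c(v_in, v_in[1])
  }
  grid <- seq(0, nominal_ms - dt_ms, by = dt_ms)
  v <- approx(t_in, v_in, xout = grid, rule = 2)$y
  wf_update(w, time_ms = grid, flow = v,
            heart_period_ms = nominal_ms, time_normalized = TRUE)
}
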