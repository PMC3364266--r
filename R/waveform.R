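#' Construct a volumetric flow waveform
#'
#' A `flow_waveform` holds one composite cardiac cycle of volumetric flow,
#' sampled at strictly increasing times from the R-wave. It is a tibble with
#' columns `time_ms` and `flow` plus metadata attributes, so it pipes through
#' the usual tidyverse verbs while the analysis functions can rely on the
#' heart period, the systole marker and the normalization state travelling
#' with the data.
#'
#' Sign conventions follow the field's usage: for CSF compartments positive
#' flow is directed cranially, for the arterial compartment positive flow is
#' inflow to the cranium.
#'
#' @param time_ms Sample times in ms from the R-wave, strictly increasing,
#'   all within `[0, heart_period_ms)`.
#' @param flow Flow values (mL/s for physical waveforms; dimensionless once
#'   amplitude-normalized).
#' @param heart_period_ms Length of the cardiac cycle in ms.
#' @param systole_end_ms End of systole in ms (time of the minimum at aortic
#'   valve closure for arterial waveforms), or `NULL` if unknown.
#' @param compartment One of `"arterial"`, `"spinal"`, `"aqueduct"`.
#' @param amp_norm Amplitude normalization state: `"none"`, `"cc_average"`
#'   or `"systolic_average"`.
#' @param time_normalized Has the cycle been normalized to the nominal 1 s
#'   grid (100 samples at 0, 10, ..., 990 ms)?
#' @param provenance Optional list of construction parameters (filled in by
#'   the synthetic generator).
#'
#' @return A `flow_waveform` tibble.
#' @export
#' @examples
#' t <- seq(0, 990, by = 10)
#' w <- flow_waveform(t, sin(2 * pi * t / 1000), heart_period_ms = 1000,
#'                    compartment = "aqueduct")
#' average_flow_rate(w)
flow_waveform <- function(time_ms, flow, heart_period_ms,
                          systole_end_ms = NULL,
                          compartment = c("arterial", "spinal", "aqueduct"),
                          amp_norm = c("none", "cc_average", "systolic_average"),
                          time_normalized = FALSE,
                          provenance = list()) {
  compartment <- arg_match(compartment)
  amp_norm <- arg_match(amp_norm)
  time_ms <- as.numeric(time_ms); flow <- as.numeric(flow)
  if (length(time_ms) == 0L) abort("empty waveform: no samples")
  if (length(time_ms) != length(flow)) abort("`time_ms` and `flow` lengths differ")
  if (any(!is.finite(flow))) abort("flow values must be finite")
  if (any(diff(time_ms) <= 0)) abort("sample times must be strictly increasing")
  if (!is.null(heart_period_ms) &&
      (time_ms[1] < 0 || time_ms[length(time_ms)] >= heart_period_ms))
    abort("sample times must lie within [0, heart_period_ms)")
  if (isTRUE(time_normalized) &&
      !(length(time_ms) == .N_NOMINAL && all(time_ms == seq(0, 990, by = 10))))
    abort("time-normalized waveforms must have 100 samples at 0,10,...,990 ms")
  out <- new_tibble(
    list(time_ms = time_ms, flow = flow),
    nrow = length(time_ms),
    class = "flow_waveform",
    heart_period_ms = heart_period_ms,
    systole_end_ms = systole_end_ms,
    compartment = compartment,
    amp_norm = amp_norm,
    time_normalized = isTRUE(time_normalized),
    provenance = provenance
  )
  out
}

wf_attr <- function(w, what) attr(w, what, exact = TRUE)

#' Waveform metadata accessors
#'
#' @param w A [flow_waveform()].
#' @return The heart period (ms), systole end (ms), compartment label,
#'   amplitude-normalization state, or time-normalization flag.
#' @export
heart_period <- function(w) wf_attr(w, "heart_period_ms")

#' @rdname heart_period
#' @export
systole_end <- function(w) wf_attr(w, "systole_end_ms")

#' @rdname heart_period
#' @export
compartment <- function(w) wf_attr(w, "compartment")

#' @rdname heart_period
#' @export
amp_norm_state <- function(w) wf_attr(w, "amp_norm")

#' @rdname heart_period
#' @export
is_time_normalized <- function(w) isTRUE(wf_attr(w, "time_normalized"))

assert_waveform <- function(w, arg = caller_arg(w)) {
  if (!inherits(w, "flow_waveform"))
    abort(sprintf("`%s` must be a flow_waveform", arg))
  if (nrow(w) == 0L) abort(sprintf("`%s` is empty", arg))
  invisible(w)
}

# Rebuild a waveform with some fields changed, keeping the rest.
wf_update <- function(w, time_ms = w$time_ms, flow = w$flow,
                      heart_period_ms = heart_period(w),
                      systole_end_ms = systole_end(w),
                      amp_norm = amp_norm_state(w),
                      time_normalized = is_time_normalized(w),
                      provenance = wf_attr(w, "provenance")) {
  flow_waveform(time_ms, flow, heart_period_ms, systole_end_ms,
                compartment(w), amp_norm, time_normalized, provenance)
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform: %s, %d samples, period %s ms, norm %s%s>\n",
              compartment(x), nrow(x),
              format(heart_period(x)), amp_norm_state(x),
              if (is_time_normalized(x)) ", time-normalized" else ""))
  NextMethod()
}

# Trapezoidal time-average of f(t) over one full cycle, treating the cycle as
# periodic (the segment from the last sample back to the first closes it).
cycle_mean <- function(time_ms, values, period_ms) {
  n <- length(values)
  if (n == 1L) return(values)
  dt <- diff(c(time_ms, time_ms[1] + period_ms))
  mids <- (values + c(values[-1], values[1])) / 2
  sum(mids * dt) / period_ms
}
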