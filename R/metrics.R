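#' Scalar flow metrics
#'
#' `average_flow_rate()` is the time-average of the absolute flow over one
#' cardiac cycle — the mean of the caudocranial and craniocaudal transport
#' magnitude. It deliberately differs from `net_flow_rate()`, the signed
#' time-average, which for CSF reflects net production rather than pulsatile
#' transport. `stroke_volume()` is the mean of the absolute areas under the
#' positive-going and negative-going lobes of the flow curve (systolic and
#' diastolic displacement), reported in microlitres.
#'
#' Physical waveforms (mL/s) yield mL/min for the rate metrics and µL for the
#' stroke volume; amplitude-normalized waveforms yield dimensionless rates.
#' A waveform with only one flow direction contributes zero area for the
#' missing lobe.
#'
#' @param w A [flow_waveform()].
#' @return A scalar.
#' @export
#' @examples
#' t <- seq(0, 990, by = 10)
#' w <- flow_waveform(t, sin(2 * pi * t / 1000), 1000, compartment = "aqueduct")
#' average_flow_rate(w)  # 2/pi mL/s = 38.2 mL/min
#' net_flow_rate(w)      # ~0
#' stroke_volume(w)      # ~318 uL per lobe pair
average_flow_rate <- function(w) {
  assert_waveform(w)
  avg <- cycle_mean(w$time_ms, abs(w$flow), heart_period(w))
  if (amp_norm_state(w) == "none") avg * 60 else avg
}

#' @rdname average_flow_rate
#' @export
net_flow_rate <- function(w) {
  assert_waveform(w)
  avg <- cycle_mean(w$time_ms, w$flow, heart_period(w))
  if (amp_norm_state(w) == "none") avg * 60 else avg
}

#' @rdname average_flow_rate
#' @export
stroke_volume <- function(w) {
  assert_waveform(w)
  t_ms <- w$time_ms; period <- heart_period(w)
  pos <- cycle_mean(t_ms, pmax(w$flow, 0), period) * period   # mL/s * ms = uL
  neg <- cycle_mean(t_ms, pmax(-w$flow, 0), period) * period
  (abs(pos) + abs(neg)) / 2
}
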