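# Fixture builders shared across the suite.

grid_ms <- seq(0, 990, by = 10)

sine_waveform <- function(freq_hz = 1, amplitude = 1, offset = 0,
                          period_ms = 1000, compartment = "aqueduct",
                          time_normalized = (period_ms == 1000)) {
  t <- seq(0, period_ms - 10, by = 10)
  flow_waveform(t, offset + amplitude * sin(2 * pi * freq_hz * t / 1000),
                heart_period_ms = period_ms, compartment = compartment,
                time_normalized = time_normalized)
}

# time-normalized waveform from raw values on the 10 ms grid
normgrid_waveform <- function(values, compartment = "arterial",
                              systole_end_ms = NULL) {
  flow_waveform(grid_ms, values, 1000, systole_end_ms = systole_end_ms,
                compartment = compartment, time_normalized = TRUE)
}

# circular filtering of one cycle by a rational b/a (frequency domain)
circular_filter <- function(x, b, a) {
  n <- length(x)
  w <- 2 * pi * (0:(n - 1)) / n
  H <- as.vector((exp(-1i * outer(w, seq_along(b) - 1)) %*% b) /
                 (exp(-1i * outer(w, seq_along(a) - 1)) %*% a))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# circular shift by k samples (delay)
circular_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(tail(x, k), head(x, n - k))
}

# broad-band test input: all ten harmonics plus offset
rich_input <- function(mean_level = 0.6) {
  t <- grid_ms / 1000
  amps <- 0.5 / (1:10)
  phs <- c(0.3, 1.1, 2.0, 0.5, 1.7, 2.6, 0.9, 1.4, 0.2, 2.2)
  v <- rep(mean_level, length(t))
  for (k in 1:10) v <- v + amps[k] * cos(2 * pi * k * t + phs[k])
  v
}

# small bright-disk phantom series for segmentation tests
disk_series <- function(radius = 5, n_frames = 24, value = 8,
                        grid = 24, venc = 100, compartment = "aqueduct",
                        mag_levels = c(50, 300)) {
  xs <- matrix(rep(0:(grid - 1), grid), grid, grid)
  ys <- matrix(rep(0:(grid - 1), each = grid), grid, grid)
  ctr <- (grid - 1) / 2
  radii <- rep_len(radius, n_frames)
  ph <- array(0, c(grid, grid, n_frames))
  mg <- array(mag_levels[1], c(grid, grid, n_frames))
  for (i in seq_len(n_frames)) {
    lum <- (xs - ctr)^2 + (ys - ctr)^2 <= radii[i]^2
    p <- matrix(0, grid, grid); p[lum] <- value
    ph[, , i] <- p
    m <- mg[, , i]; m[lum] <- mag_levels[2]
    mg[, , i] <- m
  }
  velocity_series(ph, mg, venc, c(1, 1),
                  seq(0, by = 30, length.out = n_frames), compartment)
}

square_roi <- function(lo, hi) roi_polygon(c(lo, hi, hi, lo), c(lo, lo, hi, hi))
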