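# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (stats::fft, solve()-based interpolation,
# polyroot maximisation) so agreement is a real cross-check.

# O(N^2) discrete Fourier transform magnitudes, direct from the definition.
naive_dft_amps <- function(x) {
  N <- length(x)
  vapply(0:(N - 1L), function(k) {
    ang <- -2 * pi * (0:(N - 1L)) * k / N
    sqrt(sum(x * cos(ang))^2 + sum(x * sin(ang))^2)
  }, numeric(1))
}

# Lagrange-form polynomial interpolation evaluated at x0.
lagrange_eval <- function(xs, ys, x0) {
  sum(vapply(seq_along(xs), function(i) {
    others <- xs[-i]
    ys[i] * prod((x0 - others) / (xs[i] - others))
  }, numeric(1)))
}

# Brute-force argmax of the interpolating polynomial on a dense grid.
grid_argmax <- function(xs, ys, lo, hi, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  vals <- vapply(grid, function(g) lagrange_eval(xs, ys, g), numeric(1))
  grid[which.max(vals)]
}

# Walking-band frequencies at the default window (bins k = 2..6).
default_band_freqs <- function() (2:6) * 20 / 64

# A single-axis sinusoid trace at the default sampling frequency.
sine_trace <- function(freq, n, amplitude = 1, fs = 20, axis = "y",
                       phase = 0) {
  t <- (0:(n - 1L)) / fs
  s <- amplitude * sin(2 * pi * freq * t + phase)
  z <- numeric(n)
  gyro_trace(wx = if (axis == "x") s else z,
             wy = if (axis == "y") s else z,
             wz = if (axis == "z") s else z, fs = fs)
}

# Spectrum whose interpolating quartic peaks exactly at `peak` Hz: amplitudes
# follow the parabola A(f) = -(f - peak)^2 + height on the five band bins,
# so the exact interpolation reproduces the parabola and its vertex.
parabola_spectrum <- function(peak = 1.5, height = 60) {
  freqs <- (0:63) * 20 / 64
  amps <- numeric(64)
  amps[3:7] <- -(freqs[3:7] - peak)^2 + height
  structure(list(freqs = freqs, amps = amps, fs = 20, N = 64L),
            class = "gyro_spectrum")
}

# Noise level putting the sensitive axis of a default walk_bout() at the
# requested signal-to-noise ratio (dB).
walk_noise_for_snr <- function(snr_db, amplitude = 6, mix_max = 0.6,
                               harmonics = c(0.3, 0.15)) {
  sig_power <- (amplitude * sqrt(mix_max))^2 * (1 + sum(harmonics^2)) / 2
  sqrt(sig_power / 10^(snr_db / 10))
}
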