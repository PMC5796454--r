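#' Walking-detection configuration
#'
#' Parameters of the per-window frequency-domain decision rule. The window's
#' amplitude spectrum is averaged over two disjoint bands: the typical human
#' walking band (0.6-2 Hz) giving `omega_c`, and the sub-walking band below
#' it giving `omega_0`. A window is classified as walking iff both
#' `omega_c > omega_0` (the spectrum peaks in the walking band rather than
#' at slow drifts) and `omega_c > amp_threshold` (the motion is energetic
#' enough to rule out mild handling such as standing and typing).
#'
#' The threshold applies to unnormalized DFT magnitudes `|X(k)|` of a rad/s
#' signal over an `N`-sample window (no `1/N`, no one-sided doubling); its
#' default of 10 assumes those units and `N = 64` at 20 Hz, and must be
#' recalibrated under any other scaling.
#'
#' The DC bin is excluded from the sub-walking band by default: at rest it
#' carries the gyroscope's constant bias, not motion energy. Set
#' `include_dc = TRUE` to include it.
#'
#' @param band_walk Walking band in Hz, a closed interval (default
#'   `c(0.6, 2)`; spans the five spectral bins 0.625-1.875 Hz at the default
#'   window).
#' @param band_low Sub-walking band in Hz (default `c(0, 0.6)`, open at 0).
#' @param amp_threshold Minimum walking-band mean amplitude (default 10).
#' @param include_dc Include bin 0 in the sub-walking band? Default `FALSE`.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(band_walk = c(0.6, 2), band_low = c(0, 0.6),
                             amp_threshold = 10, include_dc = FALSE) {
  band_walk <- as.numeric(band_walk); band_low <- as.numeric(band_low)
  if (length(band_walk) != 2L || length(band_low) != 2L ||
      band_walk[1L] >= band_walk[2L] || band_low[1L] >= band_low[2L])
    stop("bands must be increasing length-2 intervals in Hz", call. = FALSE)
  if (band_low[2L] > band_walk[1L] + 1e-12 && band_walk[2L] > band_low[1L])
    if (max(band_low[1L], band_walk[1L]) < min(band_low[2L], band_walk[2L]) - 1e-12)
      stop("'band_walk' and 'band_low' must be disjoint", call. = FALSE)
  if (!is.finite(amp_threshold) || amp_threshold < 0)
    stop("'amp_threshold' must be >= 0", call. = FALSE)
  structure(list(band_walk = band_walk, band_low = band_low,
                 amp_threshold = amp_threshold,
                 include_dc = isTRUE(include_dc)),
            class = "detection_config")
}

#' Select the most sensitive gyroscope axis
#'
#' The axis best coupled to the current motion is taken to be the one with
#' the largest summed absolute angular velocity over the window,
#' `argmax_a sum_i |w_a(i)|`. Working on a single real axis (rather than the
#' 3-D magnitude, which loses sign/phase structure) keeps the cyclic walking
#' signature intact whatever the phone placement. Ties break deterministically
#' in axis order x < y < z.
#'
#' @param window A `window_view` from [iter_windows()], or an `N x 3`
#'   numeric matrix with columns x, y, z.
#' @return `"x"`, `"y"` or `"z"`.
#' @export
select_sensitive_axis <- function(window) {
  m <- if (inherits(window, "window_view")) window$samples else as.matrix(window)
  stopifnot(ncol(m) == 3L)
  sums <- colSums(abs(m))
  c("x", "y", "z")[which.max(sums)]  # which.max returns the first maximum
}

#' Amplitude spectrum of a window's sensitive-axis signal
#'
#' Unnormalized DFT magnitudes `amps[k] = |sum_n w(n) exp(-i 2 pi n k / N)|`
#' for `k = 0..N-1`, with bin `k` at frequency `k * fs / N` Hz. For real
#' input the magnitudes are symmetric about the Nyquist bin.
#'
#' @param x Numeric vector of `N` real samples; `N` must be a power of 2.
#' @param fs Sampling frequency, Hz.
#' @return An object of class `gyro_spectrum`: list with `freqs` (Hz),
#'   `amps`, `fs`, `N`.
#' @examples
#' sp <- compute_spectrum(sin(2 * pi * 0.9375 * (0:63) / 20), fs = 20)
#' sp$freqs[4]  # bin 3: 0.9375 Hz
#' @export
compute_spectrum <- function(x, fs) {
  x <- as.numeric(x)
  N <- length(x)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L)
    stop("spectrum length must be a power of 2; adjust the windowing config (N)",
         call. = FALSE)
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  structure(list(freqs = (0:(N - 1L)) * fs / N,
                 amps = Mod(stats::fft(x)),
                 fs = fs, N = N),
            class = "gyro_spectrum")
}

#' @export
print.gyro_spectrum <- function(x, ...) {
  k <- which.max(x$amps[2:(x$N %/% 2L)]) + 1L
  cat(sprintf("<gyro_spectrum> N = %d, fs = %g Hz; peak (excl. DC) %.4g at %.4g Hz\n",
              x$N, x$fs, x$amps[k], x$freqs[k]))
  invisible(x)
}

# 1-based indices of the spectral bins falling in each band (internal).
# Only the one-sided half (k = 0..N/2) is considered, so mirror bins never
# enter a band.
band_bins <- function(freqs, N, cfg) {
  half <- freqs[seq_len(N %/% 2L + 1L)]
  walk <- which(half >= cfg$band_walk[1L] - 1e-12 &
                half <= cfg$band_walk[2L] + 1e-12)
  low <- which(half > cfg$band_low[1L] + 1e-12 &
               half < cfg$band_low[2L] - 1e-12)
  if (cfg$include_dc && cfg$band_low[1L] <= 0)
    low <- sort(unique(c(1L, low)))
  list(walk = walk, low = low)
}

#' Mean spectral amplitudes in the walking and sub-walking bands
#'
#' Averages the amplitude spectrum over the bins whose frequencies fall in
#' the walking band (`omega_c`) and the sub-walking band (`omega_0`). At the
#' defaults (`fs = 20`, `N = 64`) the walking band holds exactly five bins,
#' k = 2..6 (0.625-1.875 Hz), and the sub-walking band holds bin 1
#' (0.3125 Hz), with the DC bin excluded.
#'
#' @param spec A [compute_spectrum()] result.
#' @param cfg A [detection_config()].
#' @return Named numeric vector `c(omega_c = , omega_0 = )`.
#' @export
band_mean_amplitudes <- function(spec, cfg = detection_config()) {
  stopifnot(inherits(spec, "gyro_spectrum"), inherits(cfg, "detection_config"))
  bb <- band_bins(spec$freqs, spec$N, cfg)
  if (!length(bb$walk))
    stop("no spectral bins fall in 'band_walk'; check the band/fs/N configuration",
         call. = FALSE)
  if (!length(bb$low))
    stop("no spectral bins fall in 'band_low'; check the band/fs/N configuration",
         call. = FALSE)
  c(omega_c = mean(spec$amps[bb$walk]), omega_0 = mean(spec$amps[bb$low]))
}

#' The two-condition walking decision
#'
#' A window is walking iff `omega_c > omega_0` and
#' `omega_c > cfg$amp_threshold`, both strict. The first condition demands
#' that spectral energy concentrates in the walking band (placement switches
#' and slow drifts concentrate below it); the second rejects low-energy
#' narrowband motion such as typing while standing. Ties classify as
#' non-walking.
#'
#' @param omega_c,omega_0 Band mean amplitudes from [band_mean_amplitudes()].
#' @param cfg A [detection_config()].
#' @return Logical.
#' @export
detect_walking <- function(omega_c, omega_0, cfg = detection_config()) {
  stopifnot(inherits(cfg, "detection_config"))
  (omega_c > omega_0) & (omega_c > cfg$amp_threshold)
}

#' Per-window walking detection over a whole trace
#'
#' Runs the full detection chain — sensitive axis, spectrum, band averages,
#' decision — on every sliding window and forms predicted activity segments
#' by attributing each window's label to its trailing 1.2 s slide interval
#' (matching the rule that each detected window contributes one slide of
#' walking duration) and merging adjacent equal labels.
#'
#' @param trace A [gyro_trace()].
#' @param windowing A [windowing_config()].
#' @param detection A [detection_config()].
#' @return A list with `records` (a data frame: `window_index`, `start_time`,
#'   `axis`, `omega_c`, `omega_0`, `is_walking`) and `segments`
#'   (a [label_segments()] tiling the trace).
#' @export
detect_trace <- function(trace, windowing = windowing_config(fs = trace$fs),
                         detection = detection_config()) {
  fit <- gyrostep(trace, windowing = windowing, detection = detection)
  list(records = fit$records[c("window_index", "start_time", "axis",
                               "omega_c", "omega_0", "is_walking")],
       segments = fit$segments)
}
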