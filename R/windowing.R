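#' Sliding-window configuration
#'
#' The analysis window is `N` samples long (a power of 2, for the radix-2
#' FFT) and advances by `hop` samples. At the defaults, `N = 64` samples at
#' 20 Hz span `(N-1)/fs = 3.15` s — slightly longer than one gait cycle —
#' and the hop of 24 samples advances the window by exactly `hop/fs = 1.2` s,
#' the per-window walking-duration increment used by the step counter. The
#' 1.2 s slide covers `hop + 1 = 25` sample instants inclusive, by the same
#' endpoint-span convention under which 64 samples span 3.15 s.
#'
#' @param N Window length in samples; must be a power of 2 (default 64).
#' @param hop Window advance in samples, `0 < hop <= N` (default 24).
#' @param fs Sampling frequency in Hz (default 20).
#' @return An object of class `windowing_config`.
#' @examples
#' cfg <- windowing_config()
#' window_span(cfg)     # 3.15 s
#' slide_duration(cfg)  # 1.2 s
#' @export
windowing_config <- function(N = 64L, hop = 24L, fs = 20) {
  N <- as.integer(N); hop <- as.integer(hop)
  if (N < 2L || bitwAnd(N, N - 1L) != 0L)
    stop("'N' must be a power of 2 (radix-2 FFT)", call. = FALSE)
  if (hop < 1L || hop > N)
    stop("'hop' must satisfy 0 < hop <= N", call. = FALSE)
  if (!is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive number", call. = FALSE)
  structure(list(N = N, hop = hop, fs = fs), class = "windowing_config")
}

#' @rdname windowing_config
#' @param cfg A `windowing_config`.
#' @export
window_span <- function(cfg) (cfg$N - 1L) / cfg$fs

#' @rdname windowing_config
#' @export
slide_duration <- function(cfg) cfg$hop / cfg$fs

#' Enumerate sliding analysis windows over a trace
#'
#' Produces the windows at sample offsets `0, hop, 2*hop, ...`; a trailing
#' stretch too short to fill a window is discarded (the spectrum assumes
#' exactly `N` real samples, so partial windows are never zero-padded).
#' The number of windows is `floor((L - N)/hop) + 1` for a trace of length
#' `L >= N`.
#'
#' @param trace A [gyro_trace()]; its sampling frequency must equal
#'   `cfg$fs` (resample first if not).
#' @param cfg A [windowing_config()].
#' @return A list of `window_view` objects, each a list with `index`
#'   (1-based ordinal), `start_sample` (0-based offset), `start_time`
#'   (seconds), `samples` (an `N x 3` matrix with columns `x`, `y`, `z`),
#'   `N` and `fs`.
#' @export
iter_windows <- function(trace, cfg = windowing_config(fs = trace$fs)) {
  stopifnot(inherits(trace, "gyro_trace"), inherits(cfg, "windowing_config"))
  if (abs(trace$fs - cfg$fs) > 1e-6 * cfg$fs)
    stop(sprintf("trace is sampled at %g Hz but the window config assumes %g Hz; resample_trace() first",
                 trace$fs, cfg$fs), call. = FALSE)
  L <- length(trace$t)
  if (L < cfg$N)
    stop(sprintf("trace has %d samples but at least N = %d are required for one window",
                 L, cfg$N), call. = FALSE)
  offsets <- seq.int(0L, L - cfg$N, by = cfg$hop)
  w <- cbind(x = trace$wx, y = trace$wy, z = trace$wz)
  lapply(seq_along(offsets), function(i) {
    o <- offsets[i]
    structure(list(index = i,
                   start_sample = o,
                   start_time = trace$t[o + 1L],
                   samples = w[(o + 1L):(o + cfg$N), , drop = FALSE],
                   N = cfg$N, fs = cfg$fs),
              class = "window_view")
  })
}
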