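#' Step-counting configuration
#'
#' @param alpha Weight of the previous estimate in the exponentially
#'   weighted moving average of the walking frequency,
#'   `f_smooth <- alpha * f_smooth_prev + (1 - alpha) * f_hat`;
#'   `0 <= alpha < 1` (default 0.8).
#' @param reset_on_gap Number of consecutive non-walking windows after which
#'   the smoothed cadence is forgotten, so the next walking bout starts
#'   afresh. Default `Inf`: the cadence persists across gaps within a trace.
#' @return An object of class `counting_config`.
#' @export
counting_config <- function(alpha = 0.8, reset_on_gap = Inf) {
  if (!is.finite(alpha) || alpha < 0 || alpha >= 1)
    stop("'alpha' must satisfy 0 <= alpha < 1", call. = FALSE)
  if (!(is.infinite(reset_on_gap) || (reset_on_gap >= 1 &&
        reset_on_gap == as.integer(reset_on_gap))))
    stop("'reset_on_gap' must be a positive integer or Inf", call. = FALSE)
  structure(list(alpha = alpha, reset_on_gap = reset_on_gap),
            class = "counting_config")
}

# Coefficients (ascending powers) of the quartic through 5 points, by
# solving the Vandermonde system. With five points and five coefficients the
# "fit" is an exact interpolation.
quartic_coefficients <- function(freq, amp) {
  stopifnot(length(freq) == 5L, length(amp) == 5L)
  solve(outer(freq, 0:4, "^"), amp)
}

# Argmax of a polynomial (ascending coefficients) over [lo, hi]: evaluate at
# the real roots of the derivative inside the interval plus the endpoints.
polynomial_argmax <- function(coef, lo, hi) {
  dcoef <- coef[-1L] * seq_len(length(coef) - 1L)
  cand <- c(lo, hi)
  if (any(dcoef != 0)) {
    r <- polyroot(dcoef)
    re <- Re(r)[abs(Im(r)) < 1e-8]
    cand <- c(cand, re[re > lo & re < hi])
  }
  vals <- vapply(cand, function(f) sum(coef * f^(0:4)), numeric(1))
  cand[which.max(vals)]
}

#' Estimate the walking frequency from a window spectrum
#'
#' The spectral bins are 0.3125 Hz apart, far coarser than cadence
#' differences of interest, so the peak bin alone is a poor cadence
#' estimate. Instead a quartic `A = a f^4 + b f^3 + c f^2 + d f + e` is
#' interpolated through the five walking-band (frequency, amplitude) pairs
#' and the estimate is the frequency maximising it. The maximisation runs
#' over the intersection of the walking band with the span of the five fit
#' frequencies (0.625-1.875 Hz at the defaults): outside the fit nodes the
#' quartic extrapolates and its values carry no spectral meaning, so the
#' extrapolated edges are excluded. Candidates are the real roots of the
#' derivative inside the interval plus its endpoints.
#'
#' When all five amplitudes are equal the quartic is flat and carries no
#' peak information; the central bin frequency is returned with
#' `degenerate = TRUE`.
#'
#' @param spec A [compute_spectrum()] result (from a window classified as
#'   walking).
#' @param cfg A [detection_config()] (supplies the walking band).
#' @return An object of class `frequency_fit`: list with `coefficients`
#'   (named `a`..`e`, descending powers), `f_hat` (Hz), `fit_points`
#'   (data frame `freq`, `amp`), `degenerate`.
#' @export
estimate_walking_frequency <- function(spec, cfg = detection_config()) {
  stopifnot(inherits(spec, "gyro_spectrum"), inherits(cfg, "detection_config"))
  bb <- band_bins(spec$freqs, spec$N, cfg)
  if (length(bb$walk) != 5L)
    stop(sprintf("the quartic interpolation needs exactly 5 walking-band bins, found %d",
                 length(bb$walk)), call. = FALSE)
  freq <- spec$freqs[bb$walk]
  amp <- spec$amps[bb$walk]
  fit_points <- data.frame(freq = freq, amp = amp)
  if (diff(range(amp)) <= 1e-12 * max(abs(amp), 1)) {
    return(structure(list(coefficients = c(a = 0, b = 0, c = 0, d = 0,
                                           e = amp[1L]),
                          f_hat = freq[3L], fit_points = fit_points,
                          degenerate = TRUE),
                     class = "frequency_fit"))
  }
  co <- quartic_coefficients(freq, amp)  # ascending: e, d, c, b, a
  lo <- max(cfg$band_walk[1L], min(freq))
  hi <- min(cfg$band_walk[2L], max(freq))
  f_hat <- polynomial_argmax(co, lo, hi)
  structure(list(coefficients = c(a = co[5L], b = co[4L], c = co[3L],
                                  d = co[2L], e = co[1L]),
                 f_hat = f_hat, fit_points = fit_points, degenerate = FALSE),
            class = "frequency_fit")
}

#' @export
print.frequency_fit <- function(x, ...) {
  cat(sprintf("<frequency_fit> f_hat = %.4f Hz%s\n", x$f_hat,
              if (x$degenerate) " (degenerate: flat spectrum)" else ""))
  invisible(x)
}

#' Smooth a walking-frequency estimate
#'
#' Exponentially weighted moving average across windows:
#' `alpha * f_prev + (1 - alpha) * f_hat`, initialised to `f_hat` when no
#' previous estimate exists (`f_prev` is `NA`).
#'
#' @param f_prev Previous smoothed cadence in Hz, or `NA` for the first
#'   walking window (or after a gap reset).
#' @param f_hat Current raw estimate, Hz.
#' @param alpha Smoothing weight on the previous estimate, `0 <= alpha < 1`.
#' @return Updated smoothed cadence, Hz.
#' @export
smooth_frequency <- function(f_prev, f_hat, alpha = 0.8) {
  if (is.na(f_prev)) f_hat else alpha * f_prev + (1 - alpha) * f_hat
}

#' Running step-count state
#'
#' Holds the accumulated walking duration `walking_time` (s), the smoothed
#' cadence `f_smooth` (Hz, `NA` until the first walking window), and the
#' real-valued running step count `steps` (`round()` it for reporting).
#' Each detected walking window adds one slide (1.2 s by default) of
#' walking duration and `slide * f_smooth` steps — the incremental form of
#' "steps = duration x cadence" that applies each window's cadence only to
#' its own slide.
#'
#' @param counting A [counting_config()].
#' @param slide Seconds of walking credited per detected window (the window
#'   slide, `hop/fs`; default 1.2).
#' @return An object of class `step_state`.
#' @seealso [update_step_count()]
#' @export
step_state <- function(counting = counting_config(), slide = 1.2) {
  stopifnot(inherits(counting, "counting_config"), slide > 0)
  structure(list(walking_time = 0, f_smooth = NA_real_, steps = 0,
                 alpha = counting$alpha, slide = slide,
                 reset_on_gap = counting$reset_on_gap, gap = 0L),
            class = "step_state")
}

#' @export
print.step_state <- function(x, ...) {
  cat(sprintf("<step_state> %.1f steps (%d rounded) over %.1f s walking; cadence %s Hz\n",
              x$steps, round(x$steps), x$walking_time,
              if (is.na(x$f_smooth)) "unset" else sprintf("%.3f", x$f_smooth)))
  invisible(x)
}

#' Advance the step-count state by one window
#'
#' If the window was classified as walking: the walking duration grows by
#' one slide, the cadence estimate from the window's spectrum is folded into
#' the smoothed cadence, and `slide * f_smooth` steps are added. Otherwise
#' the state is unchanged except for the gap counter, which can reset the
#' smoothed cadence after `reset_on_gap` consecutive non-walking windows.
#'
#' @param state A [step_state()].
#' @param record A list or one-row data frame with element `is_walking`
#'   (e.g. a [detect_trace()] record).
#' @param spec The same window's [compute_spectrum()] result (required when
#'   walking).
#' @param cfg A [detection_config()] (walking band for the cadence fit).
#' @return The updated `step_state`.
#' @export
update_step_count <- function(state, record, spec = NULL,
                              cfg = detection_config()) {
  stopifnot(inherits(state, "step_state"))
  if (isTRUE(as.logical(record$is_walking))) {
    if (is.null(spec))
      stop("'spec' is required to update the cadence for a walking window",
           call. = FALSE)
    fit <- estimate_walking_frequency(spec, cfg)
    state$f_smooth <- smooth_frequency(state$f_smooth, fit$f_hat, state$alpha)
    state$walking_time <- state$walking_time + state$slide
    state$steps <- state$steps + state$slide * state$f_smooth
    state$gap <- 0L
  } else {
    state$gap <- state$gap + 1L
    if (state$gap >= state$reset_on_gap) state$f_smooth <- NA_real_
  }
  state
}

#' Detect walking and count steps over a whole trace
#'
#' Runs detection and counting jointly in one pass (see [gyrostep()], which
#' this wraps) and returns the final [step_state()] together with the
#' per-window log.
#'
#' @inheritParams detect_trace
#' @param counting A [counting_config()].
#' @return A list with `state` (final [step_state()]), `log` (per-window
#'   data frame: `window_index`, `start_time`, `is_walking`, `f_hat`,
#'   `f_smooth`, `walking_time`, `steps`) and `segments`.
#' @export
count_trace <- function(trace, windowing = windowing_config(fs = trace$fs),
                        detection = detection_config(),
                        counting = counting_config()) {
  fit <- gyrostep(trace, windowing = windowing, detection = detection,
                  counting = counting)
  list(state = fit$state,
       log = fit$records[c("window_index", "start_time", "is_walking",
                           "f_hat", "f_smooth", "walking_time", "steps")],
       segments = fit$segments)
}
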