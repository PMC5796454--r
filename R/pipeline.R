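#' Walking detection and step counting for a gyroscope trace
#'
#' The main entry point: runs the full frequency-domain pipeline over a
#' 3-axis angular-velocity trace in a single pass. For each 64-sample
#' sliding window it (1) selects the most sensitive axis by summed absolute
#' angular velocity, (2) computes the FFT amplitude spectrum of that axis,
#' (3) averages the spectrum over the walking band (0.6-2 Hz) and the
#' sub-walking band and classifies the window as walking iff the walking
#' band dominates and exceeds the amplitude threshold, and (4) for walking
#' windows updates the smoothed cadence (quartic spectral interpolation +
#' exponentially weighted moving average) and accumulates
#' `slide x cadence` steps.
#'
#' @param trace A [gyro_trace()].
#' @param windowing A [windowing_config()]; its `fs` must match the trace.
#' @param detection A [detection_config()].
#' @param counting A [counting_config()].
#' @return An object of class `gyrostep`: a list with
#'   \describe{
#'     \item{records}{per-window data frame: `window_index`, `start_time`,
#'       `axis`, `omega_c`, `omega_0`, `is_walking`, `f_hat` (`NA` for
#'       non-walking windows), `f_smooth`, `walking_time`, `steps`
#'       (cumulative, real-valued).}
#'     \item{segments}{predicted [label_segments()] tiling the trace.}
#'     \item{state}{final [step_state()].}
#'     \item{steps}{final step count, rounded to the nearest integer.}
#'     \item{walking_time}{total detected walking duration, seconds.}
#'     \item{config}{the three configuration objects.}
#'   }
#' @examples
#' res <- generate_trace(activity_script(walk_bout(30, cadence = 1.25)),
#'                       seed = 1)
#' fit <- gyrostep(res$trace)
#' fit
#' coef(fit)
#' @export
gyrostep <- function(trace, windowing = windowing_config(fs = trace$fs),
                     detection = detection_config(),
                     counting = counting_config()) {
  stopifnot(inherits(trace, "gyro_trace"),
            inherits(windowing, "windowing_config"),
            inherits(detection, "detection_config"),
            inherits(counting, "counting_config"))
  windows <- iter_windows(trace, windowing)
  nw <- length(windows)
  state <- step_state(counting, slide = slide_duration(windowing))
  rec <- data.frame(window_index = integer(nw), start_time = numeric(nw),
                    axis = character(nw), omega_c = numeric(nw),
                    omega_0 = numeric(nw), is_walking = logical(nw),
                    f_hat = rep(NA_real_, nw), f_smooth = rep(NA_real_, nw),
                    walking_time = numeric(nw), steps = numeric(nw),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nw)) {
    w <- windows[[i]]
    axis <- select_sensitive_axis(w)
    spec <- compute_spectrum(w$samples[, axis], windowing$fs)
    bm <- band_mean_amplitudes(spec, detection)
    walking <- detect_walking(bm[["omega_c"]], bm[["omega_0"]], detection)
    f_hat <- NA_real_
    if (walking) f_hat <- estimate_walking_frequency(spec, detection)$f_hat
    state <- update_step_count(state, list(is_walking = walking), spec,
                               detection)
    rec$window_index[i] <- i
    rec$start_time[i] <- w$start_time
    rec$axis[i] <- axis
    rec$omega_c[i] <- bm[["omega_c"]]
    rec$omega_0[i] <- bm[["omega_0"]]
    rec$is_walking[i] <- walking
    rec$f_hat[i] <- f_hat
    rec$f_smooth[i] <- state$f_smooth
    rec$walking_time[i] <- state$walking_time
    rec$steps[i] <- state$steps
  }
  trace_end <- trace$t[length(trace$t)] + 1 / trace$fs
  structure(list(records = rec,
                 segments = segments_from_records(rec, windowing,
                                                  trace$t[1L], trace_end),
                 state = state,
                 steps = round(state$steps),
                 walking_time = state$walking_time,
                 config = list(windowing = windowing, detection = detection,
                               counting = counting)),
            class = "gyrostep")
}

# Predicted segments from per-window labels. Each window's label is
# attributed to its trailing slide interval (the window's last hop/fs
# seconds) -- the same span the counter credits with walking duration. The
# first/last intervals are extended to the trace bounds so the segments
# tile the whole trace; adjacent equal labels are merged.
segments_from_records <- function(records, windowing, t0, t_end) {
  span <- window_span(windowing)
  slide <- slide_duration(windowing)
  ends <- records$start_time + span
  starts <- ends - slide
  starts[1L] <- t0
  ends[length(ends)] <- max(ends[length(ends)], t_end)
  lab <- ifelse(records$is_walking, "walking", "non_walking")
  merge_segments(label_segments(starts, pmax(ends, starts + 1e-9), lab))
}

#' @export
print.gyrostep <- function(x, ...) {
  cat("Gyroscope walking detection and step counting\n")
  cat(sprintf("  windows analysed : %d (N = %d, hop = %d, fs = %g Hz)\n",
              nrow(x$records), x$config$windowing$N, x$config$windowing$hop,
              x$config$windowing$fs))
  cat(sprintf("  walking windows  : %d\n", sum(x$records$is_walking)))
  cat(sprintf("  walking duration : %.1f s\n", x$walking_time))
  cat(sprintf("  cadence (smoothed): %s\n",
              if (is.na(x$state$f_smooth)) "none detected"
              else sprintf("%.3f Hz", x$state$f_smooth)))
  cat(sprintf("  step count       : %d (raw %.2f)\n", x$steps, x$state$steps))
  invisible(x)
}

#' @export
summary.gyrostep <- function(object, ...) {
  structure(list(fit = object,
                 n_windows = nrow(object$records),
                 n_walking = sum(object$records$is_walking),
                 segments = object$segments,
                 cadence_range = if (any(object$records$is_walking))
                   range(object$records$f_hat, na.rm = TRUE) else c(NA, NA)),
            class = "summary.gyrostep")
}

#' @export
print.summary.gyrostep <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$cadence_range[1L]))
    cat(sprintf("  raw cadence range: %.3f - %.3f Hz\n",
                x$cadence_range[1L], x$cadence_range[2L]))
  cat("  predicted segments:\n")
  print.data.frame(x$segments, row.names = FALSE)
  invisible(x)
}

#' @describeIn gyrostep Headline estimates: total steps, walking seconds and
#'   final smoothed cadence (Hz).
#' @param object,... Method arguments.
#' @export
coef.gyrostep <- function(object, ...) {
  c(steps = object$steps, walking_time = object$walking_time,
    cadence = object$state$f_smooth)
}

#' @describeIn gyrostep Two-panel base-graphics display: the sensitive-axis
#'   band averages with the detection threshold, and the cumulative step
#'   count, with detected walking shaded.
#' @param x A `gyrostep` object.
#' @export
plot.gyrostep <- function(x, ...) {
  r <- x$records
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    seg <- x$segments[x$segments$label == "walking", , drop = FALSE]
    if (nrow(seg)) {
      usr <- graphics::par("usr")
      graphics::rect(seg$start, usr[3L], seg$end, usr[4L],
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
    }
  }
  graphics::plot(r$start_time, r$omega_c, type = "l",
                 xlab = "window start time [s]",
                 ylab = "band mean amplitude",
                 main = "walking-band vs sub-walking-band amplitude", ...)
  shade()
  graphics::lines(r$start_time, r$omega_0, lty = 2, col = "grey40")
  graphics::abline(h = x$config$detection$amp_threshold, col = "firebrick",
                   lty = 3)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "grey40", "firebrick"),
                   legend = c("omega_c (walking band)",
                              "omega_0 (sub-walking)", "threshold"))
  graphics::plot(r$start_time, r$steps, type = "s",
                 xlab = "window start time [s]", ylab = "cumulative steps",
                 main = "accumulated step count")
  shade()
  invisible(x)
}
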