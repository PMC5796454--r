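#' Construct a gyroscope trace
#'
#' A `gyro_trace` holds a uniformly sampled 3-axis angular-velocity time
#' series: time stamps `t` in seconds and per-axis angular velocities `wx`,
#' `wy`, `wz` in rad/s, sampled at `fs` Hz. All downstream analysis (the
#' sliding window, the FFT frequency mapping) assumes exactly uniform
#' sampling, so construction validates that successive time deltas deviate
#' from `1/fs` by less than `tol * (1/fs)`; non-uniform input is rejected
#' rather than silently fixed (use [resample_trace()] first).
#'
#' @param wx,wy,wz Numeric vectors of equal length: angular velocity about
#'   the device x, y and z axes, rad/s.
#' @param fs Sampling frequency, Hz. Inferred from the median time delta of
#'   `t` when `NULL` and `t` is given.
#' @param t Optional time stamps in seconds (monotone increasing, uniform).
#'   Defaults to `(0:(n-1))/fs`.
#' @param tol Relative tolerance on the deviation of successive time deltas
#'   from `1/fs` (default 0.1, i.e. 10% of a sample interval).
#' @return An object of class `gyro_trace`: a list with elements `t`, `wx`,
#'   `wy`, `wz`, `fs`.
#' @seealso [read_trace()], [resample_trace()]
#' @examples
#' tr <- gyro_trace(wx = sin(2 * pi * 1.25 * (0:63) / 20),
#'                  wy = numeric(64), wz = numeric(64), fs = 20)
#' tr
#' @export
gyro_trace <- function(wx, wy, wz, fs = NULL, t = NULL, tol = 0.1) {
  wx <- as.numeric(wx); wy <- as.numeric(wy); wz <- as.numeric(wz)
  n <- length(wx)
  if (n < 1L || length(wy) != n || length(wz) != n)
    stop("'wx', 'wy', 'wz' must have identical length >= 1", call. = FALSE)
  if (is.null(t)) {
    if (is.null(fs)) stop("either 'fs' or 't' must be supplied", call. = FALSE)
    t <- (seq_len(n) - 1L) / fs
  } else {
    t <- as.numeric(t)
    if (length(t) != n) stop("'t' must match the axis series length", call. = FALSE)
    if (is.null(fs)) {
      if (n < 2L) stop("cannot infer 'fs' from a single sample", call. = FALSE)
      fs <- 1 / stats::median(diff(t))
    }
  }
  if (!is.finite(fs) || fs <= 0) stop("'fs' must be a positive number", call. = FALSE)
  if (n >= 2L) {
    dt <- diff(t)
    dev <- abs(dt - 1 / fs)
    bad <- which(dev > tol / fs)
    if (length(bad))
      stop(sprintf(paste0("non-uniform sampling: delta t[%d] -> t[%d] is %.6g s, ",
                          "expected %.6g s (tolerance %g%%); resample_trace() first"),
                   bad[1L], bad[1L] + 1L, dt[bad[1L]], 1 / fs, 100 * tol),
           call. = FALSE)
  }
  structure(list(t = t, wx = wx, wy = wy, wz = wz, fs = fs),
            class = "gyro_trace")
}

#' @export
print.gyro_trace <- function(x, ...) {
  cat(sprintf("<gyro_trace> %d samples at %g Hz (%.2f s)\n",
              length(x$t), x$fs, length(x$t) / x$fs))
  invisible(x)
}

#' @export
as.data.frame.gyro_trace <- function(x, ...) {
  data.frame(t = x$t, wx = x$wx, wy = x$wy, wz = x$wz)
}

#' @export
length.gyro_trace <- function(x) length(x$t)

#' Read a gyroscope trace from CSV
#'
#' Expects a comma-separated file with a header containing at least the
#' columns `t` (seconds), `wx`, `wy`, `wz` (rad/s); extra columns are
#' ignored. The sampling frequency is inferred from the median time delta
#' unless `fs_expected` is given, and uniform sampling is validated.
#'
#' @param path Path to the CSV file.
#' @param fs_expected Expected sampling frequency in Hz, or `NULL` to infer.
#' @param tol Relative sampling-uniformity tolerance, see [gyro_trace()].
#' @param units Unit of the angular-velocity columns; `"deg/s"` input is
#'   converted to rad/s on ingest.
#' @return A validated [gyro_trace()].
#' @export
read_trace <- function(path, fs_expected = NULL, tol = 0.1,
                       units = c("rad/s", "deg/s")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "wx", "wy", "wz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("trace file '%s' lacks required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  for (col in need)
    if (!is.numeric(df[[col]]))
      stop(sprintf("trace column '%s' is not numeric in '%s'", col, path),
           call. = FALSE)
  k <- if (units == "deg/s") pi / 180 else 1
  gyro_trace(wx = k * df$wx, wy = k * df$wy, wz = k * df$wz,
             fs = fs_expected, t = df$t, tol = tol)
}

#' Write a gyroscope trace to CSV
#'
#' Emits the same dialect [read_trace()] consumes (`t,wx,wy,wz` header).
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the numbers exactly.
#'
#' @param trace A [gyro_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "gyro_trace"))
  df <- data.frame(t = sprintf("%.17g", trace$t),
                   wx = sprintf("%.17g", trace$wx),
                   wy = sprintf("%.17g", trace$wy),
                   wz = sprintf("%.17g", trace$wz))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation of all three axes onto a uniform grid at `fs_target`
#' spanning the original time range. The detection pipeline assumes its
#' nominal sampling frequency exactly (the FFT bin -> Hz mapping depends on
#' it), so traces recorded at other rates are resampled explicitly.
#'
#' @param trace A [gyro_trace()].
#' @param fs_target Target sampling frequency, Hz.
#' @return A [gyro_trace()] at `fs_target`.
#' @export
resample_trace <- function(trace, fs_target) {
  stopifnot(inherits(trace, "gyro_trace"))
  if (!is.finite(fs_target) || fs_target <= 0)
    stop("'fs_target' must be a positive number", call. = FALSE)
  n <- length(trace$t)
  if (n < 2L)
    stop("resampling needs at least 2 samples", call. = FALSE)
  t0 <- trace$t[1L]
  span <- trace$t[n] - t0
  m <- floor(span * fs_target + 1e-9)  # guard the exact-multiple boundary
  tg <- t0 + (0:m) / fs_target
  interp <- function(y) stats::approx(trace$t, y, xout = tg, rule = 2)$y
  gyro_trace(wx = interp(trace$wx), wy = interp(trace$wy),
             wz = interp(trace$wz), fs = fs_target, t = tg)
}

#' Construct labelled activity segments
#'
#' Ground-truth (or predicted) activity intervals: each row is a half-open
#' time span `[start, end)` in seconds labelled `walking` or `non_walking`.
#' Segments must be sorted, non-overlapping, with `start < end`.
#'
#' @param start,end Numeric vectors, segment bounds in seconds.
#' @param label Character vector, each `"walking"` or `"non_walking"`.
#' @return A `data.frame` of class `label_segments` with columns
#'   `start`, `end`, `label`.
#' @seealso [read_segments()], [score_detection()]
#' @export
label_segments <- function(start, end, label) {
  start <- as.numeric(start); end <- as.numeric(end)
  label <- as.character(label)
  n <- length(start)
  if (length(end) != n || length(label) != n)
    stop("'start', 'end', 'label' must have equal length", call. = FALSE)
  if (n) {
    ord <- order(start)
    start <- start[ord]; end <- end[ord]; label <- label[ord]
    bad <- setdiff(unique(label), c("walking", "non_walking"))
    if (length(bad))
      stop(sprintf("unknown label(s): %s (use 'walking'/'non_walking')",
                   paste(bad, collapse = ", ")), call. = FALSE)
    if (any(end <= start))
      stop("every segment must satisfy start < end", call. = FALSE)
    if (n > 1L && any(start[-1L] < end[-n] - 1e-9))
      stop("segments overlap", call. = FALSE)
  }
  structure(data.frame(start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("label_segments", "data.frame"))
}

#' Read activity segments from CSV
#'
#' @param path CSV file with header `start,end,label`.
#' @return A validated [label_segments()].
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("start", "end", "label"), names(df))
  if (length(miss))
    stop(sprintf("segments file '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  label_segments(df$start, df$end, df$label)
}

#' Write activity segments to CSV
#'
#' @param segments A [label_segments()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "label_segments"))
  df <- data.frame(start = sprintf("%.17g", segments$start),
                   end = sprintf("%.17g", segments$end),
                   label = segments$label)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Merge adjacent segments carrying the same label (internal).
merge_segments <- function(segments) {
  n <- nrow(segments)
  if (n <= 1L) return(segments)
  keep <- c(TRUE, segments$label[-1L] != segments$label[-n] |
                  abs(segments$start[-1L] - segments$end[-n]) > 1e-9)
  idx <- cumsum(keep)
  label_segments(start = tapply(segments$start, idx, min),
                 end = tapply(segments$end, idx, max),
                 label = segments$label[keep])
}
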