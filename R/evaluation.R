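#' Duration-based precision and recall of walking detection
#'
#' Scores predicted against ground-truth activity segments by time, not by
#' event count: `TP` is the total duration both call walking, `FP` the
#' duration predicted walking but truly non-walking, `FN` the duration truly
#' walking but predicted non-walking. Precision is `TP/(TP+FP) * 100` and
#' recall `TP/(TP+FN) * 100`. Both segment sets are clipped to their common
#' time span first, so uncovered lead-in/lead-out is not penalised. A
#' degenerate denominator (no predicted, resp. no true, walking time) yields
#' `NaN` with a warning.
#'
#' @param pred,truth [label_segments()] covering overlapping time ranges.
#' @return An object of class `detection_score`: list with `TP`, `FP`, `FN`
#'   (seconds) and `precision`, `recall` (percent).
#' @examples
#' truth <- label_segments(c(0, 10), c(10, 20), c("walking", "non_walking"))
#' pred <- label_segments(c(0, 5), c(5, 20), c("walking", "non_walking"))
#' score_detection(pred, truth)  # P = 100%, R = 50%
#' @export
score_detection <- function(pred, truth) {
  stopifnot(inherits(pred, "label_segments"), inherits(truth, "label_segments"))
  if (!nrow(pred) || !nrow(truth))
    stop("both segment sets must be non-empty", call. = FALSE)
  lo <- max(min(pred$start), min(truth$start))
  hi <- min(max(pred$end), max(truth$end))
  if (hi <= lo)
    stop("predicted and truth segments cover disjoint time ranges", call. = FALSE)
  breaks <- sort(unique(pmin(pmax(c(pred$start, pred$end,
                                    truth$start, truth$end), lo), hi)))
  a <- breaks[-length(breaks)]
  b <- breaks[-1L]
  mid <- (a + b) / 2
  lab_at <- function(seg, x) {
    i <- findInterval(x, seg$start)
    ifelse(i >= 1L & x < seg$end[pmax(i, 1L)], seg$label[pmax(i, 1L)],
           NA_character_)
  }
  pw <- lab_at(pred, mid) == "walking"
  tw <- lab_at(truth, mid) == "walking"
  dur <- b - a
  ok <- !is.na(pw) & !is.na(tw)
  TP <- sum(dur[ok & pw & tw])
  FP <- sum(dur[ok & pw & !tw])
  FN <- sum(dur[ok & !pw & tw])
  precision <- if (TP + FP > 0) 100 * TP / (TP + FP) else {
    warning("no predicted walking time: precision undefined (NaN)")
    NaN
  }
  recall <- if (TP + FN > 0) 100 * TP / (TP + FN) else {
    warning("no true walking time: recall undefined (NaN)")
    NaN
  }
  structure(list(TP = TP, FP = FP, FN = FN,
                 precision = precision, recall = recall),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("precision = %.2f%%  recall = %.2f%%  (TP %.2f s, FP %.2f s, FN %.2f s)\n",
              x$precision, x$recall, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Step-counting accuracy
#'
#' `accuracy = (1 - |s_e - s_a| / s_a) * 100` percent, penalising over- and
#' under-counting symmetrically. The accuracy can be negative when the
#' absolute error exceeds the actual count.
#'
#' @param s_e Estimated step count.
#' @param s_a Actual step count; must be positive.
#' @return An object of class `count_score`: list with `s_e`, `s_a`,
#'   `accuracy` (percent).
#' @examples
#' score_count(96, 100)  # 96%
#' @export
score_count <- function(s_e, s_a) {
  if (!is.finite(s_a) || s_a <= 0)
    stop("'s_a' (actual step count) must be positive", call. = FALSE)
  if (!is.finite(s_e) || s_e < 0)
    stop("'s_e' (estimated step count) must be non-negative", call. = FALSE)
  structure(list(s_e = s_e, s_a = s_a,
                 accuracy = (1 - abs(s_e - s_a) / s_a) * 100),
            class = "count_score")
}

#' @export
print.count_score <- function(x, ...) {
  cat(sprintf("step accuracy = %.2f%%  (estimated %g, actual %g)\n",
              x$accuracy, x$s_e, x$s_a))
  invisible(x)
}
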