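#' Detect fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Classic I-DT: a window of consecutive valid samples is grown while its
#' spatial dispersion, `max(range(x), range(y))`, stays within
#' `dispersion_deg`; a maximal window is emitted as a fixation when its
#' wall-clock span reaches `min_duration_ms`, otherwise the window start
#' slides forward by one sample. Runs of invalid samples are bridged when the
#' time between the flanking valid samples is at most `gap_tolerance_ms`
#' (bridged samples are excluded from the centroid but the duration keeps the
#' wall-clock span); longer gaps terminate the window. Saccades are never
#' materialized: only fixations are returned.
#'
#' The defaults (1 degree dispersion, 100 ms minimum duration) match the
#' spatial criterion used for the quiet-eye analysis; the proprietary
#' detector shipped with commercial eye-tracking software is not disclosed,
#' so I-DT, the standard dispersion method, is used in its place and is not
#' claimed to reproduce it.
#'
#' @param trace A [gaze_trace()].
#' @param dispersion_deg Maximum within-fixation dispersion (degrees).
#' @param min_duration_ms Minimum fixation duration (ms).
#' @param gap_tolerance_ms Longest invalid-sample gap (ms, time between
#'   flanking valid samples) bridged inside a fixation.
#' @return A data.frame with one row per fixation: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `cx_deg`, `cy_deg`, `n_samples` (valid member samples),
#'   time-ordered and non-overlapping. Zero rows if no valid samples.
#' @examples
#' tr <- gaze_trace(seq(0, 500, length.out = 31), rep(0, 31), rep(0, 31))
#' detect_fixations(tr)
#' @export
detect_fixations <- function(trace, dispersion_deg = 1.0,
                             min_duration_ms = 100,
                             gap_tolerance_ms = 75) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (!is.finite(dispersion_deg) || dispersion_deg <= 0) {
    stop("dispersion_deg must be > 0", call. = FALSE)
  }
  if (!is.finite(min_duration_ms) || min_duration_ms <= 0) {
    stop("min_duration_ms must be > 0", call. = FALSE)
  }
  keep <- which(trace$valid)
  empty <- quick_df(list(onset_ms = numeric(0), offset_ms = numeric(0),
                         duration_ms = numeric(0), cx_deg = numeric(0),
                         cy_deg = numeric(0), n_samples = integer(0)))
  if (length(keep) == 0) return(empty)
  t <- trace$t_ms[keep]
  x <- trace$x_deg[keep]
  y <- trace$y_deg[keep]
  brk <- c(0L, as.integer(diff(t) > gap_tolerance_ms))
  win <- idt_scan(t, x, y, brk, dispersion_deg, min_duration_ms)
  if (nrow(win) == 0) return(empty)
  cx <- cumsum(x)
  cy <- cumsum(y)
  lo <- win[, 1]
  hi <- win[, 2]
  nsamp <- hi - lo + 1L
  quick_df(list(
    onset_ms = t[lo],
    offset_ms = t[hi],
    duration_ms = t[hi] - t[lo],
    cx_deg = (cx[hi] - cx[lo] + x[lo]) / nsamp,
    cy_deg = (cy[hi] - cy[lo] + y[lo]) / nsamp,
    n_samples = nsamp
  ))
}

#' Per-trial gaze data quality
#'
#' Computes the two reliability ratios used to screen trials: the tracking
#' ratio (share of samples with a valid gaze estimate) and the fixation
#' ratio (share of the trial span covered by detected fixations). A trial is
#' reliable when the tracking ratio is at least `tracking_min` and the
#' fixation ratio at least `fixation_min`; the defaults (0.85, 0.60) follow
#' published recommendations for mobile eye tracking in children.
#'
#' @param trace A [gaze_trace()].
#' @param fixations Fixations from [detect_fixations()] on the same trace.
#' @param tracking_min,fixation_min Reliability thresholds, in (0, 1].
#' @return A list with `tracking_ratio`, `fixation_ratio`, `reliable`.
#' @export
compute_quality <- function(trace, fixations,
                            tracking_min = 0.85, fixation_min = 0.60) {
  stopifnot(inherits(trace, "gaze_trace"))
  n <- nrow(trace)
  if (n == 0) stop("cannot assess quality of an empty trace", call. = FALSE)
  span <- trace$t_ms[n] - trace$t_ms[1]
  if (span <= 0) stop("trace span is zero; quality undefined", call. = FALSE)
  tracking <- sum(trace$valid) / n
  fixation <- sum(fixations$duration_ms) / span
  list(tracking_ratio = tracking,
       fixation_ratio = fixation,
       reliable = tracking >= tracking_min && fixation >= fixation_min)
}
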