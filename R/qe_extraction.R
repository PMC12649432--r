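#' Clip fixations to an analysis window
#'
#' Returns the fixations overlapping a half-open window `[start, end)`, with
#' onsets/offsets clipped to the window so that summed durations stay
#' bounded by the window width. Order is preserved.
#'
#' @param fixations Fixation data.frame from [detect_fixations()].
#' @param window Numeric length-2 `c(start, end)`, end exclusive.
#' @return The overlapping fixations with clipped `onset_ms`, `offset_ms`,
#'   `duration_ms` (centroids untouched).
#' @export
window_fixations <- function(fixations, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  keep <- fixations$offset_ms > window[1] & fixations$onset_ms < window[2]
  out <- fixations[keep, , drop = FALSE]
  out$onset_ms <- pmax(out$onset_ms, window[1])
  out$offset_ms <- pmin(out$offset_ms, window[2])
  out$duration_ms <- out$offset_ms - out$onset_ms
  rownames(out) <- NULL
  out
}

#' Locate the quiet-eye fixation
#'
#' The quiet eye is the last fixation whose centroid lies within
#' `radius_deg` of the virtual target and whose onset strictly precedes
#' movement initiation. Among qualifying fixations the one with the latest
#' onset is returned; a fixation starting exactly at initiation does not
#' qualify.
#'
#' @param fixations Unclipped fixation data.frame (whole trial).
#' @param target_deg Numeric length-2 target position (degrees).
#' @param initiation_eye_ms Movement initiation on the eye clock (ms).
#' @param radius_deg Spatial criterion (degrees); default 1, the standard
#'   quiet-eye threshold.
#' @return A one-row data.frame, or `NULL` if no fixation qualifies.
#' @export
find_qe_fixation <- function(fixations, target_deg, initiation_eye_ms,
                             radius_deg = 1.0) {
  if (nrow(fixations) == 0) return(NULL)
  d <- sqrt((fixations$cx_deg - target_deg[1])^2 +
            (fixations$cy_deg - target_deg[2])^2)
  ok <- d <= radius_deg & fixations$onset_ms < initiation_eye_ms
  if (!any(ok)) return(NULL)
  cand <- fixations[ok, , drop = FALSE]
  res <- cand[which.max(cand$onset_ms), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-trial quiet-eye and fixation metrics
#'
#' Computes the four eye-behaviour variables for one throw:
#' \describe{
#'   \item{qe_onset_ms}{interval from quiet-eye fixation onset to movement
#'     initiation (positive = onset precedes initiation); `NA` if no
#'     fixation meets the quiet-eye criterion.}
#'   \item{qe_duration_ms}{full duration of the quiet-eye fixation, not
#'     truncated at initiation (standard quiet-eye convention).}
#'   \item{n_fixations}{number of fixations overlapping the pre-throw
#'     window.}
#'   \item{tt_ms}{total fixation duration: summed window-clipped fixation
#'     time, bounded by the window width.}
#' }
#'
#' @param fixations Fixations from [detect_fixations()] for the trial.
#' @param events A [trial_events()].
#' @param offset Offset from [estimate_sync_offset()].
#' @param quality Quality list from [compute_quality()].
#' @param window_ms Pre-throw window width (ms).
#' @param qe_radius_deg Quiet-eye spatial criterion (degrees).
#' @return A one-row data.frame: `participant_id`, `trial_id`, `reliable`,
#'   `qe_onset_ms`, `qe_duration_ms`, `n_fixations`, `tt_ms`, `catch`.
#' @export
trial_metrics <- function(fixations, events, offset, quality,
                          window_ms = 2000, qe_radius_deg = 1.0) {
  stopifnot(inherits(events, "trial_events"))
  win <- pre_throw_window(events, offset, window_ms)
  on <- fixations$onset_ms
  off <- fixations$offset_ms
  inwin <- off > win[1] & on < win[2]
  initiation_eye <- to_eye_clock(events$initiation_ms, offset)
  dist <- sqrt((fixations$cx_deg - events$target_deg[1])^2 +
               (fixations$cy_deg - events$target_deg[2])^2)
  qe_ok <- which(dist <= qe_radius_deg & on < initiation_eye)
  qe <- if (length(qe_ok) == 0) NULL else qe_ok[which.max(on[qe_ok])]
  quick_df(list(
    participant_id = events$participant_id,
    trial_id = events$trial_id,
    reliable = isTRUE(quality$reliable),
    qe_onset_ms = if (is.null(qe)) NA_real_ else initiation_eye - on[qe],
    qe_duration_ms = if (is.null(qe)) NA_real_ else off[qe] - on[qe],
    n_fixations = sum(inwin),
    tt_ms = sum(pmin(off[inwin], win[2]) - pmax(on[inwin], win[1])),
    catch = events$catch
  ))
}

#' Aggregate trial metrics to participant level
#'
#' Arithmetic means over reliable trials only; quiet-eye means additionally
#' restrict to reliable trials that possess a quiet-eye fixation (no zero
#' imputation, so "no target fixation" is not conflated with "brief
#' fixation"). A participant with fewer than `min_valid` reliable trials is
#' flagged excluded and carries `NA` metrics.
#'
#' @param trials Data.frame of rows from [trial_metrics()], one participant.
#' @param min_valid Minimum reliable-trial count for inclusion.
#' @return One-row data.frame: `participant_id`, `qe_onset_ms`,
#'   `qe_duration_ms`, `n_fixations`, `tt_ms`, `n_valid_trials`,
#'   `n_catches`, `excluded`.
#' @export
aggregate_participant <- function(trials, min_valid = 5) {
  pid <- unique(trials$participant_id)
  if (length(pid) != 1) {
    stop("trials must belong to a single participant", call. = FALSE)
  }
  rel <- trials[trials$reliable, , drop = FALSE]
  excluded <- nrow(rel) < min_valid
  qe <- rel[!is.na(rel$qe_onset_ms), , drop = FALSE]
  mean_or_na <- function(v) if (length(v) == 0 || excluded) NA_real_ else mean(v)
  data.frame(
    participant_id = pid,
    qe_onset_ms = mean_or_na(qe$qe_onset_ms),
    qe_duration_ms = mean_or_na(qe$qe_duration_ms),
    n_fixations = mean_or_na(rel$n_fixations),
    tt_ms = mean_or_na(rel$tt_ms),
    n_valid_trials = nrow(rel),
    n_catches = sum(rel$catch, na.rm = TRUE),
    excluded = excluded
  )
}
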