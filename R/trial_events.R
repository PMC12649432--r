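#' Per-trial kinematic event annotations
#'
#' Holds the landmarks digitized from the external (side-view) camera
#' together with the optical synchronization flash seen by both cameras:
#' movement initiation (first frame of elbow-angle increase), ball release
#' (first frame the ball leaves the hand), the virtual target position in
#' the scene frame (the wall location of the ball rebound), and the catch
#' outcome. Times on the external clock except `flash_t_eye_ms`.
#'
#' @param flash_t_eye_ms Flash time on the eye-tracker stream clock (ms).
#' @param flash_t_ext_ms Flash time on the external-camera clock (ms).
#' @param initiation_ms Movement initiation (external clock, ms).
#' @param release_ms Ball release (external clock, ms).
#' @param target_deg Numeric length-2, virtual target in scene-frame degrees.
#' @param catch Logical, whether the rebound was caught.
#' @param participant_id,trial_id Identifiers.
#' @return An object of class `trial_events`.
#' @export
trial_events <- function(flash_t_eye_ms, flash_t_ext_ms,
                         initiation_ms, release_ms,
                         target_deg = c(NA_real_, NA_real_),
                         catch = NA,
                         participant_id = NA_character_,
                         trial_id = NA_character_) {
  if (is.finite(initiation_ms) && is.finite(release_ms)) {
    if (initiation_ms >= release_ms) {
      stop("movement initiation must precede ball release", call. = FALSE)
    }
    span <- release_ms - initiation_ms
    if (span < 100 || span > 2000) {
      warning(sprintf(
        "initiation-to-release span of %.0f ms is outside the plausible [100, 2000] ms range",
        span), call. = FALSE)
    }
  }
  structure(list(flash_t_eye_ms = flash_t_eye_ms,
                 flash_t_ext_ms = flash_t_ext_ms,
                 initiation_ms = initiation_ms,
                 release_ms = release_ms,
                 target_deg = as.numeric(target_deg),
                 catch = as.logical(catch),
                 participant_id = participant_id,
                 trial_id = trial_id),
            class = "trial_events")
}

#' Estimate the eye/external clock offset from the optical flash
#'
#' The two recordings are synchronized by a single flash of light captured
#' simultaneously by the eye-tracker scene camera and the external camera.
#' A single constant offset per recording is assumed (no drift model).
#'
#' @param events A [trial_events()].
#' @return A list with `offset_ms` = `flash_t_ext_ms - flash_t_eye_ms`.
#' @export
estimate_sync_offset <- function(events) {
  stopifnot(inherits(events, "trial_events"))
  if (!is.finite(events$flash_t_eye_ms) || !is.finite(events$flash_t_ext_ms)) {
    stop("cannot synchronize: flash timestamp missing", call. = FALSE)
  }
  list(offset_ms = events$flash_t_ext_ms - events$flash_t_eye_ms)
}

#' Map an external-camera time to the eye-tracker clock
#'
#' @param t_ext Time(s) on the external clock (ms).
#' @param offset Offset from [estimate_sync_offset()].
#' @return Time(s) on the eye clock (ms): `t_ext - offset_ms`.
#' @export
to_eye_clock <- function(t_ext, offset) {
  if (!is.finite(offset$offset_ms)) stop("offset must be finite", call. = FALSE)
  t_ext - offset$offset_ms
}

#' Release-anchored pre-throw analysis window
#'
#' Half-open interval `[release - width_ms, release)` on the eye clock. The
#' 2000 ms default covers the whole preparatory phase: movement initiation
#' in throwing typically occurs about 600 ms before release, so preparatory
#' processing begins around 1400 ms before release.
#'
#' @param events A [trial_events()].
#' @param offset Offset from [estimate_sync_offset()].
#' @param width_ms Window width (ms), > 0.
#' @return Numeric length-2 `c(start, end)`, end exclusive, eye clock.
#' @export
pre_throw_window <- function(events, offset, width_ms = 2000) {
  stopifnot(inherits(events, "trial_events"))
  if (!is.finite(width_ms) || width_ms <= 0) {
    stop("width_ms must be > 0", call. = FALSE)
  }
  if (!is.finite(events$release_ms)) {
    stop("ball-release time missing", call. = FALSE)
  }
  release_eye <- to_eye_clock(events$release_ms, offset)
  c(release_eye - width_ms, release_eye)
}

#' Read per-trial event annotations
#'
#' Reads a CSV (or JSON array) of trial event records with fields
#' `participant_id`, `trial_id`, `flash_t_eye_ms`, `flash_t_ext_ms`,
#' `initiation_ms`, `release_ms`, `target_x_deg`, `target_y_deg`, `catch`.
#'
#' @param file Path to the events file.
#' @return A list of [trial_events()] objects.
#' @export
read_trial_events <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(file)
  } else {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
  }
  need <- c("participant_id", "trial_id", "flash_t_eye_ms", "flash_t_ext_ms",
            "initiation_ms", "release_ms", "target_x_deg", "target_y_deg",
            "catch")
  if (!all(need %in% names(d))) {
    stop("events file lacks required fields: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(d)), function(i) {
    trial_events(d$flash_t_eye_ms[i], d$flash_t_ext_ms[i],
                 d$initiation_ms[i], d$release_ms[i],
                 c(d$target_x_deg[i], d$target_y_deg[i]),
                 catch = d$catch[i],
                 participant_id = as.character(d$participant_id[i]),
                 trial_id = as.character(d$trial_id[i]))
  })
}

#' Write per-trial event annotations as CSV
#'
#' @param events_list A list of [trial_events()] objects.
#' @param file Output path.
#' @export
write_trial_events <- function(events_list, file) {
  num <- function(v) formatC(v, digits = 17, format = "g")
  d <- do.call(rbind, lapply(events_list, function(e) {
    data.frame(participant_id = e$participant_id, trial_id = e$trial_id,
               flash_t_eye_ms = num(e$flash_t_eye_ms),
               flash_t_ext_ms = num(e$flash_t_ext_ms),
               initiation_ms = num(e$initiation_ms),
               release_ms = num(e$release_ms),
               target_x_deg = num(e$target_deg[1]),
               target_y_deg = num(e$target_deg[2]),
               catch = e$catch)
  }))
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
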