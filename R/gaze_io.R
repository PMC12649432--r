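#' Scene-camera specification
#'
#' Describes the head-mounted tracker's scene camera and gaze stream. The
#' defaults match a mobile eye-tracking-glasses setup recording the forward
#' view at 1280 x 960 pixels with a 60 degree horizontal and 46 degree
#' vertical field of view, and a 60 Hz gaze sample stream.
#'
#' @param width_px,height_px Scene-camera frame size in pixels.
#' @param hfov_deg,vfov_deg Horizontal / vertical field of view in degrees.
#' @param sample_rate_hz Nominal gaze sampling rate in Hz.
#' @return An object of class `camera_spec`.
#' @examples
#' camera_spec()
#' @export
camera_spec <- function(width_px = 1280, height_px = 960,
                        hfov_deg = 60, vfov_deg = 46,
                        sample_rate_hz = 60) {
  fields <- c(width_px = width_px, height_px = height_px,
              hfov_deg = hfov_deg, vfov_deg = vfov_deg,
              sample_rate_hz = sample_rate_hz)
  if (any(!is.finite(fields)) || any(fields <= 0)) {
    stop("all camera_spec fields must be positive and finite", call. = FALSE)
  }
  structure(as.list(fields), class = "camera_spec")
}

#' Convert scene-camera pixel coordinates to degrees of visual angle
#'
#' Linear (constant degrees-per-pixel) map with the origin at the frame
#' centre, x positive rightward and y positive upward. The map is affine, not
#' tangent-corrected; at the eccentricities relevant for a 1 degree quiet-eye
#' criterion the linearization error is negligible and the choice is isolated
#' here.
#'
#' @param px Numeric vector of length 2 `(x, y)`, or a two-column matrix of
#'   pixel coordinates (column 1 = x, origin at the top-left corner, y down,
#'   as in image coordinates).
#' @param camera A [camera_spec()].
#' @return Degree coordinates in the same shape as `px`.
#' @examples
#' pixels_to_degrees(c(640, 480), camera_spec())  # frame centre -> (0, 0)
#' @export
pixels_to_degrees <- function(px, camera = camera_spec()) {
  stopifnot(inherits(camera, "camera_spec"))
  sx <- camera$hfov_deg / camera$width_px
  sy <- camera$vfov_deg / camera$height_px
  if (is.matrix(px)) {
    cbind((px[, 1] - camera$width_px / 2) * sx,
          (camera$height_px / 2 - px[, 2]) * sy)
  } else {
    c((px[1] - camera$width_px / 2) * sx,
      (camera$height_px / 2 - px[2]) * sy)
  }
}

#' Construct a gaze trace
#'
#' A gaze trace is a data.frame of timestamped gaze samples in scene-camera
#' (head-fixed) degrees together with the camera specification and trial
#' identity. Invalid samples (lost pupil) are retained, carrying `NA`
#' coordinates, so that the tracking ratio keeps its denominator.
#'
#' @param t_ms Numeric vector of sample timestamps (ms, stream clock),
#'   strictly increasing.
#' @param x_deg,y_deg Gaze position in degrees (head-fixed, 0 at scene
#'   centre, y up). May be `NA` where `valid` is `FALSE`.
#' @param valid Logical vector; `FALSE` marks samples without a usable gaze
#'   estimate.
#' @param camera A [camera_spec()].
#' @param participant_id,trial_id Identifiers.
#' @param pupil_mm Optional pupil diameter (mm).
#' @return A `gaze_trace`: a data.frame with columns `t_ms`, `x_deg`,
#'   `y_deg`, `valid`, `pupil_mm` and attributes `camera`, `participant_id`,
#'   `trial_id`.
#' @export
gaze_trace <- function(t_ms, x_deg, y_deg, valid = TRUE,
                       camera = camera_spec(),
                       participant_id = NA_character_,
                       trial_id = NA_character_,
                       pupil_mm = NA_real_) {
  n <- length(t_ms)
  valid <- rep_len(as.logical(valid), n)
  pupil_mm <- rep_len(as.numeric(pupil_mm), n)
  if (n == 0) stop("gaze trace must contain at least one sample", call. = FALSE)
  if (length(x_deg) != n || length(y_deg) != n) {
    stop("x_deg and y_deg must match t_ms in length", call. = FALSE)
  }
  dt <- diff(t_ms)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    stop(sprintf("timestamps must be strictly increasing; violation at row %d",
                 bad), call. = FALSE)
  }
  valid[valid & (is.na(x_deg) | is.na(y_deg))] <- FALSE
  tr <- quick_df(list(t_ms = as.numeric(t_ms), x_deg = as.numeric(x_deg),
                      y_deg = as.numeric(y_deg), valid = valid,
                      pupil_mm = pupil_mm))
  structure(tr, camera = camera, participant_id = participant_id,
            trial_id = trial_id, class = c("gaze_trace", "data.frame"))
}

#' Read a gaze sample table
#'
#' Reads the plain CSV gaze dialect: header `t_ms,x,y,valid,pupil_mm`,
#' decimal point, comma separator, UTF-8. `x`/`y` are either degrees
#' (default) or scene-camera pixels (`units = "px"`), in which case they are
#' converted with [pixels_to_degrees()]. Rows with empty/NA coordinates or a
#' false/zero `valid` flag become invalid samples with `NA` coordinates.
#'
#' @param file Path or connection.
#' @param camera A [camera_spec()].
#' @param units `"deg"` (default) or `"px"`.
#' @param participant_id,trial_id Identifiers attached to the trace.
#' @return A [gaze_trace()].
#' @export
read_gaze_table <- function(file, camera = camera_spec(),
                            units = c("deg", "px"),
                            participant_id = NA_character_,
                            trial_id = NA_character_) {
  units <- match.arg(units)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("t_ms", "x", "y", "valid")
  if (!all(need %in% names(d))) {
    stop("malformed gaze table header: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(d$pupil_mm)) d$pupil_mm <- NA_real_
  valid <- !is.na(d$valid) & (d$valid %in% c(TRUE, 1, "1", "TRUE", "true"))
  valid <- valid & !is.na(d$x) & !is.na(d$y)
  x <- as.numeric(d$x)
  y <- as.numeric(d$y)
  if (units == "px") {
    deg <- pixels_to_degrees(cbind(x, y), camera)
    x <- deg[, 1]
    y <- deg[, 2]
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  gaze_trace(d$t_ms, x, y, valid, camera = camera,
             participant_id = participant_id, trial_id = trial_id,
             pupil_mm = as.numeric(d$pupil_mm))
}

#' Write a gaze trace in the CSV gaze dialect
#'
#' Inverse of [read_gaze_table()] (degree units); a read-write-read
#' round-trip reproduces the samples exactly.
#'
#' @param trace A [gaze_trace()].
#' @param file Path or connection.
#' @export
write_gaze_table <- function(trace, file) {
  stopifnot(inherits(trace, "gaze_trace"))
  num <- function(v) {
    # 17 significant digits: doubles survive the text round trip exactly
    out <- formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- ""
    out
  }
  out <- data.frame(t_ms = num(trace$t_ms), x = num(trace$x_deg),
                    y = num(trace$y_deg), valid = trace$valid,
                    pupil_mm = num(trace$pupil_mm))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
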