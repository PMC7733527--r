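#' Motion-capture recording
#'
#' Labeled 3-D marker trajectories sharing one sampling rate and frame count.
#' By convention the vertical axis is `z` (up positive), configurable for
#' exports that use a different lab frame.
#'
#' @param markers Named list; each element a list with `x`, `y`, `z`
#'   [sampled_series()] in millimetres.
#' @param rate_hz Common sampling rate.
#' @param meta Named list of free-form header key/values.
#' @param vertical_axis `"x"`, `"y"` or `"z"` (default).
#' @return A `nodsync_mocap` object.
#' @export
mocap_recording <- function(markers, rate_hz, meta = list(),
                            vertical_axis = "z") {
  if (length(markers) < 1L || is.null(names(markers)) ||
      any(!nzchar(names(markers)))) {
    abort_nodsync("at least one named marker is required",
                  "nodsync_precondition_error")
  }
  vertical_axis <- match.arg(vertical_axis, c("x", "y", "z"))
  lens <- unlist(lapply(markers, function(m)
    vapply(m[c("x", "y", "z")], n_frames, integer(1))))
  if (length(unique(lens)) != 1L) {
    abort_nodsync("all marker channels must share one frame count",
                  "nodsync_precondition_error")
  }
  rates <- unlist(lapply(markers, function(m)
    vapply(m[c("x", "y", "z")], function(s) s$rate_hz, numeric(1))))
  if (any(rates != rate_hz)) {
    abort_nodsync("all marker channels must share rate_hz",
                  "nodsync_precondition_error")
  }
  structure(list(markers = markers, rate_hz = rate_hz,
                 n_frames = unname(lens[1]), meta = meta,
                 vertical_axis = vertical_axis),
            class = "nodsync_mocap")
}

#' @export
print.nodsync_mocap <- function(x, ...) {
  cat(sprintf("<nodsync_mocap> %d markers x %d frames @ %g Hz (%.2f s)\n",
              length(x$markers), x$n_frames, x$rate_hz,
              x$n_frames / x$rate_hz))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one marker axis as a series
#'
#' @param mocap A [mocap_recording()].
#' @param marker Marker label.
#' @param axis Axis name; defaults to the recording's vertical axis.
#' @return A [sampled_series()].
#' @export
marker_channel <- function(mocap, marker, axis = mocap$vertical_axis) {
  stopifnot(inherits(mocap, "nodsync_mocap"))
  if (!marker %in% names(mocap$markers)) {
    abort_nodsync(sprintf("marker '%s' not found (have: %s)", marker,
                          paste(names(mocap$markers), collapse = ", ")),
                  "nodsync_format_error")
  }
  mocap$markers[[marker]][[match.arg(axis, c("x", "y", "z"))]]
}

#' Eye-tracker recording
#'
#' Per-frame pupil image coordinates plus a validity flag. Frames where the
#' pupil was not detected (blinks, tracking loss) are marked missing in both
#' pupil channels.
#'
#' @param pupil_x,pupil_y Numeric vectors or [sampled_series()] in image px.
#' @param valid Logical vector: pupil detected in that frame.
#' @param rate_hz Sampling rate (50 Hz for the supported tracker class).
#' @param meta Named list of header key/values.
#' @return A `nodsync_gaze` object.
#' @export
gaze_recording <- function(pupil_x, pupil_y, valid, rate_hz, meta = list()) {
  as_chan <- function(v) {
    if (inherits(v, "nodsync_series")) v$values else as.numeric(v)
  }
  px <- as_chan(pupil_x); py <- as_chan(pupil_y)
  valid <- as.logical(valid)
  if (length(px) != length(py) || length(px) != length(valid)) {
    abort_nodsync("pupil channels and validity mask must share length",
                  "nodsync_precondition_error")
  }
  miss <- !valid | is.na(px) | is.na(py)
  structure(list(
    pupil_x = sampled_series(px, rate_hz, missing = miss, units = "px"),
    pupil_y = sampled_series(py, rate_hz, missing = miss, units = "px"),
    valid = !miss, rate_hz = rate_hz, meta = meta
  ), class = "nodsync_gaze")
}

#' @export
print.nodsync_gaze <- function(x, ...) {
  cat(sprintf(
    "<nodsync_gaze> %d frames @ %g Hz (%.2f s), %d invalid\n",
    n_frames(x$pupil_y), x$rate_hz, n_frames(x$pupil_y) / x$rate_hz,
    sum(!x$valid)))
  invisible(x)
}
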