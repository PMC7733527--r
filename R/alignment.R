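#' Temporal offset between two sync points
#'
#' The offset is the mocap sync time minus the eye sync time, each on its own
#' clock. The mocap system is conventionally started first, so the offset is
#' normally positive and equals the amount to trim from the start of the
#' mocap recording.
#'
#' @param sp_mocap,sp_eye [sync_point()]s (or plain times in seconds).
#' @return Offset in seconds (positive: mocap started earlier).
#' @export
compute_offset <- function(sp_mocap, sp_eye) {
  t_of <- function(sp) if (inherits(sp, "nodsync_sync_point")) sp$time_s else
    as.numeric(sp)
  t_of(sp_mocap) - t_of(sp_eye)
}

#' Period of one frame in milliseconds
#'
#' Convenience for expressing accuracies in frame units: 120 Hz -> 8.3 ms,
#' 200 Hz -> 5 ms, 50 Hz -> 20 ms.
#'
#' @param rate_hz Sampling rate.
#' @return Milliseconds per frame.
#' @export
frame_period_ms <- function(rate_hz) 1000 / rate_hz

#' Trim the earlier-started stream so the nods align
#'
#' A non-negative offset removes `round(offset_s * mocap rate)` frames from
#' the start of every mocap channel; a negative offset (the eye tracker
#' started first, not the usual protocol but supported by symmetry) trims the
#' gaze stream instead. Trimming whole frames is the only lossless choice
#' without resampling; the sub-frame remainder is reported as `residual_s`.
#'
#' @param mocap A [mocap_recording()].
#' @param gaze A [gaze_recording()].
#' @param offset_s Seconds, from [compute_offset()].
#' @return A list with the trimmed `mocap`, `gaze`, and a `sync` element of
#'   class `nodsync_sync_result` (fields `offset_s`, `trimmed_stream`,
#'   `trimmed_frames`, `residual_s`).
#' @export
trim_to_sync <- function(mocap, gaze, offset_s) {
  stopifnot(inherits(mocap, "nodsync_mocap"), inherits(gaze, "nodsync_gaze"))
  if (offset_s >= 0) {
    rate <- mocap$rate_hz
    k <- as.integer(round(offset_s * rate))
    if (k >= mocap$n_frames) {
      abort_nodsync("offset exceeds the mocap stream duration",
                    "nodsync_alignment_error")
    }
    if (k > 0) {
      drop1 <- function(s) series_with(s, s$values[-seq_len(k)],
                                       missing = s$missing[-seq_len(k)])
      mocap$markers <- lapply(mocap$markers, function(m) lapply(m, drop1))
      mocap$n_frames <- mocap$n_frames - k
    }
    trimmed_stream <- "mocap"
  } else {
    rate <- gaze$rate_hz
    k <- as.integer(round(-offset_s * rate))
    if (k >= n_frames(gaze$pupil_y)) {
      abort_nodsync("offset exceeds the gaze stream duration",
                    "nodsync_alignment_error")
    }
    if (k > 0) {
      idx <- -seq_len(k)
      gaze <- gaze_recording(gaze$pupil_x$values[idx],
                             gaze$pupil_y$values[idx],
                             gaze$valid[idx], gaze$rate_hz, gaze$meta)
    }
    trimmed_stream <- "eye"
  }
  residual <- abs(offset_s) - k / rate
  sync <- structure(list(offset_s = offset_s, trimmed_stream = trimmed_stream,
                         trimmed_frames = k, residual_s = residual),
                    class = "nodsync_sync_result")
  list(mocap = mocap, gaze = gaze, sync = sync)
}

#' @export
print.nodsync_sync_result <- function(x, ...) {
  cat(sprintf(
    "<sync result> offset %.4f s; trimmed %d %s frames (residual %+.4f s)\n",
    x$offset_s, x$trimmed_frames, x$trimmed_stream, x$residual_s))
  invisible(x)
}

#' Drift between two streams from a start/end nod pair
#'
#' Each stream measures, on its own clock, the duration between its start-nod
#' and end-nod sync points. If both clocks ran true, the durations are equal;
#' a consistent sign in the difference over long recordings indicates clock
#' drift (a "faster" eye tracker yields a negative difference).
#'
#' @param start_m,end_m Mocap start/end [sync_point()]s (or times in seconds).
#' @param start_e,end_e Eye-tracker start/end sync points (or seconds).
#' @return A `nodsync_drift_report` with `mocap_duration_s`, `eye_duration_s`
#'   and `difference_s = eye - mocap`.
#' @export
evaluate_drift <- function(start_m, end_m, start_e, end_e) {
  t_of <- function(sp) if (inherits(sp, "nodsync_sync_point")) sp$time_s else
    as.numeric(sp)
  dm <- t_of(end_m) - t_of(start_m)
  de <- t_of(end_e) - t_of(start_e)
  if (dm <= 0 || de <= 0) {
    abort_nodsync("end-nod sync point must come after the start nod",
                  "nodsync_drift_error")
  }
  structure(list(mocap_duration_s = dm, eye_duration_s = de,
                 difference_s = de - dm),
            class = "nodsync_drift_report")
}

#' @export
print.nodsync_drift_report <- function(x, ...) {
  cat(sprintf(
    "<drift report> mocap %.3f s, eye %.3f s, difference %+.3f s\n",
    x$mocap_duration_s, x$eye_duration_s, x$difference_s))
  invisible(x)
}

#' Summarize drift across sessions
#'
#' Aggregates per-session duration differences as the mean of their absolute
#' values (rounding errors make individual signs flip, so the magnitude is
#' the informative per-participant statistic), plus range and count.
#'
#' @param reports A list of `nodsync_drift_report`s, or a numeric vector of
#'   duration differences in seconds.
#' @return A one-row tibble: `n`, `mean_abs_s`, `min_s`, `max_s`.
#' @export
summarize_drift <- function(reports) {
  d <- if (is.numeric(reports)) reports else
    vapply(reports, function(r) {
      stopifnot(inherits(r, "nodsync_drift_report"))
      r$difference_s
    }, numeric(1))
  if (length(d) == 0L) {
    abort_nodsync("no drift reports to summarize",
                  "nodsync_precondition_error")
  }
  tibble::tibble(n = length(d), mean_abs_s = mean(abs(d)),
                 min_s = min(d), max_s = max(d))
}
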