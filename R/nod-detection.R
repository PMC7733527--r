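#' Nod-detection parameters
#'
#' @param threshold_z Detection threshold on the z-scored velocity (default
#'   -2): the nod's velocity minimum must fall below this value. Negative by
#'   contract; adjustable because nod vigour varies across settings.
#' @param prefix_zero_mocap_s Seconds of mocap velocity zeroed at the start
#'   (default 1.5; the mocap system is started first, so its settling window
#'   is longer).
#' @param prefix_zero_pupil_s Seconds of pupil velocity zeroed (default 1.0).
#' @param filt [filter_params()] for the smoothed differentiation.
#' @param dip_sign +1 if the nod is a minimum in the raw channel (mocap z up,
#'   image y down both give minima for a downward nod), -1 to flip a channel
#'   whose axis polarity is inverted.
#' @param sd_type z-scoring convention, see [zscore_series()].
#' @param blink_overlap_max If the gap-filled (interpolated) fraction of the
#'   nod's velocity flanks exceeds this (default 0.5), the sync point is
#'   flagged low-confidence: the dip was largely reconstructed from a blink.
#' @param prominence_min Post-hoc nod check: the detected velocity minimum
#'   must exceed `prominence_min` (default 5) times the channel's robust
#'   noise scale (MAD). A real nod towers over the noise floor; when a blink
#'   swallows the nod entirely, gap-filling leaves only noise, whose z-scored
#'   extremes still dip below -2 — the prominence check flags such
#'   detections low-confidence instead of reporting a spurious sync point.
#' @return A `nodsync_nod_params` list.
#' @export
nod_params <- function(threshold_z = -2, prefix_zero_mocap_s = 1.5,
                       prefix_zero_pupil_s = 1.0, filt = filter_params(),
                       dip_sign = 1, sd_type = "sample",
                       blink_overlap_max = 0.5, prominence_min = 5) {
  if (!is.numeric(threshold_z) || threshold_z >= 0) {
    abort_nodsync("threshold_z must be negative", "nodsync_config_error")
  }
  if (prefix_zero_mocap_s < 0 || prefix_zero_pupil_s < 0) {
    abort_nodsync("prefix durations must be >= 0", "nodsync_config_error")
  }
  if (!dip_sign %in% c(-1, 1)) {
    abort_nodsync("dip_sign must be +1 or -1", "nodsync_config_error")
  }
  structure(list(threshold_z = threshold_z,
                 prefix_zero_mocap_s = prefix_zero_mocap_s,
                 prefix_zero_pupil_s = prefix_zero_pupil_s,
                 filt = filt, dip_sign = dip_sign, sd_type = sd_type,
                 blink_overlap_max = blink_overlap_max,
                 prominence_min = prominence_min),
            class = "nodsync_nod_params")
}

#' Synchronization point in one stream
#'
#' @param frame 0-based frame index in the stream's own frames.
#' @param rate_hz The stream's sampling rate; `time_s = frame / rate_hz`.
#' @param channel_id Which stream (e.g. `"mocap"`, `"eye"`).
#' @param method `"velocity"` (peak-picking + zero-crossing) or
#'   `"position_minimum"` (the validation oracle).
#' @param low_confidence `TRUE` when the supporting flanks were mostly
#'   gap-filled (blink collision).
#' @return A `nodsync_sync_point`.
#' @export
sync_point <- function(frame, rate_hz, channel_id = "",
                       method = c("velocity", "position_minimum"),
                       low_confidence = FALSE) {
  method <- match.arg(method)
  frame <- as.integer(frame)
  if (frame < 0L) {
    abort_nodsync("frame index must be >= 0", "nodsync_precondition_error")
  }
  structure(list(frame = frame, time_s = frame / rate_hz, rate_hz = rate_hz,
                 channel_id = channel_id, method = method,
                 low_confidence = isTRUE(low_confidence)),
            class = "nodsync_sync_point")
}

#' @export
print.nodsync_sync_point <- function(x, ...) {
  cat(sprintf("<sync point> %s: frame %d (%.4f s) [%s]%s\n", x$channel_id,
              x$frame, x$time_s, x$method,
              if (x$low_confidence) " LOW CONFIDENCE" else ""))
  invisible(x)
}

#' Prepare a raw channel for nod detection
#'
#' Runs the fixed preparation chain: flip by `dip_sign`, gap-fill, smoothed
#' differentiation, prefix zeroing, z-scoring. The z-score statistics include
#' the zeroed prefix, so the threshold applies to the stream as processed, not
#' to a trimmed version of it.
#'
#' @param raw A [sampled_series()] (position channel; may contain gaps).
#' @param params [nod_params()].
#' @param prefix_s Prefix-zeroing duration for this stream (pass
#'   `params$prefix_zero_mocap_s` or `params$prefix_zero_pupil_s`).
#' @return A z-scored velocity series ready for [detect_sync_point()]; carries
#'   the `"filled"` attribute marking interpolated frames.
#' @export
prepare_channel <- function(raw, params = nod_params(), prefix_s = 0) {
  stopifnot(inherits(raw, "nodsync_series"))
  x <- raw
  if (params$dip_sign == -1) {
    x <- sampled_series(-x$values, x$rate_hz, x$start_s, x$missing, x$units)
  }
  x <- fill_gaps_linear(x)
  x <- differentiate_velocity(x, params$filt)
  x <- zero_prefix(x, prefix_s)
  zscore_series(x, sd_type = params$sd_type)
}

# strict local minima; a flat minimal plateau contributes its first frame.
# returns 1-based indices.
local_minima_idx <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  if (k < 3L) return(integer(0))
  i <- 2L:(k - 1L)
  is_min <- runs$values[i] < runs$values[i - 1L] &
    runs$values[i] < runs$values[i + 1L]
  starts[i][is_min]
}

#' Locate the nod sync point in a z-scored velocity channel
#'
#' Forward direction (start nod): scan in increasing time for the first local
#' minimum below `threshold_z`; from there, the first frame pair with
#' `vz[n] < 0` and `vz[n+1] >= 0` marks the velocity zero-crossing at the
#' nod's apex, and frame `n` — the frame before the crossing — is the sync
#' point. Reverse direction (end nod): scan from the end of the recording for
#' the first qualifying minimum (i.e. the last one in forward time), then
#' apply the same forward zero-crossing rule. The velocity is never exactly
#' zero in practice, which is why the frame before the sign change is used.
#'
#' @param vz Z-scored velocity series from [prepare_channel()].
#' @param threshold_z Negative detection threshold (default -2).
#' @param direction `"forward"` or `"reverse"`.
#' @param channel_id Stream label carried into the result.
#' @param blink_overlap_max See [nod_params()]; used only when `vz` carries a
#'   `"filled"` attribute.
#' @param prominence_min See [nod_params()]; set to 0 to disable the
#'   prominence check.
#' @return A [sync_point()] with `method = "velocity"`.
#' @export
detect_sync_point <- function(vz, threshold_z = -2,
                              direction = c("forward", "reverse"),
                              channel_id = "", blink_overlap_max = 0.5,
                              prominence_min = 5) {
  stopifnot(inherits(vz, "nodsync_series"))
  direction <- match.arg(direction)
  if (threshold_z >= 0) {
    abort_nodsync("threshold_z must be negative", "nodsync_config_error")
  }
  v <- vz$values
  mins <- local_minima_idx(v)
  mins <- mins[v[mins] < threshold_z]
  if (length(mins) == 0L) {
    abort_nodsync(sprintf("no local minimum below %g found (%s)",
                          threshold_z, channel_id),
                  "nodsync_no_nod_error")
  }
  m <- if (direction == "forward") mins[1L] else mins[length(mins)]
  # forward zero-crossing rule from the minimum, in both directions
  n <- length(v)
  cross <- NA_integer_
  if (m < n) {
    idx <- m:(n - 1L)
    hit <- idx[v[idx] < 0 & v[idx + 1L] >= 0]
    if (length(hit)) cross <- hit[1L]
  }
  if (is.na(cross)) {
    abort_nodsync(sprintf(
      "velocity never crosses zero after the minimum at frame %d (%s)",
      m - 1L, channel_id), "nodsync_no_zero_crossing_error")
  }
  low_conf <- FALSE
  if (prominence_min > 0) {
    noise_scale <- stats::mad(v)
    low_conf <- noise_scale > 0 && abs(v[m]) < prominence_min * noise_scale
  }
  filled <- attr(vz, "filled")
  if (!is.null(filled)) {
    # nod support: from the last non-negative frame before the minimum to the
    # frame after the zero-crossing
    lo <- m
    while (lo > 1L && v[lo - 1L] < 0) lo <- lo - 1L
    hi <- min(cross + 1L, n)
    frac <- mean(filled[lo:hi])
    low_conf <- low_conf || (is.finite(frac) && frac > blink_overlap_max)
  }
  sync_point(cross - 1L, vz$rate_hz, channel_id, "velocity",
             low_confidence = low_conf)
}

#' Position-minimum ground truth
#'
#' The validation oracle: the frame of the global minimum of the (gap-filled)
#' vertical position channel within a window, i.e. the point of maximal
#' downward dislocation of the head during the nod. This replaces manual
#' inspection of the position trace and lets the velocity-based detector be
#' checked automatically.
#'
#' @param position Gap-free position [sampled_series()].
#' @param window Optional `c(start_s, end_s)` on the stream's own clock;
#'   default: the whole stream.
#' @return A [sync_point()] with `method = "position_minimum"`; ties go to the
#'   first frame.
#' @export
ground_truth_minimum <- function(position, window = NULL) {
  stopifnot(inherits(position, "nodsync_series"))
  if (any(position$missing)) {
    abort_nodsync("position channel must be gap-filled first",
                  "nodsync_precondition_error")
  }
  t <- series_times(position)
  keep <- if (is.null(window)) rep(TRUE, length(t)) else
    t >= window[1] & t <= window[2]
  if (!any(keep)) {
    abort_nodsync("search window contains no frames",
                  "nodsync_precondition_error")
  }
  idx <- which(keep)
  best <- idx[which.min(position$values[idx])]
  sync_point(best - 1L, position$rate_hz, method = "position_minimum")
}
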