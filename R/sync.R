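#' Detect the nod sync point in both streams and compute the offset
#'
#' Runs the full detection chain on the vertical head-marker channel and the
#' vertical pupil channel — gap-fill, smoothed differentiation, prefix
#' zeroing, z-scoring, thresholded peak-picking, zero-crossing — and returns
#' the per-stream sync points together with the inter-stream offset
#' (mocap sync time minus eye sync time).
#'
#' @param mocap A [mocap_recording()].
#' @param gaze A [gaze_recording()].
#' @param marker Head-marker label (default `"head_front_left"`).
#' @param params [nod_params()].
#' @param direction `"forward"` for the start nod, `"reverse"` for the end
#'   nod. The channel preparation is identical in both directions; a reverse
#'   scan reports its sync point relative to the recording start, so no
#'   trimming is implied.
#' @return A `nodsync_fit` with elements `sp_mocap`, `sp_eye`, `offset_s`,
#'   the prepared velocity channels (`vz_mocap`, `vz_eye`) and the inputs'
#'   rates. Use [glance()] / [tidy()] for tabular views and
#'   [trim_to_sync()] to apply the offset.
#' @export
sync_nod <- function(mocap, gaze, marker = "head_front_left",
                     params = nod_params(),
                     direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(mocap, "nodsync_mocap"), inherits(gaze, "nodsync_gaze"))
  vz_m <- prepare_channel(marker_channel(mocap, marker), params,
                          params$prefix_zero_mocap_s)
  vz_e <- prepare_channel(gaze$pupil_y, params, params$prefix_zero_pupil_s)
  sp_m <- detect_sync_point(vz_m, params$threshold_z, direction, "mocap",
                            params$blink_overlap_max, params$prominence_min)
  sp_e <- detect_sync_point(vz_e, params$threshold_z, direction, "eye",
                            params$blink_overlap_max, params$prominence_min)
  structure(list(sp_mocap = sp_m, sp_eye = sp_e,
                 offset_s = compute_offset(sp_m, sp_e),
                 vz_mocap = vz_m, vz_eye = vz_e,
                 marker = marker, direction = direction, params = params),
            class = "nodsync_fit")
}

#' @export
print.nodsync_fit <- function(x, ...) {
  cat(sprintf("<nodsync_fit> (%s nod)\n", x$direction))
  print(x$sp_mocap); print(x$sp_eye)
  cat(sprintf("  offset (mocap - eye): %.4f s\n", x$offset_s))
  invisible(x)
}

#' Full drift evaluation from a start and an end nod
#'
#' Detects the start nod (forward scan) and the end nod (reverse scan) in
#' both streams, then compares the durations between them on each stream's
#' own clock. Equal-length sessions give a difference near zero; a
#' consistently negative difference over long sessions means the eye
#' tracker's clock runs fast relative to the mocap system.
#'
#' @inheritParams sync_nod
#' @return A `nodsync_drift_report` (see [evaluate_drift()]) with the four
#'   sync points attached as attribute `"fits"`.
#' @export
drift_nod <- function(mocap, gaze, marker = "head_front_left",
                      params = nod_params()) {
  start_fit <- sync_nod(mocap, gaze, marker, params, "forward")
  end_fit <- sync_nod(mocap, gaze, marker, params, "reverse")
  rep <- evaluate_drift(start_fit$sp_mocap, end_fit$sp_mocap,
                        start_fit$sp_eye, end_fit$sp_eye)
  attr(rep, "fits") <- list(start = start_fit, end = end_fit)
  rep
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.nodsync_fit <- function(x, ...) {
  tibble::tibble(
    channel = c("mocap", "eye"),
    frame = c(x$sp_mocap$frame, x$sp_eye$frame),
    time_s = c(x$sp_mocap$time_s, x$sp_eye$time_s),
    rate_hz = c(x$sp_mocap$rate_hz, x$sp_eye$rate_hz),
    method = c(x$sp_mocap$method, x$sp_eye$method),
    low_confidence = c(x$sp_mocap$low_confidence, x$sp_eye$low_confidence)
  )
}

#' @exportS3Method generics::glance
glance.nodsync_fit <- function(x, ...) {
  tibble::tibble(
    offset_s = x$offset_s,
    mocap_sync_s = x$sp_mocap$time_s,
    eye_sync_s = x$sp_eye$time_s,
    direction = x$direction,
    low_confidence = x$sp_mocap$low_confidence || x$sp_eye$low_confidence
  )
}

#' @exportS3Method generics::tidy
tidy.nodsync_drift_report <- function(x, ...) {
  tibble::tibble(
    mocap_duration_s = x$mocap_duration_s,
    eye_duration_s = x$eye_duration_s,
    difference_s = x$difference_s
  )
}

#' @exportS3Method generics::glance
glance.nodsync_drift_report <- function(x, ...) tidy(x, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.nodsync_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$vz_mocap), channel = "mocap"),
    dplyr::mutate(as_tibble(object$vz_eye), channel = "eye"))
  sp <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$params$threshold_z,
                        linetype = "dashed", colour = "darkorange") +
    ggplot2::geom_vline(data = sp, ggplot2::aes(xintercept = .data$time_s),
                        colour = "red") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "time on own clock [s]", y = "z-scored velocity",
                  title = sprintf("nod sync points (%s), offset %.3f s",
                                  object$direction, object$offset_s)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
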