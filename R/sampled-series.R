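#' Uniformly sampled scalar channel
#'
#' The universal signal currency of the package: a numeric vector sampled at a
#' fixed rate on one device's own clock, with a per-frame missing mask for
#' marker occlusions and blinks. Frames are 0-based; frame `n` occurs at
#' `start_s + n / rate_hz` seconds on that clock.
#'
#' @param values Numeric vector, one sample per frame. `NA` entries are taken
#'   as missing unless `missing` says otherwise.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param start_s Clock time of frame 0 in seconds (default 0).
#' @param missing Logical vector marking invalid frames; defaults to
#'   `is.na(values)`.
#' @param units Optional unit label (e.g. `"mm"`, `"px"`, `"mm/s"`, `"z"`).
#'
#' @return An object of class `nodsync_series`.
#' @examples
#' s <- sampled_series(c(1, NA, 3), rate_hz = 50)
#' n_frames(s)
#' as_tibble(s)
#' @export
sampled_series <- function(values, rate_hz, start_s = 0, missing = NULL,
                           units = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    abort_nodsync("a sampled series needs at least one frame",
                  "nodsync_precondition_error")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    abort_nodsync("rate_hz must be a single positive number",
                  "nodsync_precondition_error")
  }
  if (is.null(missing)) missing <- is.na(values)
  missing <- as.logical(missing)
  if (length(missing) != length(values)) {
    abort_nodsync("missing mask must match the series length",
                  "nodsync_precondition_error")
  }
  missing <- missing | is.na(values)
  structure(
    list(values = values, rate_hz = as.numeric(rate_hz),
         start_s = as.numeric(start_s), missing = missing, units = units),
    class = "nodsync_series"
  )
}

#' @rdname sampled_series
#' @param x A `nodsync_series`.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.nodsync_series <- function(x) length(x$values)

#' @rdname sampled_series
#' @export
series_duration <- function(x) {
  stopifnot(inherits(x, "nodsync_series"))
  n_frames(x) / x$rate_hz
}

#' Clock times of every frame
#' @param x A `nodsync_series`.
#' @return Numeric vector of times in seconds on the stream's own clock.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "nodsync_series"))
  x$start_s + (seq_along(x$values) - 1L) / x$rate_hz
}

# internal: clone with new values, keeping clock metadata
series_with <- function(x, values, missing = rep(FALSE, length(values)),
                        units = x$units) {
  sampled_series(values, rate_hz = x$rate_hz, start_s = x$start_s,
                 missing = missing, units = units)
}

#' @export
print.nodsync_series <- function(x, ...) {
  cat(sprintf("<nodsync_series> %d frames @ %g Hz (%.3f s)%s, %d missing\n",
              n_frames(x), x$rate_hz, series_duration(x),
              if (is.null(x$units)) "" else paste0(" [", x$units, "]"),
              sum(x$missing)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @exportS3Method tibble::as_tibble
as_tibble.nodsync_series <- function(x, ...) {
  tibble::tibble(
    frame = seq_along(x$values) - 1L,
    time_s = series_times(x),
    value = x$values,
    missing = x$missing
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.nodsync_series <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(data = df[df$missing, ], colour = "red", size = 0.8) +
    ggplot2::labs(x = "time [s]",
                  y = if (is.null(object$units)) "value" else object$units) +
    ggplot2::theme_minimal()
}
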