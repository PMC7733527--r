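#' Smoothing-filter parameters for velocity computation
#'
#' Parameters of the low-pass Butterworth smoothing applied after numerical
#' differentiation. The filter runs forward and backward (zero-phase) so the
#' timing of the nod's velocity minimum and zero-crossing is not shifted.
#'
#' The cutoff defaults to 10 Hz: a quick head nod lasts a few hundred
#' milliseconds, so its velocity content sits well below 10 Hz, while
#' frame-to-frame sensor noise sits above.
#'
#' @param order Filter order (default 2).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the Nyquist rate of
#'   the series it is applied to.
#' @param zero_phase Apply forward-backward (default `TRUE`). A single forward
#'   pass delays the dip and is only useful for diagnostics.
#' @return A `nodsync_filter_params` list.
#' @export
filter_params <- function(order = 2, cutoff_hz = 10, zero_phase = TRUE) {
  if (order < 1) {
    abort_nodsync("filter order must be >= 1", "nodsync_filter_error")
  }
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) {
    abort_nodsync("cutoff_hz must be positive", "nodsync_filter_error")
  }
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "nodsync_filter_params")
}

#' Linearly fill gaps in a sampled series
#'
#' Replaces every run of missing samples (blinks in the pupil trace, marker
#' occlusions in the mocap trace) by linear interpolation between the nearest
#' valid neighbours, irrespective of gap length. Leading and trailing missing
#' runs have only one valid neighbour and are filled by holding its value.
#' Valid samples pass through unchanged.
#'
#' @param series A [sampled_series()].
#' @return The series with an all-`FALSE` missing mask. An attribute
#'   `"filled"` records which frames were interpolated, so downstream
#'   detection can flag sync points whose supporting flanks were mostly
#'   reconstructed from a blink.
#' @export
fill_gaps_linear <- function(series) {
  stopifnot(inherits(series, "nodsync_series"))
  miss <- series$missing
  if (all(miss)) {
    abort_nodsync("cannot gap-fill a series with no valid sample",
                  "nodsync_gap_fill_error")
  }
  v <- series$values
  if (any(miss)) {
    idx <- seq_along(v)
    # rule = 2 holds the nearest valid value at the edges
    v <- stats::approx(idx[!miss], v[!miss], xout = idx, method = "linear",
                       rule = 2)$y
  }
  out <- series_with(series, v)
  attr(out, "filled") <- miss
  out
}

#' Instantaneous velocity by smoothed numerical differentiation
#'
#' Computes frame-to-frame velocity with central differences (one-sided at the
#' edges) scaled to units per second, then low-pass filters the result with a
#' Butterworth smoothing filter applied forward and backward so the net phase
#' shift is zero. Zero phase matters: the velocity zero-crossing at the nod's
#' apex must not move in time, or the synchronization point would be biased.
#'
#' @param series A gap-free [sampled_series()]; run [fill_gaps_linear()] first.
#' @param filt [filter_params()].
#' @return A series of equal length and rate in units/s. The `"filled"`
#'   attribute of the input, if any, is carried through.
#' @export
differentiate_velocity <- function(series, filt = filter_params()) {
  stopifnot(inherits(series, "nodsync_series"))
  if (any(series$missing)) {
    abort_nodsync("series still contains missing samples; gap-fill first",
                  "nodsync_precondition_error")
  }
  x <- series$values
  n <- length(x)
  # filtfilt's internal padding needs a few filter lengths of data
  min_len <- max(2L * filt$order + 1L, 3L * (filt$order + 1L))
  if (n < min_len) {
    abort_nodsync(sprintf("series too short to filter (%d < %d frames)",
                          n, min_len), "nodsync_filter_error")
  }
  nyq <- series$rate_hz / 2
  if (filt$cutoff_hz >= nyq) {
    abort_nodsync(sprintf("cutoff %g Hz is not below the Nyquist rate %g Hz",
                          filt$cutoff_hz, nyq), "nodsync_filter_error")
  }
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * series$rate_hz
  v[n] <- (x[n] - x[n - 1L]) * series$rate_hz
  if (n > 2L) {
    i <- 2L:(n - 1L)
    v[i] <- (x[i + 1L] - x[i - 1L]) * series$rate_hz / 2
  }
  bw <- signal::butter(filt$order, filt$cutoff_hz / nyq, type = "low")
  v <- if (filt$zero_phase) signal::filtfilt(bw, v) else
    as.numeric(signal::filter(bw, v))
  units <- if (is.null(series$units)) "units/s" else paste0(series$units, "/s")
  out <- series_with(series, v, units = units)
  attr(out, "filled") <- attr(series, "filled")
  out
}

#' Zero out the first seconds of a series
#'
#' Recording devices are started consecutively, so the first moments of each
#' stream can contain settling artefacts (the participant not yet fixating the
#' target). Zeroing the prefix removes spurious velocity minima there before
#' peak-picking. The stream started first gets the longer prefix.
#'
#' @param series A [sampled_series()].
#' @param duration_s Seconds to zero from the start; the first
#'   `floor(duration_s * rate_hz)` frames are set to 0.
#' @return The modified series (missing mask and `"filled"` attribute kept).
#' @export
zero_prefix <- function(series, duration_s) {
  stopifnot(inherits(series, "nodsync_series"))
  if (duration_s < 0 || duration_s > series_duration(series)) {
    abort_nodsync(sprintf(
      "prefix duration %.3f s outside the series duration %.3f s",
      duration_s, series_duration(series)), "nodsync_prefix_error")
  }
  k <- floor(duration_s * series$rate_hz)
  v <- series$values
  if (k > 0) v[seq_len(min(k, length(v)))] <- 0
  out <- series_with(series, v, missing = series$missing)
  attr(out, "filled") <- attr(series, "filled")
  out
}

#' Standardize a series to mean 0, sd 1
#'
#' Participants nod at different speeds, so raw velocity scales differ; after
#' z-scoring, one detection threshold (in z-units) works across participants.
#' Statistics are computed over all samples, including any zeroed prefix.
#'
#' @param series A gap-free [sampled_series()].
#' @param sd_type `"sample"` (divide by n-1, the default, matching the common
#'   statistics-toolbox convention) or `"population"` (divide by n). The
#'   detection threshold is expressed in these units, so the convention is
#'   pinned and configurable rather than implicit.
#' @return The standardized series (units `"z"`).
#' @export
zscore_series <- function(series, sd_type = c("sample", "population")) {
  stopifnot(inherits(series, "nodsync_series"))
  sd_type <- match.arg(sd_type)
  x <- series$values
  if (any(series$missing)) {
    abort_nodsync("z-scoring requires a gap-free series",
                  "nodsync_precondition_error")
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) {
    abort_nodsync("cannot z-score a constant series (sd = 0)",
                  "nodsync_degenerate_series_error")
  }
  out <- series_with(series, (x - m) / s, units = "z")
  attr(out, "filled") <- attr(series, "filled")
  out
}
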