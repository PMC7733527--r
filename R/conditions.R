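# Classed conditions so callers (and the CLI) can branch on failure modes
# without string-matching messages.

abort_nodsync <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "nodsync_error"), ...)
}

#' @name nodsync-conditions
#' @title Condition classes signalled by nodsync
#' @description
#' All errors raised by the package inherit from `nodsync_error` plus one
#' specific class:
#' \describe{
#'   \item{`nodsync_gap_fill_error`}{gap-filling a series with no valid sample}
#'   \item{`nodsync_filter_error`}{series too short for the smoothing filter,
#'     or an invalid cutoff}
#'   \item{`nodsync_precondition_error`}{an operation's input contract violated
#'     (e.g. missing samples where none are allowed, empty window)}
#'   \item{`nodsync_prefix_error`}{prefix-zeroing duration outside the series}
#'   \item{`nodsync_degenerate_series_error`}{z-scoring a constant series}
#'   \item{`nodsync_no_nod_error`}{no velocity minimum below the threshold}
#'   \item{`nodsync_no_zero_crossing_error`}{a sub-threshold minimum was found
#'     but the velocity never crosses zero afterwards}
#'   \item{`nodsync_format_error`}{unparseable or inconsistent input file}
#'   \item{`nodsync_alignment_error`}{offset exceeds the stream to be trimmed}
#'   \item{`nodsync_drift_error`}{end-nod sync point not after the start nod}
#'   \item{`nodsync_config_error`}{invalid simulation or run configuration}
#'   \item{`nodsync_io_error`}{unwritable output location}
#' }
#' @keywords internal
NULL
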