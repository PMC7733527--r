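#' Read a motion-capture TSV export
#'
#' Parses the tab-separated text dialect produced by optical mocap suites: a
#' header of `KEY<TAB>value...` lines — `FREQUENCY` and `MARKER_NAMES` are
#' required, others (e.g. `NO_OF_FRAMES`) are kept as metadata — followed by
#' one row per frame with an X/Y/Z triplet per marker, in millimetres.
#' Unparseable cells (e.g. `NULL` for an occluded marker) become missing
#' samples.
#'
#' @param path File path.
#' @param vertical_axis Which axis is vertical in this lab frame (default
#'   `"z"`).
#' @return A [mocap_recording()].
#' @export
read_mocap_tsv <- function(path, vertical_axis = "z") {
  if (!file.exists(path)) {
    abort_nodsync(paste("file not found:", path), "nodsync_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_data_row <- function(ln) {
    first <- strsplit(ln, "\t", fixed = TRUE)[[1]][1]
    first == "NULL" || !is.na(suppressWarnings(as.numeric(first)))
  }
  n_head <- 0L
  while (n_head < length(lines) && !is_data_row(lines[n_head + 1L])) {
    n_head <- n_head + 1L
  }
  meta <- list()
  for (ln in lines[seq_len(n_head)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  if (is.null(meta$FREQUENCY) || is.null(meta$MARKER_NAMES)) {
    abort_nodsync("header must declare FREQUENCY and MARKER_NAMES",
                  "nodsync_format_error")
  }
  rate <- suppressWarnings(as.numeric(meta$FREQUENCY[1]))
  if (!is.finite(rate) || rate <= 0) {
    abort_nodsync("FREQUENCY must be a positive number",
                  "nodsync_format_error")
  }
  marker_names <- meta$MARKER_NAMES
  body <- lines[-seq_len(n_head)]
  if (length(body) == 0L) {
    abort_nodsync("no data rows found", "nodsync_format_error")
  }
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_exp <- 3L * length(marker_names)
  bad <- which(lengths(cells) != ncol_exp)
  if (length(bad)) {
    abort_nodsync(sprintf("row %d has %d columns, expected %d",
                          bad[1], lengths(cells)[bad[1]], ncol_exp),
                  "nodsync_format_error")
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(body),
           ncol = ncol_exp, byrow = TRUE))
  markers <- purrr::imap(
    stats::setNames(seq_along(marker_names), marker_names),
    function(i, nm) {
      cols <- (i - 1L) * 3L + 1:3
      list(x = sampled_series(mat[, cols[1]], rate, units = "mm"),
           y = sampled_series(mat[, cols[2]], rate, units = "mm"),
           z = sampled_series(mat[, cols[3]], rate, units = "mm"))
    })
  mocap_recording(markers, rate, meta = meta, vertical_axis = vertical_axis)
}

#' Write a motion-capture recording in the TSV dialect
#'
#' @param mocap A [mocap_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mocap_tsv <- function(mocap, path) {
  stopifnot(inherits(mocap, "nodsync_mocap"))
  fmt_chan <- function(s) {
    out <- sprintf("%.6f", s$values)
    out[s$missing | !is.finite(s$values)] <- "NULL"
    out
  }
  cols <- unlist(lapply(mocap$markers, function(m)
    list(fmt_chan(m$x), fmt_chan(m$y), fmt_chan(m$z))), recursive = FALSE)
  body <- do.call(paste, c(cols, sep = "\t"))
  header <- c(
    paste0("NO_OF_FRAMES\t", mocap$n_frames),
    paste0("FREQUENCY\t", format(mocap$rate_hz, digits = 12)),
    paste0("MARKER_NAMES\t", paste(names(mocap$markers), collapse = "\t")))
  ok <- tryCatch({
    writeLines(c(header, body), path); TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort_nodsync(paste("cannot write", path), "nodsync_io_error")
  }
  invisible(path)
}

#' Column mapping for delimited eye-tracker exports
#'
#' Vendor export schemas vary; a column map names the delimiter, decimal
#' separator and the columns holding the frame counter, timestamps, pupil
#' image coordinates and the validity flag. The shipped default matches a
#' tab-separated export with point decimals and columns `frame`, `time_s`,
#' `pupil_x`, `pupil_y`, `valid`.
#'
#' @param delimiter One of `"\t"`, `";"`, `","`.
#' @param decimal `"."` or `","`.
#' @param frame,time,pupil_x,pupil_y,validity Column names (character) or
#'   1-based indices (numeric). `frame` and `time` may be `NULL` if absent.
#' @param header_rows 1 if the first row holds column names, 0 for headerless
#'   files addressed by index.
#' @param rate_hz Sampling rate; if `NULL`, inferred from the time column as
#'   the reciprocal of the median frame interval.
#' @return A `nodsync_column_map`.
#' @export
column_map <- function(delimiter = "\t", decimal = ".", frame = "frame",
                       time = "time_s", pupil_x = "pupil_x",
                       pupil_y = "pupil_y", validity = "valid",
                       header_rows = 1, rate_hz = NULL) {
  if (!delimiter %in% c("\t", ";", ",")) {
    abort_nodsync("delimiter must be tab, semicolon or comma",
                  "nodsync_format_error")
  }
  if (delimiter == "," && decimal == ",") {
    abort_nodsync("comma cannot be both delimiter and decimal separator",
                  "nodsync_format_error")
  }
  structure(list(delimiter = delimiter, decimal = decimal, frame = frame,
                 time = time, pupil_x = pupil_x, pupil_y = pupil_y,
                 validity = validity, header_rows = header_rows,
                 rate_hz = rate_hz),
            class = "nodsync_column_map")
}

resolve_col <- function(df, spec, what, required = TRUE) {
  if (is.null(spec)) {
    if (required) {
      abort_nodsync(paste("no column mapped for", what),
                    "nodsync_format_error")
    }
    return(NULL)
  }
  if (is.numeric(spec)) {
    if (spec < 1 || spec > ncol(df)) {
      abort_nodsync(sprintf("column index %d for %s out of range (%d cols)",
                            as.integer(spec), what, ncol(df)),
                    "nodsync_format_error")
    }
    return(df[[spec]])
  }
  if (!spec %in% names(df)) {
    if (required) {
      abort_nodsync(sprintf("column '%s' (%s) not found", spec, what),
                    "nodsync_format_error")
    }
    return(NULL)
  }
  df[[spec]]
}

#' Read an eye-tracker numeric export
#'
#' Parses a delimited per-frame export into a [gaze_recording()]. Frames
#' whose validity flag is false, or whose pupil cells are non-numeric, are
#' marked missing. The sampling rate comes from the column map if given,
#' otherwise from the median interval of the time column.
#'
#' @param path File path.
#' @param colmap A [column_map()].
#' @return A [gaze_recording()].
#' @export
read_gaze_export <- function(path, colmap = column_map()) {
  stopifnot(inherits(colmap, "nodsync_column_map"))
  if (!file.exists(path)) {
    abort_nodsync(paste("file not found:", path), "nodsync_format_error")
  }
  df <- tryCatch(
    utils::read.table(path, sep = colmap$delimiter, dec = colmap$decimal,
                      header = colmap$header_rows >= 1,
                      skip = max(0, colmap$header_rows - 1),
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) abort_nodsync(
      paste("cannot parse", path, ":", conditionMessage(e)),
      "nodsync_format_error"))
  as_num <- function(v) suppressWarnings(as.numeric(v))
  px <- as_num(resolve_col(df, colmap$pupil_x, "pupil_x"))
  py <- as_num(resolve_col(df, colmap$pupil_y, "pupil_y"))
  vraw <- resolve_col(df, colmap$validity, "validity")
  valid <- if (is.logical(vraw)) vraw else as_num(vraw) != 0
  valid[is.na(valid)] <- FALSE
  tcol <- resolve_col(df, colmap$time, "time", required = is.null(colmap$rate_hz))
  rate <- colmap$rate_hz
  if (is.null(rate)) {
    tt <- as_num(tcol)
    dt <- diff(tt)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      abort_nodsync("time column is not strictly increasing",
                    "nodsync_format_error")
    }
    rate <- 1 / stats::median(dt)
  }
  gaze_recording(px, py, valid & !is.na(px) & !is.na(py), rate,
                 meta = list(source = path))
}

#' Write an eye-tracker export in a column-map dialect
#'
#' @param gaze A [gaze_recording()].
#' @param path Output path.
#' @param colmap A [column_map()] with character column names.
#' @return `path`, invisibly.
#' @export
write_gaze_export <- function(gaze, path, colmap = column_map()) {
  stopifnot(inherits(gaze, "nodsync_gaze"),
            inherits(colmap, "nodsync_column_map"))
  n <- n_frames(gaze$pupil_y)
  num <- function(v) {
    out <- sprintf("%.6f", v)
    if (colmap$decimal == ",") out <- gsub(".", ",", out, fixed = TRUE)
    out
  }
  cols <- list(); nms <- character(0)
  if (!is.null(colmap$frame)) {
    cols <- c(cols, list(as.character(seq_len(n) - 1L)))
    nms <- c(nms, colmap$frame)
  }
  if (!is.null(colmap$time)) {
    cols <- c(cols, list(num((seq_len(n) - 1L) / gaze$rate_hz)))
    nms <- c(nms, colmap$time)
  }
  cols <- c(cols, list(num(gaze$pupil_x$values), num(gaze$pupil_y$values),
                       as.character(as.integer(gaze$valid))))
  nms <- c(nms, colmap$pupil_x, colmap$pupil_y, colmap$validity)
  body <- do.call(paste, c(cols, sep = colmap$delimiter))
  lines <- if (colmap$header_rows >= 1) {
    c(paste(nms, collapse = colmap$delimiter), body)
  } else body
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) abort_nodsync(paste("cannot write", path), "nodsync_io_error")
  invisible(path)
}

#' Write an aligned session: both streams plus a sync report
#'
#' Writes the (typically trimmed) mocap recording and gaze recording back in
#' their text dialects, plus a YAML sync report recording the offset, the
#' sync points and the rates, so downstream annotation tools can reconstruct
#' the alignment.
#'
#' @param mocap A [mocap_recording()].
#' @param gaze A [gaze_recording()].
#' @param out_dir Output directory (created if needed).
#' @param sync Optional list/`nodsync_sync_result` with `offset_s`; sync
#'   points may be supplied as `sp_mocap` / `sp_eye`.
#' @param colmap [column_map()] for the gaze file.
#' @return Named character vector of the three paths
#'   (`mocap`, `gaze`, `report`).
#' @export
write_aligned <- function(mocap, gaze, out_dir, sync = NULL,
                          colmap = column_map()) {
  stopifnot(inherits(mocap, "nodsync_mocap"), inherits(gaze, "nodsync_gaze"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_nodsync(paste("cannot create", out_dir),
                           "nodsync_io_error")
  }
  paths <- c(mocap = file.path(out_dir, "mocap_aligned.tsv"),
             gaze = file.path(out_dir, "gaze_aligned.tsv"),
             report = file.path(out_dir, "sync_report.yaml"))
  write_mocap_tsv(mocap, paths[["mocap"]])
  write_gaze_export(gaze, paths[["gaze"]], colmap)
  report <- list(
    offset_s = if (is.null(sync)) NA else sync$offset_s,
    mocap_sync_frame = if (!is.null(sync$sp_mocap)) sync$sp_mocap$frame else NA,
    mocap_sync_s = if (!is.null(sync$sp_mocap)) sync$sp_mocap$time_s else NA,
    eye_sync_frame = if (!is.null(sync$sp_eye)) sync$sp_eye$frame else NA,
    eye_sync_s = if (!is.null(sync$sp_eye)) sync$sp_eye$time_s else NA,
    rates = list(mocap_hz = mocap$rate_hz, eye_hz = gaze$rate_hz))
  yaml::write_yaml(report, paths[["report"]])
  paths
}
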