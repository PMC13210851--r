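#' Raw sensor recording
#'
#' The in-memory form of one acquisition file: integer millisecond
#' timestamps (strictly increasing) and three sensor channels.
#'
#' @param timestamps_ms Integer vector of timestamps in milliseconds.
#' @param channels Numeric matrix with 3 columns (x, y, z), one row per
#'   timestamp; m/s^2 for accelerometers, rad/s for gyroscopes.
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param placement `"pocket"` or `"wrist"`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(timestamps_ms, channels,
                          sensor_kind = c("accelerometer", "gyroscope"),
                          placement = c("pocket", "wrist")) {
  sensor_kind <- match.arg(sensor_kind)
  placement <- match.arg(placement)
  channels <- as.matrix(channels)
  if (ncol(channels) != 3L) {
    stop("channels must have exactly 3 columns", call. = FALSE)
  }
  if (nrow(channels) != length(timestamps_ms)) {
    stop("channels and timestamps length mismatch", call. = FALSE)
  }
  if (length(timestamps_ms) > 1L) {
    d <- diff(as.numeric(timestamps_ms))
    if (any(d <= 0)) {
      row <- which(d <= 0)[1] + 1L
      stop("timestamps not strictly increasing at row ", row,
           call. = FALSE)
    }
  }
  if (is.null(colnames(channels))) colnames(channels) <- c("x", "y", "z")
  structure(list(sensor_kind = sensor_kind,
                 timestamps_ms = as.numeric(timestamps_ms),
                 channels = channels,
                 placement = placement),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s (%s), %d samples, %.1f s\n",
              x$sensor_kind, x$placement, length(x$timestamps_ms),
              diff(range(x$timestamps_ms)) / 1000))
  invisible(x)
}

#' Trial start/stop markers
#'
#' A pair of sample indices on the raw accelerometer axis bracketing the
#' active walking region (the stationary pads lie outside them).
#'
#' @param i_start_raw,i_stop_raw 1-based sample indices.
#' @param raw_length Total raw recording length (for validation); may be
#'   `NULL` to skip the upper-bound check.
#' @return A list of class `trial_markers`.
#' @export
trial_markers <- function(i_start_raw, i_stop_raw, raw_length = NULL) {
  i_start_raw <- as.integer(i_start_raw)
  i_stop_raw <- as.integer(i_stop_raw)
  if (i_start_raw < 1L || i_start_raw >= i_stop_raw) {
    stop("markers must satisfy 1 <= i_start_raw < i_stop_raw",
         call. = FALSE)
  }
  if (!is.null(raw_length) && i_stop_raw > raw_length) {
    stop("i_stop_raw exceeds recording length", call. = FALSE)
  }
  structure(list(i_start_raw = i_start_raw, i_stop_raw = i_stop_raw),
            class = "trial_markers")
}

#' Read one sensor CSV file
#'
#' The acquisition format is a four-column comma-separated file:
#' `timestamp_ms` then the three sensor axes, dot decimal separator, one
#' header row.
#'
#' @param path File path.
#' @param sensor_kind `"accelerometer"` or `"gyroscope"`.
#' @param placement Device placement recorded in the returned object.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, sensor_kind = "accelerometer",
                           placement = "pocket") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = "numeric", showProgress = FALSE)
  if (ncol(dt) != 4L) {
    stop("expected 4 columns (timestamp + 3 axes), got ", ncol(dt),
         " in ", path, call. = FALSE)
  }
  if (nrow(dt) > 0 && !all(vapply(dt, is.numeric, logical(1)))) {
    stop("non-numeric values in ", path, call. = FALSE)
  }
  ch <- as.matrix(dt[, 2:4])
  colnames(ch) <- c("x", "y", "z")
  raw_recording(dt[[1]], ch, sensor_kind = sensor_kind,
                placement = placement)
}

#' Write one sensor CSV file
#'
#' Inverse of [read_recording()]: four columns, full double precision, so
#' that a write/read round trip preserves values exactly.
#'
#' @param recording A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  dt <- data.table::data.table(
    timestamp_ms = recording$timestamps_ms,
    c1 = recording$channels[, 1],
    c2 = recording$channels[, 2],
    c3 = recording$channels[, 3])
  data.table::fwrite(dt, path, sep = ",", dec = ".", na = "NA")
  invisible(path)
}

#' Load and validate a session manifest
#'
#' A manifest is a YAML file with a `sampling_rate` and an `entries` list;
#' each entry records `participant_id`, `condition`, `placement`, a
#' `files` map (sensor kind to CSV path, relative to the manifest
#' directory), and `markers` (`i_start_raw`, `i_stop_raw`). Validation
#' enforces unique (participant, condition) pairs, known condition
#' labels, and the existence of every referenced file.
#'
#' @param path Manifest YAML path.
#' @return An object of class `session_manifest`: the parsed list plus a
#'   `dir` attribute used to resolve relative file paths.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- yaml::read_yaml(path)
  if (is.null(m$entries) || length(m$entries) == 0L) {
    stop("manifest has no entries", call. = FALSE)
  }
  if (is.null(m$sampling_rate)) {
    stop("manifest missing required key: sampling_rate", call. = FALSE)
  }
  dir <- dirname(normalizePath(path))
  keys <- character(length(m$entries))
  for (i in seq_along(m$entries)) {
    e <- m$entries[[i]]
    for (key in c("participant_id", "condition", "files", "markers")) {
      if (is.null(e[[key]])) {
        stop("manifest entry ", i, " missing required key: ", key,
             call. = FALSE)
      }
    }
    check_condition_label(e$condition)
    keys[i] <- paste(e$participant_id, e$condition, sep = ".")
    for (f in unlist(e$files)) {
      fp <- file.path(dir, f)
      if (!file.exists(fp)) {
        stop("manifest references missing file: ", f, call. = FALSE)
      }
    }
    trial_markers(e$markers$i_start_raw, e$markers$i_stop_raw)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate (participant, condition) pair in manifest: ",
         keys[duplicated(keys)][1], call. = FALSE)
  }
  structure(m, dir = dir, class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> %d entries at %g Hz\n",
              length(x$entries), x$sampling_rate))
  invisible(x)
}

#' Read the recordings referenced by one manifest entry
#'
#' @param manifest A [load_manifest()] object.
#' @param i Entry index.
#' @return List with `recording` (accelerometer [raw_recording()]),
#'   `markers`, `condition`, `participant_id`.
#' @export
manifest_entry_recording <- function(manifest, i) {
  stopifnot(inherits(manifest, "session_manifest"))
  e <- manifest$entries[[i]]
  path <- file.path(attr(manifest, "dir"), e$files$accelerometer)
  list(recording = read_recording(path, "accelerometer",
                                  placement = e$placement %||% "pocket"),
       markers = trial_markers(e$markers$i_start_raw, e$markers$i_stop_raw),
       condition = e$condition,
       participant_id = e$participant_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
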