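#' Synchronise raw sensor streams onto a uniform time axis
#'
#' Linearly interpolates every channel of every stream onto one uniformly
#' sampled axis at `rate` Hz covering the temporal overlap of all
#' streams. With a single already-uniform stream at the target rate this
#' is the identity at the shared sample points.
#'
#' @param raw_streams A [raw_recording()] or list of them.
#' @param rate Target rate in Hz (default 50).
#' @return An object of class `synced_recording`: `rate`, `time_s`
#'   (uniform axis, seconds), `channels` (matrix, one column per input
#'   channel).
#' @export
synchronise <- function(raw_streams, rate = 50) {
  if (inherits(raw_streams, "raw_recording")) {
    raw_streams <- list(raw_streams)
  }
  stopifnot(length(raw_streams) >= 1L)
  for (s in raw_streams) {
    if (length(s$timestamps_ms) < 2L) {
      stop("each stream needs at least 2 samples", call. = FALSE)
    }
    if (any(diff(s$timestamps_ms) <= 0)) {
      stop("non-monotone timestamps in input stream", call. = FALSE)
    }
  }
  t0 <- max(vapply(raw_streams, function(s) min(s$timestamps_ms),
                   numeric(1))) / 1000
  t1 <- min(vapply(raw_streams, function(s) max(s$timestamps_ms),
                   numeric(1))) / 1000
  if (t1 <= t0) stop("streams have empty temporal overlap", call. = FALSE)
  time_s <- seq(t0, t1, by = 1 / rate)
  cols <- list()
  for (s in raw_streams) {
    ts <- s$timestamps_ms / 1000
    for (j in seq_len(ncol(s$channels))) {
      nm <- colnames(s$channels)[j]
      if (length(raw_streams) > 1L) nm <- paste(s$sensor_kind, nm, sep = ".")
      cols[[nm]] <- stats::approx(ts, s$channels[, j], xout = time_s,
                                  method = "linear")$y
    }
  }
  structure(list(rate = rate, time_s = time_s,
                 channels = do.call(cbind, cols)),
            class = "synced_recording")
}

#' Map raw marker indices onto the synchronised axis
#'
#' Raw marker indices are converted to timestamps via the raw time
#' vector, then each timestamp is mapped to the first synced sample at or
#' after it.
#'
#' @param markers A [trial_markers()].
#' @param raw_timestamps_ms Raw accelerometer timestamps (ms).
#' @param synced A [synchronise()] result.
#' @return List with `t_start`, `t_stop` (seconds) and `i_start`,
#'   `i_stop` (indices on the synced axis).
#' @export
map_markers <- function(markers, raw_timestamps_ms, synced) {
  stopifnot(inherits(markers, "trial_markers"))
  n_raw <- length(raw_timestamps_ms)
  if (markers$i_stop_raw > n_raw) {
    stop("marker index exceeds raw recording length", call. = FALSE)
  }
  t_start <- raw_timestamps_ms[markers$i_start_raw] / 1000
  t_stop <- raw_timestamps_ms[markers$i_stop_raw] / 1000
  eps <- 1e-9
  i_start <- which(synced$time_s >= t_start - eps)[1]
  i_stop <- which(synced$time_s >= t_stop - eps)[1]
  if (is.na(i_start) || is.na(i_stop) || t_stop < synced$time_s[1]) {
    stop("markers fall outside the synchronised span", call. = FALSE)
  }
  if (i_start >= i_stop) {
    stop("mapped markers collapse to an empty interval", call. = FALSE)
  }
  list(t_start = t_start, t_stop = t_stop,
       i_start = i_start, i_stop = i_stop)
}

#' Crop a synchronised recording to an index interval
#'
#' @param synced A [synchronise()] result.
#' @param i_start,i_stop 1-based indices on the synced axis (inclusive).
#' @return A `synced_recording` restricted to the interval.
#' @export
crop_synced <- function(synced, i_start, i_stop) {
  stopifnot(i_start >= 1L, i_stop <= length(synced$time_s),
            i_start < i_stop)
  structure(list(rate = synced$rate,
                 time_s = synced$time_s[i_start:i_stop],
                 channels = synced$channels[i_start:i_stop, ,
                                            drop = FALSE]),
            class = "synced_recording")
}

#' Subtract standard gravity from the vertical channel
#'
#' Simplified gravity compensation: 9.81 m/s^2 is subtracted from the
#' `z` channel; the other channels are untouched. No orientation
#' normalisation is attempted.
#'
#' @param synced A `synced_recording` with a channel named `z`.
#' @return The recording with the offset applied.
#' @export
gravity_offset <- function(synced) {
  zc <- which(colnames(synced$channels) == "z")
  if (length(zc) != 1L) {
    stop("no unique 'z' channel to offset", call. = FALSE)
  }
  synced$channels[, zc] <- synced$channels[, zc] - 9.81
  synced
}

#' Sliding-window autocorrelation periodicity profile
#'
#' For each sliding window of the acceleration-magnitude signal, the
#' maximum normalised autocorrelation over a physiological lag range
#' (roughly one stride) is taken as that window's periodicity score:
#' the correlation of the window's first `window_s` seconds with the
#' lag-shifted segment of the same length, both demeaned, so a
#' perfectly periodic signal scores 1 at its period regardless of the
#' lag. Channels are demeaned before the magnitude is formed, so the
#' profile is invariant to constant offsets on any channel. Local
#' maxima of the score sequence that clear the validity threshold are
#' marked as candidate gait-pattern locations.
#'
#' @param synced A `synced_recording` (typically cropped to the marker
#'   interval and gravity-offset).
#' @param window_s Window duration, seconds (default 2.56 s = 128 samples
#'   at 50 Hz).
#' @param lag_range_s Autocorrelation lag range, seconds (default
#'   0.4--1.5, one stride).
#' @param hop_s Hop between window centres, seconds.
#' @param threshold Validity threshold on the normalised autocorrelation.
#' @return List of class `periodicity_profile`: `window_centres` (sample
#'   indices on the input axis), `scores` (in \[-1, 1\]),
#'   `peak_locations` (indices into `window_centres` of valid local
#'   maxima), plus the parameters.
#' @export
periodicity_profile <- function(synced, window_s = 2.56,
                                lag_range_s = c(0.4, 1.5),
                                hop_s = 0.32, threshold = 0.4) {
  ch <- synced$channels
  rate <- synced$rate
  n <- nrow(ch)
  w <- as.integer(round(window_s * rate))
  hop <- max(1L, as.integer(round(hop_s * rate)))
  lags <- seq(as.integer(round(lag_range_s[1] * rate)),
              as.integer(round(lag_range_s[2] * rate)))
  lags <- lags[lags >= 1L]
  if (length(lags) == 0L) stop("empty lag range", call. = FALSE)
  span <- w + max(lags) # reference part plus the largest shift
  if (span > n) stop("window longer than signal", call. = FALSE)

  mag <- sqrt(rowSums(sweep(ch, 2, colMeans(ch))^2))
  starts <- seq(1L, n - span + 1L, by = hop)
  centres <- starts + span %/% 2L
  scores <- vapply(starts, function(s) {
    seg <- mag[s:(s + span - 1L)]
    x1 <- seg[seq_len(w)]
    x1 <- x1 - mean(x1)
    e1 <- sum(x1^2)
    if (e1 < 1e-12) return(0)
    max(vapply(lags, function(l) {
      x2 <- seg[l + seq_len(w)]
      x2 <- x2 - mean(x2)
      e2 <- sum(x2^2)
      if (e2 < 1e-12) return(0)
      sum(x1 * x2) / sqrt(e1 * e2)
    }, numeric(1)))
  }, numeric(1))

  peaks <- local_maxima(scores)
  peaks <- peaks[scores[peaks] >= threshold]
  structure(list(window_centres = centres, scores = scores,
                 peak_locations = peaks, threshold = threshold,
                 window_s = window_s, lag_range_s = lag_range_s,
                 hop_s = hop_s),
            class = "periodicity_profile")
}

# Indices of local maxima, with plateau runs collapsed to their first
# element; endpoints count when they dominate their single neighbour.
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || runs$values[i - 1] < runs$values[i]
    right_ok <- i == k || runs$values[i + 1] < runs$values[i]
    if (left_ok && right_ok) out <- c(out, starts[i])
  }
  out
}

#' Extract the steady-gait segment of a traversal
#'
#' The retained interval runs from the (n_trim + 1)-th valid detected
#' gait-pattern location to the (last - n_trim)-th, excluding the first
#' and last few detected patterns and thereby the gait initiation and
#' termination transients.
#'
#' @param synced The marker-cropped, gravity-offset `synced_recording`.
#' @param profile Its [periodicity_profile()].
#' @param n_trim Number of leading/trailing detected patterns to discard.
#' @param label,participant_id Metadata carried onto the segment.
#' @param offset Index offset of `synced`'s first sample on the full
#'   synchronised axis (for bookkeeping in `bounds`).
#' @return An object of class `steady_segment`: `values` (T x C matrix),
#'   `label`, `participant_id`, `bounds` (first/last sample index on the
#'   full synced axis), `rate`.
#' @export
extract_steady_segment <- function(synced, profile, n_trim = 3,
                                   label = NA_character_,
                                   participant_id = NA_character_,
                                   offset = 0L) {
  pk <- profile$peak_locations
  # 2*n_trim + 2 valid patterns leave at least two distinct pattern
  # locations after trimming, i.e. a non-degenerate segment
  need <- 2L * n_trim + 2L
  if (length(pk) < need) {
    stop("no steady gait: only ", length(pk),
         " valid gait patterns detected (need >= ", need, ")",
         call. = FALSE)
  }
  first <- profile$window_centres[pk[n_trim + 1L]]
  last <- profile$window_centres[pk[length(pk) - n_trim]]
  stopifnot(first < last)
  structure(list(values = synced$channels[first:last, , drop = FALSE],
                 label = label,
                 participant_id = participant_id,
                 bounds = c(start = first + offset, stop = last + offset),
                 rate = synced$rate),
            class = "steady_segment")
}

#' Preprocess one traversal end to end
#'
#' Runs the full chain: synchronise, map markers, crop to the marker
#' interval, gravity-offset the vertical channel, compute the
#' periodicity profile, and extract the steady-gait segment.
#'
#' @param recording Accelerometer [raw_recording()].
#' @param markers [trial_markers()] on the raw axis.
#' @param label,participant_id Metadata for the segment.
#' @param rate Target rate, Hz.
#' @param n_trim,window_s,lag_range_s,hop_s,threshold Passed to
#'   [periodicity_profile()] / [extract_steady_segment()].
#' @return A `steady_segment`.
#' @export
preprocess_traversal <- function(recording, markers,
                                 label = NA_character_,
                                 participant_id = NA_character_,
                                 rate = 50, n_trim = 3,
                                 window_s = 2.56,
                                 lag_range_s = c(0.4, 1.5),
                                 hop_s = 0.32, threshold = 0.4) {
  synced <- synchronise(recording, rate = rate)
  mm <- map_markers(markers, recording$timestamps_ms, synced)
  cropped <- crop_synced(synced, mm$i_start, mm$i_stop)
  cropped <- gravity_offset(cropped)
  prof <- periodicity_profile(cropped, window_s = window_s,
                              lag_range_s = lag_range_s, hop_s = hop_s,
                              threshold = threshold)
  extract_steady_segment(cropped, prof, n_trim = n_trim, label = label,
                         participant_id = participant_id,
                         offset = mm$i_start - 1L)
}

#' Preprocess every traversal in a manifest
#'
#' @param manifest A [load_manifest()] object.
#' @param ... Passed to [preprocess_traversal()].
#' @return List with `segments` (list of `steady_segment`, named
#'   `participant.condition`) and `qc` (data.frame of segment bounds and
#'   lengths per traversal).
#' @export
preprocess_cohort <- function(manifest, ...) {
  n <- length(manifest$entries)
  segments <- vector("list", n)
  qc <- vector("list", n)
  for (i in seq_len(n)) {
    er <- manifest_entry_recording(manifest, i)
    seg <- preprocess_traversal(er$recording, er$markers,
                                label = er$condition,
                                participant_id = er$participant_id,
                                rate = manifest$sampling_rate, ...)
    segments[[i]] <- seg
    names(segments)[i] <- paste(er$participant_id, er$condition, sep = ".")
    qc[[i]] <- data.frame(participant_id = er$participant_id,
                          condition = er$condition,
                          start = seg$bounds["start"],
                          stop = seg$bounds["stop"],
                          length = nrow(seg$values))
  }
  list(segments = segments, qc = do.call(rbind, qc))
}
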