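#' Windowing configuration
#'
#' Defaults follow the study protocol: 256-sample (5.12 s at 50 Hz)
#' sliding windows with stride 4, a chronological within-traversal 80/20
#' train/test split, and train-only augmentation producing 10 noisy
#' copies per original window with zero-mean white noise of variance 0.2
#' (the alternative setting used for the largest model is variance 0.1
#' with 5 copies).
#'
#' @param window_len Window length in samples.
#' @param stride Window stride in samples.
#' @param train_fraction Fraction of each traversal allocated to training.
#' @param noise_variance Augmentation noise variance.
#' @param n_augmented Noisy copies per original training window.
#' @param seed Integer seed for the augmentation noise.
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_len = 256L, stride = 4L,
                             train_fraction = 0.8, noise_variance = 0.2,
                             n_augmented = 10L, seed = 1L) {
  check_scalar_number(window_len, "window_len", positive = TRUE)
  check_scalar_number(stride, "stride", positive = TRUE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (noise_variance < 0) stop("noise_variance must be >= 0", call. = FALSE)
  if (n_augmented < 0) stop("n_augmented must be >= 0", call. = FALSE)
  structure(list(window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 train_fraction = train_fraction,
                 noise_variance = noise_variance,
                 n_augmented = as.integer(n_augmented),
                 seed = as.integer(seed)),
            class = "windowing_config")
}

#' Chronological train/test split of one traversal
#'
#' Splits the segment at `floor(T * train_fraction)`: the initial part is
#' allocated to training, the remainder to testing. The parts are
#' contiguous, disjoint, and concatenate back to the input.
#'
#' @param values T x C matrix (or a `steady_segment`).
#' @param train_fraction Fraction in (0, 1).
#' @return List with `train` and `test` matrices.
#' @export
split_traversal <- function(values, train_fraction = 0.8) {
  if (inherits(values, "steady_segment")) values <- values$values
  n <- nrow(values)
  cut <- floor(n * train_fraction)
  if (cut < 1L || cut >= n) {
    stop("segment too short to split at fraction ", train_fraction,
         call. = FALSE)
  }
  list(train = values[seq_len(cut), , drop = FALSE],
       test = values[(cut + 1L):n, , drop = FALSE])
}

#' Cut a series into fixed-length sliding windows
#'
#' Window count is `floor((T - L) / stride) + 1`; windows are ordered by
#' start index. A series shorter than one window yields an empty window
#' set (zero rows), flagged with attribute `too_short`.
#'
#' @param series T x C numeric matrix.
#' @param window_len Window length L.
#' @param stride Stride between window starts.
#' @return Array `[N, L, C]` of windows.
#' @export
make_windows <- function(series, window_len = 256L, stride = 4L) {
  series <- as.matrix(series)
  n <- nrow(series)
  ncol_c <- ncol(series)
  if (n < window_len) {
    out <- array(numeric(0), dim = c(0L, window_len, ncol_c))
    attr(out, "too_short") <- TRUE
    return(out)
  }
  starts <- seq(1L, n - window_len + 1L, by = stride)
  idx <- outer(starts - 1L, seq_len(window_len), `+`) # N x L
  out <- array(NA_real_, dim = c(length(starts), window_len, ncol_c))
  for (c_ in seq_len(ncol_c)) {
    out[, , c_] <- series[, c_][idx]
  }
  dimnames(out) <- list(NULL, NULL, colnames(series))
  out
}

#' White-noise window augmentation
#'
#' Returns the original windows unmodified followed by `n_copies` noisy
#' replicas of each, with i.i.d. zero-mean Gaussian noise of the given
#' variance added to every sample and channel. Copies are grouped in
#' blocks: all originals, then copy block 1, block 2, ...
#'
#' @param windows Array `[N, L, C]`.
#' @param variance Noise variance (>= 0).
#' @param n_copies Copies per original window.
#' @param seed Integer seed.
#' @return Array `[N * (1 + n_copies), L, C]`.
#' @export
augment_with_noise <- function(windows, variance = 0.2, n_copies = 10L,
                               seed = 1L) {
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  n <- dim(windows)[1]
  if (n_copies == 0L || n == 0L) return(windows)
  d <- dim(windows)
  out <- array(NA_real_, dim = c(n * (1L + n_copies), d[2], d[3]))
  out[seq_len(n), , ] <- windows
  sd_ <- sqrt(variance)
  with_seed(seed, {
    for (j in seq_len(n_copies)) {
      rows <- j * n + seq_len(n)
      out[rows, , ] <- windows +
        array(stats::rnorm(prod(d), 0, sd_), dim = d)
    }
  })
  dimnames(out) <- list(NULL, NULL, dimnames(windows)[[3]])
  out
}

new_window_dataset <- function(windows, labels, groups, channel_names) {
  stopifnot(dim(windows)[1] == length(labels),
            dim(windows)[1] == nrow(groups))
  structure(list(windows = windows, labels = labels, groups = groups,
                 channel_names = channel_names),
            class = "window_dataset")
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("<window_dataset> %d windows of %d x %d (%s)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              paste(x$channel_names, collapse = ",")))
  invisible(x)
}

# Bind a list of (windows, labels, groups) chunks into one dataset.
# An all-empty chunk list yields an empty (zero-window) dataset.
bind_window_chunks <- function(chunks, channel_names) {
  keep <- vapply(chunks, function(ch) dim(ch$windows)[1] > 0, logical(1))
  if (!any(keep)) {
    chunks <- chunks[1]
  } else {
    chunks <- chunks[keep]
  }
  w <- do.call(abind1, lapply(chunks, `[[`, "windows"))
  new_window_dataset(
    w,
    unlist(lapply(chunks, `[[`, "labels"), use.names = FALSE),
    do.call(rbind, lapply(chunks, `[[`, "groups")),
    channel_names)
}

# rbind for [N, L, C] arrays along the first margin
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k > 0) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' Assemble train/test window datasets from steady segments
#'
#' Per traversal: split chronologically first, window each part
#' independently (so no window straddles the split boundary and train and
#' test never share a sample), then augment the training windows only.
#' Labels are inherited from the source traversal; group ids record
#' participant, traversal and split.
#'
#' @param segments Named list of `steady_segment`s (names
#'   `participant.condition`), e.g. from [preprocess_cohort()].
#' @param config A [windowing_config()].
#' @return List with `train` and `test` [window_dataset]s.
#' @export
assemble_dataset <- function(segments, config = windowing_config()) {
  stopifnot(inherits(config, "windowing_config"))
  ch_names <- colnames(segments[[1]]$values)
  train_chunks <- list()
  test_chunks <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    if (!identical(colnames(seg$values), ch_names)) {
      stop("mixed channel sets across segments", call. = FALSE)
    }
    trav <- names(segments)[i] %||% as.character(i)
    parts <- split_traversal(seg$values, config$train_fraction)
    w_tr <- make_windows(parts$train, config$window_len, config$stride)
    w_te <- make_windows(parts$test, config$window_len, config$stride)
    w_tr <- augment_with_noise(w_tr, config$noise_variance,
                               config$n_augmented,
                               derive_seed(config$seed, "augment", i))
    train_chunks[[i]] <- list(
      windows = w_tr,
      labels = rep(seg$label, dim(w_tr)[1]),
      groups = data.frame(
        participant = rep(seg$participant_id, dim(w_tr)[1]),
        traversal = rep(trav, dim(w_tr)[1]),
        split = rep("train", dim(w_tr)[1])))
    test_chunks[[i]] <- list(
      windows = w_te,
      labels = rep(seg$label, dim(w_te)[1]),
      groups = data.frame(
        participant = rep(seg$participant_id, dim(w_te)[1]),
        traversal = rep(trav, dim(w_te)[1]),
        split = rep("test", dim(w_te)[1])))
  }
  list(train = bind_window_chunks(train_chunks, ch_names),
       test = bind_window_chunks(test_chunks, ch_names))
}

#' Assemble one cross-validation fold
#'
#' Fold `fold` of `k` takes the `fold`-th contiguous 1/k chunk of every
#' traversal as its test part and the remainder (one or two contiguous
#' pieces, windowed separately) as training, consistent with the
#' within-traversal evaluation protocol.
#'
#' @inheritParams assemble_dataset
#' @param fold Fold index in 1..k.
#' @param k Number of folds.
#' @return List with `train` and `test` [window_dataset]s.
#' @export
assemble_fold_dataset <- function(segments, config = windowing_config(),
                                  fold, k = 5L) {
  stopifnot(fold >= 1L, fold <= k)
  ch_names <- colnames(segments[[1]]$values)
  train_chunks <- list()
  test_chunks <- list()
  ci <- 0L
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    trav <- names(segments)[i] %||% as.character(i)
    n <- nrow(seg$values)
    cuts <- floor(n * (0:k) / k)
    te_rows <- (cuts[fold] + 1L):cuts[fold + 1L]
    pieces_tr <- list()
    if (cuts[fold] >= 1L) {
      pieces_tr <- c(pieces_tr, list(seq_len(cuts[fold])))
    }
    if (cuts[fold + 1L] < n) {
      pieces_tr <- c(pieces_tr, list((cuts[fold + 1L] + 1L):n))
    }
    mk_chunk <- function(rows, split) {
      w <- make_windows(seg$values[rows, , drop = FALSE],
                        config$window_len, config$stride)
      list(windows = w,
           labels = rep(seg$label, dim(w)[1]),
           groups = data.frame(
             participant = rep(seg$participant_id, dim(w)[1]),
             traversal = rep(trav, dim(w)[1]),
             split = rep(split, dim(w)[1])))
    }
    for (piece in pieces_tr) {
      ci <- ci + 1L
      chunk <- mk_chunk(piece, "train")
      chunk$windows <- augment_with_noise(
        chunk$windows, config$noise_variance, config$n_augmented,
        derive_seed(config$seed, "augment_fold", ci + fold * 10000L))
      chunk$labels <- rep(seg$label, dim(chunk$windows)[1])
      chunk$groups <- chunk$groups[rep(1L, dim(chunk$windows)[1]), ,
                                   drop = FALSE]
      train_chunks <- c(train_chunks, list(chunk))
    }
    test_chunks <- c(test_chunks, list(mk_chunk(te_rows, "test")))
  }
  list(train = bind_window_chunks(train_chunks, ch_names),
       test = bind_window_chunks(test_chunks, ch_names))
}
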