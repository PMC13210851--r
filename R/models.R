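#' Architecture specification for the model zoo
#'
#' Declarative description of one of the five investigated sequence
#' classifiers. All take `[B, T, in_channels]` windows and emit
#' unnormalised scores over `n_classes`:
#'
#' * `A1`: Conv1D (in -> 64, kernel 3, ReLU) -> global average pooling
#'   -> dropout -> FC 64 -> classes. 1,030 parameters at 3 channels.
#' * `A2`: BiLSTM (in -> 32 per direction) -> dropout -> FC 64 ->
#'   classes. 9,862 parameters.
#' * `A3`: Conv1D x3 (in -> 64 -> 64 -> 64) -> affine-free layer norm ->
#'   BiLSTM (64 -> 32 x 2) -> dropout -> FC. 50,822 parameters.
#' * `A4`: Conv1D x2 -> parameter-free 4-head self-attention (residual)
#'   -> affine-free layer norm -> BiLSTM -> dropout -> FC. 38,470
#'   parameters.
#' * `A5`: Conv1D x2 -> two projected 4-head self-attention blocks (each
#'   with learned Q/K/V/output projections, residual, and an
#'   elementwise-affine layer norm) -> BiLSTM -> dropout -> FC. 72,006
#'   parameters.
#'
#' Convolutions are stride-1, length-preserving, kernel 3, with bias and
#' ReLU; the BiLSTM uses 32 hidden units per direction with two bias
#' vectors per gate block; the classifier head takes the concatenated
#' hidden states of both directions, mean-pooled over time, through
#' dropout (p = 0.2) into an affine 64 -> classes map.
#'
#' @param name One of `"A1"` ... `"A5"`.
#' @param in_channels Input channel count (3 by default; 2 or 1 for
#'   channel-ablation variants).
#' @param n_classes Number of output classes (default 6).
#' @param dropout_p Dropout probability before the head.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(name, in_channels = 3L, n_classes = 6L,
                              dropout_p = 0.2) {
  if (!name %in% paste0("A", 1:5)) {
    stop("unknown architecture name: '", name,
         "' (expected A1, A2, A3, A4 or A5)", call. = FALSE)
  }
  check_scalar_number(in_channels, "in_channels", positive = TRUE)
  structure(list(name = name, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 dropout_p = dropout_p),
            class = "architecture_spec")
}

#' Build a model from an architecture specification
#'
#' Weights are initialised uniformly in \[-1/sqrt(fan_in), +1/sqrt(fan_in)\]
#' under the given seed, so identical (spec, seed) pairs give identical
#' models.
#'
#' @param spec An [architecture_spec()] (or an architecture name, for
#'   convenience).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `gait_model`: the spec plus the layer list.
#' @export
build_model <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- architecture_spec(spec)
  stopifnot(inherits(spec, "architecture_spec"))
  cin <- spec$in_channels
  nc <- spec$n_classes
  dp <- spec$dropout_p
  layers <- with_seed(seed, switch(
    spec$name,
    A1 = list(layer_conv1d(cin, 64L),
              layer_gap(),
              layer_dropout(dp),
              layer_dense(64L, nc)),
    A2 = list(layer_bilstm(cin, 32L),
              layer_dropout(dp),
              layer_dense(64L, nc)),
    A3 = list(layer_conv1d(cin, 64L),
              layer_conv1d(64L, 64L),
              layer_conv1d(64L, 64L),
              layer_layernorm(64L),
              layer_bilstm(64L, 32L),
              layer_dropout(dp),
              layer_dense(64L, nc)),
    A4 = list(layer_conv1d(cin, 64L),
              layer_conv1d(64L, 64L),
              layer_attn_pf(64L, 4L),
              layer_layernorm(64L),
              layer_bilstm(64L, 32L),
              layer_dropout(dp),
              layer_dense(64L, nc)),
    A5 = list(layer_conv1d(cin, 64L),
              layer_conv1d(64L, 64L),
              layer_attn_proj(64L, 4L),
              layer_attn_proj(64L, 4L),
              layer_bilstm(64L, 32L),
              layer_dropout(dp),
              layer_dense(64L, nc))))
  structure(list(spec = spec, layers = layers), class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %s: %d channels -> %d classes, %d parameters\n",
              x$spec$name, x$spec$in_channels, x$spec$n_classes,
              count_trainable_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' Sum of the lengths of every learnable tensor (weights and biases of
#' convolutions, both LSTM directions including both bias vectors per
#' gate block, attention projections, affine layer-norm scales/shifts,
#' and the classifier head).
#'
#' @param model A [build_model()] result.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "gait_model"))
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}

#' Class probabilities for a batch of windows
#'
#' Runs the model in evaluation mode (dropout disabled) and applies a
#' row-wise softmax to the class scores.
#'
#' @param model A trained (or freshly built) `gait_model`.
#' @param windows Array `[N, T, C]` with `C` equal to the model's input
#'   channel count, or a [window_dataset].
#' @param batch_size Forward-pass batch size.
#' @return `N x n_classes` matrix of class probabilities (rows sum to 1),
#'   with class labels as column names when the model carries them.
#' @export
predict_proba <- function(model, windows, batch_size = 64L) {
  stopifnot(inherits(model, "gait_model"))
  if (inherits(windows, "window_dataset")) windows <- windows$windows
  if (length(dim(windows)) != 3L) {
    stop("windows must be an [N, T, C] array", call. = FALSE)
  }
  if (dim(windows)[3] != model$spec$in_channels) {
    stop("channel-count mismatch: model expects ",
         model$spec$in_channels, " channels, got ", dim(windows)[3],
         call. = FALSE)
  }
  n <- dim(windows)[1]
  out <- matrix(NA_real_, n, model$spec$n_classes)
  at <- 1L
  while (at <= n) {
    idx <- at:min(at + batch_size - 1L, n)
    xb <- windows[idx, , , drop = FALSE]
    out[idx, ] <- softmax_rows(nn_forward(model$layers, xb,
                                          training = FALSE)$out)
    at <- at + batch_size
  }
  if (!is.null(model$class_levels)) colnames(out) <- model$class_levels
  out
}

#' Predicted class labels for a batch of windows
#'
#' @inheritParams predict_proba
#' @param class_levels Label for each output unit; defaults to the
#'   levels stored on the model by [train_classifier()], else the
#'   canonical condition labels.
#' @return Character vector of predicted labels (argmax of
#'   [predict_proba()]).
#' @export
predict_labels <- function(model, windows, class_levels = NULL,
                           batch_size = 64L) {
  p <- predict_proba(model, windows, batch_size = batch_size)
  levels <- class_levels %||% model$class_levels %||%
    condition_labels()[seq_len(ncol(p))]
  levels[max.col(p, ties.method = "first")]
}
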