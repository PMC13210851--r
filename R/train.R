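#' Classifier training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 1.5e-3,
#' batch size 32, cross-entropy loss, gradient clipping at global norm
#' 1.0, up to 20 epochs with no early stopping.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Number of training epochs.
#' @param grad_clip_max_norm Global gradient-norm clip (`NULL` disables).
#' @param seed Integer seed for weight init order, shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1.5e-3, batch_size = 32L,
                            max_epochs = 20L, grad_clip_max_norm = 1.0,
                            seed = 1L) {
  check_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  check_scalar_number(batch_size, "batch_size", positive = TRUE)
  check_scalar_number(max_epochs, "max_epochs", positive = TRUE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 grad_clip_max_norm = grad_clip_max_norm,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Encoder pretraining configuration
#'
#' Masked-prediction self-supervision of the convolutional stem: 15% of
#' time steps are zero-masked in contiguous spans of 8 samples, and the
#' stem plus a mirrored transposed decoder are trained for 3 epochs to
#' reconstruct the unmasked input under mean-squared error.
#'
#' @param epochs Pretraining epochs.
#' @param mask_fraction Fraction of time steps masked per window.
#' @param mask_span Length of each contiguous masked span, samples.
#' @param learning_rate,batch_size Adam settings for pretraining.
#' @param seed Integer seed.
#' @return An object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 3L, mask_fraction = 0.15,
                            mask_span = 8L, learning_rate = 1.5e-3,
                            batch_size = 32L, seed = 1L) {
  if (mask_fraction < 0 || mask_fraction >= 1) {
    stop("mask_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 mask_fraction = mask_fraction,
                 mask_span = as.integer(mask_span),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

labels_to_classes <- function(labels, class_levels) {
  y <- match(labels, class_levels)
  if (anyNA(y)) {
    stop("label outside the class set: '",
         labels[which(is.na(y))[1]], "'", call. = FALSE)
  }
  y
}

#' Train a classifier on a window dataset
#'
#' Mini-batch Adam training with seeded shuffling, cross-entropy loss
#' and gradient clipping. Fixed (model seed, config seed, data) triples
#' give identical loss histories.
#'
#' @param model A [build_model()] result.
#' @param dataset A [window_dataset] (or a plain list with `windows` and
#'   `labels`).
#' @param config A [training_config()].
#' @param class_levels Class label for each output unit, in order;
#'   defaults to the canonical condition labels restricted to the labels
#'   present when fewer classes are used.
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained, with `class_levels` attached) and
#'   `history` (data.frame: epoch, loss, accuracy).
#' @export
train_classifier <- function(model, dataset, config = training_config(),
                             class_levels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "gait_model"))
  windows <- dataset$windows
  labels <- dataset$labels
  n <- dim(windows)[1]
  if (is.null(n) || n == 0L) stop("empty training dataset", call. = FALSE)
  if (is.null(class_levels)) {
    canon <- condition_labels()
    class_levels <- if (all(labels %in% canon)) {
      canon[canon %in% unique(labels)]
    } else {
      sort(unique(labels))
    }
    if (model$spec$n_classes >= length(canon) && all(labels %in% canon)) {
      class_levels <- canon
    }
  }
  if (length(class_levels) > model$spec$n_classes) {
    stop("more classes than model outputs", call. = FALSE)
  }
  y <- labels_to_classes(labels, class_levels)

  layers <- model$layers
  state <- adam_state_init(layers)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_hits <- 0L
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(at + config$batch_size - 1L, n)]
        xb <- windows[idx, , , drop = FALSE]
        yb <- y[idx]
        fw <- nn_forward(layers, xb, training = TRUE)
        lg <- ce_loss_grad(fw$out, yb)
        grads <- nn_backward(layers, fw$caches, lg$dlogits)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, step,
                         lr = config$learning_rate,
                         clip_norm = config$grad_clip_max_norm)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(idx)
        ep_hits <- ep_hits +
          sum(max.col(fw$out, ties.method = "first") == yb)
        at <- at + config$batch_size
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n,
                                  accuracy = ep_hits / n))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, accuracy %.3f", epoch,
                        ep_loss / n, ep_hits / n))
      }
    }
  })
  model$layers <- layers
  model$class_levels <- class_levels
  list(model = model, history = history)
}

# zero-mask contiguous spans covering ~mask_fraction of the time axis;
# returns the masked copy of a [B, T, C] batch
mask_spans <- function(xb, mask_fraction, mask_span) {
  d <- dim(xb)
  n_spans <- max(1L, round(mask_fraction * d[2] / mask_span))
  for (b in seq_len(d[1])) {
    starts <- sample.int(max(1L, d[2] - mask_span + 1L), n_spans,
                         replace = TRUE)
    for (s in starts) {
      xb[b, s:min(s + mask_span - 1L, d[2]), ] <- 0
    }
  }
  xb
}

#' Masked-prediction pretraining of the convolutional stem
#'
#' The model's leading Conv1D layers act as the encoder of an
#' autoencoder whose decoder mirrors them in reverse (64 -> ... -> input
#' channels, final layer linear). Random contiguous spans of the input
#' are zeroed and the autoencoder is trained to reconstruct the original
#' window under mean-squared error on all positions. Afterwards the
#' trained encoder weights are copied back into the classifier and the
#' decoder is discarded. Architectures without a convolutional stem
#' (A2) are returned unchanged with a warning.
#'
#' @param model A [build_model()] result.
#' @param windows Training windows, `[N, T, C]` array or
#'   [window_dataset].
#' @param config A [pretrain_config()].
#' @return List with `model` (encoder updated) and `loss_history`
#'   (mean reconstruction loss per epoch, length `epochs`).
#' @export
pretrain_encoder <- function(model, windows, config = pretrain_config()) {
  stopifnot(inherits(model, "gait_model"))
  if (inherits(windows, "window_dataset")) windows <- windows$windows
  conv_idx <- which(vapply(model$layers, function(l) l$type == "conv1d",
                           logical(1)))
  if (length(conv_idx) == 0L ||
      !identical(conv_idx, seq_along(conv_idx))) {
    conv_idx <- conv_idx[conv_idx == seq_along(conv_idx)]
  }
  if (length(conv_idx) == 0L) {
    warning("architecture ", model$spec$name,
            " has no convolutional stem; pretraining is a no-op")
    return(list(model = model,
                loss_history = rep(NA_real_, config$epochs)))
  }
  encoder <- model$layers[conv_idx]
  # mirrored decoder: reversed channel dimensions, last layer linear
  decoder <- with_seed(derive_seed(config$seed, "decoder"), {
    dims <- c(vapply(rev(encoder), function(l) l$out_ch, integer(1)),
              encoder[[1]]$in_ch)
    lapply(seq_len(length(dims) - 1L), function(i) {
      layer_conv1d(dims[i], dims[i + 1L],
                   kernel = encoder[[1]]$kernel,
                   relu = i < length(dims) - 1L)
    })
  })
  layers <- c(encoder, decoder)
  state <- adam_state_init(layers)
  n <- dim(windows)[1]
  loss_history <- numeric(config$epochs)
  step <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(at + config$batch_size - 1L, n)]
        xb <- windows[idx, , , drop = FALSE]
        xm <- mask_spans(xb, config$mask_fraction, config$mask_span)
        fw <- nn_forward(layers, xm, training = FALSE)
        resid <- fw$out - xb
        loss <- mean(resid^2)
        dout <- 2 * resid / length(resid)
        grads <- nn_backward(layers, fw$caches, dout)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, step,
                         lr = config$learning_rate, clip_norm = 1.0)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        at <- at + config$batch_size
      }
      loss_history[epoch] <- ep_loss / n
    }
  })
  model$layers[conv_idx] <- layers[seq_along(conv_idx)]
  list(model = model, loss_history = loss_history,
       decoder = layers[-seq_along(conv_idx)])
}
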