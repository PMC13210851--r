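test_that("parameter counts reproduce the published architecture table", {
  counts <- vapply(paste0("A", 1:5), function(a) {
    count_trainable_parameters(build_model(a, seed = 1))
  }, numeric(1))
  expect_equal(unname(counts), c(1030, 9862, 50822, 38470, 72006))

  # ablation ladder: each removed input channel drops exactly
  # kernel * 64 = 192 first-conv weights
  abl <- vapply(c(3, 2, 1), function(ch) {
    count_trainable_parameters(
      build_model(architecture_spec("A5", in_channels = ch), seed = 1))
  }, numeric(1))
  expect_equal(unname(abl), c(72006, 71814, 71622))
  expect_equal(diff(abl), c(-192, -192))
})

test_that("layer-level counts match closed-form arithmetic", {
  m <- build_model("A5", seed = 1)
  n_params <- function(l) sum(vapply(l$params, length, numeric(1)))
  expect_equal(n_params(m$layers[[1]]), 3 * 64 * 3 + 64) # 640
  expect_equal(n_params(m$layers[[3]]), 4 * (64 * 64 + 64) + 2 * 64)
  expect_equal(n_params(m$layers[[7]]), 64 * 6 + 6) # 390
  # A4's attention stage contributes zero trainable parameters
  a4 <- build_model("A4", seed = 1)
  attn <- a4$layers[[which(vapply(a4$layers, `[[`, "", "type") ==
                             "attn_pf")]]
  expect_length(attn$params, 0L)
  # A2's BiLSTM carries two bias vectors per gate block and direction
  a2 <- build_model("A2", seed = 1)
  expect_equal(length(a2$layers[[1]]$params$b_ih_f), 128L)
  expect_equal(length(a2$layers[[1]]$params$b_hh_f), 128L)
})

test_that("unknown architectures are rejected", {
  expect_error(architecture_spec("A9"), "A9")
  expect_error(build_model("A0"), "A0")
})

test_that("forward pass honours the shape contract", {
  for (a in c("A1", "A2", "A5")) {
    m <- build_model(a, seed = 2)
    x <- array(rnorm(2 * 64 * 3), c(2, 64, 3))
    out <- gaitshift:::nn_forward(m$layers, x)$out
    expect_equal(dim(out), c(2L, 6L))
  }
})

test_that("backpropagation matches finite differences in every layer", {
  withr::with_seed(99, {
    for (arch in paste0("A", 1:5)) {
      m <- build_model(architecture_spec(arch, n_classes = 4,
                                         dropout_p = 0), seed = 3)
      b <- 2L; t_len <- 12L
      x <- array(rnorm(b * t_len * 3), c(b, t_len, 3))
      y <- sample(4L, b, replace = TRUE)
      fw <- gaitshift:::nn_forward(m$layers, x)
      lg <- gaitshift:::ce_loss_grad(fw$out, y)
      grads <- gaitshift:::nn_backward(m$layers, fw$caches, lg$dlogits)
      loss_at <- function(layers) {
        gaitshift:::ce_loss_grad(gaitshift:::nn_forward(layers, x)$out, y)$loss
      }
      for (i in seq_along(m$layers)) {
        for (nm in names(m$layers[[i]]$params)) {
          p <- m$layers[[i]]$params[[nm]]
          for (k in sample(length(p), min(3L, length(p)))) {
            eps <- 1e-5
            up <- m$layers; up[[i]]$params[[nm]][k] <- p[k] + eps
            dn <- m$layers; dn[[i]]$params[[nm]][k] <- p[k] - eps
            num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
            # central differences are only ~3-digit accurate across
            # ReLU kinks; real gradient bugs are off by far more
            expect_equal(grads[[i]][[nm]][k], num, tolerance = 5e-3,
                         label = paste(arch, "layer", i, nm))
          }
        }
      }
    }
  })
})

test_that("prediction outputs are proper probabilities", {
  m <- build_model("A1", seed = 4)
  x <- array(rnorm(5 * 64 * 3), c(5, 64, 3))
  p <- predict_proba(m, x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # argmax is invariant to positive rescaling of the scores
  z <- matrix(rnorm(40), 8, 5)
  expect_equal(max.col(gaitshift:::softmax_rows(z)), max.col(gaitshift:::softmax_rows(3 * z)))
  # channel mismatch is a hard error
  expect_error(predict_proba(m, array(0, c(2, 64, 2))), "mismatch")
})

test_that("training is deterministic and histories are bounded", {
  d <- two_class_windows(n_per_class = 16, t_len = 32)
  cfg <- training_config(max_epochs = 2, seed = 5)
  r1 <- train_classifier(build_model(architecture_spec("A2"), seed = 6),
                         d, cfg)
  r2 <- train_classifier(build_model(architecture_spec("A2"), seed = 6),
                         d, cfg)
  expect_identical(r1$history, r2$history)
  expect_lte(nrow(r1$history), 2L)
})

test_that("a single-class toy problem is learnt almost immediately", {
  withr::with_seed(8, {
    w <- array(rnorm(40 * 32 * 3), c(40, 32, 3))
    d <- list(windows = w, labels = rep("green", 40))
    r <- train_classifier(build_model("A2", seed = 2), d,
                          training_config(max_epochs = 5, seed = 3))
    expect_gte(max(r$history$accuracy), 0.99)
  })
})

test_that("a separable two-class problem reaches high held-out accuracy", {
  d <- two_class_windows(n_per_class = 80, t_len = 64, seed = 12)
  idx_tr <- c(1:60, 81:140)
  idx_te <- setdiff(seq_len(160), idx_tr)
  r <- train_classifier(
    build_model(architecture_spec("A2"), seed = 10),
    list(windows = d$windows[idx_tr, , , drop = FALSE],
         labels = d$labels[idx_tr]),
    training_config(batch_size = 16, max_epochs = 25, seed = 11))
  pred <- predict_labels(r$model, d$windows[idx_te, , , drop = FALSE])
  acc <- mean(pred == d$labels[idx_te])
  expect_gte(acc, 0.95)
})

test_that("empty datasets and foreign labels are rejected", {
  m <- build_model("A2", seed = 1)
  expect_error(train_classifier(m, list(windows = array(0, c(0, 8, 3)),
                                        labels = character(0))),
               "empty")
  w <- array(rnorm(4 * 16 * 3), c(4, 16, 3))
  expect_error(train_classifier(m, list(windows = w,
                                        labels = rep("purple", 4)),
                                class_levels = condition_labels()),
               "purple")
})
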