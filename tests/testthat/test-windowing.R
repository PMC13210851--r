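test_that("the chronological split follows the floor rule", {
  m1000 <- matrix(seq_len(3000), ncol = 3)
  sp <- split_traversal(m1000, 0.8)
  expect_equal(nrow(sp$train), 800L)
  expect_equal(nrow(sp$test), 200L)

  m1001 <- matrix(seq_len(3003), ncol = 3)
  sp2 <- split_traversal(m1001, 0.8)
  expect_equal(nrow(sp2$train), 800L)
  expect_equal(nrow(sp2$test), 201L)

  # concatenating the parts restores the segment
  expect_equal(rbind(sp$train, sp$test), m1000)
})

test_that("window counts follow floor((T - L) / stride) + 1", {
  mk <- function(t) matrix(rnorm(t * 3), ncol = 3)
  expect_equal(dim(make_windows(mk(256), 256, 4))[1], 1L)
  w264 <- make_windows(mk(264), 256, 4)
  expect_equal(dim(w264)[1], 3L) # start indices 1, 5, 9
  w255 <- make_windows(mk(255), 256, 4)
  expect_equal(dim(w255)[1], 0L)
  expect_true(isTRUE(attr(w255, "too_short")))

  # windows are ordered by start index and reproduce the series slices
  s <- mk(300)
  w <- make_windows(s, 256, 4)
  expect_equal(w[1, , ], s[1:256, ], ignore_attr = TRUE)
  expect_equal(w[2, , ], s[5:260, ], ignore_attr = TRUE)
})

test_that("noise augmentation multiplies counts and preserves originals", {
  w <- make_windows(matrix(rnorm(576), ncol = 3), 128, 16)
  n0 <- dim(w)[1] # (192 - 128) / 16 + 1
  expect_equal(n0, 5L)
  a <- augment_with_noise(w, variance = 0.2, n_copies = 10, seed = 3)
  expect_equal(dim(a)[1], 55L)
  expect_equal(a[seq_len(n0), , ], w, ignore_attr = TRUE)

  z <- augment_with_noise(w, variance = 0, n_copies = 3, seed = 3)
  expect_equal(dim(z)[1], 20L)
  for (j in 1:3) {
    expect_equal(z[j * n0 + seq_len(n0), , ], w, ignore_attr = TRUE)
  }
  expect_error(augment_with_noise(w, variance = -0.1, 2, 1), "variance")
})

test_that("augmentation noise has the configured variance", {
  # law of large numbers on > 1e5 noise samples
  w <- array(0, c(3, 120, 3))
  a <- augment_with_noise(w, variance = 0.2, n_copies = 100, seed = 11)
  noise <- as.numeric(a[-(1:3), , ])
  expect_gt(length(noise), 1e5)
  expect_gte(var(noise), 0.19)
  expect_lte(var(noise), 0.21)
  expect_lt(abs(mean(noise)), 0.01)
})

test_that("datasets split before windowing and never leak samples", {
  seg <- structure(list(values = matrix(seq_len(3840), ncol = 3,
                                        dimnames = list(NULL,
                                                        c("x", "y", "z"))),
                        label = "blue", participant_id = "P01",
                        bounds = c(start = 1, stop = 1280), rate = 50),
                   class = "steady_segment")
  cfg <- windowing_config(window_len = 256, stride = 4,
                          noise_variance = 0, n_augmented = 0, seed = 1)
  ds <- assemble_dataset(list(P01.blue = seg), cfg)
  # 1280 samples -> train on the first 1024 only, test on the last 256
  tr_vals <- ds$train$windows[, , 1]
  expect_lte(max(tr_vals), 1024)
  te_vals <- ds$test$windows[, , 1]
  expect_gte(min(te_vals), 1025)
  expect_equal(dim(ds$test$windows)[1], 1L)
  expect_equal(dim(ds$train$windows)[1], (1024 - 256) / 4 + 1)
  expect_true(all(ds$train$labels == "blue"))
  expect_true(all(ds$test$labels == "blue"))
})

test_that("train/test non-overlap holds across generated cases", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      t_len <- sample(600:1500, 1)
      seg <- structure(list(values = matrix(seq_len(3 * t_len),
                                            ncol = 3,
                                            dimnames = list(NULL,
                                                            c("x", "y", "z"))),
                            label = sample(condition_labels(), 1),
                            participant_id = "P09",
                            bounds = c(start = 1, stop = t_len),
                            rate = 50),
                       class = "steady_segment")
      stride <- sample(c(4, 8, 16), 1)
      cfg <- windowing_config(window_len = 256, stride = stride,
                              noise_variance = 0, n_augmented = 0)
      ds <- assemble_dataset(list(t = seg), cfg)
      cut <- floor(t_len * 0.8)
      if (dim(ds$train$windows)[1] > 0) {
        expect_lte(max(ds$train$windows[, , 1]), cut)
      }
      if (dim(ds$test$windows)[1] > 0) {
        expect_gt(min(ds$test$windows[, , 1]), cut)
      }
    }
  })
})

test_that("only the training split is augmented", {
  seg <- structure(list(values = matrix(rnorm(4800), ncol = 3,
                                        dimnames = list(NULL,
                                                        c("x", "y", "z"))),
                        label = "red", participant_id = "P02",
                        bounds = c(start = 1, stop = 1600), rate = 50),
                   class = "steady_segment")
  base <- assemble_dataset(list(s = seg),
                           windowing_config(stride = 8, n_augmented = 0))
  aug <- assemble_dataset(list(s = seg),
                          windowing_config(stride = 8, n_augmented = 10))
  expect_equal(dim(aug$train$windows)[1],
               11L * dim(base$train$windows)[1])
  expect_equal(dim(aug$test$windows)[1], dim(base$test$windows)[1])
  # test windows identical regardless of noise settings
  expect_equal(aug$test$windows, base$test$windows)
})

test_that("cross-validation folds partition each traversal", {
  seg <- structure(list(values = matrix(seq_len(3000), ncol = 3,
                                        dimnames = list(NULL,
                                                        c("x", "y", "z"))),
                        label = "black", participant_id = "P03",
                        bounds = c(start = 1, stop = 1000), rate = 50),
                   class = "steady_segment")
  cfg <- windowing_config(window_len = 128, stride = 8,
                          noise_variance = 0, n_augmented = 0)
  test_samples <- integer(0)
  for (f in 1:5) {
    ds <- assemble_fold_dataset(list(s = seg), cfg, fold = f, k = 5)
    te <- ds$test$windows[, , 1]
    tr <- ds$train$windows[, , 1]
    expect_length(intersect(unique(as.integer(te)),
                            unique(as.integer(tr))), 0L)
    test_samples <- c(test_samples, unique(as.integer(te)))
  }
  # fold test chunks are disjoint
  expect_equal(anyDuplicated(test_samples), 0L)
})
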