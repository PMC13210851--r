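test_that("confusion matrices count label pairs exactly", {
  labs <- condition_labels()
  # all-correct -> diagonal
  tr <- rep(labs, times = 2)
  cm <- confusion_matrix(tr, tr)
  expect_equal(diag(cm), rep(2L, 6), ignore_attr = TRUE)
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  # empty input -> zero matrix
  cm0 <- confusion_matrix(character(0), character(0))
  expect_equal(sum(cm0), 0L)
  expect_equal(dim(cm0), c(6L, 6L))

  # hand-listed 12-item vectors, counted by hand
  t12 <- c("none", "none", "green", "green", "blue", "blue",
           "black", "black", "red", "red", "orange", "orange")
  p12 <- c("none", "green", "green", "green", "blue", "green",
           "black", "red", "red", "black", "orange", "red")
  cm12 <- confusion_matrix(t12, p12)
  expect_equal(cm12["none", "none"], 1L)
  expect_equal(cm12["none", "green"], 1L)
  expect_equal(cm12["green", "green"], 2L)
  expect_equal(cm12["blue", "green"], 1L)
  expect_equal(cm12["black", "red"], 1L)
  expect_equal(cm12["red", "black"], 1L)
  expect_equal(cm12["orange", "red"], 1L)
  expect_equal(sum(cm12), 12L)

  expect_error(confusion_matrix("none", "turquoise"), "turquoise")
  expect_error(confusion_matrix(c("none", "red"), "none"), "equal length")
})

test_that("class-wise metrics agree with a brute-force oracle", {
  # perfect diagonal -> all ones
  cmP <- confusion_matrix(rep(condition_labels(), 3),
                          rep(condition_labels(), 3))
  cwP <- classwise_metrics(cmP)
  expect_true(all(cwP$precision == 1 & cwP$recall == 1 &
                    cwP$specificity == 1 & cwP$f1 == 1))

  # a class never predicted: precision 0 by convention, recall 0
  cmN <- confusion_matrix(c("none", "none", "green"),
                          c("green", "green", "green"))
  cwN <- classwise_metrics(cmN)
  expect_equal(cwN$precision[cwN$class == "none"], 0)
  expect_equal(cwN$recall[cwN$class == "none"], 0)
  expect_equal(cwN$f1[cwN$class == "none"], 0)

  withr::with_seed(41, {
    for (i in 1:200) {
      cm <- random_confusion()
      got <- classwise_metrics(cm)
      want <- oracle_classwise(cm)
      expect_equal(got$precision, want$precision, tolerance = 1e-12)
      expect_equal(got$recall, want$recall, tolerance = 1e-12)
      expect_equal(got$specificity, want$specificity, tolerance = 1e-12)
      expect_equal(got$f1, want$f1, tolerance = 1e-12)
    }
  })
})

test_that("aggregate indicators match their definitions", {
  withr::with_seed(42, {
    for (i in 1:100) {
      cm <- random_confusion()
      agg <- aggregate_metrics(cm)
      want <- oracle_aggregates(cm)
      expect_equal(agg$accuracy, want$accuracy, tolerance = 1e-12)
      expect_equal(agg$weighted_f1, want$weighted_f1, tolerance = 1e-12)
      expect_equal(agg$min_recall, want$min_recall, tolerance = 1e-12)
      expect_equal(agg$avg_f1, want$avg_f1, tolerance = 1e-12)
      expect_equal(agg$class_balance, want$class_balance,
                   tolerance = 1e-12)
      expect_equal(agg$avg_fpr, want$avg_fpr, tolerance = 1e-12)
      # weighted F1 lies between the extreme class F1 values
      cw <- classwise_metrics(cm)
      expect_gte(agg$weighted_f1, min(cw$f1) - 1e-12)
      expect_lte(agg$weighted_f1, max(cw$f1) + 1e-12)
    }
  })
  # perfect classifier: zero spread, zero FPR
  cmP <- confusion_matrix(rep(condition_labels(), 4),
                          rep(condition_labels(), 4))
  aggP <- aggregate_metrics(cmP)
  expect_equal(aggP$class_balance, 0)
  expect_equal(aggP$avg_fpr, 0)
})

test_that("class leakage reports the worst row-normalised mistakes", {
  # diagonal matrix -> no leakage
  cmP <- confusion_matrix(rep(condition_labels(), 2),
                          rep(condition_labels(), 2))
  expect_equal(nrow(class_leakage(cmP)), 0L)

  # constructed row with exactly 24% leakage
  cm <- matrix(0L, 6, 6, dimnames = list(true = condition_labels(),
                                         predicted = condition_labels()))
  cm["blue", "blue"] <- 76L
  cm["blue", "green"] <- 24L
  cm["red", "red"] <- 100L
  lk <- class_leakage(cm, top_k = 2)
  expect_equal(lk$from[1], "blue")
  expect_equal(lk$to[1], "green")
  expect_equal(lk$percent[1], 24)

  # ties broken by (row, column) class order
  cmT <- cm
  cmT["none", "none"] <- 76L
  cmT["none", "orange"] <- 24L
  lkT <- class_leakage(cmT, top_k = 2)
  expect_equal(lkT$from, c("none", "blue"))
  expect_equal(lkT$to, c("orange", "green"))
})

test_that("Wilson intervals obey boundaries and the closed form", {
  # p = 1 caps at exactly 1
  w1 <- wilson_interval(1, 50)
  expect_equal(w1$upper, 1)
  expect_lte(w1$lower, 1)

  # direct closed-form evaluation as the oracle
  p <- 0.5; n <- 40; z <- qnorm(0.975)
  w <- wilson_interval(p, n)
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  expect_equal(w$lower, centre - half, tolerance = 1e-12)
  expect_equal(w$upper, centre + half, tolerance = 1e-12)
  expect_lte(w$lower_offset, 0)
  expect_gte(w$upper_offset, 0)

  # large n: half-width approaches the Wald width within 1%
  p <- 0.71; n <- 1e6
  w <- wilson_interval(p, n)
  wald <- z * sqrt(p * (1 - p) / n)
  expect_equal((w$upper - w$lower) / 2, wald, tolerance = 0.01)

  expect_error(wilson_interval(0.5, 0), "n must be")
})

test_that("bootstrap intervals are seeded, stable and degenerate-safe", {
  labs <- rep(condition_labels(), each = 40)
  # all-correct predictions, accuracy metric -> zero-width at 1
  acc_fn <- function(tr, pr) mean(tr == pr)
  b <- bootstrap_interval(labs, labs, acc_fn, B = 200, seed = 1)
  expect_equal(b$lower, 1)
  expect_equal(b$upper, 1)
  expect_equal(b$point, 1)

  # doubling B with the same seed moves offsets by < 1 pp
  withr::with_seed(77, {
    pred <- ifelse(runif(length(labs)) < 0.75, labs,
                   sample(condition_labels(), length(labs), TRUE))
  })
  b1 <- bootstrap_interval(labs, pred, acc_fn, B = 500, seed = 5)
  b2 <- bootstrap_interval(labs, pred, acc_fn, B = 1000, seed = 5)
  expect_lt(abs(b1$lower_offset - b2$lower_offset), 1)
  expect_lt(abs(b1$upper_offset - b2$upper_offset), 1)
  # same seed, same B -> identical
  b3 <- bootstrap_interval(labs, pred, acc_fn, B = 500, seed = 5)
  expect_identical(b1$lower, b3$lower)

  expect_error(bootstrap_interval(labs, pred, acc_fn, B = 1), "B must be")
  expect_error(bootstrap_interval(character(0), character(0), acc_fn),
               "empty")
})

test_that("fold summaries use the Student-t construction", {
  # identical folds -> zero spread
  s0 <- summarise_folds(rep(70, 4))
  expect_equal(s0$sd, 0)
  expect_equal(s0$half_width, 0)

  # two folds: t(0.975, 1) = 12.706, checked against hand computation
  s2 <- summarise_folds(c(70, 74))
  expect_equal(s2$mean, 72)
  expect_equal(s2$sd, sd(c(70, 74)))
  expect_equal(s2$half_width, 12.70620 * sd(c(70, 74)) / sqrt(2),
               tolerance = 1e-5)

  # tabular input summarises each metric
  tab <- summarise_folds(data.frame(acc = c(70, 72, 74),
                                    f1 = c(68, 69, 70)))
  expect_equal(tab$metric, c("acc", "f1"))
  expect_equal(tab$mean, c(72, 69))

  expect_error(summarise_folds(70), "at least 2")
})

test_that("evaluation reports assemble every indicator with intervals", {
  withr::with_seed(55, {
    tr <- sample(condition_labels(), 300, replace = TRUE)
    pr <- ifelse(runif(300) < 0.7, tr,
                 sample(condition_labels(), 300, replace = TRUE))
  })
  rep_ <- evaluation_report(tr, pr, B = 100, seed = 2)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(sum(rep_$confusion), 300)
  expect_equal(rep_$intervals$accuracy$method, "wilson")
  expect_equal(rep_$intervals$accuracy$n, 300)
  expect_equal(rep_$intervals$min_recall$method, "bootstrap")
  agg <- rep_$aggregate
  expect_equal(agg$accuracy, mean(tr == pr), tolerance = 1e-12)
  for (iv in rep_$intervals) {
    expect_lte(iv$lower, iv$point + 1e-9)
    expect_gte(iv$upper, iv$point - 1e-9)
  }
})
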