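#' Confusion matrix over the condition classes
#'
#' Rows are true classes, columns predicted classes, in canonical
#' condition order (or any explicit class set).
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param labels Class set and order (default the six canonical
#'   condition labels).
#' @return Integer matrix with `counts[i, j] = #(true = i, pred = j)`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             labels = condition_labels()) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), labels)
  if (length(bad) > 0L) {
    stop("unknown label: '", bad[1], "'", call. = FALSE)
  }
  cm <- table(factor(true_labels, levels = labels),
              factor(predicted_labels, levels = labels))
  m <- matrix(as.integer(cm), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

#' Class-wise classification metrics
#'
#' One-vs-rest precision, recall, specificity and F1 per class, as
#' fractions. Undefined ratios (zero denominator) are reported as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return data.frame with one row per class: `class`, `precision`,
#'   `recall`, `specificity`, `f1`, `support`.
#' @export
classwise_metrics <- function(cm) {
  total <- sum(cm)
  k <- nrow(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  data.frame(class = rownames(cm), precision = precision, recall = recall,
             specificity = specificity, f1 = f1,
             support = rowSums(cm), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Minimum per-class recall
#'
#' @param recalls Numeric vector of per-class recalls.
#' @return The smallest recall, in the units of the input.
#' @export
min_recall <- function(recalls) min(recalls)

#' Class balance: recall spread in percentage points
#'
#' The maximum minus the minimum per-class recall. Fraction-valued
#' recalls are converted to percentage points; inputs already in percent
#' are used as is.
#'
#' @param recalls Numeric vector of per-class recalls (fractions in
#'   \[0, 1\] or percentages).
#' @return Recall spread in percentage points.
#' @export
class_balance <- function(recalls) {
  spread <- max(recalls) - min(recalls)
  if (all(recalls <= 1)) spread <- 100 * spread
  spread
}

#' Largest class-leakage entries (the classifier's worst mistakes)
#'
#' Off-diagonal confusion entries, row-normalised to percentages of the
#' true class and rounded to whole numbers, sorted descending; ties are
#' broken by (row, column) class order.
#'
#' @param cm A [confusion_matrix()].
#' @param top_k Number of entries to report.
#' @return data.frame with `from`, `to`, `percent` (whole-number
#'   percentage of the true-class rows), strongest first; zero rows for
#'   a diagonal matrix.
#' @export
class_leakage <- function(cm, top_k = 3L) {
  rs <- rowSums(cm)
  pct <- 100 * cm / ifelse(rs > 0, rs, 1)
  diag(pct) <- 0
  ord <- order(-pct, row(cm), col(cm))
  ord <- ord[pct[ord] > 0]
  ord <- utils::head(ord, top_k)
  data.frame(from = rownames(cm)[row(cm)[ord]],
             to = colnames(cm)[col(cm)[ord]],
             percent = round(pct[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate classification indicators
#'
#' The summary row the evaluation reports are built from: overall
#' accuracy, support-weighted F1, minimum per-class recall, unweighted
#' mean F1, class balance (max recall - min recall, percentage points),
#' average one-vs-rest false-positive rate (mean over classes of
#' 1 - specificity), and the top class-leakage entries.
#'
#' @param cm A [confusion_matrix()].
#' @param top_k Leakage entries to include.
#' @return List of class `aggregate_report`.
#' @export
aggregate_metrics <- function(cm, top_k = 3L) {
  cw <- classwise_metrics(cm)
  total <- sum(cm)
  acc <- if (total > 0) sum(diag(cm)) / total else 0
  wf1 <- if (total > 0) sum(cw$f1 * cw$support) / total else 0
  structure(list(
    accuracy = acc,
    weighted_f1 = wf1,
    min_recall = min_recall(cw$recall),
    avg_f1 = mean(cw$f1),
    class_balance = class_balance(cw$recall),
    avg_fpr = mean(1 - cw$specificity),
    leakage = class_leakage(cm, top_k),
    classwise = cw,
    confusion = cm
  ), class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf(paste0("<aggregate_report> accuracy %.2f%%, weighted F1 ",
                     "%.2f%%, min recall %.2f%%,\n  avg F1 %.2f%%, class ",
                     "balance %.2f pp, avg FPR %.2f%%\n"),
              100 * x$accuracy, 100 * x$weighted_f1, 100 * x$min_recall,
              100 * x$avg_f1, x$class_balance, 100 * x$avg_fpr))
  if (nrow(x$leakage) > 0) {
    cat("  worst mistakes:",
        paste(sprintf("%s -> %s (%d%%)", x$leakage$from, x$leakage$to,
                      x$leakage$percent), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Wilson score interval for a proportion
#'
#' @param p_hat Observed proportion in \[0, 1\].
#' @param n Number of observations (here: test windows).
#' @param confidence Confidence level (default 0.95).
#' @return List of class `interval_estimate`: `point` (the proportion),
#'   `lower`, `upper` (absolute bounds), `lower_offset`, `upper_offset`
#'   (percentage points relative to the point), `method`, `confidence`,
#'   `n`.
#' @export
wilson_interval <- function(p_hat, n, confidence = 0.95) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (p_hat < 0 || p_hat > 1) stop("p_hat must be in [0, 1]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  lower <- max(0, centre - half)
  upper <- min(1, centre + half)
  structure(list(point = p_hat, lower = lower, upper = upper,
                 lower_offset = 100 * (lower - p_hat),
                 upper_offset = 100 * (upper - p_hat),
                 method = "wilson", confidence = confidence, n = n),
            class = "interval_estimate")
}

#' Percentile bootstrap interval for any prediction-level metric
#'
#' Resamples (true, predicted) pairs with replacement `B` times and takes
#' the percentile interval of the metric over the resamples.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param metric_fn Function `(true, pred) -> scalar`.
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Integer seed.
#' @param confidence Confidence level.
#' @return An `interval_estimate` (offsets in percentage points when the
#'   metric is a fraction, in metric units otherwise; offsets are always
#'   `100 * (bound - point)` for fraction-valued metrics and
#'   `bound - point` for others -- here we report raw metric units times
#'   100 only when the point is at most 1).
#' @export
bootstrap_interval <- function(true_labels, predicted_labels, metric_fn,
                               B = 1000L, seed = 1L, confidence = 0.95) {
  n <- length(true_labels)
  if (n == 0L) stop("empty label vectors", call. = FALSE)
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  point <- metric_fn(true_labels, predicted_labels)
  stat <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_fn(true_labels[idx], predicted_labels[idx])
    }, numeric(1))
  })
  alpha <- 1 - confidence
  qs <- stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  scale <- if (abs(point) <= 1) 100 else 1
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 lower_offset = scale * (qs[1] - point),
                 upper_offset = scale * (qs[2] - point),
                 method = "bootstrap", confidence = confidence, n = n,
                 B = B),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("<interval_estimate> %s: %.4f [%.4f, %.4f] at %.0f%%\n",
              x$method, x$point, x$lower, x$upper, 100 * x$confidence))
  invisible(x)
}

#' Student-t summary of fold-wise metrics
#'
#' For each metric, the fold mean, sample standard deviation (n - 1
#' denominator) and the 95% confidence half-width
#' `t(0.975, k - 1) * sd / sqrt(k)`, in the units of the input.
#'
#' @param per_fold_metrics Numeric vector (one metric across folds), or
#'   a matrix/data.frame with one row per fold and one column per metric.
#' @param confidence Confidence level.
#' @return For a vector: list of class `fold_summary` with `values`,
#'   `mean`, `sd`, `half_width`, `k`. For tabular input: data.frame with
#'   one row per metric.
#' @export
summarise_folds <- function(per_fold_metrics, confidence = 0.95) {
  if (is.data.frame(per_fold_metrics) || is.matrix(per_fold_metrics)) {
    m <- as.data.frame(per_fold_metrics)
    out <- do.call(rbind, lapply(names(m), function(nm) {
      s <- summarise_folds(m[[nm]], confidence)
      data.frame(metric = nm, mean = s$mean, sd = s$sd,
                 half_width = s$half_width, k = s$k,
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }
  x <- as.numeric(per_fold_metrics)
  k <- length(x)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  s <- stats::sd(x)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = k - 1)
  structure(list(values = x, mean = mean(x), sd = s,
                 half_width = tq * s / sqrt(k), k = k,
                 confidence = confidence),
            class = "fold_summary")
}

#' Full evaluation report for one prediction set
#'
#' Confusion matrix, class-wise metrics, aggregate indicators, a Wilson
#' interval for accuracy (n = number of test windows) and percentile
#' bootstrap intervals for min recall, average F1, class balance and
#' average FPR, mirroring the study's reporting structure.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param labels Class set and order.
#' @param B Bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(true_labels, predicted_labels,
                              labels = condition_labels(), B = 500L,
                              seed = 1L) {
  cm <- confusion_matrix(true_labels, predicted_labels, labels)
  agg <- aggregate_metrics(cm)
  boot_of <- function(extract, idx) {
    bootstrap_interval(true_labels, predicted_labels, function(tr, pr) {
      extract(aggregate_metrics(confusion_matrix(tr, pr, labels)))
    }, B = B, seed = derive_seed(seed, "boot", idx))
  }
  structure(list(
    confusion = cm,
    classwise = agg$classwise,
    aggregate = agg,
    intervals = list(
      accuracy = wilson_interval(agg$accuracy, length(true_labels)),
      min_recall = boot_of(function(a) a$min_recall, 1L),
      avg_f1 = boot_of(function(a) a$avg_f1, 2L),
      class_balance = boot_of(function(a) a$class_balance, 3L),
      avg_fpr = boot_of(function(a) a$avg_fpr, 4L)
    )
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$aggregate)
  invisible(x)
}
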