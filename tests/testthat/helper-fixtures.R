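# Shared fixtures, built in code at load time.

# default participant with no pocket-orientation rotation, for tests
# that reason about axis semantics directly
flat_participant <- function(f_step = 1.8) {
  data.frame(participant_id = "P01", base_step_frequency = f_step,
             amp_x = 1.2, amp_y = 2.0, amp_z = 3.2,
             orientation_jitter = 0, stringsAsFactors = FALSE)
}

profile_for <- function(label) {
  p <- build_condition_profiles()
  p[p$label == label, ]
}

# small sinusoidal window set: two classes separated by frequency and
# amplitude
two_class_windows <- function(n_per_class = 60, t_len = 64, seed = 7) {
  withr::with_seed(seed, {
    mk <- function(freq, amp) {
      t <- seq_len(t_len) / 50
      w <- array(NA_real_, c(n_per_class, t_len, 3))
      for (i in seq_len(n_per_class)) {
        ph <- runif(1, 0, 2 * pi)
        base <- amp * sin(2 * pi * freq * t + ph)
        w[i, , 1] <- base + rnorm(t_len, 0, 0.05)
        w[i, , 2] <- 0.5 * base + rnorm(t_len, 0, 0.05)
        w[i, , 3] <- rnorm(t_len, 0, 0.05)
      }
      w
    }
    wa <- mk(1.5, 1)
    wb <- mk(6.0, 1.8)
    d <- dim(wa)
    all <- array(NA_real_, c(2 * n_per_class, t_len, 3))
    all[seq_len(n_per_class), , ] <- wa
    all[n_per_class + seq_len(n_per_class), , ] <- wb
    list(windows = all,
         labels = rep(c("none", "orange"), each = n_per_class))
  })
}

# independent one-vs-rest metric oracle: plain loops over matrix cells
oracle_classwise <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  out <- data.frame(precision = numeric(k), recall = numeric(k),
                    specificity = numeric(k), f1 = numeric(k))
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fp <- 0; fn <- 0
    for (j in seq_len(k)) {
      if (j != i) {
        fp <- fp + cm[j, i]
        fn <- fn + cm[i, j]
      }
    }
    tn <- total - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out[i, ] <- c(prec, rec, spec, f1)
  }
  out
}

oracle_aggregates <- function(cm) {
  cw <- oracle_classwise(cm)
  supports <- rowSums(cm)
  total <- sum(cm)
  list(accuracy = sum(diag(cm)) / total,
       weighted_f1 = sum(cw$f1 * supports) / total,
       min_recall = min(cw$recall),
       avg_f1 = mean(cw$f1),
       class_balance = 100 * (max(cw$recall) - min(cw$recall)),
       avg_fpr = mean(1 - cw$specificity))
}

random_confusion <- function(k = 6) {
  m <- matrix(rpois(k * k, 8), k, k)
  diag(m) <- diag(m) + rpois(k, 30)
  dimnames(m) <- list(true = condition_labels()[seq_len(k)],
                      predicted = condition_labels()[seq_len(k)])
  m
}
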