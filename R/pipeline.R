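#' Experiment configuration
#'
#' Bundles every stage configuration for an end-to-end run: cohort
#' simulation, windowing, the architectures to train, training and
#' pretraining settings, cross-validation folds and ablation channel
#' subsets. One global `seed` fans out to per-stage seeds via
#' [derive_seed()], so each stage is independently reproducible.
#'
#' @param cohort A [cohort_config()].
#' @param windowing A [windowing_config()].
#' @param architectures Character vector of architecture names.
#' @param training A [training_config()].
#' @param pretrain A [pretrain_config()], or `NULL` to skip encoder
#'   pretraining.
#' @param cv_folds Number of cross-validation folds (1 = plain 80/20
#'   split only).
#' @param channel_subsets List of channel-name vectors for ablation.
#' @param output_dir Directory for simulated data and reports (a
#'   temporary directory when `NULL`).
#' @param seed Global integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              windowing = windowing_config(),
                              architectures = "A2",
                              training = training_config(),
                              pretrain = pretrain_config(),
                              cv_folds = 5L,
                              channel_subsets = list(
                                c("x", "y", "z"), c("x", "y"),
                                c("x", "z"), "x", "z"),
                              output_dir = NULL,
                              seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(windowing, "windowing_config"),
            inherits(training, "training_config"))
  for (s in channel_subsets) {
    if (length(s) == 0L) stop("empty channel subset", call. = FALSE)
  }
  for (a in architectures) architecture_spec(a) # validates names
  structure(list(cohort = cohort, windowing = windowing,
                 architectures = architectures, training = training,
                 pretrain = pretrain, cv_folds = as.integer(cv_folds),
                 channel_subsets = channel_subsets,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

# simulate + preprocess + window under the experiment's derived seeds
prepare_experiment_data <- function(config) {
  dir <- config$output_dir %||% file.path(tempdir(), paste0(
    "gaitshift-", config$seed, "-", as.integer(stats::runif(1, 1, 1e8))))
  cohort <- config$cohort
  cohort$seed <- derive_seed(config$seed, "cohort")
  sim <- simulate_cohort(cohort, file.path(dir, "cohort"))
  prep <- preprocess_cohort(sim$manifest)
  wcfg <- config$windowing
  wcfg$seed <- derive_seed(config$seed, "windowing")
  list(dir = dir, sim = sim, segments = prep$segments, qc = prep$qc,
       windowing = wcfg)
}

has_conv_stem <- function(model) {
  model$layers[[1]]$type == "conv1d"
}

# pretrain (if applicable) + train + evaluate one model on one dataset
fit_and_evaluate <- function(arch, data, config, channels = NULL,
                             seed_tag = "fit", seed_index = 0L) {
  ds <- assemble_dataset(data$segments, data$windowing)
  fit_and_evaluate_ds(arch, ds$train, ds$test, config, channels,
                      seed_tag, seed_index)
}

fit_and_evaluate_ds <- function(arch, train_ds, test_ds, config,
                                channels = NULL, seed_tag = "fit",
                                seed_index = 0L) {
  if (!is.null(channels)) {
    train_ds <- select_channels(train_ds, channels)
    test_ds <- select_channels(test_ds, channels)
  }
  n_ch <- dim(train_ds$windows)[3]
  model <- build_model(architecture_spec(arch, in_channels = n_ch),
                       seed = derive_seed(config$seed,
                                          paste0(seed_tag, "_init"),
                                          seed_index))
  loss_history <- NULL
  if (!is.null(config$pretrain) && has_conv_stem(model)) {
    pcfg <- config$pretrain
    pcfg$seed <- derive_seed(config$seed, paste0(seed_tag, "_ssl"),
                             seed_index)
    pt <- pretrain_encoder(model, train_ds$windows, pcfg)
    model <- pt$model
    loss_history <- pt$loss_history
  }
  tcfg <- config$training
  tcfg$seed <- derive_seed(config$seed, paste0(seed_tag, "_train"),
                           seed_index)
  tr <- train_classifier(model, train_ds, tcfg)
  pred <- predict_labels(tr$model, test_ds$windows)
  report <- evaluation_report(test_ds$labels, pred,
                              seed = derive_seed(config$seed,
                                                 paste0(seed_tag, "_boot"),
                                                 seed_index))
  list(model = tr$model, history = tr$history,
       pretrain_loss = loss_history, report = report,
       parameters = count_trainable_parameters(tr$model),
       test_labels = test_ds$labels, predictions = pred)
}

#' Restrict a window dataset to named channels
#'
#' @param dataset A [window_dataset].
#' @param channels Channel names to keep (order preserved as given).
#' @return The restricted `window_dataset`.
#' @export
select_channels <- function(dataset, channels) {
  if (length(channels) == 0L) stop("empty channel subset", call. = FALSE)
  idx <- match(channels, dataset$channel_names)
  if (anyNA(idx)) {
    stop("unknown channel: '", channels[which(is.na(idx))[1]], "'",
         call. = FALSE)
  }
  dataset$windows <- dataset$windows[, , idx, drop = FALSE]
  dataset$channel_names <- channels
  dataset
}

#' Run an end-to-end experiment
#'
#' Simulates the configured cohort, preprocesses every traversal to its
#' steady-gait segment, assembles the within-traversal 80/20 window
#' datasets, then, per requested architecture: pretrains the encoder
#' (when present), trains the classifier, and evaluates on the test
#' windows. With `cv_folds > 1`, additionally retrains per fold on the
#' contiguous within-traversal folds and summarises fold metrics with
#' Student-t intervals. Fully reproducible from (config, seed).
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress.
#' @return List of class `experiment_result`: per architecture a list
#'   with `model`, `history`, `report` ([evaluation_report()]),
#'   `parameters` and (if folds were run) `folds` plus `fold_summary`;
#'   plus `qc` and the data directory.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("simulating cohort (%d participants x %d conditions)",
      config$cohort$n_participants, length(config$cohort$conditions))
  data <- tryCatch(prepare_experiment_data(config),
                   error = function(e) {
                     stop("stage [simulate/preprocess] failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
  ds <- tryCatch(assemble_dataset(data$segments, data$windowing),
                 error = function(e) {
                   stop("stage [windowing] failed: ",
                        conditionMessage(e), call. = FALSE)
                 })
  results <- list()
  for (ai in seq_along(config$architectures)) {
    arch <- config$architectures[ai]
    say("training %s on %d windows", arch, dim(ds$train$windows)[1])
    res <- tryCatch(
      fit_and_evaluate_ds(arch, ds$train, ds$test, config,
                          seed_tag = "main", seed_index = ai),
      error = function(e) {
        stop("stage [train ", arch, "] failed: ", conditionMessage(e),
             call. = FALSE)
      })
    if (config$cv_folds > 1L) {
      k <- config$cv_folds
      fold_metrics <- vector("list", k)
      folds <- vector("list", k)
      for (f in seq_len(k)) {
        say("  fold %d/%d", f, k)
        fds <- assemble_fold_dataset(data$segments, data$windowing,
                                     fold = f, k = k)
        fr <- fit_and_evaluate_ds(arch, fds$train, fds$test, config,
                                  seed_tag = paste0("fold", f),
                                  seed_index = ai)
        agg <- fr$report$aggregate
        fold_metrics[[f]] <- data.frame(
          accuracy = 100 * agg$accuracy,
          weighted_f1 = 100 * agg$weighted_f1,
          min_recall = 100 * agg$min_recall,
          avg_f1 = 100 * agg$avg_f1,
          class_balance = agg$class_balance,
          avg_fpr = 100 * agg$avg_fpr)
        folds[[f]] <- fr$report
      }
      res$folds <- folds
      res$fold_metrics <- do.call(rbind, fold_metrics)
      res$fold_summary <- summarise_folds(res$fold_metrics)
    }
    results[[arch]] <- res
  }
  structure(list(results = results, qc = data$qc, dir = data$dir,
                 config = config),
            class = "experiment_result")
}

#' Input-channel ablation study
#'
#' Trains and evaluates one architecture (A5 by default) on each
#' configured channel subset of the same simulated cohort: all rows
#' share the cohort, the preprocessing, the window splits and the seed
#' derivation, so differences reflect the removed channels only.
#'
#' @param config An [experiment_config()].
#' @param arch Architecture to ablate.
#' @param verbose Print progress.
#' @return data.frame with one row per channel subset: `channels`,
#'   `parameters`, and the aggregate metric columns (percent /
#'   percentage points); the per-subset [evaluation_report()]s are
#'   attached as attribute `reports`.
#' @export
run_ablation <- function(config, arch = "A5", verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  data <- prepare_experiment_data(config)
  ds <- assemble_dataset(data$segments, data$windowing)
  rows <- list()
  reports <- list()
  for (si in seq_along(config$channel_subsets)) {
    subset <- config$channel_subsets[[si]]
    if (verbose) message("ablation subset: ", paste(subset, collapse = ","))
    res <- fit_and_evaluate_ds(arch, ds$train, ds$test, config,
                               channels = subset, seed_tag = "ablate",
                               seed_index = si)
    agg <- res$report$aggregate
    rows[[si]] <- data.frame(
      channels = paste(subset, collapse = ","),
      parameters = res$parameters,
      accuracy = 100 * agg$accuracy,
      weighted_f1 = 100 * agg$weighted_f1,
      min_recall = 100 * agg$min_recall,
      avg_f1 = 100 * agg$avg_f1,
      class_balance = agg$class_balance,
      avg_fpr = 100 * agg$avg_fpr,
      stringsAsFactors = FALSE)
    reports[[paste(subset, collapse = ",")]] <- res$report
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Frozen reduced-scale benchmark configuration
#'
#' The package's standing synthetic benchmark: a 6-participant cohort
#' with shorter traversals (2000--3000 active samples), stride-16
#' windows with a single noisy copy per training window, and 5 training
#' epochs of the BiLSTM classifier A2. These sizes keep a full run to a
#' few minutes on one CPU while preserving the study's statistical
#' structure; the calibrated default effect sizes put A2's test accuracy
#' in the 60--85% band under this config.
#'
#' @param seed Global seed.
#' @param effect_scale Condition effect scale (0 = null cohort).
#' @param architectures Architectures to train (default A2).
#' @param n_participants Cohort size.
#' @param max_epochs Training epochs.
#' @return An [experiment_config()].
#' @export
reduced_benchmark_config <- function(seed = 1L, effect_scale = 1,
                                     architectures = "A2",
                                     n_participants = 6L,
                                     max_epochs = 5L) {
  experiment_config(
    cohort = cohort_config(n_participants = n_participants,
                           active_length_range = c(2000L, 3000L),
                           target_mean_length = 2400,
                           effect_scale = effect_scale),
    windowing = windowing_config(stride = 16L, n_augmented = 1L),
    architectures = architectures,
    training = training_config(max_epochs = max_epochs),
    pretrain = NULL,
    cv_folds = 1L,
    seed = seed)
}
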