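# Reduced-scale benchmark runs are expensive (minutes each), so they are
# computed once per test session and shared across test files.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function(effect_scale, seed = 2026L) {
  key <- sprintf("scale_%s_seed_%d", format(effect_scale), seed)
  if (!exists(key, envir = .benchmark_cache)) {
    cfg <- reduced_benchmark_config(seed = seed,
                                    effect_scale = effect_scale)
    assign(key, run_experiment(cfg), envir = .benchmark_cache)
  }
  get(key, envir = .benchmark_cache)
}

smoke_config <- function(seed = 5L, cv_folds = 1L, max_epochs = 1L) {
  experiment_config(
    cohort = cohort_config(n_participants = 2L,
                           conditions = c("none", "black"),
                           active_length_range = c(1900L, 2200L),
                           target_mean_length = 2000,
                           seed = seed),
    windowing = windowing_config(stride = 16L, n_augmented = 1L),
    architectures = "A2",
    training = training_config(max_epochs = max_epochs),
    pretrain = NULL,
    cv_folds = cv_folds,
    seed = seed)
}
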