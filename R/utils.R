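#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global random
#' stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage-specific seed from a global seed
#'
#' One global experiment seed fans out to per-stage seeds via a fixed
#' affine map modulo 2^31 - 1, so each pipeline stage (cohort simulation,
#' windowing noise, weight initialisation, batch shuffling, ...) is
#' independently reproducible. `index` separates repeated uses within a
#' stage (e.g. per traversal or per fold).
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @param index Optional non-negative integer sub-index (default 0).
#' @return An integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  m <- 2147483647 # 2^31 - 1, prime
  v <- (as.double(seed) %% m) * 48271 + h * 16807 + as.double(index) * 69621
  as.integer(v %% (m - 1)) + 1L
}

# stopifnot-style scalar checks used across modules
check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single number", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be positive", call. = FALSE)
  invisible(x)
}
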