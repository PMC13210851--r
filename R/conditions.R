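#' Canonical goggle condition labels
#'
#' The six walking conditions, ordered by the midpoint of the simulated
#' blood-alcohol concentration (BAC) range declared by the goggle
#' manufacturer: no goggles first, then strap colours of increasing
#' simulated impairment. This ordering is used everywhere a class axis is
#' needed (confusion matrices, reports).
#'
#' @return Character vector of the six labels in canonical order.
#' @export
condition_labels <- function() {
  c("none", "green", "blue", "black", "red", "orange")
}

# Manufacturer-declared simulated BAC range (%) per strap colour.
.bac_ranges <- list(
  none   = c(0.00, 0.00),
  green  = c(0.04, 0.06),
  blue   = c(0.06, 0.08),
  black  = c(0.08, 0.15),
  red    = c(0.15, 0.25),
  orange = c(0.26, 0.35)
)

#' Simulated BAC range for a condition label
#'
#' @param label Condition label (one of [condition_labels()]).
#' @return Numeric length-2 vector, the declared BAC range in percent.
#' @export
bac_range <- function(label) {
  check_condition_label(label)
  .bac_ranges[[label]]
}

#' Impairment severity of a condition
#'
#' Severity is the midpoint of the condition's simulated BAC range divided
#' by the largest midpoint across all six conditions, so that the
#' no-goggles condition has severity 0 and the strongest goggles
#' (orange, 0.26--0.35% BAC) have severity 1.
#'
#' @inheritParams bac_range
#' @return Fraction in \[0, 1\].
#' @export
condition_severity <- function(label) {
  check_condition_label(label)
  mids <- vapply(.bac_ranges, mean, numeric(1))
  mean(.bac_ranges[[label]]) / max(mids)
}

check_condition_label <- function(label) {
  if (length(label) != 1L || !is.character(label) ||
      !label %in% condition_labels()) {
    stop("unknown condition label: '", paste(label, collapse = ","),
         "' (expected one of ", paste(condition_labels(), collapse = ", "),
         ")", call. = FALSE)
  }
  invisible(label)
}

#' Condition-dependent gait perturbation profiles
#'
#' Maps each condition's severity onto the multipliers the synthetic gait
#' generator applies: step-interval coefficient-of-variation inflation,
#' mediolateral sway amplification, cadence reduction, and per-step
#' harmonic irregularity. All are deterministic, monotone functions of
#' severity and neutral (1, 1, 1, 0) at severity 0, emulating a gradual
#' transition of gait behaviour with increasing simulated impairment.
#'
#' @param labels Character vector of condition labels
#'   (default: all six in canonical order).
#' @return A data.frame with one row per label: `label`, `bac_low`,
#'   `bac_high`, `severity`, `step_time_cv_multiplier`,
#'   `sway_amplitude_multiplier`, `cadence_multiplier`,
#'   `harmonic_irregularity`.
#' @export
build_condition_profiles <- function(labels = condition_labels()) {
  for (lab in labels) check_condition_label(lab)
  if (anyDuplicated(labels)) {
    stop("duplicated condition labels", call. = FALSE)
  }
  sev <- vapply(labels, condition_severity, numeric(1))
  data.frame(
    label = labels,
    bac_low = vapply(labels, function(l) .bac_ranges[[l]][1], numeric(1)),
    bac_high = vapply(labels, function(l) .bac_ranges[[l]][2], numeric(1)),
    severity = sev,
    step_time_cv_multiplier = 1 + 2.5 * sev,
    sway_amplitude_multiplier = 1 + 4.5 * sev,
    cadence_multiplier = 1 - 0.28 * sev,
    harmonic_irregularity = 0.6 * sev,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
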