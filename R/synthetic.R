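#' Cohort configuration for the synthetic gait generator
#'
#' Defaults reproduce the study layout: 16 participants, each walking once
#' under every one of the 6 goggle conditions (96 traversals), tri-axial
#' acceleration at 50 Hz, active-walking lengths inside 2293--6211 samples
#' with a target mean of 3030, and a stationary pad at both ends of every
#' recording bracketed by start/stop markers.
#'
#' @param n_participants Number of participants (default 16).
#' @param conditions Condition labels simulated (default all six).
#' @param sampling_rate Sampling rate in Hz (default 50).
#' @param active_length_range Min/max active-walking length in samples
#'   (default `c(2293, 6211)`).
#' @param target_mean_length Target mean active length in samples
#'   (default 3030); set `NULL` for a plain uniform draw over the range.
#' @param pad_duration Stationary pad duration at each end, seconds.
#' @param effect_scale Global scale on all condition effects: 1 is the
#'   calibrated default, 0 disables every condition-dependent perturbation
#'   (the null cohort, in which the six classes are exchangeable).
#' @param include_gyro Also emit (never modelled) gyroscope channels.
#' @param noise_sd Measurement noise standard deviation, m/s^2.
#' @param seed Integer seed; the cohort is a pure function of this config.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants = 16L,
                          conditions = condition_labels(),
                          sampling_rate = 50,
                          active_length_range = c(2293L, 6211L),
                          target_mean_length = 3030,
                          pad_duration = 2,
                          effect_scale = 1,
                          include_gyro = FALSE,
                          noise_sd = 0.08,
                          seed = 1L) {
  check_scalar_number(n_participants, "n_participants", positive = TRUE)
  check_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar_number(seed, "seed")
  for (lab in conditions) check_condition_label(lab)
  if (length(active_length_range) != 2L ||
      active_length_range[1] > active_length_range[2]) {
    stop("active_length_range must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (effect_scale < 0) stop("effect_scale must be >= 0", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    conditions = conditions,
    sampling_rate = sampling_rate,
    active_length_range = as.integer(active_length_range),
    target_mean_length = target_mean_length,
    pad_duration = pad_duration,
    effect_scale = effect_scale,
    include_gyro = isTRUE(include_gyro),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw per-participant gait profiles
#'
#' Inter-subject variability: base step frequency ~1.6--2.0 Hz, per-axis
#' dynamic-acceleration amplitudes, the relative phases of the gait
#' harmonics, and a small fixed pocket-orientation rotation. All of
#' these are properties of a person's gait and device placement, so they
#' are shared by all of that participant's traversals; nothing persistent
#' distinguishes two traversals of the same participant beyond the
#' condition effects themselves, which keeps the six classes exchangeable
#' when those effects are disabled.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return data.frame with one row per participant.
#' @export
participant_profiles <- function(n, seed) {
  check_scalar_number(n, "n", positive = TRUE)
  with_seed(seed, {
    df <- data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      base_step_frequency = stats::runif(n, 1.6, 2.0),
      amp_x = stats::runif(n, 1.0, 1.8),   # mediolateral
      amp_y = stats::runif(n, 1.5, 2.5),   # anteroposterior
      amp_z = stats::runif(n, 2.5, 4.0),   # vertical (dynamic part)
      orientation_jitter = stats::rnorm(n, 0, 0.05),
      stringsAsFactors = FALSE
    )
    ph <- matrix(stats::runif(6 * n, 0, 2 * pi), n, 6)
    colnames(ph) <- paste0("phase_", 1:6)
    cbind(df, as.data.frame(ph))
  })
}

# Effect-scaled condition profile: multipliers shrunk toward neutral.
scale_condition_profile <- function(profile, effect_scale) {
  profile$step_time_cv_multiplier <-
    1 + effect_scale * (profile$step_time_cv_multiplier - 1)
  profile$sway_amplitude_multiplier <-
    1 + effect_scale * (profile$sway_amplitude_multiplier - 1)
  profile$cadence_multiplier <-
    1 + effect_scale * (profile$cadence_multiplier - 1)
  profile$harmonic_irregularity <-
    effect_scale * profile$harmonic_irregularity
  profile
}

# Piecewise-linear gait phase: 2*pi per step, with jittered step intervals.
# Returns phase at the n uniform sample times plus the realised step times.
gait_phase <- function(n, rate, f_step, cv) {
  duration <- n / rate
  n_steps <- ceiling(duration * f_step * 1.5) + 4L
  tau <- 1 / f_step
  intervals <- tau * (1 + cv * stats::rnorm(n_steps))
  intervals <- pmax(intervals, 0.4 * tau)
  bounds <- c(0, cumsum(intervals))
  t <- (seq_len(n) - 1) / rate
  k <- findInterval(t, bounds) # step index >= 1
  frac <- (t - bounds[k]) / intervals[k]
  list(phase = 2 * pi * ((k - 1) + frac),
       step_index = k,
       step_times = bounds[bounds <= duration])
}

#' Simulate one walking traversal
#'
#' Generates a padded, marker-bracketed tri-axial accelerometer recording
#' for one participant under one goggle condition. The active region is a
#' harmonic gait signal: the vertical axis carries gravity (+9.81 m/s^2)
#' plus step-frequency harmonics, the anteroposterior axis step-frequency
#' harmonics, and the mediolateral axis stride-frequency (half step
#' frequency) oscillation plus autocorrelated sway noise. Step intervals
#' are jittered with a coefficient of variation inflated by the condition
#' profile; cadence, sway amplitude and per-step amplitude irregularity
#' scale with condition severity. Stationary low-noise pads precede and
#' follow the active region and the returned markers bracket it.
#'
#' @param participant One row of [participant_profiles()].
#' @param condition_profile One row of [build_condition_profiles()].
#' @param length Active-region length in samples.
#' @param rate Sampling rate, Hz.
#' @param pad_duration Stationary pad duration at each end, seconds.
#' @param noise_sd Measurement noise standard deviation, m/s^2.
#' @param effect_scale Scale on condition effects (see [cohort_config()]).
#' @param seed Integer seed; identical seeds give identical traversals.
#' @return List with `recording` (a `raw_recording`), `markers`
#'   (`i_start_raw`, `i_stop_raw`), `label`, and `truth` (generator ground
#'   truth: active bounds, step times, effective step frequency).
#' @export
simulate_traversal <- function(participant, condition_profile, length,
                               rate = 50, pad_duration = 2,
                               noise_sd = 0.08, effect_scale = 1,
                               seed = 1L) {
  check_scalar_number(length, "length", positive = TRUE)
  check_condition_label(condition_profile$label)
  n <- as.integer(length)
  prof <- scale_condition_profile(condition_profile, effect_scale)

  with_seed(seed, {
    f_step <- participant$base_step_frequency * prof$cadence_multiplier
    cv <- 0.04 * prof$step_time_cv_multiplier
    ph <- gait_phase(n, rate, f_step, cv)
    phase <- ph$phase

    # per-step amplitude irregularity, piecewise constant over steps
    n_steps <- max(ph$step_index)
    gmod <- 1 + prof$harmonic_irregularity *
      0.5 * stats::rnorm(n_steps)
    gmod <- pmax(gmod, 0.2)
    # oscillation at fixed displacement has acceleration ~ frequency^2,
    # so reduced cadence also damps the dynamic gait amplitudes
    g <- gmod[ph$step_index] * prof$cadence_multiplier^2

    # harmonic phase structure is a participant trait (falling back to a
    # fresh draw only for hand-built profiles without phase columns)
    th <- if (all(paste0("phase_", 1:6) %in% names(participant))) {
      as.numeric(participant[1, paste0("phase_", 1:6)])
    } else {
      stats::runif(6, 0, 2 * pi)
    }
    z_dyn <- participant$amp_z * g *
      (sin(phase) + 0.4 * sin(2 * phase + th[1]) +
         0.15 * sin(3 * phase + th[2]))
    y_dyn <- participant$amp_y * g *
      (sin(phase + th[3]) + 0.3 * sin(2 * phase + th[4]))
    # mediolateral: stride frequency (alternating legs) + sway noise
    sway <- as.numeric(stats::filter(stats::rnorm(n), 0.95,
                                     method = "recursive"))
    sway <- 0.25 * prof$sway_amplitude_multiplier * sway * sqrt(1 - 0.95^2)
    x_dyn <- participant$amp_x * g *
      (sin(phase / 2 + th[5]) + 0.3 * sin(phase + th[6])) + sway

    active <- cbind(x = x_dyn, y = y_dyn, z = z_dyn + 9.81)

    pad_n <- max(1L, as.integer(round(pad_duration * rate)))
    pad <- function() cbind(x = stats::rnorm(pad_n, 0, 0.02),
                            y = stats::rnorm(pad_n, 0, 0.02),
                            z = 9.81 + stats::rnorm(pad_n, 0, 0.02))
    sig <- rbind(pad(), active, pad())

    # fixed pocket-orientation rotation (participant-level): rotate the
    # full specific-force vector, gravity included
    a <- participant$orientation_jitter
    rot <- rot_x(a) %*% rot_z(0.6 * a)
    sig <- sig %*% t(rot)
    colnames(sig) <- c("x", "y", "z")

    sig <- sig + matrix(stats::rnorm(NROW(sig) * 3, 0, noise_sd), ncol = 3)

    total <- NROW(sig)
    ts_ms <- as.integer(round((seq_len(total) - 1) * 1000 / rate))
    rec <- raw_recording(ts_ms, sig, sensor_kind = "accelerometer",
                         placement = "pocket")
    list(
      recording = rec,
      markers = trial_markers(pad_n + 1L, pad_n + n, total),
      label = condition_profile$label,
      truth = list(active_start = pad_n + 1L, active_stop = pad_n + n,
                   step_times = ph$step_times, f_step = f_step,
                   step_cv = cv)
    )
  })
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

# Active lengths: scaled Beta(1, b) over [min, max] with b chosen so the
# mean matches the configured target (the observed length distribution is
# strongly right-skewed: most traversals near the minimum, a long tail).
draw_active_lengths <- function(k, range, target_mean, seed) {
  with_seed(seed, {
    lo <- range[1]; hi <- range[2]
    if (is.null(target_mean) || hi == lo) {
      u <- stats::runif(k)
    } else {
      mu <- (target_mean - lo) / (hi - lo)
      mu <- min(max(mu, 1e-3), 1 - 1e-3)
      u <- stats::rbeta(k, 1, (1 - mu) / mu)
    }
    as.integer(round(lo + (hi - lo) * u))
  })
}

#' Simulate a full cohort and write it to disk
#'
#' One traversal per participant-condition pair, written as one
#' accelerometer CSV per traversal (plus optional gyroscope files) and a
#' YAML session manifest with participant, condition, placement, file
#' paths and raw marker indices. The output is a pure function of the
#' configuration, including its seed: rerunning with the same config
#' yields byte-identical files.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (the loaded
#'   [load_manifest()] object), `manifest_path`, and `truth` (per-traversal
#'   generator ground truth, keyed `participant.condition`).
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) {
      stop("cannot create output directory: ", dir, call. = FALSE)
    }
  }
  participants <- participant_profiles(
    config$n_participants, derive_seed(config$seed, "participants"))
  profiles <- build_condition_profiles(config$conditions)
  k <- config$n_participants * nrow(profiles)
  lengths <- draw_active_lengths(
    k, config$active_length_range, config$target_mean_length,
    derive_seed(config$seed, "lengths"))

  entries <- vector("list", k)
  truth <- vector("list", k)
  idx <- 0L
  for (p in seq_len(config$n_participants)) {
    for (cidx in seq_len(nrow(profiles))) {
      idx <- idx + 1L
      part <- participants[p, ]
      prof <- profiles[cidx, ]
      tr <- simulate_traversal(
        part, prof, lengths[idx],
        rate = config$sampling_rate, pad_duration = config$pad_duration,
        noise_sd = config$noise_sd, effect_scale = config$effect_scale,
        seed = derive_seed(config$seed, "traversal", idx))
      stem <- paste0(part$participant_id, "_", prof$label)
      accel_file <- paste0(stem, "_accelerometer.csv")
      write_recording(tr$recording, file.path(dir, accel_file))
      files <- list(accelerometer = accel_file)
      if (config$include_gyro) {
        gyro <- synth_gyro(tr$recording,
                           derive_seed(config$seed, "gyro", idx))
        gyro_file <- paste0(stem, "_gyroscope.csv")
        write_recording(gyro, file.path(dir, gyro_file))
        files$gyroscope <- gyro_file
      }
      entries[[idx]] <- list(
        participant_id = part$participant_id,
        condition = prof$label,
        placement = "pocket",
        files = files,
        markers = list(i_start_raw = tr$markers$i_start_raw,
                       i_stop_raw = tr$markers$i_stop_raw)
      )
      truth[[idx]] <- tr$truth
      names(truth)[idx] <- paste(part$participant_id, prof$label, sep = ".")
    }
  }
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(sampling_rate = config$sampling_rate,
                        entries = entries), manifest_path)
  invisible(list(manifest = load_manifest(manifest_path),
                 manifest_path = manifest_path,
                 truth = truth))
}

# Companion gyroscope channels (format fidelity only; never modelled):
# rotational velocity loosely phase-locked to the accelerometer gait.
synth_gyro <- function(accel, seed) {
  with_seed(seed, {
    n <- length(accel$timestamps_ms)
    ch <- matrix(stats::rnorm(n * 3, 0, 0.1), ncol = 3)
    ch[, 1] <- ch[, 1] + 0.3 * scale(accel$channels[, "y"])[, 1]
    colnames(ch) <- c("x", "y", "z")
    raw_recording(accel$timestamps_ms, ch, sensor_kind = "gyroscope",
                  placement = "pocket")
  })
}
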