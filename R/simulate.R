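#' Motion-generator parameters
#'
#' The simulator emulates the clinical constructs the exam scores: with
#' growing severity, repetitive movements lose amplitude and speed, show
#' progressive per-cycle amplitude decrement, and are interrupted by
#' hesitations (frozen frames). Amplitude and frequency are strictly
#' decreasing in severity; decrement and hesitation probability are
#' non-decreasing.
#'
#' @param base_amplitude Movement amplitude at severity 0, in pixels.
#' @param base_frequency Movement frequency at severity 0, in Hz.
#' @param amp_per_severity Fractional amplitude loss per severity level
#'   (default 0.18: severity 4 retains 28% of the base amplitude).
#' @param freq_per_severity Fractional frequency loss per severity level.
#' @param decrement_per_severity Per-cycle fractional amplitude decrement
#'   added per severity level (default 0.02).
#' @param hesitation_per_severity Per-cycle hesitation probability added
#'   per severity level (default 0.05).
#' @param jitter_sd Gaussian keypoint jitter SD, pixels.
#' @param onset_delay_s Static lead-in before the task starts, seconds.
#' @param tail_s Static segment after the task ends, seconds.
#' @param task_duration_s Task duration, seconds.
#' @returns A `motion_params` list.
#' @export
motion_params <- function(base_amplitude = 60, base_frequency = 3,
                          amp_per_severity = 0.18, freq_per_severity = 0.12,
                          decrement_per_severity = 0.02,
                          hesitation_per_severity = 0.05,
                          jitter_sd = 1, onset_delay_s = 2, tail_s = 2,
                          task_duration_s = 10) {
  structure(
    list(
      base_amplitude = base_amplitude, base_frequency = base_frequency,
      amp_per_severity = amp_per_severity,
      freq_per_severity = freq_per_severity,
      decrement_per_severity = decrement_per_severity,
      hesitation_per_severity = hesitation_per_severity,
      jitter_sd = jitter_sd, onset_delay_s = onset_delay_s,
      tail_s = tail_s, task_duration_s = task_duration_s
    ),
    class = "motion_params"
  )
}

severity_profile <- function(severity, params) {
  list(
    amplitude = params$base_amplitude * max(0.1, 1 - params$amp_per_severity * severity),
    frequency = params$base_frequency * max(0.2, 1 - params$freq_per_severity * severity),
    decrement = params$decrement_per_severity * severity,
    hesitation = min(0.9, params$hesitation_per_severity * severity)
  )
}

# quasi-periodic activation in [0, 1]: severity-scaled frequency with
# per-cycle amplitude decrement and random frozen-frame hesitations
oscillation <- function(n_frames, fps, prof) {
  phase <- 0
  hes_left <- 0L
  cycle <- 0L
  amp_mult <- 1
  out <- numeric(n_frames)
  dphase <- 2 * pi * prof$frequency / fps
  for (i in seq_len(n_frames)) {
    out[i] <- amp_mult * 0.5 * (1 - cos(phase))
    if (hes_left > 0L) {
      hes_left <- hes_left - 1L
    } else {
      prev_cycle <- cycle
      phase <- phase + dphase
      cycle <- floor(phase / (2 * pi))
      if (cycle > prev_cycle) {
        # decrement saturates: even severe movements stay visibly attempted
        amp_mult <- max(0.4, amp_mult - prof$decrement)
        if (stats::runif(1) < prof$hesitation) {
          hes_left <- as.integer(round(stats::runif(1, 0.15, 0.4) * fps))
        }
      }
    }
  }
  out
}

base_skeleton <- function() {
  list(
    shoulder_left = c(80, 100), shoulder_right = c(120, 100),
    hip_left = c(85, 200), hip_right = c(115, 200),
    torso = c(100, 150),
    wrist_left = c(60, 160), wrist_right = c(140, 160),
    palm_left = c(55, 170), palm_right = c(145, 170),
    thumb_tip_left = c(50, 175), thumb_tip_right = c(150, 175),
    index_tip_left = c(48, 178), index_tip_right = c(152, 178),
    middle_tip_left = c(47, 180), middle_tip_right = c(153, 180),
    ring_tip_left = c(48, 182), ring_tip_right = c(152, 182),
    pinky_tip_left = c(50, 184), pinky_tip_right = c(150, 184),
    knee_left = c(88, 260), knee_right = c(112, 260),
    ankle_left = c(90, 320), ankle_right = c(110, 320),
    toe_left = c(88, 330), toe_right = c(112, 330)
  )
}

#' Simulate one pose-keypoint clip at a given severity
#'
#' Generates a static lead-in, a quasi-periodic task segment whose
#' amplitude, frequency, per-cycle decrement and hesitation rate depend on
#' the latent severity, and a static tail. Task-relevant joints oscillate;
#' all joints get Gaussian jitter and realistic detector confidences
#' (a small fraction of observations fall below the usual 0.5 threshold).
#' Deterministic given the seed.
#'
#' @param task_id Task identifier (see [task_specs()]).
#' @param severity Latent severity in `[0, 4]` (real-valued allowed).
#' @param params A [motion_params()].
#' @param seed Integer seed.
#' @param side `"left"`/`"right"` active side for bilateral tasks.
#' @param fps Frame rate (default 30).
#' @param meta Extra metadata tags merged into the sequence metadata.
#' @returns A list: `seq` (a [pose_sequence()]) and `window` (the
#'   ground-truth task window tibble).
#' @export
simulate_sequence <- function(task_id, severity, params = motion_params(),
                              seed = 1L, side = "right", fps = 30,
                              meta = list()) {
  if (severity < 0 || severity > 4) {
    rlang::abort("severity must lie in [0, 4]", class = "kinscore_domain_error")
  }
  set.seed(as.integer(seed))
  spec <- task_spec(task_id)
  prof <- severity_profile(severity, params)
  n_pre <- round(params$onset_delay_s * fps)
  n_task <- round(params$task_duration_s * fps)
  n_post <- round(params$tail_s * fps)
  n <- n_pre + n_task + n_post
  act <- c(rep(0, n_pre), oscillation(n_task, fps, prof), rep(0, n_post))

  skel <- base_skeleton()
  joints <- unique(c(
    names(skel)[1:4], # shoulders/hips for normalization
    if (spec$bilateral) {
      c(task_joints(task_id, "left"), task_joints(task_id, "right"))
    } else {
      task_joints(task_id)
    }
  ))
  pos <- purrr::map(joints, function(j) {
    p0 <- skel[[j]]
    matrix(rep(p0, each = n), n, 2L)
  })
  names(pos) <- joints

  amp <- prof$amplitude
  move <- function(j, dx = 0, dy = 0) {
    pos[[j]][, 1L] <<- pos[[j]][, 1L] + dx
    pos[[j]][, 2L] <<- pos[[j]][, 2L] + dy
  }
  sided <- function(stub) paste0(stub, "_", side)
  if (task_id == "finger_tapping") {
    move(sided("index_tip"), dx = amp * act * if (side == "left") -1 else 1)
  } else if (task_id == "hand_movement") {
    dirs <- list(c(0, -1), c(0.5, -0.9), c(0.9, -0.5), c(1, 0))
    tips <- c("index_tip", "middle_tip", "ring_tip", "pinky_tip")
    sgn <- if (side == "left") -1 else 1
    for (i in seq_along(tips)) {
      move(sided(tips[i]),
        dx = sgn * dirs[[i]][1L] * amp * act,
        dy = dirs[[i]][2L] * amp * act
      )
    }
  } else if (task_id %in% c(
    "pronation_supination", "toe_tapping", "leg_agility"
  )) {
    j <- switch(task_id,
      pronation_supination = sided("wrist"),
      toe_tapping = sided("toe"),
      leg_agility = sided("knee")
    )
    move(j, dy = -amp * act) # up in image coordinates
  } else if (task_id == "arising_from_chair") {
    # a single rise: ramp rather than oscillation, severity scales speed
    ramp <- pmin(1, cumsum(act) / max(1, sum(act) * 0.35))
    move("torso", dy = -amp * ramp)
  } else if (task_id == "gait") {
    swing <- amp * act * sin(2 * pi * prof$frequency *
      (seq_len(n) - 1) / fps / 2)
    move("ankle_left", dx = -abs(swing) / 2 - amp * act / 4)
    move("ankle_right", dx = abs(swing) / 2 + amp * act / 4)
  } else if (task_id == "postural_stability") {
    # backward pull then damped recovery of the torso
    rec <- act * exp(-2 * (seq_len(n) - n_pre) / max(1, n_task))
    move("torso", dy = rec * amp)
  }

  jitter <- function(m) m + matrix(stats::rnorm(length(m), sd = params$jitter_sd), nrow(m))
  conf <- function() {
    c0 <- pmin(1, pmax(0, stats::rnorm(n, mean = 0.92, sd = 0.05)))
    low <- stats::runif(n) < 0.02
    c0[low] <- stats::runif(sum(low), 0.05, 0.45)
    c0
  }
  rows <- purrr::map(joints, function(j) {
    m <- jitter(pos[[j]])
    tibble::tibble(
      frame = seq_len(n) - 1L, joint = j,
      x = m[, 1L], y = m[, 2L], confidence = conf()
    )
  })
  meta_all <- c(
    list(task = task_id, side = side, severity = severity),
    if (task_id == "postural_stability") list(t_pull = n_pre) else list(),
    meta
  )
  seq <- pose_sequence(dplyr::bind_rows(rows), fps = fps, meta = meta_all)
  window <- tibble::tibble(
    start_frame = n_pre, end_frame = n_pre + n_task,
    active_side = if (spec$bilateral) side else NA_character_
  )
  list(seq = seq, window = window)
}

#' Cohort-simulation configuration
#'
#' @param n_patients Number of simulated patients.
#' @param tasks Character vector of task ids to simulate.
#' @param severity_distribution Probabilities over severities 0-4 for the
#'   OFF-medication latent severity.
#' @param med_effect Mean ON-minus-OFF latent improvement (<= 0, default
#'   -1: medication lowers latent severity by about one class).
#' @param med_noise_sd SD of the patient-level medication response.
#' @param rater_bias_sd SD of each rater's fixed additive bias.
#' @param rater_noise_base Baseline SD of per-rating noise.
#' @param rater_noise_per_cue Additional per-rating noise SD per
#'   behavioral cue of task complexity.
#' @param motion A [motion_params()].
#' @param fps Frame rate of simulated clips.
#' @param seed Integer master seed.
#' @returns A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 48L,
                          tasks = c("finger_tapping"),
                          severity_distribution = c(0.15, 0.25, 0.25, 0.2, 0.15),
                          med_effect = -1, med_noise_sd = 0.3,
                          rater_bias_sd = 0.2, rater_noise_base = 0.15,
                          rater_noise_per_cue = 0.07,
                          motion = motion_params(), fps = 30, seed = 1L) {
  if (abs(sum(severity_distribution) - 1) > 1e-8 ||
    any(severity_distribution < 0)) {
    rlang::abort("severity_distribution must be probabilities summing to 1",
      class = "kinscore_config_error"
    )
  }
  if (n_patients < 1L) {
    rlang::abort("n_patients must be >= 1", class = "kinscore_config_error")
  }
  if (med_effect > 0) {
    rlang::abort("med_effect must be <= 0 (medication does not worsen severity on average)",
      class = "kinscore_config_error"
    )
  }
  structure(
    list(
      n_patients = as.integer(n_patients), tasks = tasks,
      severity_distribution = severity_distribution,
      med_effect = med_effect, med_noise_sd = med_noise_sd,
      rater_bias_sd = rater_bias_sd, rater_noise_base = rater_noise_base,
      rater_noise_per_cue = rater_noise_per_cue,
      motion = motion, fps = fps, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a 3-rater panel for a clip
#'
#' Each rater's score is `clamp(round(severity + bias_r + noise), 0, 4)`
#' where `bias_r` is the rater's fixed additive bias and the noise SD
#' grows linearly with task complexity — encoding the observation that
#' rater dispersion increases with the number of behavioral cues a task
#' requires.
#'
#' @param true_severity Latent severity in `[0, 4]`.
#' @param complexity Task complexity (behavioral-cue count).
#' @param rater_biases Numeric vector of per-rater biases (length =
#'   number of raters, default 3 raters).
#' @param noise_base,noise_per_cue Noise-SD intercept and slope in
#'   complexity.
#' @param seed Integer seed (optional; when `NULL` the current RNG stream
#'   is used, so cohort simulation stays reproducible from its master
#'   seed).
#' @param num_classes Number of ordinal levels.
#' @returns Integer vector of rater scores.
#' @export
simulate_panel <- function(true_severity, complexity,
                           rater_biases = c(0, 0, 0),
                           noise_base = 0.15, noise_per_cue = 0.07,
                           seed = NULL, num_classes = 5L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd_eps <- noise_base + noise_per_cue * complexity
  raw <- true_severity + rater_biases + stats::rnorm(length(rater_biases), 0, sd_eps)
  as.integer(pmin(num_classes - 1L, pmax(0L, round(raw))))
}

#' Simulate a patient cohort with panels and medication states
#'
#' Draws a latent OFF severity per patient from the configured severity
#' distribution; the ON severity is `max(0, OFF + med_effect + noise)`.
#' Every patient performs every configured task in both states (bilateral
#' tasks on both sides), and every clip receives a 3-rater panel whose
#' noise grows with the task's complexity. Clip sequences are not
#' materialized here; each manifest row carries a `sim_seed` from which
#' [simulate_sequence()] reproduces the clip bit-identically.
#'
#' @param config A [cohort_config()].
#' @returns A list: `manifest` (tibble: `clip_id`, `patient_id`,
#'   `task_id`, `side`, `med_state`, `severity`, `sim_seed`) and
#'   `ratings` (tibble: `clip_id`, `rater`, `score`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  specs <- task_specs()
  rater_biases <- stats::rnorm(3L, 0, config$rater_bias_sd)
  off_sev <- sample(0:4, config$n_patients,
    replace = TRUE,
    prob = config$severity_distribution
  )
  on_sev <- pmax(0, pmin(
    4,
    off_sev + config$med_effect + stats::rnorm(config$n_patients, 0, config$med_noise_sd)
  ))

  rows <- list()
  idx <- 0L
  for (p in seq_len(config$n_patients)) {
    for (task in config$tasks) {
      spec <- specs[specs$task_id == task, ]
      sides <- if (spec$bilateral) c("left", "right") else NA_character_
      for (side in sides) {
        for (state in c("off", "on")) {
          idx <- idx + 1L
          sev <- if (state == "off") off_sev[p] else on_sev[p]
          rows[[idx]] <- tibble::tibble(
            clip_id = sprintf("p%03d_%s_%s_%s", p, task, side %||% "na", state),
            patient_id = sprintf("p%03d", p),
            task_id = task, side = side, med_state = state,
            severity = sev,
            sim_seed = (config$seed %% 100000L) * 20000L + idx
          )
        }
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  ratings <- purrr::map2(manifest$clip_id, seq_len(nrow(manifest)), function(id, i) {
    row <- manifest[i, ]
    complexity <- specs$complexity[specs$task_id == row$task_id]
    scores <- simulate_panel(
      row$severity, complexity,
      rater_biases = rater_biases,
      noise_base = config$rater_noise_base,
      noise_per_cue = config$rater_noise_per_cue
    )
    tibble::tibble(clip_id = id, rater = paste0("r", seq_along(scores)), score = scores)
  }) |> dplyr::bind_rows()
  list(manifest = manifest, ratings = ratings, rater_biases = rater_biases)
}

#' Materialize the pose sequence for one manifest row
#'
#' @param row A one-row slice of a cohort manifest.
#' @param config The [cohort_config()] that produced the manifest.
#' @returns A list: `seq`, `window` (see [simulate_sequence()]).
#' @export
materialize_clip <- function(row, config) {
  simulate_sequence(
    row$task_id, row$severity,
    params = config$motion, seed = row$sim_seed,
    side = if (is.na(row$side)) "right" else row$side,
    fps = config$fps,
    meta = list(
      patient_id = row$patient_id, med_state = row$med_state,
      clip_id = row$clip_id
    )
  )
}
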