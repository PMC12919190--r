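#' Onset-detection thresholds
#'
#' Thresholds controlling task-window detection: a joint must exceed both a
#' speed and a displacement-from-baseline threshold for onset, and the task
#' ends when speed drops back below `baseline_fraction` times the velocity
#' threshold for a sustained hold. Units are those of the (normalized)
#' pose coordinates per second.
#'
#' @param velocity Velocity threshold (> 0, normalized units/s).
#' @param displacement Displacement threshold (> 0, normalized units).
#' @param baseline_fraction Fraction of `velocity` defining "returned to
#'   baseline" (in `(0, 1]`, default 0.5).
#' @returns An `onset_thresholds` list.
#' @export
onset_thresholds <- function(velocity, displacement, baseline_fraction = 0.5) {
  if (!is.numeric(velocity) || velocity <= 0 ||
    !is.numeric(displacement) || displacement <= 0 ||
    !is.numeric(baseline_fraction) || baseline_fraction <= 0 ||
    baseline_fraction > 1) {
    rlang::abort("thresholds must be positive; baseline_fraction in (0, 1]",
      class = "kinscore_config_error"
    )
  }
  structure(
    list(
      velocity = velocity, displacement = displacement,
      baseline_fraction = baseline_fraction
    ),
    class = "onset_thresholds"
  )
}

# frames x joints matrices of x and y for the given joints, frame-sorted
joint_matrices <- function(seq, joints) {
  frames <- sort(unique(seq$frame))
  xm <- matrix(NA_real_, nrow = length(frames), ncol = length(joints))
  ym <- xm
  for (j in seq_along(joints)) {
    sub <- seq[seq$joint == joints[j], ]
    idx <- match(sub$frame, frames)
    xm[idx, j] <- sub$x
    ym[idx, j] <- sub$y
  }
  list(x = xm, y = ym, frames = frames)
}

# per-frame speed (units/s) per joint; frame 0 has speed 0
joint_speeds <- function(mats, fps) {
  dx <- apply(mats$x, 2, function(v) c(0, diff(v)))
  dy <- apply(mats$y, 2, function(v) c(0, diff(v)))
  sqrt(dx^2 + dy^2) * fps
}

# per-frame displacement from each joint's early-sequence baseline position
joint_displacements <- function(mats, baseline_frames = 10L) {
  n <- nrow(mats$x)
  k <- min(baseline_frames, n)
  bx <- apply(mats$x[seq_len(k), , drop = FALSE], 2, stats::median, na.rm = TRUE)
  by <- apply(mats$y[seq_len(k), , drop = FALSE], 2, stats::median, na.rm = TRUE)
  sqrt(sweep(mats$x, 2, bx)^2 + sweep(mats$y, 2, by)^2)
}

row_max <- function(m) {
  out <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  out[!is.finite(out)] <- 0
  out
}

task_detection_joints <- function(seq, task_id) {
  spec <- task_spec(task_id)
  joints <- if (spec$bilateral) {
    c(task_joints(task_id, "left"), task_joints(task_id, "right"))
  } else {
    task_joints(task_id)
  }
  present <- intersect(joints, pose_joints(seq))
  if (length(present) == 0L) {
    rlang::abort(
      paste0("none of the joints required by '", task_id, "' are present"),
      class = "kinscore_missing_joint_error"
    )
  }
  present
}

#' Detect the task-execution window in a pose sequence
#'
#' Onset is the first frame where the task joints' speed and displacement
#' from their initial baseline both exceed their thresholds; the window
#' ends at the first subsequent frame where speed stays below
#' `baseline_fraction * velocity` for `hold` consecutive frames. If speed
#' never returns to baseline the window runs to the last frame. Windows
#' are half-open `[start, end)` in 0-based frame indices.
#'
#' @param seq A `kin_pose`, typically cleaned with [clean_pose()].
#' @param task_id Task identifier (see [task_specs()]).
#' @param thresholds An [onset_thresholds()] object.
#' @param hold Frames speed must stay below baseline to end the task.
#' @param baseline_frames Frames defining the initial position baseline.
#' @returns A one-row tibble: `start_frame`, `end_frame`, `active_side`
#'   (`NA` until [detect_active_side()] is applied for bilateral tasks).
#' @export
detect_window <- function(seq, task_id, thresholds, hold = 15L,
                          baseline_frames = 10L) {
  stopifnot(inherits(thresholds, "onset_thresholds"))
  joints <- task_detection_joints(seq, task_id)
  mats <- joint_matrices(seq, joints)
  fps <- pose_fps(seq)
  speed <- row_max(joint_speeds(mats, fps))
  disp <- row_max(joint_displacements(mats, baseline_frames))
  n <- length(speed)

  active <- speed > thresholds$velocity & disp > thresholds$displacement
  if (!any(active)) {
    rlang::abort(
      "no frame exceeds the onset thresholds; no task activity detected",
      class = "kinscore_no_activity_error"
    )
  }
  start <- which(active)[1L] - 1L # 0-based

  # the task ends when both speed and displacement return to baseline
  low <- speed < thresholds$baseline_fraction * thresholds$velocity &
    disp < thresholds$baseline_fraction * thresholds$displacement
  end <- n # default: motion to the end
  if (start + 1L < n) {
    run <- 0L
    for (i in seq(start + 2L, n)) { # 1-based indices after onset
      run <- if (low[i]) run + 1L else 0L
      if (run >= hold) {
        end <- i - hold # 0-based first frame of the sustained-low run
        break
      }
    }
  }
  end <- max(end, start + 1L)
  tibble::tibble(
    start_frame = start, end_frame = as.integer(end),
    active_side = NA_character_
  )
}

#' Determine the active limb for a bilateral task
#'
#' Within the detected window, the side whose task joints travel the
#' greater total path length is the active side. Exact ties break to the
#' left with a warning; if one side's joints are entirely missing, the
#' present side is returned with a warning.
#'
#' @param seq A `kin_pose` containing both sides' task joints.
#' @param task_id A bilateral task identifier.
#' @param window A window tibble/list with `start_frame`, `end_frame`.
#' @returns `"left"` or `"right"`.
#' @export
detect_active_side <- function(seq, task_id, window) {
  spec <- task_spec(task_id)
  if (!spec$bilateral) {
    rlang::abort(paste0("task '", task_id, "' is not bilateral"),
      class = "kinscore_config_error"
    )
  }
  path_len <- function(side) {
    joints <- intersect(task_joints(task_id, side), pose_joints(seq))
    if (length(joints) == 0L) {
      return(NA_real_)
    }
    sub <- seq[seq$frame >= window$start_frame & seq$frame < window$end_frame, ]
    mats <- joint_matrices(sub, joints)
    steps <- joint_speeds(mats, 1) # path increments per frame
    total <- sum(steps, na.rm = TRUE)
    if (all(is.na(mats$x))) NA_real_ else total
  }
  left <- path_len("left")
  right <- path_len("right")
  if (is.na(left) && is.na(right)) {
    rlang::abort("both sides' joints are missing in the window",
      class = "kinscore_missing_joint_error"
    )
  }
  if (is.na(left)) {
    rlang::warn("left-side joints missing; falling back to right")
    return("right")
  }
  if (is.na(right)) {
    rlang::warn("right-side joints missing; falling back to left")
    return("left")
  }
  if (left == right) {
    rlang::warn("exact tie in side activity; defaulting to left")
    return("left")
  }
  if (right > left) "right" else "left"
}

#' Calibrate onset thresholds from labeled training clips
#'
#' For each labeled clip the peak within-window joint speed and
#' displacement are measured; the thresholds are a low percentile of those
#' peaks across clips, so that genuine task motion comfortably exceeds
#' them. Deterministic given its inputs.
#'
#' @param clips A list of `list(seq = <kin_pose>, window = <window>)`
#'   training examples (at least 3).
#' @param task_id Task identifier.
#' @param probs Percentile of within-window peak statistics used as the
#'   threshold (default 0.2, the 20th percentile).
#' @param safety Derating factor applied to the percentile (default 0.5).
#'   A raw percentile of peak statistics sits above that same share of
#'   clips' peaks by construction; derating keeps onset reachable for
#'   below-percentile movers while still rejecting resting jitter. Set to
#'   1 for the undecorated percentile.
#' @param baseline_fraction Passed through to [onset_thresholds()].
#' @returns An [onset_thresholds()] object.
#' @export
calibrate_thresholds <- function(clips, task_id, probs = 0.2, safety = 0.5,
                                 baseline_fraction = 0.5) {
  if (length(clips) < 3L) {
    rlang::abort("threshold calibration requires at least 3 labeled clips",
      class = "kinscore_insufficient_data_error"
    )
  }
  stats_per_clip <- purrr::map(clips, function(cl) {
    seq <- cl$seq
    window <- cl$window
    joints <- task_detection_joints(seq, task_id)
    sub <- seq[seq$frame >= window$start_frame & seq$frame < window$end_frame, ]
    mats <- joint_matrices(sub, joints)
    speed <- row_max(joint_speeds(mats, pose_fps(seq)))
    disp <- row_max(joint_displacements(mats))
    c(peak_speed = max(speed), peak_disp = max(disp))
  })
  peaks <- do.call(rbind, stats_per_clip)
  vel <- stats::quantile(peaks[, "peak_speed"], probs, names = FALSE)
  dsp <- stats::quantile(peaks[, "peak_disp"], probs, names = FALSE)
  onset_thresholds(
    velocity = safety * vel, displacement = safety * dsp,
    baseline_fraction = baseline_fraction
  )
}
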