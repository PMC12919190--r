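#' Construct a kinematic signal
#'
#' A signal is the 1D task-specific kinematic time series distilled from a
#' pose sequence: thumb-index distance for finger tapping, vertical knee
#' displacement for leg agility, and so on. Values are finite; frames with
#' unresolvable (long-gap) keypoints are excluded.
#'
#' @param values Numeric vector (length >= 2, finite after NA removal).
#' @param fps Sampling rate of the values. For per-frame signals this is
#'   the video frame rate; for the per-step gait signal it is the estimated
#'   step rate in steps/second.
#' @param t0_frame 0-based index of the signal start in the source clip.
#' @returns A `kin_signal` object.
#' @export
kin_signal <- function(values, fps, t0_frame = 0L) {
  values <- as.numeric(values[is.finite(values)])
  if (length(values) < 2L) {
    rlang::abort("a signal needs at least 2 finite values",
      class = "kinscore_degenerate_error"
    )
  }
  if (!is.numeric(fps) || fps <= 0) {
    rlang::abort("fps must be positive", class = "kinscore_config_error")
  }
  structure(
    list(values = values, fps = fps, t0_frame = as.integer(t0_frame)),
    class = "kin_signal"
  )
}

#' @export
print.kin_signal <- function(x, ...) {
  cat(sprintf(
    "<kinematic signal: %d samples at %.3g Hz (t0 = frame %d)>\n",
    length(x$values), x$fps, x$t0_frame
  ))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.kin_signal <- function(x, ...) {
  tibble::tibble(
    t = (seq_along(x$values) - 1) / x$fps,
    value = x$values
  )
}

window_slice <- function(seq, window) {
  seq[seq$frame >= window$start_frame & seq$frame < window$end_frame, ]
}

joint_series <- function(sub, joint, what = c("x", "y")) {
  rows <- sub[sub$joint == joint, ]
  if (nrow(rows) == 0L || all(is.na(rows$x))) {
    rlang::abort(paste0("joint '", joint, "' is missing in the task window"),
      class = "kinscore_missing_joint_error"
    )
  }
  rows <- rows[order(rows$frame), ]
  rows[, what, drop = FALSE]
}

first_finite <- function(v) v[which(is.finite(v))[1L]]

#' Compute the task-specific kinematic signal
#'
#' Dispatches on the task: finger tapping uses the Euclidean thumb-index
#' distance per frame; hand movement the mean fingertip-to-palm distance;
#' pronation-supination, toe tapping, leg agility and arising from chair
#' use the vertical displacement of the wrist/toe/knee/torso relative to
#' its value at the window start; gait yields a per-step sequence of
#' inter-ankle-distance peaks baseline-subtracted by the first step; and
#' postural stability the torso vertical displacement relative to the pull
#' instant.
#'
#' @param seq A cleaned `kin_pose`.
#' @param task_id Task identifier (see [task_specs()]).
#' @param window A window tibble/list with `start_frame`, `end_frame`.
#' @param side `"left"`/`"right"` for bilateral tasks.
#' @param t_pull 0-based frame of the backward perturbation for postural
#'   stability; defaults to the clip metadata `t_pull` or, failing that,
#'   the frame of peak torso speed within the window.
#' @returns A [kin_signal()].
#' @export
compute_signal <- function(seq, task_id, window, side = NA_character_,
                           t_pull = NULL) {
  spec <- task_spec(task_id)
  sub <- window_slice(seq, window)
  fps <- pose_fps(seq)
  joints <- if (spec$bilateral) task_joints(task_id, side) else task_joints(task_id)

  values <- switch(task_id,
    finger_tapping = {
      a <- joint_series(sub, joints[1L])
      b <- joint_series(sub, joints[2L])
      sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    },
    hand_movement = {
      palm <- joint_series(sub, joints[length(joints)])
      tips <- intersect(joints[-length(joints)], unique(sub$joint))
      series <- purrr::compact(purrr::map(tips, function(j) {
        tryCatch(joint_series(sub, j), kinscore_missing_joint_error = function(e) NULL)
      }))
      if (length(series) == 0L) {
        rlang::abort("no fingertip joints present in the task window",
          class = "kinscore_missing_joint_error"
        )
      }
      d <- sapply(series, function(p) {
        sqrt((p$x - palm$x)^2 + (p$y - palm$y)^2)
      })
      rowMeans(as.matrix(d))
    },
    pronation_supination = vertical_displacement(sub, joints[1L]),
    toe_tapping = vertical_displacement(sub, joints[1L]),
    leg_agility = vertical_displacement(sub, joints[1L]),
    arising_from_chair = vertical_displacement(sub, joints[1L]),
    gait = {
      return(gait_step_signal(sub, joints, fps, window))
    },
    postural_stability = {
      y <- joint_series(sub, joints[1L], c("x", "y"))
      tp <- resolve_t_pull(seq, sub, joints[1L], window, t_pull)
      ref_rows <- sub[sub$joint == joints[1L], ]
      ref_rows <- ref_rows[order(ref_rows$frame), ]
      ref <- ref_rows$y[match(tp, ref_rows$frame)]
      if (is.na(ref)) ref <- first_finite(ref_rows$y)
      y$y - ref
    },
    rlang::abort(paste0("unknown task '", task_id, "'"),
      class = "kinscore_config_error"
    )
  )
  kin_signal(values, fps = fps, t0_frame = window$start_frame)
}

vertical_displacement <- function(sub, joint) {
  y <- joint_series(sub, joint, "y")$y
  y - first_finite(y)
}

resolve_t_pull <- function(seq, sub, joint, window, t_pull) {
  if (!is.null(t_pull)) {
    return(as.integer(t_pull))
  }
  meta <- pose_meta(seq)
  if (!is.null(meta$t_pull)) {
    return(as.integer(meta$t_pull))
  }
  rows <- sub[sub$joint == joint, ]
  rows <- rows[order(rows$frame), ]
  sp <- c(0, sqrt(diff(rows$x)^2 + diff(rows$y)^2))
  rows$frame[which.max(ifelse(is.na(sp), -Inf, sp))]
}

gait_step_signal <- function(sub, joints, fps, window) {
  a <- joint_series(sub, joints[1L])
  b <- joint_series(sub, joints[2L])
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  d <- d[is.finite(d)]
  if (length(d) < 4L) {
    rlang::abort("too few frames to detect gait steps",
      class = "kinscore_insufficient_cycles_error"
    )
  }
  # step peaks of the inter-ankle distance
  cyc <- tryCatch(
    find_cycles(kin_signal(d, fps = fps, t0_frame = window$start_frame)),
    kinscore_insufficient_cycles_error = function(e) NULL
  )
  if (is.null(cyc) || length(cyc$peaks) < 2L) {
    rlang::abort("fewer than 2 steps detected in the gait clip",
      class = "kinscore_insufficient_cycles_error"
    )
  }
  steps <- d[cyc$peaks]
  step_rate <- (length(cyc$peaks) - 1L) /
    ((cyc$peaks[length(cyc$peaks)] - cyc$peaks[1L]) / fps)
  kin_signal(steps - steps[1L], fps = step_rate, t0_frame = window$start_frame)
}
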