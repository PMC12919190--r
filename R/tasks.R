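#' Task specifications for the standardized motor exam
#'
#' Each task in the motor exam (MDS-UPDRS Part III style) is scored from a
#' small set of joints, may be performed bilaterally, and carries a
#' *complexity*: the number of behavioral cues a rater must monitor
#' simultaneously to assign a score. Arising from chair requires two cues
#' (use of arms, rising speed) and gait seven (stride amplitude, stride
#' speed, foot lift, heel strike, turning, arm swing, assistive device);
#' the five repetitive-limb items are rated on speed, amplitude,
#' hesitations, halts and amplitude decrement (five cues), and postural
#' stability on steps to recover, retropulsion and falling (three cues).
#'
#' @returns A tibble with one row per task: `task_id`, `bilateral`,
#'   `complexity`, and a list-column `joints` of joint-name templates where
#'   `{side}` is substituted with `"left"`/`"right"` for bilateral tasks.
#' @examples
#' task_specs()
#' @export
task_specs <- function() {
  tibble::tibble(
    task_id = c(
      "finger_tapping", "hand_movement", "pronation_supination",
      "toe_tapping", "leg_agility", "arising_from_chair", "gait",
      "postural_stability"
    ),
    bilateral = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    complexity = c(5L, 5L, 5L, 5L, 5L, 2L, 7L, 3L),
    joints = list(
      c("thumb_tip_{side}", "index_tip_{side}"),
      c(
        "index_tip_{side}", "middle_tip_{side}", "ring_tip_{side}",
        "pinky_tip_{side}", "palm_{side}"
      ),
      c("wrist_{side}"),
      c("toe_{side}"),
      c("knee_{side}"),
      c("torso"),
      c("ankle_left", "ankle_right"),
      c("torso")
    )
  )
}

#' Look up a single task specification
#'
#' @param task_id Task identifier, one of the eight `task_specs()` rows.
#' @returns A one-row tibble (see [task_specs()]).
#' @export
task_spec <- function(task_id) {
  specs <- task_specs()
  spec <- specs[specs$task_id == task_id, ]
  if (nrow(spec) != 1L) {
    rlang::abort(
      paste0(
        "unknown task '", task_id, "'; expected one of: ",
        paste(specs$task_id, collapse = ", ")
      ),
      class = "kinscore_config_error"
    )
  }
  spec
}

#' Joint names required by a task on a given side
#'
#' @param task_id Task identifier.
#' @param side `"left"`, `"right"`, or `NA` for non-lateralized tasks.
#' @returns Character vector of concrete joint names.
#' @export
task_joints <- function(task_id, side = NA_character_) {
  spec <- task_spec(task_id)
  templates <- spec$joints[[1L]]
  if (spec$bilateral) {
    if (is.na(side) || !side %in% c("left", "right")) {
      rlang::abort(
        paste0("task '", task_id, "' is bilateral; side must be 'left' or 'right'"),
        class = "kinscore_config_error"
      )
    }
    gsub("{side}", side, templates, fixed = TRUE)
  } else {
    templates
  }
}
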