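#' Plot a pose sequence
#'
#' Joint trajectories over time, one facet per coordinate.
#'
#' @param object A `kin_pose`.
#' @param joints Optional subset of joints to show.
#' @param ... Unused.
#' @returns A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kin_pose <- function(object, joints = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(joints)) df <- df[df$joint %in% joints, ]
  df <- tidyr::pivot_longer(df, c("x", "y"),
    names_to = "coord", values_to = "value"
  )
  df$t <- df$frame / pose_fps(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value, colour = .data$joint)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~coord, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "time (s)", y = "coordinate") +
    ggplot2::theme_minimal()
}

#' Plot a kinematic signal
#'
#' @param object A `kin_signal`.
#' @param cycles Optional result of [find_cycles()] to overlay peaks and
#'   troughs.
#' @param ... Unused.
#' @returns A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kin_signal <- function(object, cycles = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "signal (normalized units)") +
    ggplot2::theme_minimal()
  if (!is.null(cycles)) {
    pk <- df[cycles$peaks, ]
    tr <- df[cycles$troughs, ]
    p <- p +
      ggplot2::geom_point(data = pk, colour = "#D55E00") +
      ggplot2::geom_point(data = tr, colour = "#0072B2")
  }
  p
}

#' Plot training history of a fitted model
#'
#' @param object A trained `kin_model`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kin_model <- function(object, ...) {
  stopifnot(!is.null(object$history))
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' Stacked agreement decomposition per task
#'
#' @param agreement A tibble as produced by the `agreement` element of
#'   [run_experiment()] or by grouping [agreement_percentages()] by task.
#' @returns A ggplot object.
#' @export
plot_agreement <- function(agreement) {
  long <- tidyr::pivot_longer(
    agreement[, c("task_id", "complete_pct", "majority_pct", "none_pct")],
    -"task_id",
    names_to = "category", values_to = "pct"
  )
  long$category <- factor(long$category,
    levels = c("none_pct", "majority_pct", "complete_pct"),
    labels = c("none", "majority", "complete")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$task_id, y = .data$pct, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(none = "#999999", majority = "#56B4E9", complete = "#009E73")
    ) +
    ggplot2::labs(x = NULL, y = "% of panels", fill = "agreement") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' OFF-to-ON medication contrast per patient
#'
#' Segments from each patient's OFF composite to the ON composite;
#' downward segments indicate predicted improvement on medication.
#'
#' @param contrast The result of [medication_contrast()].
#' @returns A ggplot object.
#' @export
plot_medication_contrast <- function(contrast) {
  df <- contrast$deltas
  df$patient <- factor(df$patient_id, levels = df$patient_id[order(df$off)])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$patient, xend = .data$patient,
        y = .data$off, yend = .data$on
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")), colour = "#0072B2"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$patient, y = .data$off),
      colour = "#D55E00"
    ) +
    ggplot2::labs(x = "patient (ordered by OFF score)", y = "composite severity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
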