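#' Summarize a rater panel
#'
#' The target the ordinal model learns is the panel mean, and the
#' distribution-aware accuracy band is the panel's sample standard
#' deviation (n-1 denominator): a panel of scores 1, 2, 2 has mean 1.67
#' and SD 0.58.
#'
#' @param scores Integer ordinal scores from at least two raters.
#' @param num_classes Number of ordinal levels (scores must lie in
#'   `[0, num_classes - 1]`).
#' @returns A one-row tibble: `mean`, `sd`, `n_raters`.
#' @export
summarize_panel <- function(scores, num_classes = 5L) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) {
    rlang::abort("a rater panel needs at least 2 scores",
      class = "kinscore_insufficient_raters_error"
    )
  }
  if (anyNA(scores) || any(scores != round(scores)) ||
    any(scores < 0 | scores > num_classes - 1L)) {
    rlang::abort(
      sprintf("scores must be integers in [0, %d]", num_classes - 1L),
      class = "kinscore_domain_error"
    )
  }
  tibble::tibble(
    mean = mean(scores), sd = stats::sd(scores),
    n_raters = length(scores)
  )
}

#' Per-clip rating summaries from a tidy ratings table
#'
#' @param ratings A tibble with one row per rating and columns `clip_id`,
#'   `score` (a `rater` column, if present, is ignored for the summary).
#' @param num_classes Number of ordinal levels.
#' @returns A tibble with one row per clip: `clip_id`, `mean`, `sd`,
#'   `n_raters`.
#' @export
rating_summaries <- function(ratings, num_classes = 5L) {
  stopifnot(all(c("clip_id", "score") %in% names(ratings)))
  ratings |>
    dplyr::group_by(.data$clip_id) |>
    dplyr::reframe(summarize_panel(.data$score, num_classes))
}

#' Classify a panel's level of agreement
#'
#' For three raters: `complete` when all agree, `majority` when exactly
#' two agree, `none` when all differ. For general panel sizes, `complete`
#' means all equal and `majority` means some score is held by a strict
#' majority of raters.
#'
#' @param scores Integer ordinal scores (>= 2 raters).
#' @returns `"complete"`, `"majority"`, or `"none"`.
#' @export
agreement_category <- function(scores) {
  if (length(scores) < 2L) {
    rlang::abort("a rater panel needs at least 2 scores",
      class = "kinscore_insufficient_raters_error"
    )
  }
  counts <- table(scores)
  if (length(counts) == 1L) {
    return("complete")
  }
  if (max(counts) > length(scores) / 2) {
    return("majority")
  }
  "none"
}

#' Decompose agreement across a set of rater panels
#'
#' Reports the percentage of panels in complete agreement, in
#' majority-only agreement, and with no agreement (disjoint categories
#' summing to 100), plus the cumulative majority-or-better percentage.
#'
#' @param panels Either a list of score vectors, or a tidy ratings tibble
#'   with `clip_id` and `score` columns.
#' @returns A one-row tibble: `complete_pct`, `majority_pct`, `none_pct`
#'   (disjoint, sum to 100), `majority_or_better_pct` (panels with at
#'   least a majority), `rating_weighted_pct` (agreed ratings divided by
#'   total ratings, the convention under which a 3-rater majority panel
#'   contributes 2 of 3), and `n_panels`.
#' @export
agreement_percentages <- function(panels) {
  if (is.data.frame(panels)) {
    panels <- split(panels$score, panels$clip_id)
  }
  if (length(panels) == 0L) {
    rlang::abort("no panels supplied", class = "kinscore_empty_input_error")
  }
  cats <- vapply(panels, agreement_category, character(1L))
  n <- length(cats)
  complete <- sum(cats == "complete") / n * 100
  majority <- sum(cats == "majority") / n * 100
  none <- sum(cats == "none") / n * 100
  tibble::tibble(
    complete_pct = complete, majority_pct = majority, none_pct = none,
    majority_or_better_pct = complete + majority,
    # agreed ratings / total ratings: a majority panel of 3 contributes 2
    rating_weighted_pct = complete + 2 / 3 * majority,
    n_panels = n
  )
}

#' Regress an agreement statistic on task complexity
#'
#' Ordinary least squares of an agreement quantity (e.g. complete
#' agreement percentage, or mean panel SD) on the task-complexity cue
#' count, with the two-sided p-value for the slope. Complex tasks are
#' expected to show lower agreement (negative slope) and larger panel SD
#' (positive slope).
#'
#' @param points A data frame with columns `complexity` and `y` (at least
#'   3 points over at least 2 distinct complexities).
#' @returns A `kin_regression` object with `slope`, `intercept`,
#'   `r_squared`, `p_value` and the underlying `lm` fit; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
complexity_regression <- function(points) {
  stopifnot(all(c("complexity", "y") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("complexity", "y")]), ]
  if (nrow(points) < 3L || length(unique(points$complexity)) < 2L) {
    rlang::abort(
      "regression needs >= 3 points over >= 2 distinct complexities",
      class = "kinscore_insufficient_data_error"
    )
  }
  fit <- stats::lm(y ~ complexity, data = points)
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  structure(
    list(
      slope = coefs["complexity", "Estimate"],
      intercept = coefs["(Intercept)", "Estimate"],
      r_squared = sm$r.squared,
      p_value = coefs["complexity", "Pr(>|t|)"],
      fit = fit, n = nrow(points)
    ),
    class = "kin_regression"
  )
}

#' @export
print.kin_regression <- function(x, ...) {
  cat(sprintf(
    "<complexity regression: slope %.3g, r^2 %.3g, p %.3g (n = %d)>\n",
    x$slope, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Accuracy within one class of the panel mean
#'
#' A prediction is correct when its predicted mean severity lies within
#' one class of the average of the ratings: `|mu_hat - t| <= 1`, applied
#' to the continuous predicted mean.
#'
#' @param mu_hat Predicted mean severities.
#' @param target_mean Panel mean ratings, same length.
#' @returns Fraction correct in `[0, 1]`.
#' @export
within_pm1_accuracy <- function(mu_hat, target_mean) {
  check_matched(mu_hat, target_mean)
  mean(abs(mu_hat - target_mean) <= 1)
}

#' Distribution-aware accuracy
#'
#' A prediction is correct when the predicted mean lies within `width_k`
#' empirical standard deviations of the rater panel:
#' `|mu_hat - t| <= width_k * max(sd, sigma_floor)`. The band thus
#' tightens for high-consensus panels and widens where raters disagree.
#' A unanimous panel has SD 0, so a floor (default half a class) keeps
#' the criterion usable; `sigma_floor = 0` restores the strict point
#' criterion. With `strict_paper = TRUE` the panel mean and SD are first
#' rounded to 2 decimals, reproducing printed-table bands such as
#' `[1.09, 2.25]` for a 1, 2, 2 panel.
#'
#' @param mu_hat Predicted mean severities.
#' @param target_mean Panel mean ratings.
#' @param target_sd Panel sample standard deviations.
#' @param width_k Band half-width in panel SDs (1 or 1.5, typically).
#' @param sigma_floor Lower bound on the SD used in the band.
#' @param strict_paper Round mean and SD to 2 decimals before banding.
#' @returns Fraction correct in `[0, 1]`.
#' @export
distribution_aware_accuracy <- function(mu_hat, target_mean, target_sd,
                                        width_k = 1, sigma_floor = 0.5,
                                        strict_paper = FALSE) {
  check_matched(mu_hat, target_mean)
  check_matched(mu_hat, target_sd)
  if (sigma_floor < 0) {
    rlang::abort("sigma_floor must be >= 0", class = "kinscore_domain_error")
  }
  if (strict_paper) {
    target_mean <- round(target_mean, 2L)
    target_sd <- round(target_sd, 2L)
  }
  band <- width_k * pmax(target_sd, sigma_floor)
  # epsilon keeps exact band endpoints (e.g. 2.25 for the 1,2,2 panel) inside
  mean(abs(mu_hat - target_mean) <= band + 1e-9)
}

check_matched <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("prediction and target vectors differ in length",
      class = "kinscore_input_error"
    )
  }
  if (length(a) == 0L) {
    rlang::abort("no predictions to score", class = "kinscore_empty_input_error")
  }
  invisible(TRUE)
}

#' Composite motor score from per-task predictions
#'
#' The total exam severity is the sum of predicted mean severities over
#' all present task/side entries, approximating the composite motor score;
#' absent tasks are simply excluded.
#'
#' @param predictions A tibble with a `mu_hat` column (one row per
#'   task/side prediction) or a numeric vector of predicted means.
#' @returns The composite score (a single number).
#' @export
composite_score <- function(predictions) {
  mu <- if (is.data.frame(predictions)) predictions$mu_hat else predictions
  if (length(mu) == 0L) {
    rlang::abort("no task predictions to aggregate",
      class = "kinscore_empty_input_error"
    )
  }
  sum(mu)
}

#' Per-patient composite scores from a prediction table
#'
#' @param predictions A tibble with columns `patient_id`, `med_state`, and
#'   `mu_hat` (one row per task/side prediction).
#' @returns A tibble `patient_id`, `med_state`, `composite`, `n_tasks`.
#' @export
composite_scores <- function(predictions) {
  stopifnot(all(c("patient_id", "med_state", "mu_hat") %in% names(predictions)))
  predictions |>
    dplyr::group_by(.data$patient_id, .data$med_state) |>
    dplyr::summarise(
      composite = sum(.data$mu_hat), n_tasks = dplyr::n(),
      .groups = "drop"
    )
}

#' Medication-state contrast of composite scores
#'
#' Computes the per-patient ON-minus-OFF composite delta and the fraction
#' of patients whose predicted severity improves (delta < 0) on
#' medication.
#'
#' @param composites A tibble with columns `patient_id`, `med_state`
#'   (values `"off"`/`"on"`), `composite` — e.g. from
#'   [composite_scores()]. Every patient must appear in both states.
#' @returns A list with `deltas` (tibble `patient_id`, `off`, `on`,
#'   `delta`) and `fraction_improved`.
#' @export
medication_contrast <- function(composites) {
  stopifnot(all(c("patient_id", "med_state", "composite") %in% names(composites)))
  wide <- tidyr::pivot_wider(
    composites[, c("patient_id", "med_state", "composite")],
    names_from = "med_state", values_from = "composite"
  )
  if (!all(c("off", "on") %in% names(wide)) ||
    anyNA(wide$off) || anyNA(wide$on)) {
    rlang::abort("every patient needs a composite in both medication states",
      class = "kinscore_input_error"
    )
  }
  wide$delta <- wide$on - wide$off
  list(
    deltas = tibble::as_tibble(wide),
    fraction_improved = mean(wide$delta < 0)
  )
}
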