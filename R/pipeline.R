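#' Extract window, signal and features for one clip
#'
#' Runs the per-clip portion of the pipeline: task-window detection (with
#' fallback to the full sequence when no activity clears the thresholds),
#' active-side detection for bilateral tasks, task-signal construction and
#' feature extraction.
#'
#' @param seq A cleaned `kin_pose`.
#' @param task_id Task identifier.
#' @param thresholds An [onset_thresholds()] object, or `NULL` to use the
#'   full sequence as the window.
#' @param side Active side; when `NULL` and the task is bilateral it is
#'   detected from the window.
#' @returns A one-row tibble: `start_frame`, `end_frame`, `side`, a
#'   `signal` list-column, and the 12 feature columns.
#' @export
extract_clip <- function(seq, task_id, thresholds = NULL, side = NULL) {
  spec <- task_spec(task_id)
  window <- NULL
  if (!is.null(thresholds)) {
    window <- tryCatch(
      detect_window(seq, task_id, thresholds),
      kinscore_no_activity_error = function(e) NULL
    )
  }
  if (is.null(window)) {
    window <- tibble::tibble(
      start_frame = 0L, end_frame = n_frames(seq),
      active_side = NA_character_
    )
  }
  if (spec$bilateral && is.null(side)) {
    side <- suppressWarnings(detect_active_side(seq, task_id, window))
  }
  sig <- compute_signal(seq, task_id, window, side = side %||% NA_character_)
  feats <- extract_features(sig)
  dplyr::bind_cols(
    tibble::tibble(
      start_frame = window$start_frame, end_frame = window$end_frame,
      side = side %||% NA_character_, signal = list(sig)
    ),
    feats
  )
}

#' Batch feature extraction over pose files
#'
#' Reads each pose file, cleans it, and extracts the task window, signal
#' and features. Clips that fail are logged and skipped; the run only
#' errors if no clip succeeds.
#'
#' @param files Tibble with columns `clip_id`, `path`, `task_id` and
#'   optionally `side`.
#' @param dialect Pose-file dialect for [read_pose()].
#' @param thresholds Optional [onset_thresholds()].
#' @param confidence_threshold,smooth_window Passed to [clean_pose()].
#' @returns A tibble with one row per successful clip (`clip_id`,
#'   `task_id`, window columns, `signal`, features).
#' @export
run_extract <- function(files, dialect = "long-csv", thresholds = NULL,
                        confidence_threshold = 0.5, smooth_window = 5L) {
  stopifnot(all(c("clip_id", "path", "task_id") %in% names(files)))
  out <- purrr::map(seq_len(nrow(files)), function(i) {
    row <- files[i, ]
    tryCatch(
      {
        seq <- read_pose(row$path, dialect = dialect)
        seq <- clean_pose(seq,
          confidence_threshold = confidence_threshold,
          smooth_window = smooth_window
        )
        side <- if ("side" %in% names(row) && !is.na(row$side)) row$side else NULL
        res <- extract_clip(seq, row$task_id, thresholds = thresholds, side = side)
        dplyr::bind_cols(
          tibble::tibble(clip_id = row$clip_id, task_id = row$task_id), res
        )
      },
      error = function(e) {
        rlang::inform(paste0("clip '", row$clip_id, "' failed: ", conditionMessage(e)))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    rlang::abort("no clip could be processed", class = "kinscore_run_error")
  }
  out
}

extract_cohort_features <- function(manifest, config, n_calibration = 10L) {
  results <- list()
  for (task in unique(manifest$task_id)) {
    rows <- manifest[manifest$task_id == task, ]
    calib_rows <- utils::head(rows, max(3L, min(n_calibration, nrow(rows))))
    calib_clips <- purrr::map(seq_len(nrow(calib_rows)), function(i) {
      cl <- materialize_clip(calib_rows[i, ], config)
      list(seq = clean_pose(cl$seq), window = cl$window)
    })
    thr <- tryCatch(
      calibrate_thresholds(calib_clips, task),
      error = function(e) NULL
    )
    task_out <- purrr::map(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      cl <- materialize_clip(row, config)
      seq <- clean_pose(cl$seq)
      tryCatch(
        {
          res <- extract_clip(seq, task, thresholds = thr, side = row$side)
          dplyr::bind_cols(
            row[, c(
              "clip_id", "patient_id", "task_id", "side", "med_state",
              "severity"
            )],
            res[, setdiff(names(res), "side")]
          )
        },
        error = function(e) {
          rlang::inform(paste0("clip '", row$clip_id, "' failed: ", conditionMessage(e)))
          NULL
        }
      )
    })
    results[[task]] <- dplyr::bind_rows(task_out)
  }
  dplyr::bind_rows(results)
}

#' Run configuration for the end-to-end experiment
#'
#' @param cohort A [cohort_config()] describing the simulated study.
#' @param model A [model_config()].
#' @param train_fraction Fraction of patients in the training split
#'   (grouping by patient prevents leakage between splits).
#' @param sigma_floor Floor on the panel SD in the distribution-aware
#'   accuracy band.
#' @param min_samples Minimum training clips for a task to be modeled.
#' @param ablate `"none"`, `"no_cnn"`, or `"no_mlp"`: optionally disable
#'   one model branch by zeroing its input at train and predict time.
#' @returns A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), model = model_config(),
                       train_fraction = 0.8, sigma_floor = 0.5,
                       min_samples = 10L, ablate = c("none", "no_cnn", "no_mlp")) {
  ablate <- match.arg(ablate)
  structure(
    list(
      cohort = cohort, model = model, train_fraction = train_fraction,
      sigma_floor = sigma_floor, min_samples = as.integer(min_samples),
      ablate = ablate
    ),
    class = "run_config"
  )
}

apply_ablation <- function(data, ablate) {
  if (ablate == "no_cnn") {
    data$signal <- purrr::map(data$signal, function(s) {
      kin_signal(rep(c(0, 1e-6), length.out = max(2L, length(s$values))),
        fps = s$fps, t0_frame = s$t0_frame
      )
    })
  } else if (ablate == "no_mlp") {
    for (f in intersect(feature_names(), names(data))) data[[f]] <- 0
  }
  data
}

#' Run the full simulate-extract-train-evaluate experiment
#'
#' Simulates a cohort, extracts signals and features for every clip,
#' splits patients into training and held-out groups, trains one ordinal
#' model per task on the training patients, and evaluates: within-one
#' and distribution-aware accuracies, Spearman correlation between the
#' latent severity and the predicted mean, agreement decomposition,
#' per-patient composite scores and the medication contrast. A provenance
#' block (seed, config hash, package version) is attached to the report.
#'
#' @param config A [run_config()].
#' @returns A list of class `kin_report`: `per_task` metrics tibble,
#'   `predictions`, `agreement`, `contrast`, `composites`, `models`, and
#'   `provenance`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$cohort)
  features <- extract_cohort_features(cohort$manifest, config$cohort)
  if (nrow(features) == 0L) {
    rlang::abort("no clip could be processed", class = "kinscore_run_error")
  }
  summaries <- rating_summaries(cohort$ratings,
    num_classes = config$model$num_classes
  )
  data <- dplyr::inner_join(features, summaries, by = "clip_id")
  data$target_mean <- data$mean
  data <- apply_ablation(data, config$ablate)

  patients <- sort(unique(data$patient_id))
  set.seed(config$cohort$seed + 1L)
  n_train <- max(1L, round(config$train_fraction * length(patients)))
  train_patients <- sort(sample(patients, n_train))
  data$split <- ifelse(data$patient_id %in% train_patients, "train", "test")

  models <- list()
  preds <- list()
  per_task <- list()
  for (task in unique(data$task_id)) {
    td <- data[data$task_id == task, ]
    tr <- td[td$split == "train", ]
    if (nrow(tr) < config$min_samples) {
      rlang::warn(paste0("task '", task, "' has too few training clips; skipped"))
      next
    }
    model <- train_model(tr, config$model)
    models[[task]] <- model
    pr <- predict(model, td)
    pr <- dplyr::bind_cols(
      td[, c(
        "clip_id", "patient_id", "task_id", "side", "med_state",
        "severity", "mean", "sd", "split"
      )],
      pr[, c("mu_hat", "sigma2_hat", "pred_class")]
    )
    preds[[task]] <- pr
    te <- pr[pr$split == "test", ]
    eval_set <- if (nrow(te) >= 5L) te else pr
    per_task[[task]] <- tibble::tibble(
      task_id = task,
      n_train = nrow(tr), n_test = nrow(te),
      within_pm1 = within_pm1_accuracy(eval_set$mu_hat, eval_set$mean),
      within_1sd = distribution_aware_accuracy(
        eval_set$mu_hat, eval_set$mean, eval_set$sd,
        width_k = 1, sigma_floor = config$sigma_floor
      ),
      within_1p5sd = distribution_aware_accuracy(
        eval_set$mu_hat, eval_set$mean, eval_set$sd,
        width_k = 1.5, sigma_floor = config$sigma_floor
      ),
      spearman = stats::cor(eval_set$severity, eval_set$mu_hat,
        method = "spearman"
      ),
      final_loss = utils::tail(model$history$loss, 1L)
    )
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0L) {
    rlang::abort("no task had enough training clips", class = "kinscore_run_error")
  }

  agreement <- cohort$ratings |>
    dplyr::left_join(
      cohort$manifest[, c("clip_id", "task_id")],
      by = "clip_id"
    ) |>
    dplyr::group_by(.data$task_id) |>
    dplyr::group_modify(~ agreement_percentages(.x)) |>
    dplyr::ungroup()

  composites <- composite_scores(predictions)
  contrast <- medication_contrast(composites)

  report <- list(
    per_task = dplyr::bind_rows(per_task),
    predictions = predictions,
    agreement = agreement,
    composites = composites,
    contrast = contrast,
    models = models,
    provenance = list(
      seed = config$cohort$seed,
      config_hash = rlang::hash(config[c(
        "cohort", "model", "train_fraction", "sigma_floor", "min_samples",
        "ablate"
      )]),
      package_version = as.character(utils::packageVersion("kinscore")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  class(report) <- "kin_report"
  report
}

#' @export
print.kin_report <- function(x, ...) {
  cat("<experiment report>\n")
  print(x$per_task)
  cat(sprintf(
    "fraction of patients improved ON medication: %.2f\n",
    x$contrast$fraction_improved
  ))
  invisible(x)
}

#' Consensus-mechanism experiment on simulated rater panels
#'
#' Simulates 3-rater panels for every task at its shipped complexity,
#' with rater noise growing in complexity, then fits the two
#' complexity-consensus regressions: complete-agreement percentage on
#' complexity (expected negative slope) and mean panel SD on complexity
#' (expected positive slope).
#'
#' @param n_panels_per_task Panels simulated per task.
#' @param config A [cohort_config()] providing the rater-noise settings.
#' @returns A list: `by_task` tibble (agreement stats and mean SD per
#'   task), `agreement_fit` and `sd_fit` ([complexity_regression()]
#'   objects).
#' @export
consensus_experiment <- function(n_panels_per_task = 300L,
                                 config = cohort_config()) {
  set.seed(config$seed)
  specs <- task_specs()
  rater_biases <- stats::rnorm(3L, 0, config$rater_bias_sd)
  sev_pool <- sample(0:4, n_panels_per_task,
    replace = TRUE,
    prob = config$severity_distribution
  )
  by_task <- purrr::map(seq_len(nrow(specs)), function(i) {
    cx <- specs$complexity[i]
    panels <- purrr::map(sev_pool, function(s) {
      simulate_panel(s, cx,
        rater_biases = rater_biases,
        noise_base = config$rater_noise_base,
        noise_per_cue = config$rater_noise_per_cue
      )
    })
    ag <- agreement_percentages(panels)
    mean_sd <- mean(vapply(panels, stats::sd, numeric(1L)))
    dplyr::bind_cols(
      tibble::tibble(task_id = specs$task_id[i], complexity = cx),
      ag,
      tibble::tibble(mean_panel_sd = mean_sd)
    )
  }) |> dplyr::bind_rows()

  agreement_fit <- complexity_regression(
    data.frame(complexity = by_task$complexity, y = by_task$complete_pct)
  )
  sd_fit <- complexity_regression(
    data.frame(complexity = by_task$complexity, y = by_task$mean_panel_sd)
  )
  list(by_task = by_task, agreement_fit = agreement_fit, sd_fit = sd_fit)
}
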