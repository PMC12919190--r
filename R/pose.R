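#' Construct a pose sequence
#'
#' A pose sequence is a long tibble of per-frame 2D keypoint observations —
#' the raw material of every downstream stage. Each row is one observation
#' of one joint in one frame; missing detections are encoded as `NA`
#' coordinates with `NA` confidence, never as `(0, 0)` with positive
#' confidence. The frame rate and free-form metadata (patient id, task,
#' side, medication state, ...) travel as attributes so the object still
#' behaves as an ordinary tibble in dplyr pipelines.
#'
#' @param data A data frame with columns `frame` (0-based integer), `joint`
#'   (character), `x`, `y` (pixels or normalized units), `confidence`
#'   (in `[0, 1]` or `NA` for missing).
#' @param fps Frames per second, a single positive number.
#' @param meta Named list of free-form tags.
#' @returns A `kin_pose` tibble, complete (one row per frame x joint,
#'   missing combinations filled with `NA` observations) and sorted by
#'   frame then joint.
#' @export
pose_sequence <- function(data, fps, meta = list()) {
  stopifnot(is.data.frame(data))
  required <- c("frame", "joint", "x", "y", "confidence")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("pose data lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "kinscore_input_error"
    )
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    rlang::abort("fps must be a single positive number",
      class = "kinscore_config_error"
    )
  }
  data <- tibble::as_tibble(data[required])
  data$frame <- as.integer(data$frame)
  bad_conf <- !is.na(data$confidence) &
    (data$confidence < 0 | data$confidence > 1)
  if (any(bad_conf)) {
    rlang::abort("confidence values must lie in [0, 1]",
      class = "kinscore_input_error"
    )
  }
  # (0,0,0) is the classic missing-detection encoding of some pose
  # estimators; decode it to an explicit missing observation.
  zero_zero <- !is.na(data$x) & !is.na(data$y) &
    data$x == 0 & data$y == 0 &
    !is.na(data$confidence) & data$confidence == 0
  data$x[zero_zero] <- NA_real_
  data$y[zero_zero] <- NA_real_
  data$confidence[zero_zero] <- NA_real_
  # missing coordinates never carry confidence
  no_xy <- is.na(data$x) | is.na(data$y)
  data$x[no_xy] <- NA_real_
  data$y[no_xy] <- NA_real_
  data$confidence[no_xy] <- NA_real_

  joints <- unique(data$joint)
  frames <- sort(unique(data$frame))
  grid <- tidyr::expand_grid(frame = frames, joint = joints)
  data <- dplyr::left_join(grid, data, by = c("frame", "joint"))
  data <- dplyr::arrange(data, .data$frame, match(.data$joint, joints))

  new_pose(data, fps = fps, meta = meta, joints = joints)
}

new_pose <- function(data, fps, meta, joints) {
  out <- tibble::new_tibble(
    data,
    fps = fps, meta = meta, joints = joints,
    class = "kin_pose"
  )
  out
}

#' @export
print.kin_pose <- function(x, ...) {
  cat(sprintf(
    "<pose sequence: %d frames, %d joints, %.3g fps>\n",
    n_frames(x), length(pose_joints(x)), pose_fps(x)
  ))
  NextMethod()
}

#' @exportS3Method tibble::as_tibble
as_tibble.kin_pose <- function(x, ...) {
  tibble::new_tibble(as.data.frame(x), class = NULL)
}

#' Accessors for pose-sequence attributes
#'
#' @param seq A `kin_pose` object.
#' @returns `pose_fps()` the frame rate; `pose_meta()` the metadata list;
#'   `pose_joints()` the ordered joint names; `n_frames()` the number of
#'   frames.
#' @export
pose_fps <- function(seq) attr(seq, "fps")

#' @rdname pose_fps
#' @export
pose_meta <- function(seq) attr(seq, "meta")

#' @rdname pose_fps
#' @export
pose_joints <- function(seq) attr(seq, "joints")

#' @rdname pose_fps
#' @export
n_frames <- function(seq) length(unique(seq$frame))

restore_pose <- function(data, template) {
  new_pose(data,
    fps = pose_fps(template), meta = pose_meta(template),
    joints = pose_joints(template)
  )
}

#' Read pose-keypoint trajectories from a pose-estimator output file
#'
#' Two estimator-agnostic dialects are supported. `"long-csv"` is a flat
#' table with columns `frame,joint,x,y,confidence`. `"per-frame-json"` is a
#' JSON object `{"fps": ..., "frames": [...]}` where each frame is an
#' object with a `keypoints` member mapping joint name to a flat
#' `[x, y, confidence]` triple, matching common pose-estimator output.
#' Frames that cannot be parsed become all-missing frames rather than being
#' dropped, so frame indexing stays aligned with the source video.
#'
#' @param path Path to the input file.
#' @param dialect `"long-csv"` or `"per-frame-json"`.
#' @param fps Frame rate override; for `"long-csv"` (which carries no frame
#'   rate) the default is 30 fps.
#' @param meta Named list of free-form tags attached to the sequence.
#' @returns A [pose_sequence()] tibble with frames in temporal order.
#' @export
read_pose <- function(path, dialect = c("long-csv", "per-frame-json"),
                      fps = NULL, meta = list()) {
  if (length(dialect) == 1L && !dialect %in% c("long-csv", "per-frame-json")) {
    rlang::abort(paste0("unknown pose dialect '", dialect, "'"),
      class = "kinscore_config_error"
    )
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rlang::abort(paste0("pose file not found: ", path),
      class = "kinscore_input_error"
    )
  }
  if (dialect == "long-csv") {
    data <- readr::read_csv(path,
      col_types = readr::cols(
        frame = readr::col_integer(),
        joint = readr::col_character(),
        x = readr::col_double(),
        y = readr::col_double(),
        confidence = readr::col_double()
      ),
      progress = FALSE
    )
    if (nrow(data) == 0L) {
      rlang::abort("no parsable frames in pose file",
        class = "kinscore_empty_input_error"
      )
    }
    pose_sequence(data, fps = fps %||% 30, meta = meta)
  } else {
    read_pose_json(path, fps = fps, meta = meta)
  }
}

read_pose_json <- function(path, fps = NULL, meta = list()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  frames <- raw$frames
  if (is.null(frames) || length(frames) == 0L) {
    rlang::abort("no parsable frames in pose file",
      class = "kinscore_empty_input_error"
    )
  }
  # union of joint names over parseable frames, in first-seen order
  joints <- character(0)
  for (fr in frames) {
    kp <- tryCatch(fr$keypoints, error = function(e) NULL)
    if (is.list(kp)) joints <- union(joints, names(kp))
  }
  if (length(joints) == 0L) {
    rlang::abort("no parsable frames in pose file",
      class = "kinscore_empty_input_error"
    )
  }
  rows <- purrr::imap(frames, function(fr, i) {
    kp <- tryCatch(fr$keypoints, error = function(e) NULL)
    parse_triple <- function(j) {
      tr <- if (is.list(kp)) kp[[j]] else NULL
      tr <- tryCatch(as.numeric(unlist(tr)), warning = function(w) NULL)
      if (is.null(tr) || length(tr) != 3L || anyNA(tr)) {
        c(NA_real_, NA_real_, NA_real_)
      } else {
        tr
      }
    }
    triples <- vapply(joints, parse_triple, numeric(3L))
    tibble::tibble(
      frame = i - 1L, joint = joints,
      x = unname(triples[1L, ]), y = unname(triples[2L, ]),
      confidence = unname(triples[3L, ])
    )
  })
  data <- dplyr::bind_rows(rows)
  pose_sequence(data, fps = fps %||% (raw$fps %||% 30), meta = meta)
}

#' Write a pose sequence to the long-CSV dialect
#'
#' @param seq A `kin_pose` object.
#' @param path Output path; columns `frame,joint,x,y,confidence`.
#' @returns `path`, invisibly.
#' @export
write_pose <- function(seq, path) {
  readr::write_csv(as.data.frame(seq), path, progress = FALSE)
  invisible(path)
}

#' Mask low-confidence keypoint observations
#'
#' Observations whose detector confidence falls below `threshold` become
#' missing; the conventional minimum confidence for pose-estimator output
#' is 0.5. Idempotent at a fixed threshold.
#'
#' @param seq A `kin_pose` object.
#' @param threshold Minimum confidence in `[0, 1]`; observations with
#'   `confidence < threshold` are masked.
#' @returns A `kin_pose` with low-confidence observations set to missing.
#' @export
filter_confidence <- function(seq, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
    is.na(threshold) || threshold < 0 || threshold > 1) {
    rlang::abort("threshold must be a single number in [0, 1]",
      class = "kinscore_config_error"
    )
  }
  data <- tibble::as_tibble(seq)
  low <- !is.na(data$confidence) & data$confidence < threshold
  data$x[low] <- NA_real_
  data$y[low] <- NA_real_
  data$confidence[low] <- NA_real_
  restore_pose(data, seq)
}

# Linear interpolation of interior NA runs no longer than max_gap.
interpolate_gaps <- function(v, max_gap) {
  if (!anyNA(v) || sum(!is.na(v)) < 2L) {
    return(v)
  }
  filled <- stats::approx(
    x = which(!is.na(v)), y = v[!is.na(v)],
    xout = seq_along(v), method = "linear", rule = 1
  )$y
  runs <- rle(is.na(v))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep_na <- rep(FALSE, length(v))
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i] && runs$lengths[i] > max_gap) {
      keep_na[starts[i]:ends[i]] <- TRUE
    }
  }
  filled[keep_na] <- NA_real_
  filled
}

# Centered moving average with shrinking windows at the edges; positions
# that are NA on input stay NA (long gaps are not invented).
moving_average <- function(v, window) {
  half <- (window - 1L) %/% 2L
  n <- length(v)
  vals <- ifelse(is.na(v), 0, v)
  fin <- as.numeric(!is.na(v))
  kernel <- rep(1, window)
  sums <- stats::filter(vals, kernel, sides = 2)
  cnts <- stats::filter(fin, kernel, sides = 2)
  out <- as.numeric(sums / pmax(cnts, 1))
  # shrinking windows at the edges where stats::filter yields NA
  for (i in seq_len(min(half, n))) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(v[lo:hi], na.rm = TRUE)
    j <- n - i + 1L
    lo <- max(1L, j - half)
    hi <- min(n, j + half)
    out[j] <- mean(v[lo:hi], na.rm = TRUE)
  }
  out[is.na(v)] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Smooth joint trajectories with a centered moving average
#'
#' Interior gaps of missing observations no longer than `max_gap` frames
#' are first filled by linear interpolation; longer gaps stay missing and
#' are excluded from downstream signals. Each coordinate is then replaced
#' by its centered moving average; edge frames use shrinking windows, so
#' the sequence length never changes.
#'
#' @param seq A `kin_pose` object.
#' @param window Odd window length in frames (default 5, about 0.17 s at
#'   30 fps). `window = 1` is the identity.
#' @param max_gap Longest missing run (frames) to bridge by interpolation.
#' @returns A smoothed `kin_pose` of identical length and frame rate.
#' @export
smooth_pose <- function(seq, window = 5L, max_gap = 15L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    rlang::abort("window must be a positive odd integer",
      class = "kinscore_config_error"
    )
  }
  nf <- n_frames(seq)
  if (window > nf) {
    rlang::abort(
      sprintf("smoothing window (%d) exceeds sequence length (%d)", window, nf),
      class = "kinscore_degenerate_error"
    )
  }
  data <- tibble::as_tibble(seq)
  data <- data |>
    dplyr::group_by(.data$joint) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      x = moving_average(interpolate_gaps(.data$x, max_gap), window),
      y = moving_average(interpolate_gaps(.data$y, max_gap), window)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, match(.data$joint, pose_joints(seq)))
  miss <- is.na(data$x) | is.na(data$y)
  data$x[miss] <- NA_real_
  data$y[miss] <- NA_real_
  data$confidence[miss] <- NA_real_
  restore_pose(data, seq)
}

#' Normalize image coordinates for kinematic analysis
#'
#' Image coordinates grow downward; vertical-displacement signals need a
#' consistent "up" direction, so `y` is sign-flipped. Coordinates are then
#' scaled by the median shoulder-to-hip distance (averaged over sides and
#' taken over frames) to remove camera-distance effects, yielding
#' scale-free body-relative units.
#'
#' @param seq A `kin_pose` object.
#' @param flip_y Flip the vertical axis so up is positive (default `TRUE`).
#' @param scale Scale coordinates by the median shoulder-hip distance
#'   (default `TRUE`); requires `shoulder_left/right` and `hip_left/right`
#'   joints, otherwise the scale is left at 1 with a warning.
#' @returns A normalized `kin_pose`.
#' @export
normalize_pose <- function(seq, flip_y = TRUE, scale = TRUE) {
  data <- tibble::as_tibble(seq)
  if (flip_y) data$y <- -data$y
  s <- 1
  if (scale) {
    s <- torso_scale(data)
    if (is.na(s) || s <= 0) {
      rlang::warn("shoulder/hip joints unavailable; coordinates left unscaled")
      s <- 1
    }
  }
  data$x <- data$x / s
  data$y <- data$y / s
  restore_pose(data, seq)
}

torso_scale <- function(data) {
  get_xy <- function(j) {
    sub <- data[data$joint == j, c("frame", "x", "y")]
    if (nrow(sub) == 0L) {
      return(NULL)
    }
    sub
  }
  dists <- c()
  for (side in c("left", "right")) {
    sh <- get_xy(paste0("shoulder_", side))
    hp <- get_xy(paste0("hip_", side))
    if (is.null(sh) || is.null(hp)) next
    m <- dplyr::inner_join(sh, hp, by = "frame", suffix = c("_s", "_h"))
    d <- sqrt((m$x_s - m$x_h)^2 + (m$y_s - m$y_h)^2)
    dists <- c(dists, d[is.finite(d)])
  }
  if (length(dists) == 0L) {
    return(NA_real_)
  }
  stats::median(dists)
}

#' Clean a pose sequence in one call
#'
#' Convenience wrapper applying, in order: confidence filtering,
#' gap interpolation + moving-average smoothing, and (optionally)
#' coordinate normalization.
#'
#' @param seq A `kin_pose` object.
#' @param confidence_threshold Minimum keypoint confidence (default 0.5).
#' @param smooth_window Moving-average window in frames (odd, default 5).
#' @param max_gap Longest missing run bridged by interpolation (frames).
#' @param normalize Apply [normalize_pose()] (default `TRUE`).
#' @returns A cleaned `kin_pose`.
#' @export
clean_pose <- function(seq, confidence_threshold = 0.5, smooth_window = 5L,
                       max_gap = 15L, normalize = TRUE) {
  out <- filter_confidence(seq, confidence_threshold)
  out <- smooth_pose(out, window = smooth_window, max_gap = max_gap)
  if (normalize) out <- normalize_pose(out)
  out
}
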