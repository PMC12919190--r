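# a single-sided toe-tapping clip with a known motion burst
burst_clip <- function(n = 150L, burst = 30:89, amp = 1, fps = 30,
                       joint = "toe_right", seed = 1) {
  set.seed(seed)
  y <- rep(10, n)
  y[burst + 1L] <- 10 - amp * (1 - cos(2 * pi * 3 * seq_along(burst) / fps)) / 2
  named_pose(joint, x = rep(5, n), y = y, fps = fps)
}

toy_thresholds <- function() {
  onset_thresholds(velocity = 1, displacement = 0.1)
}

test_that("a synthetic motion burst is localized within smoothing tolerance", {
  seq <- smooth_pose(burst_clip(), 5L)
  w <- detect_window(seq, "toe_tapping", toy_thresholds())
  expect_lte(abs(w$start_frame - 30L), 5L)
  expect_lte(abs(w$end_frame - 90L), 15L) # end needs the sustained-low hold
  expect_lt(w$start_frame, w$end_frame)
})

test_that("motion running to the end saturates the window at the last frame", {
  n <- 90L
  y <- 10 - (1 - cos(2 * pi * 3 * (0:(n - 1)) / 30)) / 2
  seq <- named_pose("toe_right", x = rep(5, n), y = y)
  w <- detect_window(seq, "toe_tapping", toy_thresholds())
  expect_equal(w$end_frame, n)
})

test_that("a static clip raises a no-activity error", {
  seq <- named_pose("toe_right", x = rep(5, 60), y = rep(10, 60))
  expect_error(
    detect_window(seq, "toe_tapping", toy_thresholds()),
    class = "kinscore_no_activity_error"
  )
})

test_that("window detection shifts with a prepended static segment", {
  base <- burst_clip()
  w0 <- detect_window(base, "toe_tapping", toy_thresholds())
  shift <- 40L
  df <- tibble::as_tibble(base)
  pre <- tibble::tibble(
    frame = 0:(shift - 1L), joint = "toe_right",
    x = 5, y = 10, confidence = 0.9
  )
  df$frame <- df$frame + shift
  shifted <- pose_sequence(dplyr::bind_rows(pre, df), fps = 30)
  w1 <- detect_window(shifted, "toe_tapping", toy_thresholds())
  expect_lte(abs((w1$start_frame - shift) - w0$start_frame), 2L)
})

test_that("lowering the velocity threshold never shrinks the window", {
  seq <- smooth_pose(burst_clip(), 5L)
  w_hi <- detect_window(seq, "toe_tapping", onset_thresholds(2, 0.1))
  w_lo <- detect_window(seq, "toe_tapping", onset_thresholds(0.5, 0.1))
  expect_lte(w_lo$start_frame, w_hi$start_frame)
  expect_gte(w_lo$end_frame, w_hi$end_frame)
})

two_sided_clip <- function(left_amp, right_amp, n = 120L, fps = 30) {
  t <- 0:(n - 1L)
  osc <- function(a) 10 - a * (1 - cos(2 * pi * 3 * t / fps)) / 2
  pose_sequence(
    tibble::tibble(
      frame = rep(t, 2L),
      joint = rep(c("toe_left", "toe_right"), each = n),
      x = rep(c(4, 6), each = n),
      y = c(osc(left_amp), osc(right_amp)),
      confidence = 0.9
    ),
    fps = fps
  )
}

test_that("the side with dominant movement is the active side", {
  seq <- two_sided_clip(left_amp = 0.01, right_amp = 1)
  w <- tibble::tibble(start_frame = 0L, end_frame = 120L)
  expect_equal(detect_active_side(seq, "toe_tapping", w), "right")

  sym <- two_sided_clip(left_amp = 1, right_amp = 1)
  expect_warning(
    side <- detect_active_side(sym, "toe_tapping", w),
    "tie"
  )
  expect_equal(side, "left")
})

test_that("a fully-missing side falls back to the present side with a warning", {
  seq <- two_sided_clip(left_amp = 1, right_amp = 1)
  df <- tibble::as_tibble(seq)
  df$x[df$joint == "toe_left"] <- NA_real_
  df$y[df$joint == "toe_left"] <- NA_real_
  df$confidence[df$joint == "toe_left"] <- NA_real_
  seq2 <- pose_sequence(df, fps = 30)
  w <- tibble::tibble(start_frame = 0L, end_frame = 120L)
  expect_warning(
    side <- detect_active_side(seq2, "toe_tapping", w),
    "missing"
  )
  expect_equal(side, "right")
})

test_that("threshold calibration matches the percentile oracle", {
  mk <- function(amp) {
    seq <- burst_clip(amp = amp)
    list(seq = seq, window = tibble::tibble(start_frame = 30L, end_frame = 90L))
  }
  clips <- lapply(c(0.5, 1, 1.5), mk)

  # oracle: the percentile of within-window peak speeds, computed directly
  peak_speed <- function(cl) {
    sub <- cl$seq[cl$seq$frame >= 30L & cl$seq$frame < 90L, ]
    rows <- sub[order(sub$frame), ]
    max(sqrt(diff(rows$x)^2 + diff(rows$y)^2) * 30)
  }
  speeds <- vapply(clips, peak_speed, numeric(1L))

  thr <- calibrate_thresholds(clips, "toe_tapping", probs = 0.5, safety = 1)
  expect_equal(thr$velocity, unname(stats::quantile(speeds, 0.5)), tolerance = 1e-8)

  # default derating halves the percentile
  thr_derated <- calibrate_thresholds(clips, "toe_tapping", probs = 0.5)
  expect_equal(thr_derated$velocity, thr$velocity / 2, tolerance = 1e-8)

  # identical clips: the threshold equals that clip's statistic
  same <- lapply(rep(1, 3), mk)
  thr_same <- calibrate_thresholds(same, "toe_tapping", probs = 0.2, safety = 1)
  expect_equal(thr_same$velocity, peak_speed(same[[1L]]), tolerance = 1e-8)

  expect_error(
    calibrate_thresholds(clips[1:2], "toe_tapping"),
    class = "kinscore_insufficient_data_error"
  )
})

test_that("calibrated thresholds recover labeled windows on simulated clips", {
  clips <- lapply(1:12, function(i) {
    sim <- simulate_sequence("finger_tapping", (i - 1) %% 4, seed = 100 + i)
    list(seq = clean_pose(sim$seq), window = sim$window)
  })
  thr <- calibrate_thresholds(clips, "finger_tapping")
  jaccard <- vapply(clips, function(cl) {
    # the documented fallback: no-activity clips keep the full sequence
    w <- tryCatch(
      detect_window(cl$seq, "finger_tapping", thr),
      kinscore_no_activity_error = function(e) full_window(cl$seq)
    )
    inter <- max(0, min(w$end_frame, cl$window$end_frame) -
      max(w$start_frame, cl$window$start_frame))
    uni <- max(w$end_frame, cl$window$end_frame) -
      min(w$start_frame, cl$window$start_frame)
    inter / uni
  }, numeric(1L))
  expect_gte(mean(jaccard >= 0.7), 0.9)
})
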