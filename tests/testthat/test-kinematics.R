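test_that("finger-tapping signal is the thumb-index Euclidean distance", {
  n <- 10L
  df <- tibble::tibble(
    frame = rep(0:(n - 1L), 2L),
    joint = rep(c("thumb_tip_right", "index_tip_right"), each = n),
    x = c(rep(0, n), rep(3, n)),
    y = c(rep(0, n), rep(4, n)),
    confidence = 0.9
  )
  seq <- pose_sequence(df, fps = 30)
  sig <- compute_signal(seq, "finger_tapping", full_window(seq), side = "right")
  expect_equal(sig$values, rep(5, n)) # the 3-4-5 triangle
})

test_that("vertical-displacement signals are zero when the joint never moves", {
  seq <- named_pose("toe_left", x = rep(2, 8), y = rep(7, 8))
  sig <- compute_signal(seq, "toe_tapping", full_window(seq), side = "left")
  expect_equal(sig$values, rep(0, 8))
})

test_that("hand-movement signal averages fingertip-palm distances", {
  n <- 6L
  df <- tibble::tibble(
    frame = rep(0:(n - 1L), 3L),
    joint = rep(c("palm_right", "index_tip_right", "middle_tip_right"), each = n),
    x = c(rep(0, n), rep(2, n), rep(4, n)),
    y = rep(0, 3L * n),
    confidence = 0.9
  )
  seq <- pose_sequence(df, fps = 30)
  sig <- compute_signal(seq, "hand_movement", full_window(seq), side = "right")
  expect_equal(sig$values, rep(3, n)) # mean of distances 2 and 4
})

test_that("a fully-missing required joint raises a missing-joint error", {
  seq <- named_pose("thumb_tip_right", x = 1:10, y = 1:10)
  expect_error(
    compute_signal(seq, "finger_tapping", full_window(seq), side = "right"),
    class = "kinscore_missing_joint_error"
  )
})

test_that("gait produces a per-step signal baselined at the first step", {
  sim <- simulate_sequence("gait", 0, seed = 5)
  seq <- clean_pose(sim$seq)
  sig <- compute_signal(seq, "gait", sim$window)
  expect_equal(sig$values[1L], 0) # first step is the baseline
  expect_gt(length(sig$values), 2L)
  expect_gt(sig$fps, 0.5) # plausible step rate, steps/s
  expect_lt(sig$fps, 6)
})

test_that("cycle detection counts the periods of a clean or noisy sine", {
  sig <- sine_signal(A = 1, f = 1, fps = 50, dur = 5)
  cyc <- find_cycles(sig)
  expect_equal(length(cyc$peaks), 5L)
  expect_equal(length(cyc$troughs), 5L)

  set.seed(2)
  noisy <- kin_signal(
    sig$values + rnorm(length(sig$values), 0, 0.03),
    fps = 50
  )
  cyc2 <- find_cycles(noisy)
  expect_equal(length(cyc2$peaks), 5L)

  ramp <- kin_signal(seq(0, 1, length.out = 100), fps = 50)
  expect_error(find_cycles(ramp), class = "kinscore_insufficient_cycles_error")
})

test_that("sine features recover the closed-form frequency, amplitude and flat decrement", {
  A <- 0.8
  ft <- extract_features(sine_signal(A = A, f = 2, fps = 100, dur = 10))
  expect_equal(ft$avg_freq, 2, tolerance = 0.1 / 2)
  expect_equal(ft$avg_amp, 2 * A, tolerance = 0.05)
  expect_lt(abs(ft$dec_amp), 0.01 * A)
  expect_equal(ft$avg_peak_dist, 0.5, tolerance = 0.05)
  expect_equal(ft$avg_trough_dist, 0.5, tolerance = 0.05)
  expect_lt(ft$period_range, 0.1)
})

test_that("constant-like signals yield zero derivatives and NA cycle features", {
  sig <- kin_signal(rep(3, 50), fps = 30)
  ft <- extract_features(sig)
  expect_equal(ft$avg_vel, 0)
  expect_equal(ft$avg_acc, 0)
  expect_equal(ft$avg_jerk, 0)
  expect_true(is.na(ft$avg_amp))
  expect_true(is.na(ft$avg_peak_dist))
  expect_true(is.na(ft$dec_amp))
})

test_that("a programmed per-cycle amplitude decay is recovered by dec_amp", {
  f <- 2
  fps <- 100
  t <- (0:(10 * fps - 1)) / fps
  cycle <- floor(f * t)
  amp <- 1 - 0.1 * cycle # 10% of base amplitude lost per cycle
  sig <- kin_signal(amp * sin(2 * pi * f * t), fps = fps)
  ft <- extract_features(sig)
  expect_lt(ft$dec_amp, 0)
  # per-cycle peak-to-trough amplitude drops ~0.2 per cycle (2A scale)
  expect_equal(abs(ft$dec_amp), 0.2, tolerance = 0.2)
})

test_that("signals are invariant to translation and distances to rotation", {
  n <- 40L
  set.seed(9)
  xa <- rnorm(n)
  ya <- rnorm(n)
  xb <- rnorm(n, 2)
  yb <- rnorm(n, 2)
  mk <- function(xa, ya, xb, yb) {
    pose_sequence(
      tibble::tibble(
        frame = rep(0:(n - 1L), 2L),
        joint = rep(c("thumb_tip_left", "index_tip_left"), each = n),
        x = c(xa, xb), y = c(ya, yb), confidence = 0.9
      ),
      fps = 30
    )
  }
  base <- mk(xa, ya, xb, yb)
  sig0 <- compute_signal(base, "finger_tapping", full_window(base), side = "left")

  shifted <- mk(xa + 7, ya - 3, xb + 7, yb - 3)
  sig1 <- compute_signal(shifted, "finger_tapping", full_window(shifted), side = "left")
  expect_equal(sig1$values, sig0$values, tolerance = 1e-10)

  th <- 0.7
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y, x2 = sin(th) * x + cos(th) * y)
  ra <- rot(xa, ya)
  rb <- rot(xb, yb)
  rotated <- mk(ra$x, ra$x2, rb$x, rb$x2)
  sig2 <- compute_signal(rotated, "finger_tapping", full_window(rotated), side = "left")
  expect_equal(sig2$values, sig0$values, tolerance = 1e-10)
})

test_that("coordinate scaling scales amplitudes but not frequencies", {
  sim <- simulate_sequence("finger_tapping", 1, seed = 21)
  seq <- clean_pose(sim$seq, normalize = FALSE)
  sig <- compute_signal(seq, "finger_tapping", sim$window, side = "right")
  ft <- extract_features(sig)

  df <- tibble::as_tibble(sim$seq)
  df$x <- df$x * 3
  df$y <- df$y * 3
  seq3 <- clean_pose(pose_sequence(df, fps = 30), normalize = FALSE)
  ft3 <- extract_features(
    compute_signal(seq3, "finger_tapping", sim$window, side = "right")
  )
  expect_equal(ft3$avg_amp, 3 * ft$avg_amp, tolerance = 1e-6)
  expect_equal(ft3$avg_freq, ft$avg_freq, tolerance = 1e-6)
})

test_that("the feature vector layout is fixed for positional consumers", {
  expect_identical(
    feature_names(),
    c(
      "avg_vel", "avg_acc", "avg_jerk", "avg_freq", "max_fft",
      "avg_peak_dist", "avg_trough_dist", "avg_amp", "amp_std",
      "dec_amp", "dec_vel", "period_range"
    )
  )
  ft <- extract_features(sine_signal())
  expect_identical(names(ft), feature_names())
  expect_equal(nrow(ft), 1L)
})
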