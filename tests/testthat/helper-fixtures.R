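# Shared fixture builders; everything is generated in code at test time.

# minimal two-joint pose tibble over n frames
toy_pose <- function(n = 10L, fps = 30, xa = NULL, ya = NULL,
                     xb = NULL, yb = NULL, conf = 0.9) {
  xa <- xa %||% seq_len(n)
  ya <- ya %||% rep(1, n)
  xb <- xb %||% rep(5, n)
  yb <- yb %||% rep(2, n)
  pose_sequence(
    tibble::tibble(
      frame = rep(0:(n - 1L), 2L),
      joint = rep(c("a", "b"), each = n),
      x = c(xa, xb), y = c(ya, yb),
      confidence = rep(conf, 2L * n)
    ),
    fps = fps
  )
}

# a single-joint pose carrying one trajectory under a given joint name
named_pose <- function(joint, x, y, fps = 30, conf = 0.9, extra = NULL) {
  n <- length(x)
  df <- tibble::tibble(
    frame = 0:(n - 1L), joint = joint, x = x, y = y, confidence = conf
  )
  if (!is.null(extra)) df <- dplyr::bind_rows(df, extra)
  pose_sequence(df, fps = fps)
}

full_window <- function(seq) {
  tibble::tibble(
    start_frame = 0L, end_frame = n_frames(seq), active_side = NA_character_
  )
}

sine_signal <- function(A = 1, f = 2, fps = 100, dur = 10, phase = 0) {
  t <- (0:(dur * fps - 1)) / fps
  kin_signal(A * sin(2 * pi * f * t + phase), fps = fps)
}

# severity-parameterized direct training rows (signal + features + target),
# bypassing pose simulation for fast model-level tests
direct_training_data <- function(n, seed, fps = 30, dur = 10) {
  set.seed(seed)
  sev <- sample(0:4, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    s <- sev[i]
    amp <- 1 - 0.18 * s
    f <- 3 * (1 - 0.12 * s)
    t <- (0:(dur * fps - 1)) / fps
    v <- amp * sin(2 * pi * f * t) + stats::rnorm(length(t), 0, 0.05)
    sig <- kin_signal(v, fps)
    dplyr::bind_cols(
      tibble::tibble(signal = list(sig), severity = s, target_mean = s),
      extract_features(sig)
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
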