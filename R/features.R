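#' Names of the kinematic features, in canonical order
#'
#' The model consumes feature vectors positionally, so the order and length
#' are fixed: average velocity/acceleration/jerk of the movement signal,
#' spectral centroid frequency and maximum spectral power, mean inter-peak
#' and inter-trough intervals, mean and SD of peak-to-trough amplitude,
#' per-cycle linear decrement of amplitude and of velocity, and the range
#' of inter-cycle periods.
#'
#' @returns Character vector of the 12 feature names.
#' @export
feature_names <- function() {
  c(
    "avg_vel", "avg_acc", "avg_jerk", "avg_freq", "max_fft",
    "avg_peak_dist", "avg_trough_dist", "avg_amp", "amp_std",
    "dec_amp", "dec_vel", "period_range"
  )
}

local_extrema <- function(v) {
  n <- length(v)
  d <- diff(v)
  s <- sign(d)
  # collapse flats so plateaus register one extremum
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  idx_max <- which(diff(s) < 0) + 1L
  idx_min <- which(diff(s) > 0) + 1L
  list(max = idx_max, min = idx_min)
}

zoo_na_locf <- function(x) {
  # last-observation-carried-forward without extra deps
  idx <- cumsum(!is.na(x))
  vals <- x[!is.na(x)]
  out <- rep(NA_real_, length(x))
  out[idx > 0] <- vals[idx[idx > 0]]
  out
}

# topographic prominence of each candidate peak (negate v for troughs)
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    left <- if (p > 1L) v[seq_len(p - 1L)] else numeric(0)
    higher_l <- which(left > v[p])
    base_l <- if (length(higher_l) > 0L) {
      min(v[(max(higher_l) + 1L):(p - 1L)])
    } else if (length(left) > 0L) {
      min(left)
    } else {
      v[p]
    }
    right <- if (p < length(v)) v[(p + 1L):length(v)] else numeric(0)
    higher_r <- which(right > v[p])
    base_r <- if (length(higher_r) > 0L) {
      min(v[(p + 1L):(p + min(higher_r) - 1L)])
    } else if (length(right) > 0L) {
      min(right)
    } else {
      v[p]
    }
    v[p] - max(base_l, base_r)
  }, numeric(1L))
}

prune_by_separation <- function(idx, values, min_sep) {
  if (length(idx) <= 1L) {
    return(idx)
  }
  keep <- idx[order(values[idx], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in keep) {
    if (all(abs(chosen - i) >= min_sep)) chosen <- c(chosen, i)
  }
  sort(chosen)
}

# enforce strict peak/trough alternation, keeping the more extreme of runs
alternate_extrema <- function(peaks, troughs, v) {
  ev <- rbind(
    data.frame(idx = peaks, type = rep("peak", length(peaks))),
    data.frame(idx = troughs, type = rep("trough", length(troughs)))
  )
  ev <- ev[order(ev$idx), ]
  if (nrow(ev) == 0L) {
    return(list(peaks = integer(0), troughs = integer(0)))
  }
  out <- ev[1L, ]
  for (i in seq_len(nrow(ev))[-1L]) {
    last <- nrow(out)
    if (ev$type[i] == out$type[last]) {
      better <- if (ev$type[i] == "peak") {
        v[ev$idx[i]] > v[out$idx[last]]
      } else {
        v[ev$idx[i]] < v[out$idx[last]]
      }
      if (better) out[last, ] <- ev[i, ]
    } else {
      out <- rbind(out, ev[i, ])
    }
  }
  list(
    peaks = out$idx[out$type == "peak"],
    troughs = out$idx[out$type == "trough"]
  )
}

#' Detect movement cycles in a kinematic signal
#'
#' The signal is smoothed with a Savitzky-Golay filter, then local maxima
#' and minima are kept if their topographic prominence exceeds a fraction
#' of the signal range and they are separated by a minimum interval;
#' finally peaks and troughs are pruned to strict alternation.
#'
#' @param sig A [kin_signal()].
#' @param sg_window Savitzky-Golay window (odd frames; shrunk for short
#'   signals).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param min_prominence Minimum prominence as a fraction of the smoothed
#'   signal range (default 0.1).
#' @param min_separation_s Minimum spacing between same-type extrema in
#'   seconds.
#' @returns A list with integer vectors `peaks` and `troughs` (1-based
#'   sample indices into `sig$values`) and the `smoothed` series.
#' @export
find_cycles <- function(sig, sg_window = 11L, sg_order = 3L,
                        min_prominence = 0.1, min_separation_s = 0.1) {
  v <- sig$values
  n <- length(v)
  w <- min(sg_window, if (n %% 2L == 1L) n else n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  ord <- min(sg_order, w - 1L)
  sm <- if (w >= 3L && ord >= 1L) {
    as.numeric(signal::sgolayfilt(v, p = ord, n = w))
  } else {
    v
  }
  rng <- diff(range(sm))
  # a numerically flat signal has no cycles (filter round-off is not motion)
  if (!is.finite(rng) || rng <= 1e-9 * max(1, max(abs(sm)))) {
    rlang::abort("signal has no dynamic range; no cycles detectable",
      class = "kinscore_insufficient_cycles_error"
    )
  }
  ext <- local_extrema(sm)
  prom_thr <- min_prominence * rng
  peaks <- ext$max[peak_prominence(sm, ext$max) >= prom_thr]
  troughs <- ext$min[peak_prominence(-sm, ext$min) >= prom_thr]
  min_sep <- max(1L, round(min_separation_s * sig$fps))
  peaks <- prune_by_separation(peaks, sm, min_sep)
  troughs <- prune_by_separation(troughs, -sm, min_sep)
  alt <- alternate_extrema(peaks, troughs, sm)
  if (length(alt$peaks) < 2L) {
    rlang::abort("fewer than 2 movement cycles detected",
      class = "kinscore_insufficient_cycles_error"
    )
  }
  list(peaks = alt$peaks, troughs = alt$troughs, smoothed = sm)
}

band_periodogram <- function(v, fps, band = c(0.25, 10)) {
  if (length(v) < 8L || stats::sd(v) == 0) {
    return(NULL)
  }
  pg <- stats::spec.pgram(stats::ts(v, frequency = fps),
    taper = 0, detrend = TRUE, demean = TRUE, plot = FALSE
  )
  keep <- pg$freq >= band[1L] & pg$freq <= band[2L]
  if (!any(keep)) {
    return(NULL)
  }
  list(freq = pg$freq[keep], power = pg$spec[keep])
}

#' Extract the kinematic feature vector from a signal
#'
#' Computes the 12 canonical features (see [feature_names()]). Velocity,
#' acceleration and jerk are means of absolute 1st/2nd/3rd finite
#' differences of the movement signal scaled by powers of the sampling
#' rate. The dominant frequency is the power-weighted mean (spectral
#' centroid) of the detrended periodogram over 0.25-10 Hz, and `max_fft`
#' its maximum power. Cycle-based features come from [find_cycles()];
#' when fewer than two cycles exist they are `NA` (never silent zeros)
#' while the difference-based features are still computed.
#'
#' @param sig A [kin_signal()].
#' @param ... Passed to [find_cycles()].
#' @returns A one-row tibble with the 12 feature columns in fixed order.
#' @export
extract_features <- function(sig, ...) {
  v <- sig$values
  fps <- sig$fps
  d1 <- diff(v)
  d2 <- diff(v, differences = 2L)
  d3 <- if (length(v) > 3L) diff(v, differences = 3L) else numeric(0)

  out <- stats::setNames(
    as.list(rep(NA_real_, length(feature_names()))), feature_names()
  )
  out$avg_vel <- mean(abs(d1)) * fps
  out$avg_acc <- if (length(d2) > 0L) mean(abs(d2)) * fps^2 else NA_real_
  out$avg_jerk <- if (length(d3) > 0L) mean(abs(d3)) * fps^3 else NA_real_

  pg <- band_periodogram(v, fps)
  if (!is.null(pg)) {
    out$avg_freq <- sum(pg$freq * pg$power) / sum(pg$power)
    out$max_fft <- max(pg$power)
  }

  cyc <- tryCatch(find_cycles(sig, ...),
    kinscore_insufficient_cycles_error = function(e) NULL,
    kinscore_degenerate_error = function(e) NULL
  )
  if (!is.null(cyc)) {
    peaks <- cyc$peaks
    troughs <- cyc$troughs
    sm <- cyc$smoothed
    if (length(peaks) >= 2L) {
      ipi <- diff(peaks) / fps
      out$avg_peak_dist <- mean(ipi)
      out$period_range <- max(ipi) - min(ipi)
    }
    if (length(troughs) >= 2L) {
      out$avg_trough_dist <- mean(diff(troughs)) / fps
    }
    amps <- adjacent_amplitudes(sm, peaks, troughs)
    if (length(amps) >= 1L) {
      out$avg_amp <- mean(amps)
      out$amp_std <- if (length(amps) >= 2L) stats::sd(amps) else NA_real_
    }
    cyc_stats <- per_cycle_stats(v, sm, peaks, troughs, fps)
    if (!is.null(cyc_stats)) {
      out$dec_amp <- cyc_stats$dec_amp
      out$dec_vel <- cyc_stats$dec_vel
    }
  }
  tibble::as_tibble(out)
}

# peak-to-adjacent-trough amplitudes over the alternating extrema sequence
adjacent_amplitudes <- function(v, peaks, troughs) {
  ev <- sort(c(peaks, troughs))
  if (length(ev) < 2L) {
    return(numeric(0))
  }
  abs(diff(v[ev]))
}

per_cycle_stats <- function(v, sm, peaks, troughs, fps) {
  if (length(peaks) < 3L) {
    return(NULL)
  }
  m <- length(peaks) - 1L
  amp <- numeric(m)
  vel <- numeric(m)
  for (i in seq_len(m)) {
    lo <- peaks[i]
    hi <- peaks[i + 1L]
    seg <- v[lo:hi]
    tr <- troughs[troughs > lo & troughs < hi]
    amp[i] <- if (length(tr) > 0L) {
      sm[lo] - min(sm[tr])
    } else {
      max(seg) - min(seg)
    }
    vel[i] <- mean(abs(diff(seg))) * fps
  }
  idx <- seq_len(m)
  list(
    dec_amp = unname(stats::coef(stats::lm(amp ~ idx))[2L]),
    dec_vel = unname(stats::coef(stats::lm(vel ~ idx))[2L])
  )
}

#' Resample a signal to a fixed length by linear interpolation
#'
#' The temporal model consumes fixed-length inputs; signals of arbitrary
#' duration are linearly interpolated onto `length_out` equally spaced
#' points spanning the original support.
#'
#' @param sig A [kin_signal()].
#' @param length_out Target length (default 256).
#' @returns A numeric vector of length `length_out`.
#' @export
resample_signal <- function(sig, length_out = 256L) {
  v <- sig$values
  stats::approx(
    x = seq(0, 1, length.out = length(v)), y = v,
    xout = seq(0, 1, length.out = length_out)
  )$y
}
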