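# Movement segmentation and discrete event detection.

# Local maxima with topographic prominence and a refractory spacing rule.
# Plateaus and equal-height ties resolve to the earliest sample.
find_peaks <- function(x, t, min_height = -Inf, min_prominence = 0,
                       min_spacing = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0L))
  is_peak <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  is_peak <- is_peak[x[is_peak] >= min_height]
  if (length(is_peak) == 0L) return(integer(0L))
  prominence <- vapply(is_peak, function(i) {
    h <- x[i]
    lo_l <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      lo_l <- min(lo_l, x[j])
      j <- j - 1L
    }
    if (j < 1L) lo_l <- min(lo_l, min(x[1:i]))
    lo_r <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      lo_r <- min(lo_r, x[j])
      j <- j + 1L
    }
    if (j > n) lo_r <- min(lo_r, min(x[i:n]))
    h - max(lo_l, lo_r)
  }, numeric(1L))
  keep <- prominence >= min_prominence
  is_peak <- is_peak[keep]
  prominence <- prominence[keep]
  if (min_spacing > 0 && length(is_peak) > 1L) {
    # greedy by height, earliest wins on ties
    ord <- order(-x[is_peak], is_peak)
    chosen <- integer(0L)
    for (i in is_peak[ord]) {
      if (all(abs(t[i] - t[chosen]) >= min_spacing)) {
        chosen <- c(chosen, i)
      }
    }
    is_peak <- sort(chosen)
  }
  is_peak
}

peak_prominences <- function(x, idx) {
  vapply(idx, function(i) {
    n <- length(x)
    h <- x[i]
    lo_l <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      lo_l <- min(lo_l, x[j])
      j <- j - 1L
    }
    if (j < 1L) lo_l <- min(lo_l, min(x[1:i]))
    lo_r <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      lo_r <- min(lo_r, x[j])
      j <- j + 1L
    }
    if (j > n) lo_r <- min(lo_r, min(x[i:n]))
    h - max(lo_l, lo_r)
  }, numeric(1L))
}

segment_stats <- function(t, v, i0, i1) {
  vv <- v[i0:i1]
  tibble::tibble(
    t_start = t[i0], t_end = t[i1],
    duration = t[i1] - t[i0],
    mean_speed = mean(vv),
    max_speed = max(vv),
    smoothness = mean(vv) / max(vv)
  )
}

#' Segment a speed profile into elementary movements
#'
#' Candidate movements are the humps of the speed profile. Local speed
#' maxima (spaced at least `refractory` apart, above a 10% noise floor) are
#' found; the minimum between two adjacent maxima separates them into two
#' movements when it drops below `theta` times the smaller of the two peak
#' speeds, otherwise the maxima are merged into one movement. Segments run
#' minimum-to-minimum (outer segments extend to the window edges), so a
#' single minimum-jerk reach spans its whole duration and its smoothness
#' equals the closed-form mean/peak ratio 1/1.875. When
#' fewer than `expected_n` movements are found and a gyroscope stream is
#' supplied, boundaries are refined from zero crossings of the (5 Hz
#' low-passed) `gyro_x` component, which resolve merged movements in severely
#' bradykinetic profiles where speed minima stay above threshold.
#'
#' Segments whose speed contains missing samples (long camera drop-outs) are
#' excluded.
#'
#' @param profile Tibble from [speed_profile()] (`time_s`, `v`).
#' @param gyro Optional IMU tibble used for the fallback refinement.
#' @param expected_n Planned movement count from the task registry; only
#'   triggers the fallback, never forces a count.
#' @param theta Relative minima threshold (default 0.2).
#' @param refractory Minimum spacing between speed minima, seconds.
#' @param gyro_fs Gyroscope sampling rate, Hz.
#' @return Tibble with one row per movement: `t_start`, `t_end`, `duration`,
#'   `mean_speed`, `max_speed`, `smoothness`. Zero rows when no movement is
#'   found.
#' @export
segment_movements <- function(profile, gyro = NULL, expected_n = NULL,
                              theta = 0.2, refractory = 0.25, gyro_fs = 64) {
  t <- profile$time_s
  v <- profile$v
  ok <- !is.na(v)
  if (!any(ok) || max(v[ok]) <= 0) {
    return(segment_stats(t, v, 1L, 1L)[0L, ])
  }
  v0 <- v
  v0[!ok] <- 0
  segs <- segment_by_minima(t, v0, theta, refractory)
  if (!is.null(expected_n) && nrow(segs) < expected_n && !is.null(gyro)) {
    refined <- segment_by_gyro(t, v0, gyro, gyro_fs, refractory)
    if (nrow(refined) > nrow(segs)) segs <- refined
  }
  if (nrow(segs) == 0L) return(segs)
  # drop movements tainted by long camera drop-outs
  tainted <- vapply(seq_len(nrow(segs)), function(i) {
    anyNA(v[t >= segs$t_start[i] & t <= segs$t_end[i]])
  }, logical(1L))
  segs[!tainted, , drop = FALSE]
}

segment_by_minima <- function(t, v, theta, refractory) {
  vmax <- max(v)
  peaks <- find_peaks(v, t, min_height = 0.1 * vmax, min_spacing = refractory)
  empty <- segment_stats(t, v, 1L, 1L)[0L, ]
  if (length(peaks) == 0L) return(empty)
  # split adjacent peaks where the intervening minimum is deep enough
  groups <- list(peaks[1L])
  if (length(peaks) > 1L) {
    for (i in 2:length(peaks)) {
      a <- peaks[i - 1L]
      b <- peaks[i]
      vmin <- min(v[a:b])
      if (vmin < theta * min(v[a], v[b])) {
        groups <- c(groups, list(b))
      } else {
        groups[[length(groups)]] <- c(groups[[length(groups)]], b)
      }
    }
  }
  # segments run minimum-to-minimum: the qualifying minimum between two
  # groups is the shared boundary; the first/last segments extend to the
  # window edges (where the profile is itself minimal)
  out <- lapply(seq_along(groups), function(g) {
    g_peaks <- groups[[g]]
    i0 <- if (g == 1L) 1L else {
      prev <- groups[[g - 1L]]
      span <- prev[length(prev)]:g_peaks[1L]
      span[which.min(v[span])]
    }
    i1 <- if (g == length(groups)) length(v) else {
      nxt <- groups[[g + 1L]]
      span <- g_peaks[length(g_peaks)]:nxt[1L]
      span[which.min(v[span])]
    }
    segment_stats(t, v, i0, i1)
  })
  res <- dplyr::bind_rows(out)
  res[res$duration > 0, , drop = FALSE]
}

segment_by_gyro <- function(t, v, gyro, gyro_fs, refractory) {
  x <- lowpass_butter(gyro$gyro_x, gyro_fs, 5)
  s <- sign(x)
  zc <- which(s[-1L] != s[-length(s)] & s[-1L] != 0) + 1L
  times <- gyro$time_s[zc]
  if (length(times) > 1L) {
    times <- times[c(TRUE, diff(times) >= refractory)]
  }
  bounds <- unique(c(t[1L], times, t[length(t)]))
  bounds <- sort(bounds)
  empty <- segment_stats(t, v, 1L, 1L)[0L, ]
  if (length(bounds) < 2L) return(empty)
  vmax <- max(v)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    i0 <- which.min(abs(t - bounds[i]))
    i1 <- which.min(abs(t - bounds[i + 1L]))
    if (i1 - i0 < 2L) next
    if (max(v[i0:i1]) < 0.1 * vmax) next
    out <- c(out, list(segment_stats(t, v, i0, i1)))
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

#' Detect hand-fully-open events
#'
#' Hand openings register as positive peaks of the `gyro_x` angular-velocity
#' component. Candidate peaks above a 10% amplitude floor must have
#' prominence at least half the median candidate prominence and be spaced at
#' least `refractory` apart.
#'
#' @param imu IMU tibble (gyroscope low-passed at 5 Hz upstream).
#' @param refractory Minimum event spacing, seconds (default 0.25).
#' @return Tibble with a single `time_s` column of event times.
#' @export
detect_hand_open_events <- function(imu, refractory = 0.25) {
  x <- imu$gyro_x
  t <- imu$time_s
  if (length(x) == 0L || max(x) <= 0) {
    return(tibble::tibble(time_s = numeric(0L)))
  }
  # a 10% amplitude floor keeps sensor-noise maxima out of the prominence
  # median, which would otherwise be dominated by them
  cand <- find_peaks(x, t, min_height = 0.1 * max(x))
  if (length(cand) == 0L) return(tibble::tibble(time_s = numeric(0L)))
  prom <- peak_prominences(x, cand)
  keep <- cand[prom >= 0.5 * median(prom)]
  if (length(keep) > 1L) {
    ord <- order(-x[keep], keep)
    chosen <- integer(0L)
    for (i in keep[ord]) {
      if (all(abs(t[i] - t[chosen]) >= refractory)) chosen <- c(chosen, i)
    }
    keep <- sort(chosen)
  }
  tibble::tibble(time_s = t[keep])
}

#' Detect strides from an ankle gyroscope
#'
#' Strides register as peaks of the `gyro_z` angular-velocity component.
#' Peaks must exceed the signal mean plus `height_k_sd` standard deviations
#' and an absolute floor of `min_height` rad/s (swing-phase shank rotation
#' peaks sit well above it; a stride-free noise trace stays below), and be
#' spaced at least `refractory` apart (0.5 s by default, below any
#' plausible stride period).
#'
#' @param imu Ankle IMU tibble (gyroscope low-passed at 5 Hz upstream).
#' @param height_k_sd Peak height threshold in SD units above the mean.
#' @param min_height Absolute peak height floor, rad/s.
#' @param refractory Minimum peak spacing, seconds.
#' @return List with `times` (peak times), `durations` (successive
#'   differences, the stride durations) and `count`.
#' @export
detect_strides <- function(imu, height_k_sd = 1, min_height = 0.5,
                           refractory = 0.5) {
  x <- imu$gyro_z
  t <- imu$time_s
  thr <- max(mean(x) + height_k_sd * stats::sd(x), min_height)
  idx <- find_peaks(x, t, min_height = thr, min_spacing = refractory)
  times <- t[idx]
  list(times = times,
       durations = if (length(times) > 1L) diff(times) else numeric(0L),
       count = length(times))
}
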