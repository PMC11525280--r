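# The canonical 62-metric motor feature battery.
#
# Each per-task computation returns a named numeric vector whose names come
# from metric_inventory(); missing data yields NA (missingness is data, not
# failure). extract_metrics() assembles the full 62-element vector for one
# session.

affected_wrist <- function(side) {
  if (identical(side, "left")) "wrist_l" else "wrist_r"
}

named_na <- function(names) stats::setNames(rep(NA_real_, length(names)), names)

#' Reaching-task metrics
#'
#' For the elbow flexion/extension and hand-to-nose tasks: the wrist speed
#' profile is computed on the most-affected side, segmented into elementary
#' movements, and summarized as mean and SD of per-movement mean speed, max
#' speed, duration and smoothness, plus the movement count and the wrist
#' path length (sum of filtered position increments over the whole task
#' window).
#'
#' @param rec A [task_recording()] for T1A, T1B or T4.
#' @param prefix Metric-name prefix (`"t1a_"`, `"t1b_"` or `"t4_"`).
#' @return Named numeric vector of 10 metrics (NA where not computable).
#' @export
reach_metrics <- function(rec, prefix) {
  names_out <- paste0(prefix, c(
    "mean_speed_mean", "mean_speed_sd", "max_speed_mean", "max_speed_sd",
    "duration_mean", "duration_sd", "smoothness_mean", "smoothness_sd",
    "n_movements", "path_length"
  ))
  out <- named_na(names_out)
  win <- task_window(rec)
  rec <- crop_streams(rec, win)
  joint <- affected_wrist(rec$side)
  prof <- speed_profile(rec$camera, joint)
  reps <- task_registry()$repetitions[task_registry()$task == rec$task]
  segs <- segment_movements(prof, gyro = rec$imus$index_finger,
                            expected_n = reps)
  # path length over the full task window, on filtered positions
  cols <- paste0(joint, "_", c("x", "y", "z"))
  pos <- vapply(cols, function(cn) {
    x <- interp_short_gaps(rec$camera[[cn]])
    if (anyNA(x)) {
      ok <- which(!is.na(x))
      x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
    }
    lowpass_fir(x, 30, 10)
  }, numeric(nrow(rec$camera)))
  out[paste0(prefix, "path_length")] <-
    sum(sqrt(rowSums(diff(pos)^2)))
  out[paste0(prefix, "n_movements")] <- nrow(segs)
  if (nrow(segs) == 0L) {
    return(out)
  }
  out[paste0(prefix, "mean_speed_mean")] <- mean(segs$mean_speed)
  out[paste0(prefix, "mean_speed_sd")] <- stats::sd(segs$mean_speed)
  out[paste0(prefix, "max_speed_mean")] <- mean(segs$max_speed)
  out[paste0(prefix, "max_speed_sd")] <- stats::sd(segs$max_speed)
  out[paste0(prefix, "duration_mean")] <- mean(segs$duration)
  out[paste0(prefix, "duration_sd")] <- stats::sd(segs$duration)
  out[paste0(prefix, "smoothness_mean")] <- mean(segs$smoothness)
  out[paste0(prefix, "smoothness_sd")] <- stats::sd(segs$smoothness)
  out
}

#' Hand opening/closing metrics
#'
#' Movement time (total task time divided by the number of hand-open
#' events) and the mean and SD of the inter-peak interval between
#' consecutive hand-fully-open events, detected from the 5 Hz low-passed
#' `gyro_x` of the finger IMU.
#'
#' @param rec A [task_recording()] for T2A or T2B.
#' @param prefix `"t2a_"` or `"t2b_"`.
#' @return Named numeric vector of 3 metrics.
#' @export
open_close_metrics <- function(rec, prefix) {
  names_out <- paste0(prefix, c("movement_time", "ipi_mean", "ipi_sd"))
  out <- named_na(names_out)
  win <- task_window(rec)
  rec <- crop_streams(rec, win)
  imu <- rec$imus$index_finger
  if (is.null(imu) || nrow(imu) < 10L) return(out)
  imu$gyro_x <- lowpass_butter(imu$gyro_x, 64, 5)
  ev <- detect_hand_open_events(imu)
  if (nrow(ev) < 2L) return(out)
  ipi <- diff(ev$time_s)
  out[paste0(prefix, "movement_time")] <- diff(win) / nrow(ev)
  out[paste0(prefix, "ipi_mean")] <- mean(ipi)
  out[paste0(prefix, "ipi_sd")] <- stats::sd(ipi)
  out
}

#' Complex-sequence metric
#'
#' Total time to complete the multi-joint motor sequence, from the marker
#' window.
#'
#' @param rec A [task_recording()] for T3.
#' @return Named numeric vector with `t3_total_time` (seconds).
#' @export
complex_task_metric <- function(rec) {
  out <- named_na("t3_total_time")
  win <- tryCatch(task_window(rec), error = function(e) NULL)
  if (!is.null(win)) out["t3_total_time"] <- diff(win)
  out
}

#' Tremor band-power metrics
#'
#' Ratio of power in the tremor band to total power of the demeaned finger
#' acceleration amplitude, estimated both with DPSS multitaper spectra and
#' with a Hann-taper periodogram. The rest-tremor band is 3-6 Hz (T5A), the
#' postural band 5-8 Hz (T5B).
#'
#' @param rec A [task_recording()] for T5A or T5B.
#' @param prefix `"t5a_"` or `"t5b_"`.
#' @param min_duration Minimum usable signal length in seconds (default 10).
#' @return Named numeric vector of 2 metrics (ratios in `[0, 1]`).
#' @export
tremor_metrics <- function(rec, prefix, min_duration = 10) {
  names_out <- paste0(prefix, c("power_ratio_mt", "power_ratio_fft"))
  out <- named_na(names_out)
  band <- if (identical(prefix, "t5a_")) c(3, 6) else c(5, 8)
  win <- task_window(rec)
  rec <- crop_streams(rec, win)
  imu <- rec$imus$index_finger
  if (is.null(imu) || nrow(imu) < min_duration * 64) return(out)
  amp <- accel_amplitude(imu)
  out[paste0(prefix, "power_ratio_mt")] <-
    band_power_ratio(amp, 64, band, method = "multitaper")
  out[paste0(prefix, "power_ratio_fft")] <-
    band_power_ratio(amp, 64, band, method = "fft")
  out
}

#' Auxiliary tremor band-power summaries
#'
#' Alternative tremor quantifications explored alongside the canonical
#' power ratios: the mean spectral power inside the tremor band and the
#' mean total power (0.5 Hz to Nyquist), from both the multitaper and the
#' Hann-periodogram estimates. These are auxiliary outputs — they are not
#' part of the 62-metric inventory.
#'
#' @inheritParams tremor_metrics
#' @return Named numeric vector of 4 values
#'   (`*_mean_band_power_{mt,fft}`, `*_mean_total_power_{mt,fft}`).
#' @export
tremor_aux_metrics <- function(rec, prefix, min_duration = 10) {
  names_out <- paste0(prefix, c("mean_band_power_mt", "mean_total_power_mt",
                                "mean_band_power_fft", "mean_total_power_fft"))
  out <- named_na(names_out)
  band <- if (identical(prefix, "t5a_")) c(3, 6) else c(5, 8)
  win <- task_window(rec)
  rec <- crop_streams(rec, win)
  imu <- rec$imus$index_finger
  if (is.null(imu) || nrow(imu) < min_duration * 64) return(out)
  amp <- accel_amplitude(imu)
  for (method in c("multitaper", "fft")) {
    spec <- power_spectrum(amp, 64, method = method)
    inband <- spec$freq >= band[1L] & spec$freq <= band[2L]
    total <- spec$freq >= 0.5
    tag <- if (method == "multitaper") "mt" else "fft"
    out[paste0(prefix, "mean_band_power_", tag)] <- mean(spec$power[inband])
    out[paste0(prefix, "mean_total_power_", tag)] <- mean(spec$power[total])
  }
  out
}

cop_ellipse <- function(cop_ml, cop_ap, level = 0.95) {
  # 95% covariance ellipse: axis length 2 * sqrt(q * eigenvalue), with q the
  # chi-squared(2) quantile at the requested level (5.991 for 95%).
  q <- stats::qchisq(level, df = 2)
  s <- stats::cov(cbind(cop_ml, cop_ap))
  ev <- eigen(s, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  list(
    major = 2 * sqrt(q * ev[1L]),
    minor = 2 * sqrt(q * ev[2L]),
    area = pi * q * sqrt(ev[1L] * ev[2L])
  )
}

#' Balance-task metrics
#'
#' Center-of-pressure sway metrics from the force plate (path length, SD of
#' the antero-posterior and medio-lateral components, and 95% covariance
#' ellipse axes and area) plus trunk smoothness metrics (mean and peak jerk
#' amplitude from the 5 Hz low-passed AP/ML acceleration of the L5 IMU).
#'
#' @param rec A [task_recording()] for T6_EO or T6_EC.
#' @param prefix `"t6_eo_"` or `"t6_ec_"`.
#' @return Named numeric vector of 8 metrics.
#' @export
balance_metrics <- function(rec, prefix) {
  names_out <- paste0(prefix, c(
    "cop_path_length", "cop_sd_ap", "cop_sd_ml",
    "ellipse_major", "ellipse_minor", "ellipse_area",
    "jerk_mean", "jerk_peak"
  ))
  out <- named_na(names_out)
  win <- task_window(rec)
  rec <- crop_streams(rec, win)
  if (!is.null(rec$plate) && nrow(rec$plate) > 3L) {
    ml <- rec$plate$cop_ml_cm
    ap <- rec$plate$cop_ap_cm
    out[paste0(prefix, "cop_path_length")] <-
      sum(sqrt(diff(ml)^2 + diff(ap)^2))
    out[paste0(prefix, "cop_sd_ap")] <- stats::sd(ap)
    out[paste0(prefix, "cop_sd_ml")] <- stats::sd(ml)
    ell <- cop_ellipse(ml, ap)
    out[paste0(prefix, "ellipse_major")] <- ell$major
    out[paste0(prefix, "ellipse_minor")] <- ell$minor
    out[paste0(prefix, "ellipse_area")] <- ell$area
  }
  l5 <- rec$imus$L5
  if (!is.null(l5) && nrow(l5) > 64L) {
    # convention: accel_x medio-lateral, accel_z antero-posterior
    ap <- lowpass_butter(l5$accel_z, 64, 5)
    ml <- lowpass_butter(l5$accel_x, 64, 5)
    js <- jerk_stats(ap, ml, 64)
    out[paste0(prefix, "jerk_mean")] <- js$mean
    out[paste0(prefix, "jerk_peak")] <- js$peak
  }
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Gait metrics from the four 10 m walks
#'
#' `gait_total_walk_time` is the mean marker-window duration across the
#' walks. `gait_normalized_jerk` averages, over walks 1-2, the mean L5 jerk
#' amplitude divided by mean walking speed (10 m divided by walk time).
#' Stride duration mean/SD and stride count are averaged over walks 3-4 from
#' the most-affected-side ankle gyroscope; the averaged count is rounded
#' half-up to stay an integer.
#'
#' @param recs Named list of available walk recordings (`T7_W1`..`T7_W4`).
#' @param side Most-affected side (`"left"` or `"right"`).
#' @param walk_distance_m Walk length in meters (default 10).
#' @return Named numeric vector of 5 metrics.
#' @export
gait_metrics <- function(recs, side = "right", walk_distance_m = 10) {
  names_out <- paste0("gait_", c(
    "total_walk_time", "normalized_jerk",
    "stride_duration_mean", "stride_duration_sd", "stride_count"
  ))
  out <- named_na(names_out)
  walks <- c("T7_W1", "T7_W2", "T7_W3", "T7_W4")
  times <- vapply(walks, function(w) {
    if (is.null(recs[[w]])) return(NA_real_)
    diff(task_window(recs[[w]]))
  }, numeric(1L))
  if (any(!is.na(times))) {
    out["gait_total_walk_time"] <- mean(times, na.rm = TRUE)
  }
  nj <- vapply(c("T7_W1", "T7_W2"), function(w) {
    rec <- recs[[w]]
    if (is.null(rec)) return(NA_real_)
    rec <- crop_streams(rec, task_window(rec))
    l5 <- rec$imus$L5
    if (is.null(l5) || nrow(l5) < 64L) return(NA_real_)
    ap <- lowpass_butter(l5$accel_z, 64, 5)
    ml <- lowpass_butter(l5$accel_x, 64, 5)
    js <- jerk_stats(ap, ml, 64)
    speed <- walk_distance_m / (diff(task_window(recs[[w]])))
    js$mean / speed
  }, numeric(1L))
  if (any(!is.na(nj))) out["gait_normalized_jerk"] <- mean(nj, na.rm = TRUE)
  ankle <- if (identical(side, "left")) "ankle_left" else "ankle_right"
  per_walk <- lapply(c("T7_W3", "T7_W4"), function(w) {
    rec <- recs[[w]]
    if (is.null(rec)) return(NULL)
    rec <- crop_streams(rec, task_window(rec))
    imu <- rec$imus[[ankle]]
    if (is.null(imu)) imu <- rec$imus[[setdiff(c("ankle_left", "ankle_right"), ankle)]]
    if (is.null(imu) || nrow(imu) < 64L) return(NULL)
    imu$gyro_z <- lowpass_butter(imu$gyro_z, 64, 5)
    st <- detect_strides(imu)
    c(mean = if (length(st$durations)) mean(st$durations) else NA_real_,
      sd = if (length(st$durations) > 1L) stats::sd(st$durations) else NA_real_,
      count = st$count)
  })
  per_walk <- per_walk[!vapply(per_walk, is.null, logical(1L))]
  if (length(per_walk) > 0L) {
    m <- do.call(rbind, per_walk)
    out["gait_stride_duration_mean"] <- mean(m[, "mean"], na.rm = TRUE)
    out["gait_stride_duration_sd"] <- mean(m[, "sd"], na.rm = TRUE)
    out["gait_stride_count"] <- round_half_up(mean(m[, "count"], na.rm = TRUE))
  }
  out
}

task_metrics <- function(sess, task) {
  rec <- sess$recordings[[task]]
  fn <- switch(task,
    T1A = function(r) reach_metrics(r, "t1a_"),
    T1B = function(r) reach_metrics(r, "t1b_"),
    T2A = function(r) open_close_metrics(r, "t2a_"),
    T2B = function(r) open_close_metrics(r, "t2b_"),
    T3 = complex_task_metric,
    T4 = function(r) reach_metrics(r, "t4_"),
    T5A = function(r) tremor_metrics(r, "t5a_"),
    T5B = function(r) tremor_metrics(r, "t5b_"),
    T6_EO = function(r) balance_metrics(r, "t6_eo_"),
    T6_EC = function(r) balance_metrics(r, "t6_ec_")
  )
  inv <- metric_inventory()
  nm <- inv$metric[inv$task == task]
  if (is.null(rec)) return(named_na(nm))
  tryCatch(fn(rec), error = function(e) named_na(nm))
}

#' Extract the 62-metric vector for one session
#'
#' Runs every per-task metric computation and assembles the canonical
#' 62-element feature vector. Metrics whose inputs are absent or degenerate
#' are `NA` (flagged missing), never dropped: the output always has exactly
#' the 62 columns of [metric_inventory()].
#'
#' @param sess A validated [session()].
#' @return One-row tibble: `subject_id`, `visit_day`, then the 62 metrics.
#' @export
#' @seealso [extract_cohort()] for many sessions, [metric_inventory()] for
#'   names and units.
extract_metrics <- function(sess) {
  if (!inherits(sess, "pd_session")) {
    abort_validation("extract_metrics expects a pd_session")
  }
  # per-task stream requirements degrade to missing metrics here (the strict
  # registry check lives in read_session/validate_session)
  vals <- named_na(metric_names())
  for (task in c("T1A", "T1B", "T2A", "T2B", "T3", "T4",
                 "T5A", "T5B", "T6_EO", "T6_EC")) {
    v <- task_metrics(sess, task)
    vals[names(v)] <- v
  }
  walks <- sess$recordings[intersect(names(sess$recordings),
                                     c("T7_W1", "T7_W2", "T7_W3", "T7_W4"))]
  if (length(walks) > 0L) {
    g <- tryCatch(gait_metrics(walks, side = sess$side),
                  error = function(e) named_na(grep("^gait_", metric_names(),
                                                    value = TRUE)))
    vals[names(g)] <- g
  }
  dplyr::bind_cols(
    tibble::tibble(subject_id = sess$subject_id, visit_day = sess$visit_day),
    tibble::as_tibble(as.list(vals))
  )
}

#' Extract metrics for a cohort of sessions
#'
#' @param sessions List of [session()] objects, or a character vector of
#'   session directories to read.
#' @return Tibble with one row per session and the 62 metric columns.
#' @export
extract_cohort <- function(sessions) {
  if (is.character(sessions)) {
    sessions <- lapply(sessions, read_session)
  }
  dplyr::bind_rows(lapply(sessions, extract_metrics))
}

#' Metric table as a matrix plus missingness mask
#'
#' @param metrics Tibble from [extract_cohort()].
#' @return List with `x` (numeric matrix, subjects x 62) and `missing`
#'   (logical mask of the same shape).
#' @export
metric_matrix <- function(metrics) {
  x <- as.matrix(metrics[metric_names()])
  rownames(x) <- metrics$subject_id
  list(x = x, missing = is.na(x))
}

#' Write a cohort metric table
#'
#' One row per subject-visit with the 62 metric columns followed by 62
#' `missing_*` flag columns.
#'
#' @param metrics Tibble from [extract_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  flags <- metrics[metric_names()]
  names(flags) <- paste0("missing_", names(flags))
  flags[] <- lapply(flags, is.na)
  readr::write_csv(dplyr::bind_cols(metrics, flags), path, progress = FALSE)
  invisible(path)
}
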