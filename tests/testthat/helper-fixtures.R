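# Shared fixture builders and a per-run cohort cache. Everything is built in
# code at test time; no stored data.

marker_tbl <- function(times, labels = NULL) {
  tibble::tibble(
    time_s = times,
    label = labels %||% rep("event", length(times))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Camera stream where one wrist follows `wrist_y` and every other joint is
# static; all 20 joints present.
camera_tbl <- function(t, wrist_y = NULL, wrist_x = NULL, joint = "wrist_r") {
  joints <- skeleton_joints()
  cols <- list(time_s = t)
  for (j in joints) {
    cols[[paste0(j, "_x")]] <- rep(0, length(t))
    cols[[paste0(j, "_y")]] <- rep(1, length(t))
    cols[[paste0(j, "_z")]] <- rep(2, length(t))
  }
  if (!is.null(wrist_y)) cols[[paste0(joint, "_y")]] <- wrist_y
  if (!is.null(wrist_x)) cols[[paste0(joint, "_x")]] <- wrist_x
  tibble::as_tibble(cols)
}

imu_tbl <- function(t, gyro_x = 0, gyro_y = 0, gyro_z = 0,
                    accel_x = 0, accel_y = 0, accel_z = 0) {
  n <- length(t)
  rep_n <- function(v) if (length(v) == 1L) rep(v, n) else v
  tibble::tibble(
    time_s = t,
    gyro_x = rep_n(gyro_x), gyro_y = rep_n(gyro_y), gyro_z = rep_n(gyro_z),
    accel_x = rep_n(accel_x), accel_y = rep_n(accel_y), accel_z = rep_n(accel_z)
  )
}

plate_tbl <- function(t, ml, ap) {
  tibble::tibble(time_s = t, cop_ml_cm = ml, cop_ap_cm = ap)
}

# Minimum-jerk speed profile: peak = 1.875 d / T, mean over [0, T] = d / T.
min_jerk_speed <- function(t, T_move, d) {
  tau <- pmin(pmax(t / T_move, 0), 1)
  30 * tau^2 * (1 - tau)^2 * d / T_move
}

# Cohort cache: full-session simulation is the dominant test cost, so
# cohorts are simulated once per configuration and reused across tests.
# Only the small summary tables are retained — holding the raw session
# streams of many 50-subject cohorts would balloon the heap and throttle
# the whole suite through garbage collection.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n = 50L, seed = 7L, phenotypes = 0L, day2 = FALSE) {
  key <- paste(n, seed, phenotypes, day2, sep = "_")
  hit <- .cohort_cache[[key]]
  if (!is.null(hit)) return(hit)
  cohort <- simulate_cohort(sim_config(n_subjects = n, seed = seed,
                                       phenotypes = phenotypes, day2 = day2))
  out <- list(
    metrics = extract_cohort(cohort$sessions),
    updrs = cohort$updrs,
    truth = cohort$truth
  )
  rm(cohort)
  gc(verbose = FALSE)
  .cohort_cache[[key]] <- out
  out
}

metric_cols <- function(metrics) metrics[metric_inventory()$metric]
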