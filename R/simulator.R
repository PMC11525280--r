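# Synthetic-session simulator.
#
# Generates task-structured multimodal recordings for the full 14-recording
# protocol with severity-dependent kinematics, plus UPDRS-III exams ordinally
# linked to the same latent severities. Five latent severities in [0, 1]
# drive the generator: bradykinesia, rest tremor, postural tremor, postural
# instability, and gait impairment. The mapping is deliberately simple and
# fully documented so parameter-recovery analyses are well defined.

#' Severity profile
#'
#' @param s_brady,s_trem_rest,s_trem_post,s_postural,s_gait Latent symptom
#'   severities, each in `[0, 1]`.
#' @return Named numeric vector of the five severities.
#' @export
severity_profile <- function(s_brady = 0, s_trem_rest = 0, s_trem_post = 0,
                             s_postural = 0, s_gait = 0) {
  out <- c(s_brady = unname(s_brady), s_trem_rest = unname(s_trem_rest),
           s_trem_post = unname(s_trem_post), s_postural = unname(s_postural),
           s_gait = unname(s_gait))
  if (any(out < 0 | out > 1)) {
    rlang::abort("severities must lie in [0, 1]",
                 class = "pdmotor_validation_error")
  }
  out
}

#' Simulator configuration
#'
#' Generator constants with documented defaults. Movement durations,
#' amplitudes and noise levels are chosen so that extracted metric
#' magnitudes fall in clinically plausible ranges (reach speeds roughly
#' 0.5-1.6 m/s, eyes-open sway paths roughly 20-80 cm, stride times
#' 1.0-1.4 s across the severity range).
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param reps Planned repetitions for the repeated-movement tasks.
#' @param balance_s Balance-hold duration, seconds.
#' @param walk_distance_m Walk length, meters.
#' @param rest_hold_s,postural_hold_s Tremor-hold durations, seconds.
#' @param camera_noise_m Camera position noise SD, meters.
#' @param gyro_noise,accel_noise IMU white-noise SDs (rad/s, m/s^2).
#' @param pink_noise_accel 1/f sensor-noise SD on tremor channels, m/s^2.
#' @param rater_noise_sd Per-item UPDRS rater noise SD (score points); the
#'   default 0.8 corresponds to roughly 3 points of noise on the 14-item
#'   total.
#' @param severity_link_sd SD of the domain-severity jitter around the
#'   latent global severity.
#' @param phenotypes Number of planted phenotype groups (0 = none; 3 plants
#'   tremor-heavy, bradykinesia-heavy and instability-heavy groups).
#' @param phenotype_gap Severity gap between a group's dominant domain and
#'   the background level.
#' @param day2 Also simulate a second visit (severity drift SD
#'   `day2_drift_sd`).
#' @param day2_drift_sd Between-visit severity drift SD.
#' @return A list of class `pd_sim_config`.
#' @export
sim_config <- function(n_subjects = 50L, seed = 1L, reps = 10L,
                       balance_s = 15, walk_distance_m = 10,
                       rest_hold_s = 30, postural_hold_s = 15,
                       camera_noise_m = 0.001, gyro_noise = 0.05,
                       accel_noise = 0.005, pink_noise_accel = 0.02,
                       rater_noise_sd = 0.8, severity_link_sd = 0.15,
                       phenotypes = 0L, phenotype_gap = 0.6,
                       day2 = FALSE, day2_drift_sd = 0.05) {
  structure(as.list(environment()), class = "pd_sim_config")
}

clip01 <- function(x) pmin(1, pmax(0, x))

# 1/f (pink) sensor noise via spectral shaping.
pink_noise <- function(n, sd) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- c(1, seq_len(n - 1L))
  shaped <- Re(stats::fft(f / sqrt(k), inverse = TRUE)) / n
  sd * shaped / stats::sd(shaped)
}

# Minimum-jerk position profile over tau in [0, 1].
min_jerk_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

empty_camera <- function(t, cfg) {
  joints <- skeleton_joints()
  # rough seated anatomy; only the tracked wrist carries task motion
  base <- c(
    hip_center = 0, spine = 0, shoulder_center = 0, head = 0,
    shoulder_l = -0.2, shoulder_r = 0.2, elbow_l = -0.25, elbow_r = 0.25,
    wrist_l = -0.3, wrist_r = 0.3, hand_l = -0.32, hand_r = 0.32,
    hip_l = -0.1, hip_r = 0.1, knee_l = -0.12, knee_r = 0.12,
    ankle_l = -0.12, ankle_r = 0.12, foot_l = -0.12, foot_r = 0.12
  )
  base_y <- c(
    hip_center = 0.5, spine = 0.7, shoulder_center = 0.95, head = 1.15,
    shoulder_l = 0.95, shoulder_r = 0.95, elbow_l = 0.75, elbow_r = 0.75,
    wrist_l = 0.6, wrist_r = 0.6, hand_l = 0.58, hand_r = 0.58,
    hip_l = 0.5, hip_r = 0.5, knee_l = 0.3, knee_r = 0.3,
    ankle_l = 0.05, ankle_r = 0.05, foot_l = 0.0, foot_r = 0.0
  )
  n <- length(t)
  cols <- list(time_s = t)
  for (j in joints) {
    cols[[paste0(j, "_x")]] <- base[[j]] + stats::rnorm(n, 0, cfg$camera_noise_m)
    cols[[paste0(j, "_y")]] <- base_y[[j]] + stats::rnorm(n, 0, cfg$camera_noise_m)
    cols[[paste0(j, "_z")]] <- 2.0 + stats::rnorm(n, 0, cfg$camera_noise_m)
  }
  tibble::as_tibble(cols)
}

imu_stream <- function(t, cfg, gyro = NULL, accel = NULL) {
  n <- length(t)
  zero <- function(m) if (is.null(m)) matrix(0, n, 3L) else m
  g <- zero(gyro)
  a <- zero(accel)
  tibble::tibble(
    time_s = t,
    gyro_x = g[, 1L] + stats::rnorm(n, 0, cfg$gyro_noise),
    gyro_y = g[, 2L] + stats::rnorm(n, 0, cfg$gyro_noise),
    gyro_z = g[, 3L] + stats::rnorm(n, 0, cfg$gyro_noise),
    accel_x = a[, 1L] + stats::rnorm(n, 0, cfg$accel_noise),
    accel_y = a[, 2L] + stats::rnorm(n, 0, cfg$accel_noise),
    accel_z = a[, 3L] + stats::rnorm(n, 0, cfg$accel_noise)
  )
}

marker_at <- function(t0, t1) {
  tibble::tibble(time_s = c(t0, t1), label = c("task_start", "task_end"))
}

# Wrist displacement trace for a repeated reaching task: alternating
# minimum-jerk strokes of amplitude `d` and duration `T_move`, separated by
# holds of `pause` seconds.
reach_trace <- function(t, reps, d, T_move, pause, t0) {
  pos <- numeric(length(t))
  level <- 0
  cursor <- t0
  for (r in seq_len(reps)) {
    dir <- if (r %% 2L == 1L) 1 else -1
    in_move <- t >= cursor & t < cursor + T_move
    tau <- (t[in_move] - cursor) / T_move
    pos[in_move] <- level + dir * d * min_jerk_pos(tau)
    level <- level + dir * d
    pos[t >= cursor + T_move] <- level
    cursor <- cursor + T_move + pause
  }
  pos
}

simulate_reach_task <- function(task, s, cfg) {
  T_move <- 0.4 * (1 + 1.5 * s[["s_brady"]])
  pause <- switch(task, T1A = 0.1, T1B = 2.0, T4 = 0.3)
  amp <- switch(task, T1A = 0.35, T1B = 0.35, T4 = 0.45)
  if (task == "T4") T_move <- T_move * 1.3
  dur <- cfg$reps * (T_move + pause)
  t_cam <- seq(0, dur + 1, by = 1 / 30)
  cam <- empty_camera(t_cam, cfg)
  y <- reach_trace(t_cam, cfg$reps, amp, T_move, pause, t0 = 0.5)
  trem <- 0.001 * s[["s_trem_post"]] *
    sin(2 * pi * 6 * t_cam + stats::runif(1, 0, 2 * pi))
  cam$wrist_r_y <- cam$wrist_r_y + y + trem
  cam$wrist_l_y <- cam$wrist_l_y + y + trem
  cam$hand_r_y <- cam$hand_r_y + y
  cam$hand_l_y <- cam$hand_l_y + y
  t_imu <- seq(0, dur + 1, by = 1 / 64)
  # forearm rotation roughly proportional to wrist velocity
  y_imu <- reach_trace(t_imu, cfg$reps, amp, T_move, pause, t0 = 0.5)
  gx <- derivative(y_imu, 64) / 0.25
  imu <- imu_stream(t_imu, cfg, gyro = cbind(gx, 0 * gx, 0 * gx))
  task_recording(task, camera = cam, imus = list(index_finger = imu),
                 marker = marker_at(0.5, 0.5 + dur))
}

simulate_open_close_task <- function(task, s, cfg) {
  period <- 0.5 * (1 + s[["s_brady"]])
  dur <- cfg$reps * period
  t_imu <- seq(0, dur + 1, by = 1 / 64)
  phase <- (t_imu - 0.5) / period
  burst <- ifelse(phase >= 0 & phase < cfg$reps,
                  pmax(0, sin(2 * pi * phase - pi / 2) + 1) / 2, 0)
  gx <- 3 * burst^2
  imu <- imu_stream(t_imu, cfg, gyro = cbind(gx, 0 * gx, 0 * gx))
  t_cam <- seq(0, dur + 1, by = 1 / 30)
  cam <- empty_camera(t_cam, cfg)
  task_recording(task, camera = cam, imus = list(index_finger = imu),
                 marker = marker_at(0.5, 0.5 + dur))
}

simulate_complex_task <- function(s, cfg) {
  dur <- 18 * (1 + 1.2 * s[["s_brady"]])
  t_cam <- seq(0, dur + 1, by = 1 / 30)
  cam <- empty_camera(t_cam, cfg)
  cam$wrist_r_y <- cam$wrist_r_y +
    0.15 * sin(2 * pi * t_cam / (1 + s[["s_brady"]]))
  cam$wrist_l_y <- cam$wrist_l_y +
    0.15 * sin(2 * pi * t_cam / (1 + s[["s_brady"]]))
  t_imu <- seq(0, dur + 1, by = 1 / 64)
  imu <- imu_stream(t_imu, cfg)
  task_recording("T3", camera = cam, imus = list(index_finger = imu),
                 marker = marker_at(0.5, 0.5 + dur))
}

simulate_tremor_task <- function(task, s, cfg) {
  hold <- if (task == "T5A") cfg$rest_hold_s else cfg$postural_hold_s
  freq <- if (task == "T5A") stats::runif(1, 3.5, 5.5) else stats::runif(1, 5.5, 7.5)
  sev <- if (task == "T5A") s[["s_trem_rest"]] else s[["s_trem_post"]]
  t_imu <- seq(0, hold + 1, by = 1 / 64)
  n <- length(t_imu)
  tremor <- 2 * sev * sin(2 * pi * freq * t_imu + stats::runif(1, 0, 2 * pi))
  # gravity mostly along x so the tremor survives the amplitude demeaning
  accel <- cbind(
    9.0 + tremor + pink_noise(n, cfg$pink_noise_accel),
    2.0 + pink_noise(n, cfg$pink_noise_accel),
    3.2 + pink_noise(n, cfg$pink_noise_accel)
  )
  imu <- imu_stream(t_imu, cfg, accel = accel)
  t_cam <- seq(0, hold + 1, by = 1 / 30)
  cam <- empty_camera(t_cam, cfg)
  task_recording(task, camera = cam, imus = list(index_finger = imu),
                 marker = marker_at(0.5, 0.5 + hold))
}

# Mean-reverting (Ornstein-Uhlenbeck) planar random walk for the CoP, cm.
simulate_cop <- function(t, sigma, theta = 1.0) {
  n <- length(t)
  dt <- diff(t[1:2])
  x <- numeric(n)
  y <- numeric(n)
  for (i in 2:n) {
    x[i] <- x[i - 1L] - theta * x[i - 1L] * dt + sigma * sqrt(dt) * stats::rnorm(1)
    y[i] <- y[i - 1L] - theta * y[i - 1L] * dt + sigma * sqrt(dt) * stats::rnorm(1)
  }
  cbind(ml = x, ap = y)
}

simulate_balance_task <- function(task, s, cfg) {
  mult <- if (task == "T6_EC") 1.5 else 1.0
  sigma <- 0.09 * (1 + 4 * s[["s_postural"]]) * mult
  dur <- cfg$balance_s
  t_fp <- seq(0, dur + 1, by = 1 / 98)
  cop <- simulate_cop(t_fp, sigma)
  plate <- tibble::tibble(time_s = t_fp, cop_ml_cm = cop[, "ml"],
                          cop_ap_cm = cop[, "ap"])
  t_imu <- seq(0, dur + 1, by = 1 / 64)
  n <- length(t_imu)
  sway_sd <- (0.003 + 0.025 * s[["s_postural"]]) * mult
  accel <- cbind(stats::rnorm(n, 0, sway_sd), 9.81 + stats::rnorm(n, 0, 0.01),
                 stats::rnorm(n, 0, sway_sd))
  imu <- imu_stream(t_imu, cfg, accel = accel)
  task_recording(task, imus = list(L5 = imu), plate = plate,
                 marker = marker_at(0.5, 0.5 + dur))
}

simulate_walk_task <- function(task, s, cfg) {
  walk_time <- cfg$walk_distance_m / (1.4 * (1 - 0.5 * s[["s_gait"]]))
  stride_period <- 1.0 * (1 + 0.4 * s[["s_gait"]])
  t_imu <- seq(0, walk_time + 1, by = 1 / 64)
  n <- length(t_imu)
  stride_times <- seq(0.8, 0.5 + walk_time - 0.3, by = stride_period)
  gz <- numeric(n)
  for (st in stride_times) {
    gz <- gz + 2.5 * exp(-(t_imu - st)^2 / (2 * 0.05^2))
  }
  step_freq <- 2 / stride_period
  amp_ap <- 1.2
  accel <- cbind(
    0.4 * sin(2 * pi * step_freq * t_imu),
    9.81 + stats::rnorm(n, 0, 0.02),
    amp_ap * sin(2 * pi * step_freq * t_imu + stats::runif(1, 0, 2 * pi))
  )
  imus <- list(L5 = imu_stream(t_imu, cfg, accel = accel))
  ankle_imu <- imu_stream(t_imu, cfg, gyro = cbind(0 * gz, 0 * gz, gz))
  if (task %in% c("T7_W3", "T7_W4")) {
    imus$ankle_right <- ankle_imu
    imus$ankle_left <- imu_stream(t_imu, cfg, gyro = cbind(0 * gz, 0 * gz, gz))
  } else {
    imus$ankle_right <- ankle_imu
  }
  task_recording(task, imus = imus, marker = marker_at(0.5, 0.5 + walk_time))
}

#' Simulate one subject-visit session
#'
#' Generates all 14 task recordings with kinematics driven by the severity
#' profile: minimum-jerk reaches slowed by bradykinesia (movement duration
#' `0.4 * (1 + 1.5 * s_brady)` s), hand open/close bursts with period
#' `0.5 * (1 + s_brady)` s, 3-6 Hz rest and 5-8 Hz postural tremor on the
#' finger accelerometer with amplitude proportional to the tremor
#' severities plus 1/f sensor noise, center-of-pressure sway as a
#' mean-reverting random walk with diffusion proportional to
#' `1 + 4 * s_postural` (eyes-closed multiplier 1.5), and gait as
#' Gaussian-windowed `gyro_z` bursts with stride period
#' `1 + 0.4 * s_gait` s and walk time `10 / (1.4 * (1 - 0.5 * s_gait))` s.
#' Marker events sit at the true task bounds.
#'
#' @param profile A [severity_profile()].
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param subject_id,visit_day Session metadata.
#' @return A validated [session()].
#' @export
simulate_subject <- function(profile, config = sim_config(), seed = 1L,
                             subject_id = "S001", visit_day = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  recs <- list()
  for (task in c("T1A", "T1B", "T4")) {
    recs[[task]] <- simulate_reach_task(task, profile, config)
  }
  for (task in c("T2A", "T2B")) {
    recs[[task]] <- simulate_open_close_task(task, profile, config)
  }
  recs$T3 <- simulate_complex_task(profile, config)
  for (task in c("T5A", "T5B")) {
    recs[[task]] <- simulate_tremor_task(task, profile, config)
  }
  for (task in c("T6_EO", "T6_EC")) {
    recs[[task]] <- simulate_balance_task(task, profile, config)
  }
  for (task in c("T7_W1", "T7_W2", "T7_W3", "T7_W4")) {
    recs[[task]] <- simulate_walk_task(task, profile, config)
  }
  recs <- recs[task_ids()]
  out <- session(subject_id, visit_day, recs, side = "right")
  validate_session(out)
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Fixed item-weight matrix linking the five severities to the 14 items.
# Rows sum to 1 so a fully severe profile scores 4 on every item.
updrs_weights <- function() {
  w <- rbind(
    Q18 = c(0.4, 0.1, 0.1, 0.2, 0.2),  # speech
    Q19 = c(0.8, 0.1, 0.1, 0.0, 0.0),  # facial expression
    Q20 = c(0.0, 1.0, 0.0, 0.0, 0.0),  # tremor at rest
    Q21 = c(0.0, 0.0, 1.0, 0.0, 0.0),  # action/postural tremor
    Q22 = c(0.5, 0.2, 0.1, 0.1, 0.1),  # rigidity (mixed)
    Q23 = c(1.0, 0.0, 0.0, 0.0, 0.0),  # finger taps
    Q24 = c(1.0, 0.0, 0.0, 0.0, 0.0),  # hand movements
    Q25 = c(1.0, 0.0, 0.0, 0.0, 0.0),  # rapid alternating movements
    Q26 = c(0.8, 0.0, 0.0, 0.0, 0.2),  # leg agility
    Q27 = c(0.2, 0.0, 0.0, 0.5, 0.3),  # arising from chair
    Q28 = c(0.0, 0.0, 0.0, 0.8, 0.2),  # posture
    Q29 = c(0.0, 0.0, 0.0, 0.2, 0.8),  # gait
    Q30 = c(0.0, 0.0, 0.0, 0.8, 0.2),  # postural stability
    Q31 = c(0.8, 0.0, 0.0, 0.1, 0.1)   # body bradykinesia
  )
  colnames(w) <- names(severity_profile())
  w
}

#' Simulate a UPDRS-III exam linked to a severity profile
#'
#' Each item score is `clip(round(4 * w_item . s + e), 0, 4)` with rater
#' noise `e ~ N(0, rater_noise_sd)`; the fixed weight matrix maps item
#' groups to symptom domains (Q20/Q21 to tremor, Q23-Q26/Q31 to
#' bradykinesia, Q27-Q30 to postural/gait, Q22 mixed) and every row sums
#' to one.
#'
#' @param profile A [severity_profile()].
#' @param rater_noise_sd Rater noise SD in score points per item.
#' @param seed Integer seed.
#' @return One-row tibble from [updrs_exam()].
#' @export
simulate_updrs <- function(profile, rater_noise_sd = 0.8, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  w <- updrs_weights()
  latent <- 4 * as.numeric(w %*% profile)
  noisy <- latent + stats::rnorm(nrow(w), 0, rater_noise_sd)
  scores <- pmin(4L, pmax(0L, as.integer(round(noisy))))
  updrs_exam(stats::setNames(scores, rownames(w)))
}

phenotype_archetypes <- function(gap) {
  base <- 0.2
  list(
    tremor_heavy = severity_profile(base, clip01(base + gap),
                                    clip01(base + gap), base, base),
    brady_heavy = severity_profile(clip01(base + gap), base, base, base, base),
    instability_heavy = severity_profile(base, base, base,
                                         clip01(base + gap), clip01(base + gap))
  )
}

draw_severities <- function(n, cfg) {
  if (cfg$phenotypes > 0L) {
    arch <- phenotype_archetypes(cfg$phenotype_gap)
    arch <- arch[seq_len(min(cfg$phenotypes, length(arch)))]
    labels <- rep(names(arch), length.out = n)
    sev <- t(vapply(labels, function(l) {
      clip01(arch[[l]] + stats::rnorm(5L, 0, 0.05))
    }, numeric(5L)))
  } else {
    g <- stats::rbeta(n, 2, 2)
    sev <- t(vapply(g, function(gi) {
      clip01(gi + stats::rnorm(5L, 0, cfg$severity_link_sd))
    }, numeric(5L)))
    labels <- rep(NA_character_, n)
  }
  colnames(sev) <- names(severity_profile())
  list(severities = sev, labels = labels)
}

#' Simulate a cohort
#'
#' Draws per-subject severity profiles either from a latent global-severity
#' model (global `g ~ Beta(2, 2)`, domain severities `clip(g + noise)`) or,
#' in planted-phenotype mode, from `phenotypes` archetype groups
#' (tremor-heavy, bradykinesia-heavy, instability-heavy) assigned in
#' balanced round-robin order. Generates a full session and a linked
#' UPDRS-III exam per subject, with an optional day-2 replicate whose
#' severities drift slightly.
#'
#' @param config A [sim_config()].
#' @return List with `sessions` (list of [session()]; day-2 sessions
#'   appended when requested), `updrs` (tibble, one exam per session) and
#'   `truth` (tibble of generating severities and phenotype labels).
#' @export
simulate_cohort <- function(config = sim_config()) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_subjects
  drawn <- draw_severities(n, config)
  subject_ids <- sprintf("S%03d", seq_len(n))
  seeds <- sample.int(.Machine$integer.max %/% 4L, n * 4L)
  sessions <- list()
  updrs_rows <- list()
  truth_rows <- list()
  for (i in seq_len(n)) {
    prof <- severity_profile(
      drawn$severities[i, 1L], drawn$severities[i, 2L],
      drawn$severities[i, 3L], drawn$severities[i, 4L],
      drawn$severities[i, 5L]
    )
    sess <- simulate_subject(prof, config, seed = seeds[i],
                             subject_id = subject_ids[i], visit_day = 1L)
    exam <- simulate_updrs(prof, config$rater_noise_sd, seed = seeds[n + i])
    sess$updrs <- exam
    sessions[[length(sessions) + 1L]] <- sess
    updrs_rows[[length(updrs_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = subject_ids[i], visit_day = 1L), exam
    )
    truth_rows[[length(truth_rows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = subject_ids[i], visit_day = 1L,
                     phenotype = drawn$labels[i]),
      tibble::as_tibble(as.list(prof))
    )
    if (isTRUE(config$day2)) {
      prof2 <- severity_profile(
        clip01(prof[["s_brady"]] + stats::rnorm(1, 0, config$day2_drift_sd)),
        clip01(prof[["s_trem_rest"]] + stats::rnorm(1, 0, config$day2_drift_sd)),
        clip01(prof[["s_trem_post"]] + stats::rnorm(1, 0, config$day2_drift_sd)),
        clip01(prof[["s_postural"]] + stats::rnorm(1, 0, config$day2_drift_sd)),
        clip01(prof[["s_gait"]] + stats::rnorm(1, 0, config$day2_drift_sd))
      )
      sess2 <- simulate_subject(prof2, config, seed = seeds[2L * n + i],
                                subject_id = subject_ids[i], visit_day = 2L)
      exam2 <- simulate_updrs(prof2, config$rater_noise_sd,
                              seed = seeds[3L * n + i])
      sess2$updrs <- exam2
      sessions[[length(sessions) + 1L]] <- sess2
      updrs_rows[[length(updrs_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subject_ids[i], visit_day = 2L), exam2
      )
      truth_rows[[length(truth_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = subject_ids[i], visit_day = 2L,
                       phenotype = drawn$labels[i]),
        tibble::as_tibble(as.list(prof2))
      )
    }
  }
  list(
    sessions = sessions,
    updrs = dplyr::bind_rows(updrs_rows),
    truth = dplyr::bind_rows(truth_rows)
  )
}

#' Write a simulated cohort to disk
#'
#' One session directory per subject-visit plus `updrs.csv` and
#' `truth.csv` at the top level (the truth table is kept separate from the
#' "observed" data).
#'
#' @param cohort Result of [simulate_cohort()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (sess in cohort$sessions) {
    write_session(sess, file.path(path, sprintf("%s_day%d", sess$subject_id,
                                                sess$visit_day)))
  }
  readr::write_csv(cohort$updrs, file.path(path, "updrs.csv"), progress = FALSE)
  readr::write_csv(cohort$truth, file.path(path, "truth.csv"), progress = FALSE)
  invisible(path)
}
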