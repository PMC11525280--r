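make_reach_rec <- function(n_reach = 10L, T_move = 0.5, d = 0.3, fs = 30) {
  dur <- n_reach * T_move
  t <- seq(0, dur, by = 1 / fs)
  y <- numeric(length(t))
  level <- 0
  for (r in seq_len(n_reach)) {
    t0 <- (r - 1L) * T_move
    dir <- if (r %% 2L == 1L) 1 else -1
    tau <- pmin(pmax((t - t0) / T_move, 0), 1)
    y <- y + dir * d * (10 * tau^3 - 15 * tau^4 + 6 * tau^5) * (t >= t0)
    # freeze the completed stroke level
    y[t >= t0 + T_move] <- level + dir * d
    level <- level + dir * d
  }
  task_recording("T1A", camera = camera_tbl(t, wrist_y = 1 + y),
                 marker = marker_tbl(c(0, dur)))
}

test_that("reach metrics recover closed-form minimum-jerk statistics", {
  rec <- make_reach_rec()
  m <- reach_metrics(rec, "t1a_")
  expect_equal(unname(m["t1a_n_movements"]), 10)
  expect_equal(unname(m["t1a_duration_mean"]), 0.5, tolerance = 0.05)
  expect_lt(unname(m["t1a_duration_sd"]), 0.05)
  expect_equal(unname(m["t1a_smoothness_mean"]), 1 / 1.875, tolerance = 0.05)
  expect_equal(unname(m["t1a_max_speed_mean"]), 1.875 * 0.3 / 0.5,
               tolerance = 0.03)
  expect_equal(unname(m["t1a_path_length"]), 3.0, tolerance = 0.05)
})

test_that("a stationary wrist yields zero movements and missing statistics", {
  t <- seq(0, 5, by = 1 / 30)
  rec <- task_recording("T1A", camera = camera_tbl(t),
                        marker = marker_tbl(c(0, 5)))
  m <- reach_metrics(rec, "t1a_")
  expect_equal(unname(m["t1a_n_movements"]), 0)
  expect_lt(unname(m["t1a_path_length"]), 1e-6)
  expect_true(all(is.na(m[c("t1a_mean_speed_mean", "t1a_duration_mean",
                            "t1a_smoothness_mean")])))
})

test_that("open/close metrics divide task time by detected events", {
  t <- seq(0, 10, by = 1 / 64)
  # hand-open bursts once per second, all with equal prominence
  gx <- Reduce(`+`, lapply(seq(0.75, 9.75, by = 1), function(ct) {
    exp(-(t - ct)^2 / (2 * 0.1^2))
  }))
  rec <- task_recording("T2A",
                        imus = list(index_finger = imu_tbl(t, gyro_x = gx)),
                        marker = marker_tbl(c(0, 10)))
  m <- open_close_metrics(rec, "t2a_")
  expect_equal(unname(m["t2a_movement_time"]), 1.0, tolerance = 0.01)
  expect_equal(unname(m["t2a_ipi_mean"]), 1.0, tolerance = 0.01)
  expect_lt(unname(m["t2a_ipi_sd"]), 0.01)
  # fewer than 2 events: flagged missing
  rec0 <- task_recording("T2A", imus = list(index_finger = imu_tbl(t)),
                         marker = marker_tbl(c(0, 10)))
  expect_true(all(is.na(open_close_metrics(rec0, "t2a_"))))
})

test_that("the complex-task metric is the marker window length", {
  m <- complex_task_metric(task_recording("T3", marker = marker_tbl(c(0, 20.06))))
  expect_equal(unname(m), 20.06)
  m2 <- complex_task_metric(task_recording("T3", marker = marker_tbl(c(1, 2))))
  expect_equal(unname(m2), 1.0)
})

test_that("tremor band-power ratios separate in-band from out-of-band", {
  t <- seq(0, 31, by = 1 / 64)
  mk <- function(freq) {
    task_recording("T5A",
                   imus = list(index_finger = imu_tbl(
                     t, accel_x = 9.81 + 0.5 * sin(2 * pi * freq * t))),
                   marker = marker_tbl(c(0.5, 30.5)))
  }
  m5 <- tremor_metrics(mk(5), "t5a_")
  expect_gt(unname(m5["t5a_power_ratio_mt"]), 0.9)
  expect_gt(unname(m5["t5a_power_ratio_fft"]), 0.9)
  m10 <- tremor_metrics(mk(10), "t5a_")
  expect_lt(unname(m10["t5a_power_ratio_mt"]), 0.05)
  # auxiliary band-power summaries respond to in-band energy
  aux5 <- tremor_aux_metrics(mk(5), "t5a_")
  aux10 <- tremor_aux_metrics(mk(10), "t5a_")
  expect_gt(unname(aux5["t5a_mean_band_power_mt"]),
            10 * unname(aux10["t5a_mean_band_power_mt"]))
  expect_gt(unname(aux5["t5a_mean_total_power_fft"]), 0)
  # too-short signal is flagged missing
  short <- task_recording("T5A",
                          imus = list(index_finger = imu_tbl(t[t <= 5])),
                          marker = marker_tbl(c(0, 5)))
  expect_true(all(is.na(tremor_metrics(short, "t5a_"))))
})

test_that("CoP path length of a square trace equals its perimeter", {
  n_edge <- 100L
  s <- seq(0, 40, length.out = 4L * n_edge + 1L)  # corners on samples
  ml <- pmin(pmax(ifelse(s <= 10, s, ifelse(s <= 20, 10,
               ifelse(s <= 30, 30 - s, 0))), 0), 10)
  ap <- pmin(pmax(ifelse(s <= 10, 0, ifelse(s <= 20, s - 10,
               ifelse(s <= 30, 10, 40 - s))), 0), 10)
  t <- seq(0, 15, length.out = length(s))
  rec <- task_recording("T6_EO", plate = plate_tbl(t, ml, ap),
                        marker = marker_tbl(c(0, 15)))
  m <- balance_metrics(rec, "t6_eo_")
  expect_equal(unname(m["t6_eo_cop_path_length"]), 40, tolerance = 1e-9)
  # jerk metrics missing without the trunk IMU
  expect_true(all(is.na(m[c("t6_eo_jerk_mean", "t6_eo_jerk_peak")])))
})

test_that("the 95% sway ellipse matches the chi-squared(2) closed form", {
  areas <- vapply(1:20, function(s) {
    withr::with_seed(400 + s, {
      t <- seq(0, 15, by = 1 / 98)
      rec <- task_recording("T6_EO",
                            plate = plate_tbl(t, rnorm(length(t)), rnorm(length(t))),
                            marker = marker_tbl(c(0, 15)))
      unname(balance_metrics(rec, "t6_eo_")["t6_eo_ellipse_area"])
    })
  }, numeric(1L))
  expect_equal(mean(areas), pi * qchisq(0.95, 2), tolerance = 0.15)
})

test_that("gait metrics average walks and count strides exactly", {
  t <- seq(0, 10, by = 1 / 64)
  burst <- function(times) {
    Reduce(`+`, lapply(times, function(ct) 2.5 * exp(-(t - ct)^2 / (2 * 0.05^2))))
  }
  mk_walk <- function(task, with_strides) {
    imus <- list(L5 = imu_tbl(t, accel_x = 0, accel_z = 0))
    if (with_strides) {
      # 8 stride bursts, 1.04 s apart, all inside the marker window
      z <- burst(seq(0.7, by = 1.04, length.out = 8))
      imus$ankle_right <- imu_tbl(t, gyro_z = z)
    }
    task_recording(task, imus = imus, marker = marker_tbl(c(0.5, 9.32)))
  }
  recs <- list(
    T7_W1 = mk_walk("T7_W1", FALSE), T7_W2 = mk_walk("T7_W2", FALSE),
    T7_W3 = mk_walk("T7_W3", TRUE), T7_W4 = mk_walk("T7_W4", TRUE)
  )
  m <- gait_metrics(recs, side = "right")
  expect_equal(unname(m["gait_total_walk_time"]), 8.82)
  expect_equal(unname(m["gait_normalized_jerk"]), 0, tolerance = 1e-6)
  expect_equal(unname(m["gait_stride_count"]), 8)
  expect_equal(unname(m["gait_stride_duration_mean"]), 1.04, tolerance = 0.01)
  # missing walks leave the affected metrics missing
  m2 <- gait_metrics(recs[c("T7_W1", "T7_W2")])
  expect_true(is.na(m2["gait_stride_count"]))
  expect_false(is.na(m2["gait_normalized_jerk"]))
})

test_that("extract_metrics always returns the canonical 62-metric vector", {
  sess <- simulate_subject(severity_profile(0.4, 0.3, 0.3, 0.4, 0.3),
                           sim_config(), seed = 31)
  m <- extract_metrics(sess)
  expect_identical(setdiff(names(m), c("subject_id", "visit_day")),
                   metric_inventory()$metric)
  expect_equal(sum(is.na(m)), 0L)
  # determinism: re-extraction is bitwise identical
  expect_identical(m, extract_metrics(sess))
  # a session without the force plate keeps 62 entries, 6 CoP metrics
  # missing per balance condition, but trunk jerk still computed
  sess$recordings$T6_EO$plate <- NULL
  sess$recordings$T6_EC$plate <- NULL
  m2 <- extract_metrics(sess)
  expect_equal(ncol(m2), 64L)
  expect_equal(sum(is.na(m2)), 12L)
  expect_false(is.na(m2$t6_eo_jerk_mean))
})

test_that("dimensionless metrics are invariant to camera unit rescaling", {
  rec <- make_reach_rec()
  m1 <- reach_metrics(rec, "t1a_")
  rec_mm <- rec
  pos_cols <- setdiff(names(rec$camera), "time_s")
  rec_mm$camera[pos_cols] <- rec$camera[pos_cols] * 1000
  m2 <- reach_metrics(rec_mm, "t1a_")
  expect_equal(m2["t1a_smoothness_mean"], m1["t1a_smoothness_mean"],
               tolerance = 1e-9)
  expect_equal(m2["t1a_duration_mean"], m1["t1a_duration_mean"],
               tolerance = 1e-9)
  expect_equal(unname(m2["t1a_mean_speed_mean"]),
               1000 * unname(m1["t1a_mean_speed_mean"]), tolerance = 1e-6)
})

test_that("bradykinesia severity slows and lengthens reaches monotonically", {
  sev <- seq(0, 0.95, length.out = 20L)
  stats <- vapply(seq_along(sev), function(i) {
    sess <- simulate_subject(severity_profile(s_brady = sev[i]),
                             sim_config(), seed = 500 + i)
    m <- reach_metrics(sess$recordings$T1A, "t1a_")
    c(m["t1a_mean_speed_mean"], m["t1a_duration_mean"])
  }, numeric(2L))
  expect_lt(cor(sev, stats[1L, ], method = "spearman"), -0.9)
  expect_gt(cor(sev, stats[2L, ], method = "spearman"), 0.9)
})
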