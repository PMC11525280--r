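test_that("FIR low-pass passes the band and rejects above cutoff", {
  t <- seq(0, 10, by = 1 / 30)
  interior <- 31:270
  x1 <- sin(2 * pi * 1 * t)
  expect_lt(max(abs(lowpass_fir(x1, 30, 10) - x1)[interior]), 0.02)
  x14 <- sin(2 * pi * 14 * t)
  expect_lt(max(abs(lowpass_fir(x14, 30, 10)[interior])), 0.05)
  # DC gain is one
  expect_equal(lowpass_fir(rep(3.7, 200), 30, 10), rep(3.7, 200),
               tolerance = 1e-6)
  expect_error(lowpass_fir(rnorm(10), 30, 10), class = "pdmotor_signal_error")
})

test_that("Butterworth low-pass matches its analytic magnitude response", {
  t <- seq(0, 10, by = 1 / 64)
  interior <- 65:570
  x1 <- sin(2 * pi * 1 * t)
  expect_lt(max(abs(lowpass_butter(x1, 64, 5) - x1)[interior]), 0.01)
  x20 <- sin(2 * pi * 20 * t)
  expect_lt(max(abs(lowpass_butter(x20, 64, 5)[interior])), 0.01)  # > 40 dB
  expect_equal(lowpass_butter(rep(-1.2, 300), 64, 5), rep(-1.2, 300),
               tolerance = 1e-6)
})

test_that("filters are linear and time-invariant", {
  withr::local_seed(4)
  x <- rnorm(400)
  y <- rnorm(400)
  lhs <- lowpass_fir(2 * x + 3 * y, 64, 10)
  rhs <- 2 * lowpass_fir(x, 64, 10) + 3 * lowpass_fir(y, 64, 10)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  lhs_b <- lowpass_butter(2 * x + 3 * y, 64, 5)
  rhs_b <- 2 * lowpass_butter(x, 64, 5) + 3 * lowpass_butter(y, 64, 5)
  expect_equal(lhs_b, rhs_b, tolerance = 1e-9)
})

test_that("central-difference derivative matches analytic derivatives", {
  t <- seq(0, 2, by = 1 / 100)
  expect_equal(derivative(t, 100), rep(1, length(t)), tolerance = 1e-9)
  x <- sin(2 * pi * t)
  err <- abs(derivative(x, 100) - 2 * pi * cos(2 * pi * t))
  expect_lt(max(err[2:(length(t) - 1L)]), 0.01 * 2 * pi)
  expect_equal(derivative(rep(5, 10), 100), rep(0, 10))
  expect_error(derivative(c(1, 2), 100), class = "pdmotor_signal_error")
})

test_that("derivative inverts cumulative integration on smooth signals", {
  t <- seq(0, 5, by = 1 / 100)
  x <- sin(2 * pi * 0.7 * t) + 0.3 * t
  xi <- cumsum(x) / 100
  back <- derivative(xi, 100)
  interior <- 5:(length(t) - 4L)
  expect_lt(max(abs(back - x)[interior]) / max(abs(x)), 0.01)
})

test_that("speed_profile recovers constructed trajectory speeds", {
  t <- seq(0, 5, by = 1 / 30)
  # straight-line motion at 1 m/s
  cam <- camera_tbl(t, wrist_y = 1 + 0.6 * t, wrist_x = 0.8 * t)
  prof <- speed_profile(cam, "wrist_r")
  interior <- 31:(nrow(cam) - 30L)
  expect_lt(max(abs(prof$v[interior] - 1)), 0.02)
  # stationary joint
  prof0 <- speed_profile(camera_tbl(t), "wrist_r")
  expect_lt(max(prof0$v), 1e-9)
  # minimum-jerk reach peaks at 1.875 d / T
  T_move <- 1
  d <- 0.4
  tau <- pmin(t / T_move, 1)
  cam_mj <- camera_tbl(t, wrist_y = 1 + d * (10 * tau^3 - 15 * tau^4 + 6 * tau^5))
  prof_mj <- speed_profile(cam_mj, "wrist_r")
  expect_equal(max(prof_mj$v), 1.875 * d / T_move, tolerance = 0.02)
  expect_error(speed_profile(cam[, 1:10], "wrist_r"),
               class = "pdmotor_signal_error")
})

test_that("speed_profile interpolates short camera gaps and flags long ones", {
  t <- seq(0, 5, by = 1 / 30)
  y <- 1 + 0.5 * t
  y_short <- y
  y_short[40:42] <- NA  # 3-frame gap: interpolated
  cam <- camera_tbl(t, wrist_y = y_short)
  prof <- speed_profile(cam, "wrist_r")
  expect_false(anyNA(prof$v))
  y_long <- y
  y_long[60:70] <- NA  # 11-frame gap: flagged
  prof2 <- speed_profile(camera_tbl(t, wrist_y = y_long), "wrist_r")
  expect_true(anyNA(prof2$v))
})

test_that("demeaned acceleration amplitude isolates tremor from gravity", {
  t <- seq(0, 10, by = 1 / 64)
  g <- 9.81
  delta <- 0.05
  imu <- imu_tbl(t, accel_x = g + delta * sin(2 * pi * 5 * t))
  amp <- accel_amplitude(imu)
  expect_lt(max(abs(amp - delta * sin(2 * pi * 5 * t))), 1e-3)
  expect_lt(max(abs(accel_amplitude(imu_tbl(t, accel_x = g)))), 1e-12)
  expect_equal(accel_amplitude(imu_tbl(t)), rep(0, length(t)))
})

test_that("band_power_ratio matches in-band, out-of-band and flat spectra", {
  t <- seq(0, 20, by = 1 / 64)
  x5 <- sin(2 * pi * 5 * t)
  expect_gt(band_power_ratio(x5, 64, c(3, 6)), 0.95)
  expect_gt(band_power_ratio(x5, 64, c(3, 6), method = "fft"), 0.95)
  x10 <- sin(2 * pi * 10 * t)
  expect_lt(band_power_ratio(x10, 64, c(3, 6)), 0.05)
  # white noise: flat spectrum expectation (6-3)/(32-0.5)
  withr::local_seed(11)
  ratios <- replicate(20, band_power_ratio(rnorm(1280), 64, c(3, 6)))
  expect_lt(abs(mean(ratios) - 3 / 31.5), 0.03)
  expect_true(all(ratios >= 0 & ratios <= 1))
  expect_error(band_power_ratio(x5, 64, c(3, 40)),
               class = "pdmotor_signal_error")
  expect_error(band_power_ratio(rnorm(64), 64, c(3, 6)),
               class = "pdmotor_signal_error")
})

test_that("multitaper and periodogram ratios agree on stationary signals", {
  t <- seq(0, 30, by = 1 / 64)
  x <- sin(2 * pi * 4.7 * t)
  mt <- band_power_ratio(x, 64, c(3, 6), method = "multitaper")
  ff <- band_power_ratio(x, 64, c(3, 6), method = "fft")
  expect_lt(abs(mt - ff), 0.1)
  withr::local_seed(3)
  diffs <- replicate(20, {
    w <- rnorm(1280)
    abs(band_power_ratio(w, 64, c(3, 6)) -
          band_power_ratio(w, 64, c(3, 6), method = "fft"))
  })
  expect_lt(mean(diffs), 0.05)
})

test_that("jerk statistics match the analytic |cos| moments", {
  t <- seq(0, 20, by = 1 / 64)
  js <- jerk_stats(sin(2 * pi * t), 0 * t, 64)
  expect_equal(js$peak, 2 * pi, tolerance = 0.01)
  expect_equal(js$mean, 4, tolerance = 0.02)
  # constant acceleration has zero jerk
  js0 <- jerk_stats(rep(2, length(t)), rep(-1, length(t)), 64)
  expect_equal(js0$mean, 0)
  expect_equal(js0$peak, 0)
  # the amplitude is symmetric in the two axes
  js_sw <- jerk_stats(0 * t, sin(2 * pi * t), 64)
  expect_equal(js_sw$mean, js$mean)
  expect_equal(js_sw$peak, js$peak)
})
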