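# Filtering, differentiation, and spectral primitives.
#
# All filters are applied forward-backward (zero phase) on an odd-reflection
# padded copy of the signal, so passband magnitude responses are squared and
# edge transients are suppressed. Derivatives are central differences with
# one-sided ends.

# Zero-phase filtering with scipy-style odd reflection padding. b/a are the
# filter polynomials; pad length covers the filter's settling region.
zero_phase_filter <- function(b, a, x, pad = NULL) {
  b <- as.numeric(b)
  a <- as.numeric(a)
  n <- length(x)
  if (is.null(pad)) pad <- 3L * max(length(b), length(a))
  pad <- min(pad, n - 1L)
  if (pad < 1L) {
    rlang::abort("signal too short to filter", class = "pdmotor_signal_error")
  }
  xp <- c(
    2 * x[1L] - x[(pad + 1L):2L],
    x,
    2 * x[n] - x[(n - 1L):(n - pad)]
  )
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Zero-phase FIR low-pass filter
#'
#' A 31-tap Hamming-window linear-phase low-pass FIR, applied
#' forward-backward so the output has zero phase lag and the designed
#' magnitude response is squared.
#'
#' @param x Uniformly sampled numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz; requires `fs > 2 * cutoff`.
#' @param taps Number of filter taps (odd; default 31).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_fir <- function(x, fs, cutoff, taps = 31L) {
  stopifnot(fs > 2 * cutoff, cutoff > 0)
  if (length(x) <= taps) {
    rlang::abort("signal shorter than the FIR filter order",
                 class = "pdmotor_signal_error")
  }
  b <- as.numeric(signal::fir1(taps - 1L, cutoff / (fs / 2), type = "low"))
  b <- b / sum(b)  # exact unit DC gain
  zero_phase_filter(b, 1, x, pad = 3L * taps)
}

#' Zero-phase Butterworth low-pass filter
#'
#' A low-pass Butterworth filter (default 4th order, matching the design
#' order; forward-backward application squares the magnitude response).
#'
#' @inheritParams lowpass_fir
#' @param order Designed filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_butter <- function(x, fs, cutoff, order = 4L) {
  stopifnot(fs > 2 * cutoff, cutoff > 0)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # generous padding lets the slowest pole's startup transient decay fully
  zero_phase_filter(bf$b, bf$a, x, pad = 300L)
}

#' First-order derivative by central differences
#'
#' Interior samples use central differences; the two ends use one-sided
#' differences, so the output has the same length as the input.
#'
#' @param x Numeric signal (length >= 3).
#' @param fs Sampling rate in Hz.
#' @return Numeric derivative, same length as `x`.
#' @export
derivative <- function(x, fs) {
  n <- length(x)
  if (n < 3L) {
    rlang::abort("derivative needs at least 3 samples",
                 class = "pdmotor_signal_error")
  }
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d
}

# Linearly interpolate flagged (NA) camera frames when the gap is at most
# `max_gap` frames; longer gaps stay NA and taint the enclosing movement.
interp_short_gaps <- function(x, max_gap = 3L) {
  if (!anyNA(x)) return(x)
  na <- is.na(x)
  r <- rle(na)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  out <- x
  for (i in which(r$values)) {
    if (r$lengths[i] <= max_gap &&
        idx_start[i] > 1L && idx_end[i] < length(x)) {
      lo <- idx_start[i] - 1L
      hi <- idx_end[i] + 1L
      out[idx_start[i]:idx_end[i]] <-
        x[lo] + (x[hi] - x[lo]) * (seq_len(r$lengths[i])) / (hi - lo)
    }
  }
  out
}

#' Speed profile of a tracked joint
#'
#' The joint's three position components are low-pass filtered (10 Hz FIR),
#' differentiated, and combined into the Euclidean speed magnitude. Flagged
#' (missing) camera frames are linearly interpolated when the gap is at most
#' three frames; longer gaps propagate as `NA` so the enclosing movement can
#' be dropped from per-movement statistics.
#'
#' @param camera Camera tibble (`time_s` + `<joint>_{x,y,z}` columns).
#' @param joint Joint name, one of [skeleton_joints()].
#' @param fs Sampling rate in Hz (default 30).
#' @param cutoff Low-pass cutoff in Hz (default 10).
#' @return Tibble with `time_s` and `v` (speed, m/s).
#' @export
speed_profile <- function(camera, joint, fs = 30, cutoff = 10) {
  cols <- paste0(joint, "_", c("x", "y", "z"))
  if (!all(cols %in% names(camera))) {
    rlang::abort(paste0("joint '", joint, "' not present in camera stream"),
                 class = "pdmotor_signal_error")
  }
  if (nrow(camera) < fs) {
    rlang::abort("need at least 1 s of camera data",
                 class = "pdmotor_signal_error")
  }
  comps <- lapply(cols, function(cn) {
    x <- interp_short_gaps(camera[[cn]])
    long_na <- is.na(x)
    if (any(long_na)) {
      if (all(long_na)) {
        rlang::abort(paste0("joint '", joint, "' has no finite samples"),
                     class = "pdmotor_signal_error")
      }
      # fill long gaps so the filter runs, then re-flag them as missing
      ok <- which(!long_na)
      x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
      d <- derivative(lowpass_fir(x, fs, cutoff), fs)
      d[long_na] <- NA_real_
      d
    } else {
      derivative(lowpass_fir(x, fs, cutoff), fs)
    }
  })
  v <- sqrt(comps[[1L]]^2 + comps[[2L]]^2 + comps[[3L]]^2)
  tibble::tibble(time_s = camera$time_s, v = v)
}

#' Demeaned acceleration amplitude
#'
#' Euclidean norm of the three accelerometer components with the mean
#' removed, so the static gravity component drops out and oscillatory
#' content (tremor) remains.
#'
#' @param imu IMU tibble with `accel_x`, `accel_y`, `accel_z`.
#' @return Numeric vector, same length as the stream.
#' @export
accel_amplitude <- function(imu) {
  amp <- sqrt(imu$accel_x^2 + imu$accel_y^2 + imu$accel_z^2)
  amp - mean(amp)
}

# ---- multitaper spectral estimation ----------------------------------------

# DPSS (Slepian) tapers via the standard symmetric tridiagonal eigenproblem.
# Cached per (n, nw, k): taper computation is O(n^3) through LAPACK but each
# distinct signal length is needed once per R session.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 4, k = 7L) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- seq_len(n) - 1L
  main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (i[-1L] * (n - i[-1L])) / 2
  tri <- diag(main)
  tri[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  tri[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  eig <- eigen(tri, symmetric = TRUE)
  tapers <- eig$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign convention (symmetric tapers positive at center)
  for (j in seq_len(k)) {
    tj <- tapers[, j]
    tj <- tj / sqrt(sum(tj^2))
    if (sum(tj) < 0) tj <- -tj
    tapers[, j] <- tj
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

periodogram_power <- function(xt) {
  n <- length(xt)
  p <- Mod(stats::fft(xt))^2
  nf <- floor(n / 2) + 1L
  p[seq_len(nf)]
}

#' Power spectrum of a signal
#'
#' Multitaper (DPSS, default NW = 4 with 7 tapers) or single Hann-taper
#' periodogram power spectral estimate.
#'
#' @param x Demeaned numeric signal.
#' @param fs Sampling rate in Hz.
#' @param method `"multitaper"` or `"fft"` (Hann periodogram).
#' @param nw Multitaper time-bandwidth product.
#' @param k Number of DPSS tapers.
#' @return Tibble with `freq` (Hz) and `power` columns.
#' @export
power_spectrum <- function(x, fs, method = c("multitaper", "fft"),
                           nw = 4, k = 7L) {
  method <- match.arg(method)
  n <- length(x)
  x <- x - mean(x)
  if (method == "multitaper") {
    tapers <- dpss_tapers(n, nw, k)
    p <- rowMeans(vapply(seq_len(k), function(j) {
      periodogram_power(x * tapers[, j])
    }, numeric(floor(n / 2) + 1L)))
  } else {
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
    hann <- hann / sqrt(sum(hann^2))
    p <- periodogram_power(x * hann)
  }
  freq <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  tibble::tibble(freq = freq, power = p)
}

#' Band-power ratio
#'
#' Ratio of spectral power inside a frequency band to total power, where
#' total power is integrated from `f_min` (default 0.5 Hz, excluding the DC
#' and residual gravity leakage) up to the Nyquist frequency.
#'
#' @param x Numeric signal (at least 4 s of samples).
#' @param fs Sampling rate in Hz.
#' @param band Numeric `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @param method `"multitaper"` (DPSS) or `"fft"` (Hann periodogram).
#' @param f_min Lower integration bound for total power, Hz.
#' @param ... Passed to [power_spectrum()].
#' @return Ratio in `[0, 1]`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 64)
#' band_power_ratio(sin(2 * pi * 5 * t), 64, c(3, 6))  # close to 1
band_power_ratio <- function(x, fs, band, method = c("multitaper", "fft"),
                             f_min = 0.5, ...) {
  method <- match.arg(method)
  if (length(x) < 4 * fs) {
    rlang::abort("band_power_ratio needs at least 4 s of signal",
                 class = "pdmotor_signal_error")
  }
  if (band[1L] <= 0 || band[2L] >= fs / 2 || band[1L] >= band[2L]) {
    rlang::abort("band must lie inside (0, Nyquist)",
                 class = "pdmotor_signal_error")
  }
  spec <- power_spectrum(x, fs, method = method, ...)
  total <- spec$freq >= f_min
  inband <- spec$freq >= band[1L] & spec$freq <= band[2L]
  denom <- sum(spec$power[total])
  if (denom <= 0) return(0)
  min(1, sum(spec$power[inband & total]) / denom)
}

#' Jerk amplitude statistics from planar acceleration
#'
#' Differentiates the antero-posterior and medio-lateral acceleration
#' components and returns the mean and peak of the Euclidean jerk amplitude.
#' The first and last 0.25 s are excluded from the statistics to suppress
#' differentiation edge transients.
#'
#' @param accel_ap,accel_ml Filtered acceleration components, m/s^2.
#' @param fs Sampling rate in Hz.
#' @param edge_trim_s Seconds trimmed from each end (default 0.25).
#' @return Named list with `amplitude` (full-length signal), `mean`, `peak`
#'   (m/s^3).
#' @export
jerk_stats <- function(accel_ap, accel_ml, fs, edge_trim_s = 0.25) {
  jap <- derivative(accel_ap, fs)
  jml <- derivative(accel_ml, fs)
  amp <- sqrt(jap^2 + jml^2)
  trim <- min(floor(edge_trim_s * fs), floor((length(amp) - 1L) / 2))
  interior <- amp[(trim + 1L):(length(amp) - trim)]
  list(amplitude = amp, mean = mean(interior), peak = max(interior))
}
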