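#' Zero-lag fourth-order Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel of a
#' stream, or of a plain numeric vector. DC gain is exactly 1, so constant
#' signals pass unchanged. Dropout samples are linearly bridged before
#' filtering and re-flagged afterwards.
#'
#' @param x a `tf_stream` or numeric vector.
#' @param cutoff_hz low-pass cutoff, Hz; must be below Nyquist.
#' @param fs sampling rate, Hz (taken from stream metadata if `x` is a
#'   stream).
#' @param order filter order (default 4).
#' @return filtered object of the same type as `x`.
#' @export
butterworth_zero_lag <- function(x, cutoff_hz, fs = NULL, order = 4) {
  if (inherits(x, "tf_stream")) {
    fs <- fs %||% attr(x, "sample_rate_hz")
    check_cutoff(cutoff_hz, fs)
    for (ch in stream_channels(x)) {
      v <- bridge_na(x[[ch]])
      x[[ch]] <- filt_fb(v, cutoff_hz, fs, order)
      x[[ch]][x$dropout] <- NA_real_
    }
    return(x)
  }
  if (is.null(fs)) tf_validation_error("fs required for plain vectors", "fs")
  check_cutoff(cutoff_hz, fs)
  filt_fb(bridge_na(x), cutoff_hz, fs, order)
}

check_cutoff <- function(cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    tf_validation_error(
      sprintf("cutoff %.3g Hz must lie in (0, Nyquist = %.3g Hz)",
              cutoff_hz, fs / 2), "cutoff_hz")
  }
}

# forward-backward filtering with odd-reflection end padding, so edge
# transients decay inside the pad rather than corrupting the signal
filt_fb <- function(v, cutoff_hz, fs, order) {
  b <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_padded(b, v)
}

filtfilt_padded <- function(b, v) {
  n <- length(v)
  L <- min(n - 1, max(3 * length(b$b), 300))
  if (L < 1) return(as.numeric(signal::filtfilt(b, v)))
  head_pad <- 2 * v[1] - v[(L + 1):2]
  tail_pad <- 2 * v[n] - v[(n - 1):(n - L)]
  out <- signal::filtfilt(b, c(head_pad, v, tail_pad))
  as.numeric(out[(L + 1):(L + n)])
}

bridge_na <- function(v) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0) return(rep(0, length(v)))
  approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Signal-to-noise ratio in decibels
#'
#' `SNR = 20 log10(A_signal / A_noise)` with RMS amplitudes. A zero noise
#' amplitude returns `Inf` with an `exact` attribute flag rather than an
#' error, since noiseless synthetic streams are legitimate inputs.
#'
#' @param signal_rms RMS amplitude of the intended measurement.
#' @param noise_rms RMS amplitude of the background noise.
#' @return SNR in dB.
#' @export
#' @examples
#' compute_snr(10, 1)  # 20
compute_snr <- function(signal_rms, noise_rms) {
  if (any(signal_rms < 0) || any(noise_rms < 0)) {
    tf_validation_error("amplitudes must be non-negative", "signal_rms")
  }
  out <- ifelse(noise_rms == 0, Inf, 20 * log10(signal_rms / noise_rms))
  if (any(noise_rms == 0)) attr(out, "exact") <- TRUE
  out
}

#' Estimate per-stream signal quality
#'
#' Separates each channel into an in-band component (zero-lag Butterworth
#' low-pass at the modality cutoff) and an out-of-band residual, and takes
#' the residual RMS as the noise amplitude estimate. Streams whose SNR falls
#' below `snr_floor_db` (default 15 dB) are flagged for recalibration.
#' `sampling_consistency` measures timestamp regularity (1 = perfectly
#' uniform) independently of amplitude quality.
#'
#' @param stream a `tf_stream`.
#' @param cutoff_hz in-band cutoff, Hz; defaults to the modality default in
#'   [tf_config()].
#' @param snr_floor_db recalibration threshold, dB.
#' @param config optional `tf_config`.
#' @return tibble of class `tf_quality_tbl`, one row per channel:
#'   channel, a_signal, a_noise, snr_db, sampling_consistency,
#'   needs_recalibration, plus per-channel noise variance `noise_var` used by
#'   the fusion weights.
#' @export
estimate_stream_quality <- function(stream, cutoff_hz = NULL,
                                    snr_floor_db = NULL, config = tf_config()) {
  fs <- attr(stream, "sample_rate_hz")
  modality <- attr(stream, "modality")
  cutoff_hz <- cutoff_hz %||% config$preprocess$cutoff_hz[[modality]]
  snr_floor_db <- snr_floor_db %||% config$preprocess$snr_floor_db
  n_ok <- sum(!stream$dropout)
  sc <- sampling_consistency(stream$t)
  if (n_ok == 0) {
    return(structure(tibble(
      channel = stream_channels(stream), a_signal = 0, a_noise = 0,
      snr_db = -Inf, sampling_consistency = sc, needs_recalibration = TRUE,
      noise_var = Inf), class = c("tf_quality_tbl", class(tibble()))))
  }
  if (nrow(stream) / fs < 2) {
    warn("estimate_stream_quality: less than 2 s of data; estimates unstable")
  }
  rows <- purrr::map_dfr(stream_channels(stream), function(ch) {
    v <- bridge_na(stream[[ch]])
    inband <- filt_fb(v, min(cutoff_hz, 0.45 * fs), fs, 4)
    resid <- v - inband
    a_sig <- rms(inband - mean(inband))   # DC excluded from the signal band
    a_noi <- rms(resid)
    tibble(channel = ch, a_signal = a_sig, a_noise = a_noi,
           snr_db = as.numeric(compute_snr(a_sig, max(a_noi, 0))),
           noise_var = a_noi^2)
  })
  rows$sampling_consistency <- sc
  rows$needs_recalibration <- rows$snr_db < snr_floor_db
  structure(rows, class = c("tf_quality_tbl", class(tibble())))
}

sampling_consistency <- function(t) {
  if (length(t) < 3) return(1)
  dt <- diff(t)
  max(0, 1 - sd(dt) / mean(dt))
}

#' Complementary orientation filter
#'
#' One step of the scalar complementary filter blending integrated gyroscope
#' rate against the accelerometer-derived inclination:
#' `theta_t = alpha * (theta_prev + omega * dt) + (1 - alpha) * phi`.
#' With constant `phi` and `omega = 0` the estimate converges to `phi`
#' geometrically with ratio `alpha`.
#'
#' @param theta_prev previous orientation estimate, degrees.
#' @param omega angular rate from the gyroscope, deg/s.
#' @param phi inclination from the accelerometer (or magnetometer heading),
#'   degrees.
#' @param alpha filter coefficient in `[0, 1]` (gyro trust; default 0.98).
#' @param dt time step, seconds.
#' @return updated orientation, degrees.
#' @export
#' @examples
#' complementary_filter(0, omega = 10, phi = 0, alpha = 1, dt = 0.005) # 0.05
complementary_filter <- function(theta_prev, omega, phi, alpha = 0.98, dt) {
  if (alpha < 0 || alpha > 1) {
    tf_validation_error("alpha must lie in [0, 1]", "alpha")
  }
  if (any(dt <= 0)) tf_validation_error("dt must be > 0", "dt")
  alpha * (theta_prev + omega * dt) + (1 - alpha) * phi
}

#' Run the complementary filter along gyro/inclination series
#'
#' @param omega vector of angular rates, deg/s.
#' @param phi vector of inclination readings, degrees (same length).
#' @param alpha filter coefficient.
#' @param dt time step, seconds.
#' @param theta0 initial orientation (default `phi[1]`).
#' @return vector of orientation estimates, degrees.
#' @export
orientation_series <- function(omega, phi, alpha = 0.98, dt, theta0 = phi[1]) {
  n <- length(omega)
  if (length(phi) != n) tf_validation_error("omega and phi lengths differ",
                                            "phi")
  th <- numeric(n)
  prev <- theta0
  for (k in seq_len(n)) {
    prev <- complementary_filter(prev, omega[k], phi[k], alpha, dt)
    th[k] <- prev
  }
  th
}
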