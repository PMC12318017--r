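# shared fixtures and independent oracles used across test files

rms_ <- function(x) sqrt(mean(x^2))

# simulator configuration with every noise source off (sensor noise,
# latency, dropouts and phase diffusion): the identity-recovery condition
zero_noise_config <- function(...) {
  sim_config(
    noise_profile = list(gps_sigma_m = 0, lps_sigma_m = 0,
                         imu_acc_sigma_g = 0, gyro_sigma_dps = 0,
                         mag_sigma_deg = 0, hr_sigma_bpm = 0,
                         insole_sigma_n = 0),
    latency_profile = list(imu = c(0, 0), gps = c(0, 0), lps = c(0, 0),
                           physio = c(0, 0), insole = c(0, 0)),
    dropout_rate = 0, phase_noise = 0, ...)
}

# exhaustive-path DTW oracle (memoized recursion over all monotone paths)
dtw_brute <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- matrix(NA_real_, n, m)
  f <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    d <- abs(x[i] - y[j])
    v <- if (i == 1 && j == 1) d else {
      best <- Inf
      if (i > 1) best <- min(best, f(i - 1, j))
      if (j > 1) best <- min(best, f(i, j - 1))
      if (i > 1 && j > 1) best <- min(best, f(i - 1, j - 1))
      d + best
    }
    memo[i, j] <<- v
    v
  }
  f(n, m)
}

# naive triple-sum oracle for the 3-mode tensor product
tensor_brute <- function(X, W1, W2, W3) {
  d <- dim(X)
  out <- array(0, c(nrow(W1), nrow(W2), nrow(W3)))
  for (a in seq_len(nrow(W1))) for (b in seq_len(nrow(W2)))
    for (c_ in seq_len(nrow(W3))) {
      s <- 0
      for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
          s <- s + X[i, j, k] * W1[a, i] * W2[b, j] * W3[c_, k]
        }
      out[a, b, c_] <- s
    }
  out
}

# brute-force recurrence-rate count
rr_brute <- function(Xi, Xj, eps) {
  Xi <- as.matrix(Xi); Xj <- as.matrix(Xj)
  hits <- 0
  for (m in seq_len(nrow(Xi))) for (n in seq_len(nrow(Xj))) {
    if (sqrt(sum((Xi[m, ] - Xj[n, ])^2)) <= eps) hits <- hits + 1
  }
  hits / (nrow(Xi) * nrow(Xj))
}

# tiny two-athlete session built by hand (no simulator)
toy_session <- function(n = 30, rate = 10) {
  t <- (seq_len(n) - 1) / rate
  mk <- function(id) {
    sensor_stream(t, list(x = cos(2 * pi * 0.3 * t) + as.numeric(factor(id)),
                          y = sin(2 * pi * 0.3 * t)),
                  id, "gps", "gps", rate, units = c(x = "m", y = "m"),
                  accuracy = c(x = 0.5, y = 0.5))
  }
  streams <- list(mk("A1"), mk("A2"))
  names(streams) <- vapply(streams, function(s)
    paste(attr(s, "athlete_id"), attr(s, "sensor_id"), sep = "/"),
    character(1))
  athletes <- tibble::tibble(
    athlete_id = c("A1", "A2"), role = "field", team = "A",
    sensors = list("gps", "gps"))
  idx <- purrr::map_dfr(streams, stream_meta)
  idx$path <- file.path("streams", paste0(idx$athlete_id, "_gps.csv"))
  manifest <- session_manifest("toy", "generic", c(-20, 20, -15, 15),
                               athletes,
                               idx[c("athlete_id", "sensor_id", "modality",
                                     "path", "sample_rate_hz", "latency_s")])
  list(manifest = manifest, streams = streams,
       events = tf_events(c(0.5, 1.5), c("pass", "pass"),
                          c("A1", "A2"), c("A2", "A1")))
}
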