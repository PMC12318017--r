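# Position estimate for one athlete under a named baseline fuser.
baseline_positions <- function(streams, grid, method, config = tf_config()) {
  mods <- vapply(streams, function(s) attr(s, "modality"), character(1))
  pos_streams <- streams[mods %in% c("gps", "lps")]
  imu <- if (any(mods == "imu")) streams[[which(mods == "imu")[1]]] else NULL
  if (method == "gps_only") {
    pos_streams <- streams[mods == "gps"]
    imu <- NULL
  }
  if (length(pos_streams) == 0) tf_abort("no positional source",
                                         class = "tf_error")
  ii <- imu_double_integral(imu)
  ests <- purrr::map(pos_streams, source_position_estimate, grid = grid,
                     ii = ii)
  ests <- ests[!vapply(ests, is.null, logical(1))]
  k <- length(ests)
  if (method %in% c("wavg", "gps_only")) {
    w <- rep(1 / k, k)
    return(list(
      x = weighted_average_fuse(purrr::map(ests, "x"), w),
      y = weighted_average_fuse(purrr::map(ests, "y"), w)))
  }
  if (method == "bayes") {
    vars <- vapply(pos_streams, function(s) {
      acc <- attr(s, "accuracy")
      v <- if (!is.null(acc) && "x" %in% names(acc)) acc[["x"]]^2 else NA_real_
      if (!is.finite(v) || v <= 0) {
        v <- stream_noise_var(s$t, s$x, attr(s, "sample_rate_hz"),
                              config$preprocess$cutoff_hz[[attr(s, "modality")]])
      }
      max(v, 1e-12)
    }, numeric(1))
    ex <- do.call(cbind, purrr::map(ests, "x"))
    ey <- do.call(cbind, purrr::map(ests, "y"))
    return(list(x = bayes_fuse(ex, vars)$mean, y = bayes_fuse(ey, vars)$mean))
  }
  if (method == "kalman") {
    dt <- grid[2] - grid[1]
    vars <- vapply(pos_streams, function(s) {
      max(stream_noise_var(s$t, s$x, attr(s, "sample_rate_hz"),
                           config$preprocess$cutoff_hz[[attr(s, "modality")]]),
          1e-12)
    }, numeric(1))
    A <- matrix(c(1, 0, dt, 1), 2, 2)
    qp <- 25  # process noise intensity (m/s^2)^2, sized for sprint dynamics
    Q <- qp * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
    H <- matrix(c(rep(1, k), rep(0, k)), k, 2)
    R <- diag(vars, nrow = k)
    out <- list()
    for (ch in c("x", "y")) {
      z <- do.call(cbind, purrr::map(ests, ch))
      v0 <- (z[2, 1] - z[1, 1]) / dt
      kf <- kalman_fuse(z, A = A, H = H, Q_proc = Q, R_meas = R,
                        x0 = c(z[1, 1], v0), P0 = diag(c(1, 4)))
      out[[ch]] <- kf$x[, 1]
    }
    return(out)
  }
  tf_validation_error(paste0("unknown fuser '", method, "'"), "method")
}

#' Compare fusion algorithms against simulator ground truth
#'
#' Runs the multi-level fuser and the reference fusers (Kalman, fixed
#' weighted average, Gaussian Bayesian, single-source GPS) on the same
#' simulated session and measures position/velocity RMSE against the known
#' truth, at the native noise level and under amplitude-proportional noise
#' injected into the GPS streams (the degraded-source robustness protocol).
#' The latency proxy is the cross-correlation lag (in output samples)
#' between fused and true x-position.
#'
#' @param sim result of [simulate_session()].
#' @param fusers character subset of
#'   `c("multilevel", "kalman", "wavg", "bayes", "gps_only")`.
#' @param noise_amplitudes numeric vector of injected amplitude fractions
#'   (0 = native session noise only).
#' @param config a [tf_config()].
#' @return tibble of class `tf_comparison`: fuser, noise_amplitude,
#'   rmse_pos_m, rmse_vel_mps, lag_samples.
#' @export
compare_fusers <- function(sim,
                           fusers = c("multilevel", "kalman", "wavg", "bayes"),
                           noise_amplitudes = c(0, 0.3),
                           config = tf_config()) {
  truth <- sim$truth$team
  ids <- unique(truth$athlete_id)
  by_ath <- split(sim$streams,
                  vapply(sim$streams, function(s) attr(s, "athlete_id"),
                         character(1)))
  out <- list()
  for (amp in noise_amplitudes) {
    streams_a <- sim$streams
    if (amp > 0) {
      for (nm in names(streams_a)) {
        if (attr(streams_a[[nm]], "modality") == "gps") {
          streams_a[[nm]] <- inject_noise(streams_a[[nm]], amp,
                                          seed = sim$truth$config$seed)
        }
      }
      by_ath <- split(streams_a,
                      vapply(streams_a, function(s) attr(s, "athlete_id"),
                             character(1)))
    }
    for (f in fusers) {
      errs <- purrr::map(ids, function(id) {
        ss <- by_ath[[id]]
        tr <- dplyr::filter(truth, .data$athlete_id == id)
        if (f == "multilevel") {
          rec <- fuse_individual(ss, config)
          grid <- rec$t
          est <- list(x = rec$x, y = rec$y)
          est_v <- list(vx = rec$vx, vy = rec$vy)
        } else {
          mods <- vapply(ss, function(s) attr(s, "modality"), character(1))
          ps <- ss[mods %in% c("gps", "lps")]
          t0 <- max(vapply(ps, function(s) min(s$t), numeric(1)))
          t1 <- min(vapply(ps, function(s) max(s$t), numeric(1)))
          grid <- seq(t0, t1, by = 1 / config$align$out_rate_hz)
          est <- baseline_positions(ss, grid, f, config)
          dtg <- grid[2] - grid[1]
          est_v <- list(vx = cgrad(est$x, dtg), vy = cgrad(est$y, dtg))
        }
        tx <- approx(tr$t, tr$x, xout = grid, rule = 2)$y
        ty <- approx(tr$t, tr$y, xout = grid, rule = 2)$y
        tvx <- approx(tr$t, tr$vx, xout = grid, rule = 2)$y
        tvy <- approx(tr$t, tr$vy, xout = grid, rule = 2)$y
        lag <- xcorr_lag(est$x - mean(est$x), tx - mean(tx), max_lag = 10)
        c(pos = sqrt(mean((est$x - tx)^2 + (est$y - ty)^2)),
          vel = sqrt(mean((est_v$vx - tvx)^2 + (est_v$vy - tvy)^2)),
          lag = lag)
      })
      m <- do.call(rbind, errs)
      out[[length(out) + 1]] <- tibble(
        fuser = f, noise_amplitude = amp,
        rmse_pos_m = sqrt(mean(m[, "pos"]^2)),
        rmse_vel_mps = sqrt(mean(m[, "vel"]^2)),
        lag_samples = mean(m[, "lag"]))
    }
  }
  structure(bind_rows(out), class = c("tf_comparison", class(tibble())))
}

xcorr_lag <- function(a, b, max_lag = 10) {
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[(1 + l):n] * b[1:(n - l)]) else
      sum(a[1:(n + l)] * b[(1 - l):n])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Fusion quality report
#'
#' Summarises fusion quality for a session: per-stream SNR before fusion,
#' information preservation `Q_info` between the raw positional signals and
#' the fused output, and, when simulator ground truth is available,
#' fused-position RMSE and the SNR of the fused trajectory against truth
#' (whence the SNR gain over the raw GPS stream).
#'
#' @param streams named list of `tf_stream` for the session.
#' @param records list of `tf_record` from [fuse_individual()].
#' @param truth optional `truth` element of [simulate_session()] output.
#' @param config a [tf_config()].
#' @return list of class `tf_quality`.
#' @export
fusion_quality_report <- function(streams, records, truth = NULL,
                                  config = tf_config()) {
  qual <- purrr::map_dfr(streams, function(s) {
    q <- estimate_stream_quality(s, config = config)
    tibble(stream = stream_id(s), modality = attr(s, "modality"),
           snr_db = mean(q$snr_db[is.finite(q$snr_db)]),
           sampling_consistency = q$sampling_consistency[1],
           needs_recalibration = any(q$needs_recalibration))
  })
  ids <- vapply(records, function(r) attr(r, "athlete_id"), character(1))
  qi <- purrr::map_dbl(records, function(r) {
    sid <- paste0(attr(r, "athlete_id"), "/gps")
    s <- streams[[sid]]
    if (is.null(s)) return(NA_real_)
    raw_x <- approx(s$t[!s$dropout], s$x[!s$dropout], xout = r$t, rule = 2)$y
    q <- q_info(raw_x, r$x, bins = config$fuse$mi_bins)
    q$q_info
  })
  rep_ <- list(
    streams = qual,
    q_info = mean(qi, na.rm = TRUE),
    fused_grid_jitter_ms = mean(purrr::map_dbl(records, function(r)
      1000 * sd(diff(r$t)))),
    raw_latency_ms = 1000 * mean(purrr::map_dbl(streams, function(s)
      attr(s, "latency_s") %||% 0)))
  if (!is.null(truth)) {
    tr <- truth$team
    errs <- purrr::map2_dbl(records, ids, function(r, id) {
      tt <- dplyr::filter(tr, .data$athlete_id == id)
      tx <- approx(tt$t, tt$x, xout = r$t, rule = 2)$y
      ty <- approx(tt$t, tt$y, xout = r$t, rule = 2)$y
      sqrt(mean((r$x - tx)^2 + (r$y - ty)^2))
    })
    snr_pair <- purrr::map2(records, ids, function(r, id) {
      tt <- dplyr::filter(tr, .data$athlete_id == id)
      tx <- approx(tt$t, tt$x, xout = r$t, rule = 2)$y
      sig <- rms(tx - mean(tx))
      fused_snr <- as.numeric(compute_snr(sig, max(rms(r$x - tx), 1e-12)))
      s <- streams[[paste0(id, "/gps")]]
      raw_snr <- NA_real_
      if (!is.null(s)) {
        rx <- approx(s$t[!s$dropout], s$x[!s$dropout], xout = r$t, rule = 2)$y
        raw_snr <- as.numeric(compute_snr(sig, max(rms(rx - tx), 1e-12)))
      }
      c(fused = fused_snr, raw = raw_snr)
    })
    sm <- do.call(rbind, snr_pair)
    rep_$position_rmse_m <- sqrt(mean(errs^2))
    rep_$fused_snr_db <- mean(sm[, "fused"], na.rm = TRUE)
    rep_$raw_gps_snr_db <- mean(sm[, "raw"], na.rm = TRUE)
    rep_$snr_gain_db <- rep_$fused_snr_db - rep_$raw_gps_snr_db
  }
  structure(rep_, class = "tf_quality")
}
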