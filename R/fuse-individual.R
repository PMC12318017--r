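# Whole-stream noise SD estimate from the out-of-band spectral residual:
# RMS of (raw - zero-lag low-pass), middle 80% of the stream to avoid
# filter edge transients, scaled up by the white-noise band fraction so the
# estimate is unbiased for broadband noise.
stream_noise_var <- function(t, v, fs, cutoff_hz) {
  v <- bridge_na(v)
  n <- length(v)
  if (n < 16) return(var(diff(v)) / 2)
  cutoff <- min(cutoff_hz, 0.45 * fs)
  resid <- v - filt_fb(v, cutoff, fs, 4)
  trim <- max(1, floor(0.1 * n))
  core <- resid[trim:(n - trim)]
  band_frac <- max(1e-3, (fs / 2 - cutoff) / (fs / 2))
  mean(core^2) / band_frac
}

# Block-wise robust noise tracker: within each block, sigma^2 is estimated
# from second differences of consecutive valid samples (for white noise
# E[d2^2] = 6 sigma^2; smooth-trajectory curvature contributes O(dt^4)).
# Returns one sigma^2 per block; empty blocks inherit the previous value.
block_noise_track <- function(t, v, block_edges) {
  nb <- length(block_edges) - 1
  out <- rep(NA_real_, nb)
  ok <- !is.na(v)
  for (b in seq_len(nb)) {
    in_b <- which(t >= block_edges[b] & t < block_edges[b + 1] & ok)
    if (length(in_b) >= 4 && all(diff(in_b) == 1)) {
      d2 <- diff(v[in_b], differences = 2)
      out[b] <- sum(d2^2) / (6 * length(d2))
    } else if (length(in_b) >= 4) {
      runs <- split(in_b, cumsum(c(1, diff(in_b) != 1)))
      d2 <- unlist(purrr::map(runs, function(r)
        if (length(r) >= 3) diff(v[r], differences = 2) else numeric(0)))
      if (length(d2) >= 2) out[b] <- sum(d2^2) / (6 * length(d2))
    }
  }
  # carry last estimate across empty blocks
  for (b in seq_len(nb)) {
    if (is.na(out[b])) out[b] <- if (b > 1) out[b - 1] else Inf
  }
  out
}

# Double time-integral of IMU acceleration used for dead-reckoning
# increments between positional fixes. Returns NULL when no IMU stream.
imu_double_integral <- function(imu) {
  if (is.null(imu)) return(NULL)
  tt <- imu$t
  out <- list(t = tt)
  for (ch in c("ax", "ay")) {
    a <- bridge_na(imu[[ch]])
    vI <- pracma::cumtrapz(tt, a)[, 1]
    out[[ch]] <- pracma::cumtrapz(tt, vI)[, 1]
  }
  out
}

# In-gap curvature correction for one positional source: between
# consecutive fixes the linearly interpolated fix estimate is bent by the
# IMU double integral (which vanishes at the fixes themselves).
gap_correction <- function(fix_t, grid, ii_t, ii_v) {
  if (is.null(ii_t) || length(fix_t) < 2) return(numeric(length(grid)))
  ii_g <- approx(ii_t, ii_v, xout = grid, rule = 2)$y
  ii_f <- approx(ii_t, ii_v, xout = fix_t, rule = 2)$y
  idx <- findInterval(grid, fix_t)
  corr <- numeric(length(grid))
  inside <- idx >= 1 & idx < length(fix_t)
  i0 <- idx[inside]
  tl <- fix_t[i0]; tr <- fix_t[i0 + 1]
  frac <- (grid[inside] - tl) / (tr - tl)
  corr[inside] <- ii_g[inside] - (ii_f[i0] + frac * (ii_f[i0 + 1] - ii_f[i0]))
  corr
}

# Sensor-level positional estimate of one source on the analysis grid:
# linear interpolation between (non-dropout) fixes plus the dead-reckoning
# increment. Exact at grid points that coincide with fixes.
source_position_estimate <- function(stream, grid, ii = NULL) {
  ok <- !stream$dropout & !is.na(stream$x)
  fix_t <- stream$t[ok]
  if (length(fix_t) < 2) return(NULL)
  est <- list()
  for (ch in c("x", "y")) {
    base <- approx(fix_t, stream[[ch]][ok], xout = grid, rule = 2)$y
    corr <- if (!is.null(ii)) {
      gap_correction(fix_t, grid, ii$t, ii[[c(x = "ax", y = "ay")[ch]]])
    } else numeric(length(grid))
    est[[ch]] <- base + corr
  }
  est
}

#' Individual-level fusion of one athlete's streams
#'
#' Consolidates all sensor streams of one athlete into a single
#' common-clock kinematic and physiological record. Position is the
#' adaptive-weight combination of the LPS/GPS estimates (each linearly
#' interpolated between fixes and bent by the IMU dead-reckoning increment
#' inside fix gaps); the per-source combination weights are
#' contextual-relevance-scaled precision weights from a block-wise noise
#' tracker, smoothed through the `lambda` recursion, so a degrading source
#' loses weight within a few update steps. Orientation comes from the
#' complementary filter on gyroscope and inclination channels, heart rate
#' is low-pass filtered, and load accumulates insole force over time.
#'
#' @param streams list of `tf_stream` for a single athlete.
#' @param config a [tf_config()].
#' @param out_rate_hz analysis grid rate, Hz (default from config).
#' @param block_s weight-update interval, seconds (default 1).
#' @return tibble of class `tf_record` with columns t, x, y, vx, vy, ax,
#'   ay, orientation_deg, heart_rate, load; attributes `athlete_id`,
#'   `weights` (per-block weight history) and `sources`.
#' @export
fuse_individual <- function(streams, config = tf_config(),
                            out_rate_hz = NULL, block_s = 1) {
  out_rate_hz <- out_rate_hz %||% config$align$out_rate_hz
  mods <- vapply(streams, function(s) attr(s, "modality"), character(1))
  athlete_id <- unique(vapply(streams, function(s) attr(s, "athlete_id"),
                              character(1)))
  if (length(athlete_id) != 1) {
    tf_validation_error("streams must all belong to one athlete", "streams")
  }
  pos_streams <- streams[mods %in% c("gps", "lps")]
  if (length(pos_streams) == 0) {
    tf_abort("no positional source (gps/lps) for athlete", class = "tf_error")
  }
  imu <- if (any(mods == "imu")) streams[[which(mods == "imu")[1]]] else NULL
  physio <- if (any(mods == "physio"))
    streams[[which(mods == "physio")[1]]] else NULL
  insole <- if (any(mods == "insole"))
    streams[[which(mods == "insole")[1]]] else NULL

  t0 <- max(vapply(pos_streams, function(s) min(s$t), numeric(1)))
  t1 <- min(vapply(pos_streams, function(s) max(s$t), numeric(1)))
  grid <- seq(t0, t1, by = 1 / out_rate_hz)
  dt <- 1 / out_rate_hz

  ii <- imu_double_integral(imu)
  ests <- purrr::map(pos_streams, source_position_estimate, grid = grid,
                     ii = ii)
  keep <- !vapply(ests, is.null, logical(1))
  pos_streams <- pos_streams[keep]; ests <- ests[keep]
  if (length(ests) == 0) tf_abort("no usable positional fixes",
                                  class = "tf_error")
  src_names <- vapply(pos_streams, stream_id, character(1))
  src_mods <- vapply(pos_streams, function(s) attr(s, "modality"),
                     character(1))

  # high-dynamics context from IMU (used by the relevance score)
  high_dyn <- rep(FALSE, length(grid))
  if (!is.null(imu)) {
    amag <- sqrt(bridge_na(imu$ax)^2 + bridge_na(imu$ay)^2)
    amag_f <- filt_fb(amag, min(2, 0.45 * attr(imu, "sample_rate_hz")),
                      attr(imu, "sample_rate_hz"), 4)
    high_dyn <- approx(imu$t, amag_f, xout = grid, rule = 2)$y >
      config$fuse$accel_context_mps2
  }

  # block-wise adaptive weights
  edges <- seq(t0, t1 + block_s, by = block_s)
  nb <- length(edges) - 1
  nv <- purrr::map(pos_streams, function(s) {
    (block_noise_track(s$t, s$x, edges) +
       block_noise_track(s$t, s$y, edges)) / 2
  })
  lambda <- config$fuse$lambda
  k <- length(ests)
  W <- matrix(0, nb, k)
  w_raw <- rep(1 / k, k)
  r_block <- vapply(seq_len(k), function(i) {
    mean(context_relevance(src_mods[i], high_dyn,
                           config$fuse$accel_context_mps2))
  }, numeric(1))
  qr_hist <- matrix(0, nb, k)
  for (b in seq_len(nb)) {
    prec <- vapply(seq_len(k), function(i)
      r_block[i] / max(nv[[i]][b], 1e-12), numeric(1))
    q_share <- prec / sum(prec)   # normalized quality*relevance in [0,1]
    if (b == 1) w_raw <- q_share  # no history yet: trust current quality
    upd <- update_weight(w_raw, q = q_share, r = 1, lambda = lambda)
    w_raw <- upd$w
    W[b, ] <- upd$w_norm
    qr_hist[b, ] <- q_share
  }
  block_mid <- (edges[-length(edges)] + edges[-1]) / 2
  w_grid <- purrr::map(seq_len(k), function(i) {
    approx(block_mid, W[, i], xout = grid, method = "constant",
           rule = 2, f = 0)$y
  })
  wsum <- Reduce(`+`, w_grid)
  w_grid <- purrr::map(w_grid, function(w) w / wsum)

  fx <- Reduce(`+`, purrr::map2(ests, w_grid, function(e, w) e$x * w))
  fy <- Reduce(`+`, purrr::map2(ests, w_grid, function(e, w) e$y * w))

  vx <- cgrad(fx, dt); vy <- cgrad(fy, dt)
  if (length(grid) > 24) {
    vx <- filt_fb(vx, min(2, 0.45 * out_rate_hz), out_rate_hz, 4)
    vy <- filt_fb(vy, min(2, 0.45 * out_rate_hz), out_rate_hz, 4)
  }
  ax <- cgrad(vx, dt); ay <- cgrad(vy, dt)

  orient <- rep(NA_real_, length(grid))
  if (!is.null(imu) && all(c("gyro_z", "incl_deg") %in% names(imu))) {
    fs_imu <- attr(imu, "sample_rate_hz")
    th <- orientation_series(bridge_na(imu$gyro_z), bridge_na(imu$incl_deg),
                             alpha = config$preprocess$alpha, dt = 1 / fs_imu)
    orient <- approx(imu$t, th, xout = grid, rule = 2)$y
  }

  hr <- rep(NA_real_, length(grid))
  if (!is.null(physio) && "hr" %in% names(physio)) {
    fs_p <- attr(physio, "sample_rate_hz")
    v <- bridge_na(physio$hr)
    if (length(v) > 24) {
      v <- filt_fb(v, min(config$preprocess$cutoff_hz$physio, 0.45 * fs_p),
                   fs_p, 4)
    }
    hr <- approx(physio$t, v, xout = grid, rule = 2)$y
  }

  load <- rep(NA_real_, length(grid))
  if (!is.null(insole) && "force" %in% names(insole)) {
    f <- bridge_na(insole$force)
    cl <- pracma::cumtrapz(insole$t, f)[, 1]
    load <- approx(insole$t, cl, xout = grid, rule = 2)$y
  } else {
    load <- pracma::cumtrapz(grid, sqrt(ax^2 + ay^2))[, 1]
  }

  weights_hist <- tibble(
    block_t = rep(block_mid, k),
    source = rep(src_names, each = nb),
    modality = rep(src_mods, each = nb),
    weight = as.vector(W),
    quality_share = as.vector(qr_hist))

  structure(
    tibble(t = grid, x = fx, y = fy, vx = vx, vy = vy, ax = ax, ay = ay,
           orientation_deg = orient, heart_rate = hr, load = load),
    class = c("tf_record", class(tibble())),
    athlete_id = athlete_id, weights = weights_hist, sources = src_names)
}
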