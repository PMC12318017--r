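#' Windowed collaborative-dynamics indicator series
#'
#' Computes the eight-indicator coordination system plus spatial entropy,
#' the relative position maintenance index and the mean Kuramoto order
#' parameter over sliding windows (default 10 s, 50% overlap) of a team
#' trajectory:
#'
#' * **SSI** — spatial synchronization: mean pairwise Pearson correlation
#'   of athletes' velocity components.
#' * **TCR** — temporal coordination rate: fraction of
#'   acceleration/deceleration onsets (|a| crossing the threshold) shared
#'   by at least half the team within the synchrony window.
#' * **FSQ** — formation stability: `1 / (1 + CV)` of centroid-centred
#'   inter-athlete distances.
#' * **TIE** — tactical information entropy: normalized Shannon entropy of
#'   the pass-count distribution over ordered athlete pairs.
#' * **CPR** — perturbation response: seconds for SSI to re-enter its
#'   pre-perturbation mean +- 1 SD band (session-level, repeated per
#'   window; NA when the session has no perturbations).
#' * **ICC** — individual-collective coupling: mean correlation between
#'   individual and centroid velocity.
#' * **DMS** — decision-making synchronicity: order parameter of athlete
#'   phases at decisive-action times inside the window.
#' * **LDH** — load distribution harmony: `1 - Gini` of per-athlete load
#'   accumulated in the window.
#'
#' Indicators whose required events are absent in a window are `NA`
#' (missing), never zero.
#'
#' @param team a `tf_team`.
#' @param events a `tf_events` (may be empty).
#' @param loads optional long tibble (t, athlete_id, load) of cumulative
#'   per-athlete load.
#' @param config a [tf_config()].
#' @param team_id restrict to one team label (default `"A"` when present).
#' @param pitch_extent pitch bounds for the zone grid; default spans the
#'   observed positions.
#' @param d_ref optional reference pairwise-distance matrix (time x pair)
#'   for RPM; default is the static session-mean template (fallback rule).
#' @return tibble of class `tf_indicators`: window centre `t` plus one
#'   column per indicator; attribute `window_s`.
#' @export
compute_indicators <- function(team, events = tf_events(), loads = NULL,
                               config = tf_config(), team_id = NULL,
                               pitch_extent = NULL, d_ref = NULL) {
  ic <- config$indicators
  if (is.null(team_id) && "A" %in% team$team) team_id <- "A"
  if (!is.null(team_id)) team <- dplyr::filter(team, .data$team == team_id)
  ids <- sort(unique(team$athlete_id))
  n <- length(ids)
  if (n < 2) tf_abort("need at least 2 athletes", class = "tf_error")
  tt <- sort(unique(team$t))
  fs <- 1 / median(diff(tt))
  if (length(tt) < 2 * ic$window_s * fs) {
    tf_abort("need at least two analysis windows of data", class = "tf_error")
  }
  wide <- function(col) {
    m <- matrix(NA_real_, length(tt), n, dimnames = list(NULL, ids))
    for (j in seq_len(n)) {
      sub <- team[team$athlete_id == ids[j], ]
      m[match(sub$t, tt), j] <- sub[[col]]
    }
    m
  }
  X <- wide("x"); Y <- wide("y"); VX <- wide("vx"); VY <- wide("vy")
  cx <- rowMeans(X); cy <- rowMeans(Y)
  cvx <- rowMeans(VX); cvy <- rowMeans(VY)
  dt <- 1 / fs
  AX <- apply(VX, 2, cgrad, dt = dt); AY <- apply(VY, 2, cgrad, dt = dt)
  AMAG <- sqrt(AX^2 + AY^2)

  # movement phases from band-passed x displacement (the band-pass removes
  # slow centroid drift; centroid-centring would also cancel the shared
  # oscillation that synchronization is supposed to reveal)
  PH <- matrix(NA_real_, length(tt), n)
  ph_valid <- rep(TRUE, length(tt))
  for (j in seq_len(n)) {
    hp <- hilbert_phase(X[, j], fs, band = ic$phase_band_hz,
                        edge_trim = ic$edge_trim)
    PH[, j] <- hp$phase
    ph_valid <- ph_valid & hp$valid
  }
  Rt <- order_parameter(PH)
  Rt[!ph_valid] <- NA_real_

  # acceleration onset times per athlete (rising threshold crossings)
  onset_times <- purrr::map(seq_len(n), function(j) {
    above <- AMAG[, j] > ic$accel_threshold_mps2
    tt[which(diff(c(FALSE, above)) == 1)]
  })

  pairs <- utils::combn(n, 2)
  pair_dist <- function(w_idx) {
    vapply(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      sqrt(((X[w_idx, i] - cx[w_idx]) - (X[w_idx, j] - cx[w_idx]))^2 +
             ((Y[w_idx, i] - cy[w_idx]) - (Y[w_idx, j] - cy[w_idx]))^2)
    }, numeric(length(w_idx)))
  }
  if (is.null(pitch_extent)) {
    pitch_extent <- c(min(X), max(X), min(Y), max(Y))
  }

  step <- ic$window_s * (1 - ic$overlap)
  starts <- seq(tt[1], tt[length(tt)] - ic$window_s, by = step)
  win <- purrr::map_dfr(starts, function(t0) {
    idx <- which(tt >= t0 & tt < t0 + ic$window_s)
    mid <- t0 + ic$window_s / 2
    ssi <- window_ssi(VX[idx, ], VY[idx, ], pairs)
    # TCR: shared accel events
    ev_all <- sort(unlist(purrr::map(onset_times, function(o)
      o[o >= t0 & o < t0 + ic$window_s])))
    tcr <- if (length(ev_all) == 0) NA_real_ else {
      shared <- vapply(ev_all, function(te) {
        hits <- vapply(onset_times, function(o)
          any(abs(o - te) <= ic$sync_window_s / 2), logical(1))
        sum(hits) >= n / 2
      }, logical(1))
      mean(shared)
    }
    D <- pair_dist(idx)
    cvs <- apply(D, 2, function(d) if (mean(d) > 0) sd(d) / mean(d) else 0)
    fsq <- 1 / (1 + mean(cvs))
    # TIE over ordered pairs of passes in window
    pw <- dplyr::filter(events, .data$event_type == "pass",
                        .data$t >= t0, .data$t < t0 + ic$window_s,
                        .data$athlete_id %in% ids,
                        .data$target_athlete_id %in% ids)
    tie <- if (nrow(pw) == 0) NA_real_ else {
      key <- paste(pw$athlete_id, pw$target_athlete_id)
      tie_entropy(table(key), n_pairs = n * (n - 1))
    }
    icc <- window_icc(VX[idx, ], VY[idx, ], cvx[idx], cvy[idx])
    dec <- dplyr::filter(events, .data$event_type == "decisive_action",
                         .data$t >= t0, .data$t < t0 + ic$window_s)
    dms <- if (nrow(dec) == 0) NA_real_ else {
      ri <- vapply(dec$t, function(te) {
        k <- which.min(abs(tt - te))
        if (ph_valid[k]) order_parameter(PH[k, ]) else NA_real_
      }, numeric(1))
      mean(ri, na.rm = TRUE)
    }
    ldh <- NA_real_
    if (!is.null(loads)) {
      inc <- vapply(ids, function(id) {
        lsub <- loads[loads$athlete_id == id, ]
        if (nrow(lsub) < 2) return(NA_real_)
        l0 <- approx(lsub$t, lsub$load, xout = t0, rule = 2)$y
        l1 <- approx(lsub$t, lsub$load, xout = t0 + ic$window_s, rule = 2)$y
        max(l1 - l0, 0)
      }, numeric(1))
      if (!anyNA(inc) && sum(inc) > 0) ldh <- 1 - gini(inc)
    }
    occ <- zone_occupancy(
      tibble(athlete_id = rep(ids, each = length(idx)),
             x = as.vector(X[idx, ]), y = as.vector(Y[idx, ])),
      n_x = ic$zone_nx, n_y = ic$zone_ny, pitch_extent = pitch_extent)
    s_sp <- spatial_entropy(occ)
    Dref <- if (is.null(d_ref)) {
      matrix(colMeans(D), 1)
    } else d_ref[idx, , drop = FALSE]
    rpm_w <- suppressWarnings(as.numeric(rpm(D, Dref)))
    tibble(t = mid, ssi = ssi, tcr = tcr, fsq = fsq, tie = tie,
           icc = icc, dms = dms, ldh = ldh, s_spatial = s_sp, rpm = rpm_w,
           r_mean = mean(Rt[idx], na.rm = TRUE))
  })

  # CPR: session-level recovery time of SSI after each perturbation
  win$cpr <- cpr_recovery(win$t, win$ssi, events, window_s = ic$window_s)
  out <- win[c("t", "ssi", "tcr", "fsq", "tie", "cpr", "icc", "dms", "ldh",
               "s_spatial", "rpm", "r_mean")]
  structure(out, class = c("tf_indicators", class(tibble())),
            window_s = ic$window_s)
}

window_ssi <- function(VX, VY, pairs) {
  vals <- vapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cx_ <- safe_cor(VX[, i], VX[, j])
    cy_ <- safe_cor(VY[, i], VY[, j])
    mean(c(cx_, cy_), na.rm = TRUE)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

window_icc <- function(VX, VY, cvx, cvy) {
  vals <- vapply(seq_len(ncol(VX)), function(j) {
    mean(c(safe_cor(VX[, j], cvx), safe_cor(VY[, j], cvy)), na.rm = TRUE)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

safe_cor <- function(a, b) {
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
  cor(a, b)
}

tie_entropy <- function(counts, n_pairs) {
  p <- as.numeric(counts) / sum(counts)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  if (n_pairs <= 1) return(NA_real_)
  h / log2(n_pairs)
}

# Recovery time to the pre-perturbation SSI band (mean +- 1 SD of the
# baseline windows); mean over perturbations, NA when none or unrecovered.
cpr_recovery <- function(wt, ssi, events, window_s, lookback_s = 30) {
  pert <- events$t[events$event_type == "perturbation"]
  if (length(pert) == 0) return(rep(NA_real_, length(wt)))
  recov <- vapply(pert, function(tp) {
    base_idx <- which(wt < tp & wt >= tp - lookback_s)
    if (length(base_idx) < 2) return(NA_real_)
    mu <- mean(ssi[base_idx], na.rm = TRUE)
    sdv <- sd(ssi[base_idx], na.rm = TRUE)
    after <- which(wt > tp)
    if (length(after) == 0) return(NA_real_)
    ok <- after[!is.na(ssi[after]) & ssi[after] >= mu - sdv]
    if (length(ok) == 0) return(NA_real_)  # unrecovered
    wt[ok[1]] - tp
  }, numeric(1))
  rep(mean(recov, na.rm = TRUE), length(wt))
}
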