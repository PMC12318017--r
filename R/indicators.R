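#' Zone occupancy distribution on a pitch grid
#'
#' Fraction of time each athlete spends in each cell of an axis-aligned
#' grid over the pitch. With `joint = TRUE` (default) the distribution is
#' normalized over athletes and zones jointly (sums to 1 overall); with
#' `joint = FALSE` each athlete's row distribution sums to 1.
#'
#' @param team a `tf_team` (or data frame with athlete_id, x, y).
#' @param n_x,n_y zone counts along x and y.
#' @param pitch_extent `c(x_min, x_max, y_min, y_max)`, metres.
#' @param joint joint or per-athlete normalization.
#' @return tibble of class `tf_zones`: athlete_id, zone_x, zone_y, p.
#' @export
zone_occupancy <- function(team, n_x = 6, n_y = 4, pitch_extent,
                           joint = TRUE) {
  bx <- seq(pitch_extent[1], pitch_extent[2], length.out = n_x + 1)
  by <- seq(pitch_extent[3], pitch_extent[4], length.out = n_y + 1)
  zx <- pmin(pmax(findInterval(team$x, bx, all.inside = TRUE), 1), n_x)
  zy <- pmin(pmax(findInterval(team$y, by, all.inside = TRUE), 1), n_y)
  counts <- dplyr::count(tibble(athlete_id = team$athlete_id,
                                zone_x = zx, zone_y = zy),
                         .data$athlete_id, .data$zone_x, .data$zone_y)
  if (joint) {
    counts$p <- counts$n / sum(counts$n)
  } else {
    counts <- counts |>
      group_by(.data$athlete_id) |>
      mutate(p = .data$n / sum(.data$n)) |>
      ungroup()
  }
  structure(select(counts, -"n"),
            class = c("tf_zones", class(tibble())), joint = joint)
}

#' Team spatial entropy
#'
#' Shannon entropy (bits) of the occupancy probabilities `p_{i,j}` of
#' athletes over spatial zones: `S = -sum p log2 p` with `0 log 0 = 0`.
#' Uniform occupancy over `n` cells gives `log2(n)`, full concentration
#' gives 0.
#'
#' @param p a `tf_zones` from [zone_occupancy()] or a numeric probability
#'   vector (must sum to 1 within 1e-6).
#' @return entropy in bits.
#' @export
#' @examples
#' spatial_entropy(c(0.5, 0.25, 0.125, 0.125))  # 1.75
spatial_entropy <- function(p) {
  if (inherits(p, "tf_zones") || is.data.frame(p)) p <- p$p
  if (abs(sum(p) - 1) > 1e-6) {
    tf_validation_error("occupancy probabilities must sum to 1", "p")
  }
  if (any(p < 0)) tf_validation_error("probabilities must be >= 0", "p")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Relative position maintenance index
#'
#' Mean over athlete pairs of the Pearson correlation between observed and
#' reference inter-athlete distance series. Pairs whose observed or
#' reference series is constant are excluded with a warning; when the
#' reference is constant for every pair (a static tactical template makes
#' the normalized covariance degenerate) the documented fallback
#' `1 - min(1, MAE / reference)` per pair is used instead and flagged via
#' the `"fallback"` attribute.
#'
#' @param d numeric matrix of observed pairwise distances, time in rows,
#'   one column per pair.
#' @param d_ref matching matrix of reference distances (a time series, or
#'   constant columns for a static template).
#' @return RPM in `[-1, 1]` (NA if undefined for all pairs).
#' @export
rpm <- function(d, d_ref) {
  d <- as.matrix(d); d_ref <- as.matrix(d_ref)
  if (nrow(d_ref) == 1) d_ref <- d_ref[rep(1, nrow(d)), , drop = FALSE]
  if (!all(dim(d) == dim(d_ref))) {
    tf_validation_error("d and d_ref must have matching dimensions", "d_ref")
  }
  sd_obs <- apply(d, 2, sd)
  sd_ref <- apply(d_ref, 2, sd)
  if (all(sd_ref < 1e-12)) {
    # static-template fallback: agreement = 1 - normalized MAE
    vals <- vapply(seq_len(ncol(d)), function(j) {
      ref <- mean(d_ref[, j])
      if (ref <= 0) return(NA_real_)
      1 - min(1, mean(abs(d[, j] - ref)) / ref)
    }, numeric(1))
    out <- mean(vals, na.rm = TRUE)
    attr(out, "fallback") <- "constant_reference"
    return(out)
  }
  usable <- sd_obs > 1e-12 & sd_ref > 1e-12
  if (!any(usable)) {
    warn("rpm: all pairs constant; undefined")
    return(structure(NA_real_, fallback = "undefined"))
  }
  if (!all(usable)) warn("rpm: constant pair series excluded")
  mean(vapply(which(usable), function(j) cor(d[, j], d_ref[, j]), numeric(1)))
}

#' Cross-recurrence quantification between two state trajectories
#'
#' Thresholded cross-recurrence matrix
#' `CR(m, n) = 1 if ||X_i(m) - X_j(n)|| <= epsilon` and its line-structure
#' statistics: recurrence rate RR, determinism DET (fraction of recurrent
#' points on diagonal lines of length >= `l_min`), laminarity LAM (same for
#' vertical lines) and the Shannon entropy (bits) of the diagonal line
#' length distribution. `scale > 1` applies block-mean coarse-graining to
#' both trajectories first (the multi-scale variant).
#'
#' @param Xi,Xj numeric matrices (time in rows, state components in
#'   columns) of equal column count.
#' @param epsilon recurrence threshold, > 0, in state-distance units.
#' @param scale coarse-graining factor (>= 1).
#' @param l_min minimum line length (default 2).
#' @return list of class `tf_crqa`: `CR`, `RR`, `DET`, `LAM`, `ENT_diag`,
#'   `epsilon`, `scale`.
#' @export
cross_recurrence <- function(Xi, Xj, epsilon, scale = 1, l_min = 2) {
  if (epsilon <= 0) tf_validation_error("epsilon must be > 0", "epsilon")
  Xi <- as.matrix(Xi); Xj <- as.matrix(Xj)
  if (ncol(Xi) != ncol(Xj)) {
    tf_validation_error("state dimensions differ", "Xj")
  }
  if (scale > 1) {
    Xi <- coarse_grain(Xi, scale)
    Xj <- coarse_grain(Xj, scale)
  }
  D2 <- outer(rowSums(Xi^2), rowSums(Xj^2), `+`) - 2 * Xi %*% t(Xj)
  D2[D2 < 0] <- 0
  CR <- (sqrt(D2) <= epsilon) * 1L
  diag_lengths <- line_lengths(CR, "diagonal")
  vert_lengths <- line_lengths(CR, "vertical")
  n_rec <- sum(CR)
  det_ <- if (n_rec > 0) {
    sum(diag_lengths[diag_lengths >= l_min]) / n_rec
  } else NA_real_
  lam <- if (n_rec > 0) {
    sum(vert_lengths[vert_lengths >= l_min]) / n_rec
  } else NA_real_
  dl <- diag_lengths[diag_lengths >= l_min]
  ent <- if (length(dl) > 0) discrete_entropy(table(dl)) else 0
  structure(list(CR = CR, RR = mean(CR), DET = det_, LAM = lam,
                 ENT_diag = ent, epsilon = epsilon, scale = scale,
                 l_min = l_min),
            class = "tf_crqa")
}

coarse_grain <- function(X, scale) {
  n <- floor(nrow(X) / scale)
  if (n < 1) tf_validation_error("series too short for this scale", "scale")
  idx <- rep(seq_len(n), each = scale)
  apply(X[seq_len(n * scale), , drop = FALSE], 2, function(v)
    tapply(v, idx, mean))
}

# run lengths of 1s along all diagonals or all columns of a binary matrix
line_lengths <- function(CR, direction = c("diagonal", "vertical")) {
  direction <- match.arg(direction)
  out <- integer(0)
  if (direction == "vertical") {
    for (j in seq_len(ncol(CR))) {
      r <- rle(CR[, j])
      out <- c(out, r$lengths[r$values == 1])
    }
  } else {
    n <- nrow(CR); m <- ncol(CR)
    for (k in seq(-(n - 1), m - 1)) {
      i <- max(1, 1 - k):min(n, m - k)
      v <- CR[cbind(i, i + k)]
      r <- rle(v)
      out <- c(out, r$lengths[r$values == 1])
    }
  }
  out
}

#' Multi-scale cross-recurrence analysis
#'
#' [cross_recurrence()] at several coarse-graining scales with a common
#' threshold rule: `epsilon` is the given quantile fraction of the maximum
#' pairwise state distance at scale 1.
#'
#' @param Xi,Xj state matrices as in [cross_recurrence()] (z-scored
#'   internally per component).
#' @param scales integer coarse-graining factors.
#' @param eps_frac epsilon as a fraction of the maximum state distance.
#' @param l_min minimum line length.
#' @return tibble: scale, epsilon, RR, DET, LAM, ENT_diag.
#' @export
ms_crqa <- function(Xi, Xj, scales = c(1, 2, 4), eps_frac = 0.1, l_min = 2) {
  zs <- function(M) apply(as.matrix(M), 2, function(v) {
    s <- sd(v)
    if (s > 0) (v - mean(v)) / s else v - mean(v)
  })
  Xi <- zs(Xi); Xj <- zs(Xj)
  D2 <- outer(rowSums(Xi^2), rowSums(Xj^2), `+`) - 2 * Xi %*% t(Xj)
  eps <- eps_frac * sqrt(max(D2, 0))
  if (eps <= 0) eps <- 1e-12
  purrr::map_dfr(scales, function(sc) {
    r <- cross_recurrence(Xi, Xj, eps, scale = sc, l_min = l_min)
    tibble(scale = sc, epsilon = eps, RR = r$RR, DET = r$DET,
           LAM = r$LAM, ENT_diag = r$ENT_diag)
  })
}

#' Instantaneous movement phase via the Hilbert transform
#'
#' Band-passes the movement signal (default 0.1-2 Hz, the bulk of team
#' displacement dynamics), removes the mean, and takes the unwrapped phase
#' of the FFT-based analytic signal. The first and last `edge_trim`
#' fraction of samples carry transform edge effects; `valid` marks the
#' trustworthy core.
#'
#' @param x numeric movement signal.
#' @param fs sampling rate, Hz.
#' @param band band-pass corner frequencies `c(lo, hi)` in Hz, or `NULL`
#'   to skip filtering.
#' @param edge_trim fraction trimmed at each end for `valid`.
#' @return list of class `tf_phase`: `phase` (unwrapped, radians), `valid`
#'   (logical), `flat` flag.
#' @export
hilbert_phase <- function(x, fs, band = c(0.1, 2), edge_trim = 0.05) {
  xc <- x - mean(x, na.rm = TRUE)
  xc[is.na(xc)] <- 0
  n <- length(xc)
  if (max(abs(xc)) < 1e-12) {
    return(structure(list(phase = rep(NA_real_, n),
                          valid = rep(FALSE, n), flat = TRUE),
                     class = "tf_phase"))
  }
  if (!is.null(band)) {
    lo <- max(band[1], 1e-3); hi <- min(band[2], 0.45 * fs)
    if (hi > lo && n > 30) {
      b <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
      xc <- filtfilt_padded(b, xc)
    }
  }
  ph <- signal::unwrap(Arg(analytic_signal(xc)))
  k <- max(1, floor(edge_trim * n))
  valid <- rep(TRUE, n)
  valid[seq_len(k)] <- FALSE
  valid[seq(n - k + 1, n)] <- FALSE
  structure(list(phase = ph, valid = valid, flat = FALSE),
            class = "tf_phase")
}

#' Kuramoto order parameter
#'
#' `R(t) = |mean_j exp(i phi_j(t))|`: 1 when all athletes' phases
#' coincide, near 0 for incoherent phases.
#'
#' @param phases numeric matrix, time in rows, one column per athlete (a
#'   single time point may be given as a vector).
#' @return numeric vector of `R(t)` in `[0, 1]`.
#' @export
#' @examples
#' order_parameter(matrix(c(0, 0, 0), 1))  # 1
order_parameter <- function(phases) {
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1)
  Mod(rowMeans(exp(1i * phases)))
}
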