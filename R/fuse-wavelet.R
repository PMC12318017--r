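# Orthonormal Daubechies scaling filters (sum = sqrt(2), unit energy).
wp_filters <- function(wavelet = c("db4", "db2", "db1")) {
  wavelet <- match.arg(wavelet)
  h <- switch(wavelet,
    db1 = c(1, 1) / sqrt(2),
    db2 = c(0.482962913144690, 0.836516303737469,
            0.224143868041857, -0.129409522550921),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

# periodized analysis step: correlate with stride 2 (length N -> N/2)
wp_down <- function(x, f) {
  N <- length(x)
  L <- length(f)
  k <- seq(0, N / 2 - 1)
  out <- numeric(N / 2)
  for (n in seq_len(L)) {
    out <- out + f[n] * x[((2 * k + n - 1) %% N) + 1]
  }
  out
}

# transpose (synthesis) step: length N/2 -> N
wp_up <- function(a, f, N) {
  L <- length(f)
  y <- numeric(N)
  ks <- seq(0, N / 2 - 1)
  for (n in seq_len(L)) {
    idx <- ((2 * ks + n - 1) %% N) + 1
    contrib <- f[n] * a
    y[idx] <- y[idx] + contrib
  }
  y
}

#' Wavelet packet decomposition
#'
#' Full wavelet packet tree to depth `K` with an orthonormal Daubechies
#' filter pair applied in periodized form: at every level both the low-pass
#' (approximation) and high-pass (detail) branches are split again, yielding
#' `2^K` leaf nodes covering contiguous frequency bands. Orthonormality
#' gives perfect reconstruction and exact energy conservation across leaves.
#' Signals whose length is not a multiple of `2^K` are zero-padded (the
#' original length is restored on reconstruction).
#'
#' @param x numeric signal, `length(x) >= 2^K`.
#' @param K decomposition depth (default 5).
#' @param wavelet `"db4"` (default), `"db2"` or `"db1"`.
#' @return list of class `tf_wavelet`: `leaves` (list of `2^K` coefficient
#'   vectors in natural tree order), `K`, `wavelet`, `n` (original length),
#'   `n_pad`.
#' @export
wavelet_packet <- function(x, K = 5, wavelet = "db4") {
  n <- length(x)
  if (n < 2^K) {
    tf_validation_error(sprintf(
      "signal too short: need at least 2^K = %d samples, got %d", 2^K, n),
      "x")
  }
  filt <- wp_filters(wavelet)
  n_pad <- ceiling(n / 2^K) * 2^K
  xp <- c(x, numeric(n_pad - n))
  nodes <- list(xp)
  for (lev in seq_len(K)) {
    nxt <- vector("list", 2 * length(nodes))
    for (j in seq_along(nodes)) {
      nxt[[2 * j - 1]] <- wp_down(nodes[[j]], filt$h)
      nxt[[2 * j]] <- wp_down(nodes[[j]], filt$g)
    }
    nodes <- nxt
  }
  structure(list(leaves = nodes, K = K, wavelet = wavelet,
                 n = n, n_pad = n_pad),
            class = "tf_wavelet")
}

#' Reconstruct a signal from its wavelet packet leaves
#'
#' Exact inverse of [wavelet_packet()] (relative error at numerical
#' round-off for untouched coefficients).
#'
#' @param wf a `tf_wavelet`.
#' @return numeric vector of the original length.
#' @export
wavelet_reconstruct <- function(wf) {
  filt <- wp_filters(wf$wavelet)
  nodes <- wf$leaves
  for (lev in seq_len(wf$K)) {
    N <- 2 * length(nodes[[1]])
    nxt <- vector("list", length(nodes) / 2)
    for (j in seq_along(nxt)) {
      nxt[[j]] <- wp_up(nodes[[2 * j - 1]], filt$h, N) +
        wp_up(nodes[[2 * j]], filt$g, N)
    }
    nodes <- nxt
  }
  nodes[[1]][seq_len(wf$n)]
}

#' Energy-ranked wavelet feature selection
#'
#' Keeps the top `ceil(alpha_feat * total)` packet coefficients by energy
#' and zeroes the rest, recording the reconstruction error of the reduced
#' representation. With orthonormal filters the retained energy fraction
#' equals one minus the squared relative reconstruction error, so the error
#' is non-increasing in `alpha_feat`.
#'
#' @param wf a `tf_wavelet`.
#' @param alpha_feat fraction of coefficients to keep, in `(0, 1]`
#'   (default 0.15).
#' @return list of class `tf_features`: `coefficients` (kept values),
#'   `index` (flat positions), `alpha_feat`, `n_kept`,
#'   `retained_energy_fraction`, `reconstruction_error` (relative L2),
#'   `reduced` (the thresholded `tf_wavelet`).
#' @export
select_features <- function(wf, alpha_feat = 0.15) {
  if (alpha_feat <= 0 || alpha_feat > 1) {
    tf_validation_error("alpha_feat must lie in (0, 1]", "alpha_feat")
  }
  flat <- unlist(wf$leaves)
  total <- length(flat)
  n_keep <- ceiling(alpha_feat * total)
  ord <- order(flat^2, decreasing = TRUE)
  keep_idx <- sort(ord[seq_len(n_keep)])
  mask <- logical(total)
  mask[keep_idx] <- TRUE
  reduced_flat <- ifelse(mask, flat, 0)
  sizes <- lengths(wf$leaves)
  reduced <- wf
  reduced$leaves <- split(reduced_flat,
                          rep(seq_along(sizes), sizes))
  names(reduced$leaves) <- NULL
  x0 <- wavelet_reconstruct(wf)
  x1 <- wavelet_reconstruct(reduced)
  denom <- sqrt(sum(x0^2))
  err <- if (denom > 0) sqrt(sum((x0 - x1)^2)) / denom else 0
  e_total <- sum(flat^2)
  structure(list(
    coefficients = flat[keep_idx], index = keep_idx,
    alpha_feat = alpha_feat, n_kept = n_keep,
    retained_energy_fraction = if (e_total > 0)
      sum(flat[keep_idx]^2) / e_total else 1,
    reconstruction_error = err, reduced = reduced),
    class = "tf_features")
}
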