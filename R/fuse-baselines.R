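#' Kalman filter fusion (baseline)
#'
#' Standard linear Kalman predict/update cycle
#' `x_k = x_pred + K_k (z_k - H x_pred)`, used as one of the reference
#' fusers in the comparison harness. Measurement rows with all-`NA` entries
#' are treated as missing (prediction only); individual `NA` components are
#' dropped from that update.
#'
#' @param z measurement series: numeric vector or matrix (time in rows).
#' @param A state transition matrix (default identity).
#' @param H observation matrix mapping state to measurement.
#' @param Q_proc process noise covariance.
#' @param R_meas measurement noise covariance.
#' @param x0 initial state.
#' @param P0 initial state covariance.
#' @return list of class `tf_kalman`: `x` (states, time in rows), `P_final`,
#'   `gain_final`.
#' @export
kalman_fuse <- function(z, A = NULL, H, Q_proc, R_meas, x0, P0) {
  z <- as.matrix(z)
  H <- as.matrix(H)
  Q_proc <- as.matrix(Q_proc)
  R_meas <- as.matrix(R_meas)
  ns <- length(x0)
  if (is.null(A)) A <- diag(ns)
  check_psd <- function(M, nm) {
    if (any(abs(M - t(M)) > 1e-8) || any(eigen(M, TRUE, TRUE)$values < -1e-10))
      tf_validation_error(paste0(nm, " must be symmetric PSD"), nm)
  }
  check_psd(Q_proc, "Q_proc"); check_psd(R_meas, "R_meas")
  x <- matrix(0, nrow(z), ns)
  xk <- as.numeric(x0)
  P <- as.matrix(P0)
  K <- matrix(0, ns, nrow(H))
  for (k in seq_len(nrow(z))) {
    xp <- A %*% xk
    Pp <- if (any(is.infinite(P))) P else A %*% P %*% t(A) + Q_proc
    zk <- z[k, ]
    obs <- !is.na(zk)
    if (any(obs) && any(is.infinite(Pp))) {
      # flat / improper prior: exact information-form update
      Ho <- H[obs, , drop = FALSE]
      Ro <- R_meas[obs, obs, drop = FALSE]
      info <- crossprod(Ho, solve(Ro, Ho))
      if (rcond(info) < 1e-14) {
        tf_abort("state not identifiable under flat prior",
                 class = "tf_numeric_error")
      }
      P <- solve(info)
      xk <- as.numeric(P %*% crossprod(Ho, solve(Ro, zk[obs])))
      x[k, ] <- xk
      next
    }
    if (any(obs)) {
      Ho <- H[obs, , drop = FALSE]
      Ro <- R_meas[obs, obs, drop = FALSE]
      S <- Ho %*% Pp %*% t(Ho) + Ro
      if (rcond(S) < 1e-14) {
        tf_abort("singular innovation covariance", class = "tf_numeric_error")
      }
      Ko <- Pp %*% t(Ho) %*% solve(S)
      xk <- as.numeric(xp + Ko %*% (zk[obs] - Ho %*% xp))
      P <- (diag(ns) - Ko %*% Ho) %*% Pp
      K[, obs] <- Ko
    } else {
      xk <- as.numeric(xp)
      P <- Pp
    }
    x[k, ] <- xk
  }
  structure(list(x = x, P_final = P, gain_final = K), class = "tf_kalman")
}

#' Fixed-weight average fusion (baseline)
#'
#' Convex combination of parallel source series with constant weights — the
#' non-adaptive reference fuser.
#'
#' @param sources list of numeric vectors of equal length.
#' @param weights non-negative weights summing to 1 (default equal).
#' @return fused numeric vector.
#' @export
weighted_average_fuse <- function(sources, weights = NULL) {
  k <- length(sources)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (any(weights < 0)) tf_validation_error("weights must be non-negative",
                                            "weights")
  if (abs(sum(weights) - 1) > 1e-8) {
    tf_validation_error("weights must sum to 1", "weights")
  }
  Reduce(`+`, purrr::map2(sources, weights, `*`))
}

#' Gaussian Bayesian fusion (baseline)
#'
#' Conjugate-Gaussian evidence combination: precisions add, the posterior
#' mean is the precision-weighted mean of prior and sources. Equivalent to
#' a static Kalman update on the same inputs.
#'
#' @param means numeric vector (or matrix, sources in columns) of source
#'   measurements.
#' @param vars numeric vector of source measurement variances.
#' @param prior_mean,prior_var optional Gaussian prior; `prior_var = Inf`
#'   (default) is the flat prior.
#' @return list: `mean` (posterior mean, same shape as one source),
#'   `var` (posterior variance).
#' @export
bayes_fuse <- function(means, vars, prior_mean = 0, prior_var = Inf) {
  if (is.matrix(means)) {
    stopifnot(length(vars) == ncol(means))
    prec <- 1 / vars
    prior_prec <- if (is.infinite(prior_var)) 0 else 1 / prior_var
    post_prec <- sum(prec) + prior_prec
    post_mean <- (means %*% prec + prior_prec * prior_mean) / post_prec
    return(list(mean = as.numeric(post_mean), var = 1 / post_prec))
  }
  stopifnot(length(vars) == length(means))
  prec <- 1 / vars
  prior_prec <- if (is.infinite(prior_var)) 0 else 1 / prior_var
  post_prec <- sum(prec) + prior_prec
  list(mean = sum(means * prec, prior_prec * prior_mean) / post_prec,
       var = 1 / post_prec)
}
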