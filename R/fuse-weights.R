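#' Adaptive fusion weight update
#'
#' One step of the exponential-decay weight recursion used at every fusion
#' level: `w_t = lambda * w_{t-1} + (1 - lambda) * q_t * r_t`, applied
#' per source and then renormalized so the weights of one fusion node sum
#' to 1. `lambda` balances established reliability against the immediate
#' quality assessment; `q` is the normalized signal quality in `[0, 1]` and
#' `r` the contextual relevance of the source for the current movement
#' pattern.
#'
#' @param w numeric vector of previous (pre-normalization) weights, one per
#'   source.
#' @param q numeric vector of qualities in `[0, 1]`.
#' @param r numeric vector of relevances in `[0, 1]` (recycled).
#' @param lambda temporal smoothing factor in `[0, 1]` (default 0.65).
#' @return list: `w` (updated raw weights), `w_norm` (renormalized to sum 1).
#' @export
#' @examples
#' update_weight(0.5, q = 1, r = 1, lambda = 0.65)$w  # 0.675
update_weight <- function(w, q, r = 1, lambda = 0.65) {
  if (lambda < 0 || lambda > 1) {
    tf_validation_error("lambda must lie in [0, 1]", "lambda")
  }
  if (any(q < 0 | q > 1) || any(r < 0 | r > 1)) {
    tf_validation_error("q and r must lie in [0, 1]", "q")
  }
  r <- rep_len(r, length(w))
  q <- rep_len(q, length(w))
  w_new <- lambda * w + (1 - lambda) * q * r
  s <- sum(w_new)
  list(w = w_new, w_norm = if (s > 0) w_new / s else rep(1 / length(w_new),
                                                         length(w_new)))
}

# SNR (dB) -> normalized quality in [0, 1]; 30 dB and above counts as fully
# trustworthy. Used for reporting and the recalibration logic.
snr_quality <- function(snr_db, snr_high_db = 30) {
  pmin(1, pmax(0, snr_db / snr_high_db))
}

# Contextual relevance of a modality given the local movement state.
# IMU information is most valuable during high-dynamics windows, satellite
# positioning during steady locomotion; LPS is reliable throughout.
context_relevance <- function(modality, high_dynamics,
                              accel_context_mps2 = 2) {
  base <- c(imu = 0.6, gps = 1.0, lps = 1.0, physio = 1.0, insole = 1.0)
  r <- rep(base[[modality]], length(high_dynamics))
  if (modality == "imu") r[high_dynamics] <- 1.0
  if (modality == "gps") r[high_dynamics] <- 0.8
  r
}
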