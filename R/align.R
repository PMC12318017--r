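#' Dynamic time warping distance and path
#'
#' Classic dynamic-programming DTW between two series under an elementwise
#' metric, with step set \{(1,0), (0,1), (1,1)\} (no slope weighting) and
#' both endpoints anchored. The returned distance is the minimal sum of
#' `metric(x[i], y[j])` over all admissible monotone warping paths.
#'
#' @param x,y non-empty numeric vectors.
#' @param metric elementwise distance, default absolute difference.
#' @return list of class `tf_warp`: `distance`, `path` (two-column matrix of
#'   1-based index pairs from (1,1) to (n,m)), `metric` name.
#' @export
#' @examples
#' dtw(c(0, 1), c(0, 1, 1))$distance  # 0
dtw <- function(x, y, metric = function(a, b) abs(a - b)) {
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) tf_validation_error("dtw inputs must be non-empty", "x")
  d <- outer(x, y, metric)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- d[i, j] +
        min(D[i, j], D[i, j + 1], D[i + 1, j])
    }
  }
  # backtrack
  path <- matrix(0L, n + m, 2)
  i <- n; j <- m; k <- 0L
  while (i > 0 && j > 0) {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1 && j == 1) break
    choices <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
    step <- which.min(choices)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
  }
  path <- path[k:1, , drop = FALSE]
  structure(list(distance = D[n + 1, m + 1], path = path,
                 metric = deparse(substitute(metric))),
            class = "tf_warp")
}

#' Detect fundamental movement-cycle events
#'
#' Identifies one anchor event per fundamental movement cycle (stride peaks,
#' oscillation crests): the dominant frequency is estimated from the
#' spectrum, the signal is low-pass smoothed just above it, and peaks at
#' least ~0.6 cycle apart and above a relative height floor are kept.
#'
#' @param x numeric signal (one channel).
#' @param fs sampling rate, Hz.
#' @param t optional timestamps (default regular grid from `fs`).
#' @param min_height_frac minimum peak height as a fraction of the maximum
#'   absolute amplitude of the centred signal.
#' @return tibble of class `tf_phase_events` with column `event_times`
#'   (seconds, strictly increasing); attribute `flat = TRUE` and zero rows
#'   when the signal carries no cyclic content.
#' @export
detect_phase_events <- function(x, fs, t = NULL, min_height_frac = 0.3) {
  if (is.null(t)) t <- (seq_along(x) - 1) / fs
  xc <- x - mean(x, na.rm = TRUE)
  xc[is.na(xc)] <- 0
  empty <- structure(
    tibble(event_times = numeric()),
    class = c("tf_phase_events", class(tibble())), flat = TRUE)
  if (max(abs(xc)) < 1e-12) {
    warn("detect_phase_events: flat signal, no events")
    return(empty)
  }
  f_dom <- dominant_frequency(xc, fs)
  if (is.na(f_dom) || f_dom <= 0) {
    warn("detect_phase_events: no dominant cycle found")
    return(empty)
  }
  sm <- filt_fb(xc, min(3 * f_dom, 0.45 * fs), fs, 4)
  mpd <- max(1, round(0.6 * fs / f_dom))
  pk <- pracma::findpeaks(sm, minpeakdistance = mpd,
                          minpeakheight = min_height_frac * max(abs(sm)))
  if (is.null(pk)) {
    warn("detect_phase_events: no peaks above height floor")
    return(empty)
  }
  times <- sort(t[pk[, 2]])
  structure(tibble(event_times = times),
            class = c("tf_phase_events", class(tibble())), flat = FALSE,
            f_dominant_hz = f_dom)
}

dominant_frequency <- function(xc, fs) {
  n <- length(xc)
  if (n < 8) return(NA_real_)
  spec <- Mod(fft(xc))[1:floor(n / 2)]
  spec[1] <- 0  # DC out
  if (max(spec) < 1e-10) return(NA_real_)
  (which.max(spec) - 1) * fs / n
}

#' Phase-matched non-uniform B-spline alignment
#'
#' Re-expresses a stream on the clock of a reference stream: matched
#' movement-cycle events define a piecewise-linear time warp (stream event
#' times map onto reference event times, linear between anchors), an
#' interpolating B-spline of the requested degree is built on the warped
#' sample times (clamped knot vector by knot averaging, control points
#' solved from the samples so the spline passes through every measurement),
#' and the spline is evaluated on a uniform output grid.
#'
#' Events are paired in order; a count mismatch larger than
#' `max(2, 25%)` of the matched count raises an alignment error, smaller
#' surpluses are dropped from the tail on both sides.
#'
#' @param t,x sample times (seconds) and values of the stream to align.
#' @param events `tf_phase_events` (or numeric times) of the stream.
#' @param reference_events `tf_phase_events` (or numeric times) of the
#'   reference stream, on the reference clock.
#' @param degree B-spline degree (default 3).
#' @param out_rate_hz output grid rate, Hz (default 20).
#' @param reference optional reference signal (list with `t`, `x`) used to
#'   compute the phase-coherence QC of the alignment.
#' @return list of class `tf_alignment`: `grid`, `values`, `control_points`,
#'   `knots`, `degree`, `warp` (anchor pairs), `c_phase` (or NA).
#' @export
bspline_align <- function(t, x, events, reference_events, degree = 3,
                          out_rate_hz = 20, reference = NULL) {
  ev <- as_event_times(events)
  rev_ <- as_event_times(reference_events)
  k <- min(length(ev), length(rev_))
  if (abs(length(ev) - length(rev_)) > max(2, ceiling(0.25 * max(k, 1)))) {
    tf_abort(sprintf(
      "event count mismatch beyond tolerance (%d vs %d)",
      length(ev), length(rev_)), class = "tf_alignment_error")
  }
  ev <- ev[seq_len(k)]; rev_ <- rev_[seq_len(k)]
  keep <- ev > min(t) & ev < max(t)
  ev <- ev[keep]; rev_ <- rev_[keep]

  # piecewise-linear warp stream clock -> reference clock
  anchors_x <- c(min(t), ev, max(t))
  span_ref <- if (length(rev_)) {
    c(min(rev_) - (ev[1] - min(t)), max(rev_) + (max(t) - ev[length(ev)]))
  } else {
    range(t)
  }
  anchors_y <- c(span_ref[1], rev_, span_ref[2])
  ok <- !duplicated(anchors_x)
  anchors_x <- anchors_x[ok]; anchors_y <- anchors_y[ok]
  if (is.unsorted(anchors_y, strictly = TRUE)) {
    tf_abort("warp anchors not monotone; event pairing failed",
             class = "tf_alignment_error")
  }
  u <- approx(anchors_x, anchors_y, xout = t, rule = 2)$y

  spl <- bspline_interp(u, x, degree)
  grid <- seq(min(u), max(u), by = 1 / out_rate_hz)
  vals <- bspline_eval(spl, grid)

  c_phase <- NA_real_
  if (!is.null(reference)) {
    ref_on_grid <- approx(reference$t, reference$x, xout = grid, rule = 2)$y
    ph_a <- Arg(analytic_signal(vals - mean(vals)))
    ph_r <- Arg(analytic_signal(ref_on_grid - mean(ref_on_grid)))
    trim <- seq(ceiling(0.05 * length(grid)) + 1,
                floor(0.95 * length(grid)))
    c_phase <- phase_coherence(ph_a[trim], ph_r[trim])
  }
  structure(list(grid = grid, values = vals,
                 control_points = spl$coef, knots = spl$knots,
                 degree = degree,
                 warp = tibble(from = anchors_x, to = anchors_y),
                 c_phase = c_phase),
            class = "tf_alignment")
}

as_event_times <- function(e) {
  if (inherits(e, "tf_phase_events") || is.data.frame(e)) {
    return(sort(e$event_times))
  }
  sort(as.numeric(e))
}

# Interpolating B-spline on possibly non-uniform sites: clamped knot vector
# by knot averaging (Schoenberg-Whitney holds), banded collocation solve.
bspline_interp <- function(u, x, degree) {
  stopifnot(length(u) == length(x))
  ord <- degree + 1
  if (length(u) < ord) {
    tf_validation_error(sprintf(
      "need at least degree + 1 = %d control points, got %d", ord, length(u)),
      "degree")
  }
  n <- length(u)
  interior <- if (n > ord) {
    vapply(seq_len(n - ord), function(j) mean(u[(j + 1):(j + degree)]),
           numeric(1))
  } else {
    numeric(0)
  }
  knots <- c(rep(u[1], ord), interior, rep(u[n], ord))
  B <- splines::splineDesign(knots, u, ord = ord, sparse = TRUE)
  coef <- as.numeric(Matrix::solve(B, x))
  list(knots = knots, coef = coef, ord = ord)
}

bspline_eval <- function(spl, tt) {
  tt <- pmin(pmax(tt, spl$knots[1]), spl$knots[length(spl$knots)])
  B <- splines::splineDesign(spl$knots, tt, ord = spl$ord, sparse = TRUE)
  as.numeric(B %*% spl$coef)
}

#' Phase coherence against a reference phase
#'
#' `C_phase = (1/N) sum_i cos(phi_i - phi_ref)`: 1 when all phases agree
#' with the reference, ~0 for uniformly scattered phases.
#'
#' @param phases numeric vector of phases, radians.
#' @param reference_phase scalar or vector reference phase, radians.
#' @return value in `[-1, 1]`.
#' @export
#' @examples
#' phase_coherence(c(0.3, 0.3), 0.3)  # 1
phase_coherence <- function(phases, reference_phase) {
  if (length(phases) < 1) tf_validation_error("need at least one phase",
                                              "phases")
  mean(cos(phases - reference_phase))
}
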