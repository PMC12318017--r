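test_that("spatial entropy hits closed-form values", {
  expect_equal(spatial_entropy(rep(1 / 24, 24)), log2(24))
  expect_equal(spatial_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(spatial_entropy(c(0.5, 0.25, 0.125, 0.125)), 1.75)
  expect_error(spatial_entropy(c(0.5, 0.2)), class = "tf_validation_error")
})

test_that("zone occupancy normalizes jointly or per athlete", {
  team <- tibble::tibble(athlete_id = rep(c("A1", "A2"), each = 50),
                         x = runif(100, -10, 10), y = runif(100, -5, 5))
  zj <- zone_occupancy(team, 4, 3, c(-10, 10, -5, 5), joint = TRUE)
  expect_equal(sum(zj$p), 1)
  za <- zone_occupancy(team, 4, 3, c(-10, 10, -5, 5), joint = FALSE)
  sums <- tapply(za$p, za$athlete_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  expect_lte(spatial_entropy(zj), log2(4 * 3 * 2))
})

test_that("rpm equals the mean pairwise correlation oracle", {
  set.seed(21)
  d <- matrix(rnorm(60), 20, 3)
  dref <- matrix(rnorm(60), 20, 3)
  oracle <- mean(vapply(1:3, function(j) cor(d[, j], dref[, j]), numeric(1)))
  expect_equal(as.numeric(rpm(d, dref)), oracle, tolerance = 1e-12)
  expect_equal(as.numeric(rpm(d, d)), 1)
  expect_equal(as.numeric(rpm(d, -d + 3)), -1)
})

test_that("rpm falls back cleanly on a constant reference", {
  set.seed(22)
  d <- matrix(5 + 0.1 * rnorm(40), 20, 2)
  ref <- matrix(5, 20, 2)
  out <- rpm(d, ref)
  expect_identical(attr(out, "fallback"), "constant_reference")
  expect_gt(as.numeric(out), 0.9)  # small deviations: high maintenance
})

test_that("cross recurrence matches hand-counted line structure", {
  # self-recurrence: main diagonal always on
  set.seed(23)
  X <- matrix(rnorm(16), 8, 2)
  r <- cross_recurrence(X, X, epsilon = 1e-9)
  expect_true(all(diag(r$CR) == 1))
  # threshold beyond the data: everything recurs; with l_min = 2 the two
  # single-cell corner diagonals of the all-ones matrix stay excluded, so
  # the hand count is (64 - 2) / 64
  rall <- cross_recurrence(X, X, epsilon = 100)
  expect_equal(rall$RR, 1)
  expect_equal(rall$DET, 62 / 64)
  expect_equal(cross_recurrence(X, X, epsilon = 100, l_min = 1)$DET, 1)
  # hand-constructed 8x8: two length-3 diagonals + 2 isolated points,
  # realized geometrically with epsilon = 0.5
  Xi <- matrix(c(0, 10, 20, 500, 100, 110, 120, -0.45), ncol = 1)
  Xj <- matrix(c(0, 10, 20, 900, 700, 100, 110, 120), ncol = 1)
  rh <- cross_recurrence(Xi, Xj, epsilon = 0.5)
  CRtarget <- matrix(0L, 8, 8)
  CRtarget[cbind(1:3, 1:3)] <- 1L   # length-3 diagonal at the origin
  CRtarget[cbind(5:7, 6:8)] <- 1L   # length-3 off-diagonal
  CRtarget[8, 1] <- 1L              # isolated recurrent point
  expect_equal(rh$CR, CRtarget)
  expect_equal(rh$RR, 7 / 64)
  expect_equal(rh$DET, 6 / 7)       # hand count: 6 of 7 points on lines >= 2
  # two diagonal lines of equal length 3: zero diagonal-line entropy
  expect_equal(rh$ENT_diag, 0)
  expect_error(cross_recurrence(Xi, Xj, epsilon = 0),
               class = "tf_validation_error")
})

test_that("recurrence rate equals brute-force counting on random instances", {
  set.seed(24)
  for (k in 1:10) {
    n <- sample(5:20, 1); m <- sample(5:20, 1)
    Xi <- matrix(rnorm(n * 2), n, 2)
    Xj <- matrix(rnorm(m * 2), m, 2)
    eps <- runif(1, 0.5, 2)
    r <- cross_recurrence(Xi, Xj, eps)
    expect_equal(r$RR, rr_brute(Xi, Xj, eps), tolerance = 1e-12)
  }
})

test_that("coarse-graining shortens the matrix by the scale factor", {
  X <- matrix(rnorm(40), 20, 2)
  r2 <- cross_recurrence(X, X, epsilon = 1, scale = 2)
  expect_equal(dim(r2$CR), c(10, 10))
  ms <- ms_crqa(X, X, scales = c(1, 2, 4))
  expect_equal(nrow(ms), 3)
  expect_true(all(ms$RR >= 0 & ms$RR <= 1))
})

test_that("Hilbert phase slope recovers the tone frequency", {
  fs <- 100
  t <- (0:999) / fs
  hp <- hilbert_phase(cos(2 * pi * 1 * t), fs, band = NULL)
  sl <- coef(lm(hp$phase[hp$valid] ~ t[hp$valid]))[2]
  expect_equal(as.numeric(sl), 2 * pi, tolerance = 0.01)
  flat <- hilbert_phase(rep(0, 100), fs)
  expect_true(flat$flat)
})

test_that("order parameter spans synchrony extremes", {
  fs <- 100
  t <- (0:999) / fs
  ph <- hilbert_phase(cos(2 * pi * 0.7 * t), fs, band = NULL)
  PH <- cbind(ph$phase, ph$phase, ph$phase)
  expect_equal(max(abs(order_parameter(PH) - 1)), 0, tolerance = 1e-9)
  anti <- cbind(ph$phase, ph$phase + pi)
  expect_lte(max(order_parameter(anti)[ph$valid]), 0.02)
  set.seed(25)
  expect_equal(as.numeric(order_parameter(runif(1e4, 0, 2 * pi))), 0,
               tolerance = 0.02)
  expect_true(all(order_parameter(matrix(rnorm(300), 100, 3)) <= 1))
})

test_that("gini closed forms anchor load distribution harmony", {
  expect_equal(gini(rep(3, 6)), 0)
  n <- 5
  expect_equal(gini(c(rep(0, n - 1), 7)), (n - 1) / n)
  expect_error(gini(c(-1, 2)), class = "tf_validation_error")
})

test_that("windowed indicators hit synchrony and entropy extremes", {
  # all athletes share one velocity series -> SSI = ICC = 1
  fs <- 20
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  base_x <- 3 * sin(2 * pi * 0.4 * t)
  vx <- teamfuse:::cgrad(base_x, 1 / fs)
  mk <- function(id, off) tibble::tibble(
    t = t, athlete_id = id, team = "A",
    x = base_x + off, y = base_x - off, vx = vx, vy = vx)
  team <- teamfuse:::new_team_trajectory(
    dplyr::bind_rows(mk("A1", 0), mk("A2", 4), mk("A3", 8)))
  # uniform passes over all 6 ordered pairs; decisive actions present
  ids <- c("A1", "A2", "A3")
  prs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  prs <- prs[prs$from != prs$to, ]
  # a burst covering all 6 ordered pairs every 5 s: every 10-s window sees
  # each pair equally often, so window TIE is exactly 1
  bursts <- seq(2.5, 37.5, by = 5)
  ev <- tf_events(t = rep(bursts, each = 6) + rep(0:5 * 0.01, length(bursts)),
                  event_type = "pass",
                  athlete_id = rep(prs$from, length(bursts)),
                  target_athlete_id = rep(prs$to, length(bursts)))
  loads <- tidyr::expand_grid(athlete_id = ids, t = t) |>
    dplyr::mutate(load = t)  # equal accumulation
  ind <- compute_indicators(team, ev, loads = loads,
                            pitch_extent = c(-20, 20, -15, 15))
  expect_s3_class(ind, "tf_indicators")
  expect_true(all(abs(ind$ssi - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(ind$icc - 1) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(ind$ldh - 1) < 1e-9, na.rm = TRUE))
  # every window with passes spanning all pairs equally: TIE = 1
  expect_true(all(abs(ind$tie[!is.na(ind$tie)] - 1) < 1e-9))
  expect_true(all(ind$fsq > 0 & ind$fsq <= 1, na.rm = TRUE))
  expect_true(all(ind$s_spatial <= log2(6 * 4 * 3) + 1e-9, na.rm = TRUE))
  # no perturbations: CPR flagged missing, not zero
  expect_true(all(is.na(ind$cpr)))
})

test_that("TIE collapses to zero when all passes use one pair", {
  counts <- table(rep("A1 A2", 10))
  expect_equal(teamfuse:::tie_entropy(counts, n_pairs = 6), 0)
  unif <- table(rep(paste("p", 1:6), each = 2))
  expect_equal(teamfuse:::tie_entropy(unif, n_pairs = 6), 1)
})

test_that("SSI is invariant to global translation and rotation", {
  sim <- simulate_session(sim_config(n_athletes_per_team = 3,
                                     duration_s = 30, modalities = "gps",
                                     seed = 26))
  team <- sim$truth$team
  ind0 <- compute_indicators(team, tf_events(),
                             pitch_extent = sim$truth$config$pitch_extent)
  th <- 0.7
  rot <- dplyr::mutate(team,
    xn = cos(th) * x - sin(th) * y + 5, yn = sin(th) * x + cos(th) * y - 3,
    vxn = cos(th) * vx - sin(th) * vy, vyn = sin(th) * vx + cos(th) * vy)
  rot <- dplyr::mutate(rot, x = xn, y = yn, vx = vxn, vy = vyn)
  ind1 <- compute_indicators(teamfuse:::new_team_trajectory(
    rot[c("t", "athlete_id", "team", "x", "y", "vx", "vy")]), tf_events(),
    pitch_extent = c(-40, 40, -40, 40))
  expect_equal(ind1$ssi, ind0$ssi, tolerance = 0.05)
})

test_that("CPR recovers a constructed step perturbation within one window", {
  wt <- seq(5, 95, by = 5)
  ssi <- rep(0.8, length(wt))
  drop_idx <- wt > 50 & wt <= 65
  ssi[drop_idx] <- 0.2
  ev <- tf_events(50, "perturbation")
  cpr <- teamfuse:::cpr_recovery(wt, ssi, ev, window_s = 10)
  # ssi re-enters the baseline band at the first window after 65 s
  expect_equal(cpr[1], 70 - 50, tolerance = 5)
})
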