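test_that("weight recursion matches its defining arithmetic", {
  expect_equal(update_weight(0.5, q = 1, r = 1, lambda = 0.65)$w, 0.675)
  expect_equal(update_weight(0.4, q = 0.9, r = 0.5, lambda = 0)$w, 0.45)
  expect_error(update_weight(0.5, 0.5, 1, lambda = 1.5),
               class = "tf_validation_error")
  expect_error(update_weight(0.5, q = 2, r = 1), class = "tf_validation_error")
})

test_that("weight recursion converges geometrically to constant q*r", {
  set.seed(5)
  for (k in 1:20) {
    w0 <- runif(1); cc <- runif(1)
    w <- w0
    for (t_ in 1:12) {
      w <- update_weight(w, q = cc, r = 1, lambda = 0.65)$w
      expect_lt(abs(abs(w - cc) - 0.65^t_ * abs(w0 - cc)), 1e-12)
    }
  }
})

test_that("normalized weights sum to one and stay in [0, 1]", {
  set.seed(6)
  w <- runif(4)
  for (i in 1:30) {
    upd <- update_weight(w, q = runif(4), r = runif(4), lambda = 0.65)
    w <- upd$w
    expect_equal(sum(upd$w_norm), 1)
    expect_true(all(upd$w_norm >= 0 & upd$w_norm <= 1))
  }
})

test_that("wavelet packet reconstructs random signals and conserves energy", {
  set.seed(7)
  for (wl in c("db1", "db2", "db4")) {
    for (k in 1:5) {
      n <- sample(c(64, 200, 333), 1)
      x <- rnorm(n)
      wf <- wavelet_packet(x, K = 4, wavelet = wl)
      xr <- wavelet_reconstruct(wf)
      expect_lt(max(abs(x - xr)) / max(abs(x)), 1e-8)
      expect_equal(sum(unlist(wf$leaves)^2), sum(x^2), tolerance = 1e-8)
    }
  }
  expect_error(wavelet_packet(rnorm(16), K = 5), class = "tf_validation_error")
})

test_that("constant signal energy lands in the lowest-frequency node", {
  x <- rep(2, 64)
  wf <- wavelet_packet(x, K = 3, wavelet = "db2")
  energies <- vapply(wf$leaves, function(l) sum(l^2), numeric(1))
  expect_equal(energies[1] / sum(energies), 1, tolerance = 1e-10)
})

test_that("feature selection keeps the top energy and is monotone in alpha", {
  t <- (0:1023) / 64
  x <- sin(2 * pi * 1 * t) + 0.6 * sin(2 * pi * 3 * t) +
    0.3 * sin(2 * pi * 5 * t)
  wf <- wavelet_packet(x, K = 5, wavelet = "db4")
  full <- select_features(wf, alpha_feat = 1)
  expect_equal(full$reconstruction_error, 0, tolerance = 1e-10)
  sel <- select_features(wf, alpha_feat = 0.15)
  expect_gte(sel$retained_energy_fraction, 0.94)
  errs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1), function(a)
    select_features(wf, a)$reconstruction_error, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("tensor fusion equals the naive triple-sum oracle", {
  set.seed(8)
  X <- array(rnorm(24), c(2, 3, 4))
  W1 <- matrix(rnorm(4), 2, 2)
  W2 <- matrix(rnorm(6), 2, 3)
  W3 <- matrix(rnorm(12), 3, 4)
  out <- tensor_fuse(X, W1, W2, W3)
  expect_lt(max(abs(out$tensor - tensor_brute(X, W1, W2, W3))), 1e-12)
  # identity projections leave the tensor unchanged
  id <- tensor_fuse(X, diag(2), diag(3), diag(4))
  expect_identical(dim(id$tensor), dim(X))
  expect_lt(max(abs(id$tensor - X)), 1e-14)
  # mode products commute across distinct modes
  a <- teamfuse:::mode_n_product(
    teamfuse:::mode_n_product(teamfuse:::mode_n_product(X, W2, 2), W1, 1),
    W3, 3)
  expect_lt(max(abs(a - out$tensor)), 1e-12)
  expect_error(tensor_fuse(X, matrix(0, 2, 5), NULL, NULL),
               class = "tf_validation_error")
})

test_that("q_info spans its extremes and decreases with added noise", {
  set.seed(9)
  x <- rnorm(1e4)
  expect_gte(q_info(x, x)$q_info, 0.99)
  expect_lte(q_info(x, rnorm(1e4))$q_info, 0.05)
  sds <- c(0.1, 0.3, 1, 3, 10)
  qs <- vapply(sds, function(s) q_info(x, x + s * rnorm(1e4))$q_info,
               numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_true(all(qs >= 0 & qs <= 1))
  deg <- q_info(rep(1, 200), rnorm(200))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$q_info))
})

test_that("static Kalman fusion equals the precision-weighted closed form", {
  z <- matrix(c(1.2, 0.8), 1, 2)
  kf <- kalman_fuse(z, A = matrix(1), H = matrix(c(1, 1), 2, 1),
                    Q_proc = matrix(0), R_meas = diag(c(0.01, 0.25)),
                    x0 = 0, P0 = matrix(Inf))
  closed <- (1.2 / 0.01 + 0.8 / 0.25) / (1 / 0.01 + 1 / 0.25)
  expect_equal(kf$x[1, 1], closed, tolerance = 1e-14)
  bf <- bayes_fuse(c(1.2, 0.8), c(0.01, 0.25))
  expect_equal(kf$x[1, 1], bf$mean, tolerance = 1e-14)
})

test_that("Kalman limits: R -> 0 tracks data, gain 0 keeps the prediction", {
  z <- matrix(c(1, 2, 3), 3, 1)
  kf0 <- kalman_fuse(z, A = matrix(1), H = matrix(1), Q_proc = matrix(1),
                     R_meas = matrix(1e-14), x0 = 0, P0 = matrix(1))
  expect_equal(kf0$x[, 1], c(1, 2, 3), tolerance = 1e-6)
  kfI <- kalman_fuse(z, A = matrix(1), H = matrix(1), Q_proc = matrix(0),
                     R_meas = matrix(1e14), x0 = 5, P0 = matrix(1e-12))
  expect_equal(kfI$x[, 1], rep(5, 3), tolerance = 1e-6)
  expect_error(kalman_fuse(z, A = matrix(1), H = matrix(1),
                           Q_proc = matrix(-1), R_meas = matrix(1),
                           x0 = 0, P0 = matrix(1)),
               class = "tf_validation_error")
})

test_that("weighted average and Bayesian fusion basics hold", {
  s <- list(c(1, 2, 3), c(1, 2, 3))
  expect_equal(weighted_average_fuse(s), c(1, 2, 3))
  expect_error(weighted_average_fuse(s, c(0.7, 0.4)),
               class = "tf_validation_error")
  expect_error(weighted_average_fuse(s, c(-0.5, 1.5)),
               class = "tf_validation_error")
  # flat prior + one source: posterior mean = measurement
  expect_equal(bayes_fuse(2.5, 0.3)$mean, 2.5)
})
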