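test_that("path model recovers known coefficients exactly without noise", {
  set.seed(31)
  n <- 40
  cs <- rnorm(n); ct <- rnorm(n); P <- matrix(rnorm(n * 4), n, 4)
  w <- c(0.4, 0.3, 0.2, 0.1)
  pt <- 0.5 * cs + 0.3 * ct + 0.2 * as.numeric(P %*% w)
  fit <- suppressWarnings(fit_path_model(
    tibble::tibble(p_team = pt, c_spatial = cs, c_temporal = ct), P, w))
  expect_lt(max(abs(fit$coefficients[2:4] - c(0.5, 0.3, 0.2))), 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # matches the normal-equations oracle
  X <- cbind(1, cs, ct, as.numeric(P %*% w))
  beta_ne <- solve(crossprod(X), crossprod(X, pt))
  expect_equal(unname(fit$coefficients), as.numeric(beta_ne),
               tolerance = 1e-10)
  # summary.lm warns about the essentially perfect fit; that is the point
  td <- suppressWarnings(tidy(fit))
  expect_equal(nrow(td), 4)
  expect_equal(suppressWarnings(glance(fit))$nobs, n)
})

test_that("constant predictors are flagged unidentifiable", {
  set.seed(32)
  n <- 20
  d <- tibble::tibble(p_team = rnorm(n), c_spatial = 0, c_temporal = rnorm(n))
  expect_error(fit_path_model(d, matrix(rnorm(n * 2), n, 2)),
               class = "tf_identifiability_error")
  # collinear design
  ct <- rnorm(n)
  d2 <- tibble::tibble(p_team = rnorm(n), c_spatial = 2 * ct + 1e-12 * rnorm(n),
                       c_temporal = ct)
  expect_error(fit_path_model(d2, matrix(rnorm(n * 2), n, 2)),
               class = "tf_identifiability_error")
  expect_error(fit_path_model(d[1:5, ], matrix(rnorm(10), 5, 2)),
               class = "tf_validation_error")
})

test_that("path coefficient estimates are near-unbiased under noise", {
  set.seed(33)
  reps <- 200
  n <- 200
  est <- replicate(reps, {
    cs <- rnorm(n); ct <- rnorm(n); P <- matrix(rnorm(n * 3), n, 3)
    comp <- rowMeans(P)
    pt <- 0.5 * cs + 0.3 * ct + 0.2 * comp + 0.1 * rnorm(n)
    fit <- fit_path_model(
      tibble::tibble(p_team = pt, c_spatial = cs, c_temporal = ct), P)
    fit$coefficients[2:4]
  })
  bias <- rowMeans(est) - c(0.5, 0.3, 0.2)
  expect_lt(max(abs(bias)), 0.02)
})

test_that("classifier log-likelihood is non-decreasing across IRLS steps", {
  set.seed(34)
  X <- cbind(1, matrix(rnorm(200), 100, 2))
  y <- rbinom(100, 1, 1 / (1 + exp(-X %*% c(0.2, 1, -0.5))))
  res <- teamfuse:::irls_logistic(X, y)
  expect_true(all(diff(res$log_lik_trace) > -1e-8))
  expect_true(res$converged)
  # cross-check against glm on the same data
  g <- glm.fit(X, y, family = binomial())
  expect_equal(res$beta, unname(coef(g)), tolerance = 1e-6)
})

test_that("classifier handles chance, separable and 1-sigma regimes", {
  d0 <- make_outcome_dataset(
    sim_config(outcome_effect = c(tcr = 0, cpr = 0, ssi = 0, icc = 0),
               seed = 41), 200)
  acc0 <- loso_accuracy(d0)
  expect_gte(acc0, 0.40); expect_lte(acc0, 0.60)
  d5 <- make_outcome_dataset(
    sim_config(outcome_effect = c(tcr = 5, cpr = -5, ssi = 5, icc = 5),
               seed = 42), 200)
  expect_gte(loso_accuracy(d5), 0.99)
  expect_error(fit_outcome_classifier(
    dplyr::mutate(d0, outcome = "win")), class = "tf_validation_error")
})

test_that("separation triggers the ridge-stabilized fallback with a warning", {
  d <- tibble::tibble(outcome = rep(c("win", "loss"), each = 20),
                      tcr = c(rnorm(20, 5), rnorm(20, -5)),
                      cpr = rnorm(40), ssi = rnorm(40), icc = rnorm(40))
  expect_warning(fit <- fit_outcome_classifier(d), "separation")
  expect_true(fit$separation)
  p <- predict(fit, d)
  expect_true(all(p > 0 & p < 1))
})

test_that("change points: exact on a noiseless step, calibrated on null", {
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(detect_change_points(x)$change_indices, 50L)
  set.seed(43)
  fp <- mean(vapply(1:100, function(i)
    length(detect_change_points(rnorm(100))$change_indices) > 0, logical(1)))
  expect_lte(fp, 0.05)
  set.seed(44)
  hits <- vapply(1:100, function(i) {
    xx <- c(rep(0, 50), rep(3, 50)) + rnorm(100)
    cp <- detect_change_points(xx)$change_indices
    length(cp) >= 1 && min(abs(cp - 50)) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(detect_change_points(rnorm(10)), class = "tf_validation_error")
})

test_that("early warning fires exactly at constructed rule crossings", {
  ind <- structure(tibble::tibble(
    t = seq(5, 100, by = 5),
    ssi = c(rep(0.3, 10), 0.5, rep(0.3, 9)),
    tcr = c(rep(0.2, 10), 0.7, rep(0.2, 9))),
    class = c("tf_indicators", class(tibble::tibble())))
  al <- early_warning(ind)
  expect_equal(nrow(al), 1)
  expect_equal(al$t, ind$t[11])
  expect_equal(nrow(early_warning(ind, rules = list())), 0)
  expect_error(early_warning(ind, rules = list(
    list(indicator = "nope", type = "level", threshold = 1))),
    class = "tf_validation_error")
})

test_that("alerts precede perturbations on ramped synthetic indicator series", {
  # generative coupling: SSI ramps up and TCR is elevated just before each
  # perturbation
  ok <- vapply(1:50, function(sd) {
    set.seed(sd)
    wt <- seq(5, 300, by = 5)
    ssi <- 0.3 + 0.02 * rnorm(length(wt))
    tcr <- 0.2 + 0.05 * rnorm(length(wt))
    pert_t <- c(100, 200, 280)
    for (pt in pert_t) {
      pre <- which(wt >= pt - 10 & wt < pt)
      ssi[pre] <- ssi[pre] + c(0.15, 0.3)[seq_along(pre)]
      tcr[pre] <- 0.7
    }
    ind <- structure(tibble::tibble(t = wt, ssi = ssi, tcr = tcr),
                     class = c("tf_indicators", class(tibble::tibble())))
    al <- early_warning(ind)
    all(vapply(pert_t, function(pt)
      any(al$t >= pt - 10 & al$t < pt), logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("classifier tidiers report on the original metric scale", {
  d <- make_outcome_dataset(
    sim_config(outcome_effect = c(tcr = 2, cpr = 0, ssi = 0, icc = 0),
               seed = 45), 300)
  fit <- fit_outcome_classifier(d)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "tcr", "cpr", "ssi", "icc"))
  # rebuild probabilities from tidied coefficients
  eta <- td$estimate[1] + as.matrix(d[c("tcr", "cpr", "ssi", "icc")]) %*%
    td$estimate[-1]
  expect_equal(as.numeric(1 / (1 + exp(-eta))), predict(fit, d),
               tolerance = 1e-8)
  expect_gt(td$estimate[td$term == "tcr"], 0)
})
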