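test_that("single noiseless positional source passes through exactly", {
  t <- seq(0, 20, by = 0.025)
  x <- 3 * sin(2 * pi * 0.3 * t); y <- 2 * cos(2 * pi * 0.3 * t)
  lps <- sensor_stream(t, list(x = x, y = y), "A1", "lps", "lps", 40)
  rec <- fuse_individual(list(lps), out_rate_hz = 20)
  expect_equal(rec$x, approx(t, x, xout = rec$t)$y, tolerance = 1e-12)
  expect_equal(rec$y, approx(t, y, xout = rec$t)$y, tolerance = 1e-12)
  w <- attr(rec, "weights")
  expect_true(all(w$weight == 1))
})

test_that("no positional source is an error", {
  t <- seq(0, 5, by = 0.1)
  hr <- sensor_stream(t, list(hr = rep(70, length(t))), "A1", "hr",
                      "physio", 10)
  expect_error(fuse_individual(list(hr)), class = "tf_error")
})

test_that("quality-driven fusion approaches the inverse-variance optimum", {
  # two unbiased sources of a slowly varying signal, sigma 0.1 and 0.5
  set.seed(11)
  fs <- 40
  t <- seq(1 / fs, 250, by = 1 / fs)
  truth_x <- 2 * sin(2 * pi * 0.05 * t)
  truth_y <- 2 * cos(2 * pi * 0.05 * t)
  s1 <- sensor_stream(t, list(x = truth_x + 0.1 * rnorm(length(t)),
                              y = truth_y + 0.1 * rnorm(length(t))),
                      "A1", "lps", "lps", fs)
  s2 <- sensor_stream(t, list(x = truth_x + 0.5 * rnorm(length(t)),
                              y = truth_y + 0.5 * rnorm(length(t))),
                      "A1", "gps", "gps", fs)
  rec <- fuse_individual(list(s1, s2), out_rate_hz = 40)
  tx <- approx(t, truth_x, xout = rec$t)$y
  err <- rec$x - tx
  sigma_opt <- (0.1^-2 + 0.5^-2)^-0.5
  expect_lt(rms_(err), 1.05 * sigma_opt)
  expect_lt(rms_(err), 1.05 * 0.1)  # better than the best single source
})

test_that("a degrading source loses weight within the next updates", {
  set.seed(12)
  fs <- 40
  t <- seq(1 / fs, 40, by = 1 / fs)
  truth_x <- 2 * sin(2 * pi * 0.05 * t)
  mk <- function(id, modality, sigma_late) {
    noise <- 0.1 * rnorm(length(t))
    late <- t > 20
    noise[late] <- noise[late] + sigma_late * rnorm(sum(late))
    sensor_stream(t, list(x = truth_x + noise, y = truth_x + noise),
                  "A1", id, modality, fs)
  }
  good <- mk("lps", "lps", 0)
  bad <- mk("gps", "gps", 1.5)   # heavy corruption from t = 20 s
  rec <- fuse_individual(list(good, bad), out_rate_hz = 20)
  w <- attr(rec, "weights")
  wb <- w$weight[w$source == "A1/gps"]
  tb <- w$block_t[w$source == "A1/gps"]
  after <- which(tb > 20 & tb <= 30)
  expect_true(all(diff(wb[after]) < 0))
  expect_lt(wb[max(after)], wb[min(after)] / 2)
})

test_that("team fusion computes the centroid and is order-invariant", {
  t <- seq(0, 1, by = 0.25)
  mk <- function(id, x0) {
    structure(tibble::tibble(t = t, x = rep(x0, 5), y = rep(x0, 5),
                             vx = 0, vy = 0),
              class = c("tf_record", class(tibble::tibble())),
              athlete_id = id)
  }
  team <- fuse_team(list(mk("A1", 0), mk("A2", 2)))
  cen <- team_centroid(team)
  expect_equal(cen$cx, rep(1, 5))
  expect_equal(cen$cy, rep(1, 5))
  team2 <- fuse_team(list(mk("A2", 2), mk("A1", 0)))
  expect_equal(team_centroid(team2)$cx, cen$cx)
  expect_error(fuse_team(list(mk("A1", 0))), class = "tf_error")
  bad <- mk("A3", 1); bad$t <- bad$t + 0.01
  expect_error(fuse_team(list(mk("A1", 0), bad)), class = "tf_error")
})

test_that("zero-noise simulation passed through the pipeline recovers truth", {
  sim <- simulate_session(zero_noise_config(n_athletes_per_team = 2,
                                            duration_s = 20, seed = 31))
  res <- run_pipeline(sim$manifest, sim$streams, sim$truth$events,
                      truth = sim$truth)
  expect_lt(res$quality$position_rmse_m, 1e-6)
  # centroid of fused team equals truth centroid
  cen <- team_centroid(res$team)
  tcen <- team_centroid(sim$truth$team)
  tc <- dplyr::filter(tcen, team == "A")
  fc <- dplyr::filter(cen, team == "A")
  cx <- approx(tc$t, tc$cx, xout = fc$t)$y
  expect_lt(rms_(fc$cx - cx), 1e-6)
})

test_that("fused positions beat single-source GPS under deployment noise", {
  sim <- simulate_session(sim_config(n_athletes_per_team = 2,
                                     duration_s = 30,
                                     modalities = c("gps", "lps", "imu"),
                                     seed = 32))
  cmp <- compare_fusers(sim, fusers = c("multilevel", "gps_only"),
                        noise_amplitudes = 0)
  rm <- cmp$rmse_pos_m[cmp$fuser == "multilevel"]
  rg <- cmp$rmse_pos_m[cmp$fuser == "gps_only"]
  expect_lt(rm, rg)
  # fused output has no residual lag; raw GPS may carry its transmission
  # latency (up to one output sample here)
  expect_equal(cmp$lag_samples[cmp$fuser == "multilevel"], 0)
  expect_lte(abs(cmp$lag_samples[cmp$fuser == "gps_only"]), 1)
})

test_that("adaptive fusion degrades less than fixed weights under injection", {
  sim <- simulate_session(sim_config(n_athletes_per_team = 2,
                                     duration_s = 30,
                                     modalities = c("gps", "lps", "imu"),
                                     seed = 33))
  cmp <- compare_fusers(sim, fusers = c("multilevel", "wavg"),
                        noise_amplitudes = c(0, 0.3))
  d <- function(f) {
    r <- cmp[cmp$fuser == f, ]
    r$rmse_pos_m[r$noise_amplitude == 0.3] -
      r$rmse_pos_m[r$noise_amplitude == 0]
  }
  expect_lt(d("multilevel"), d("wavg"))
})

test_that("quality report fields are coherent", {
  sim <- simulate_session(sim_config(n_athletes_per_team = 2,
                                     duration_s = 20, seed = 34))
  res <- run_pipeline(sim$manifest, sim$streams, sim$truth$events,
                      truth = sim$truth)
  q <- res$quality
  expect_true(q$q_info >= 0 && q$q_info <= 1)
  expect_gt(q$snr_gain_db, 0)
  expect_lt(q$fused_grid_jitter_ms, 1e-6)
  expect_true(all(c("stream", "snr_db", "needs_recalibration") %in%
                    names(q$streams)))
  p <- file.path(withr::local_tempdir(), "q.json")
  write_output(q, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$q_info, q$q_info, tolerance = 1e-9)
})
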