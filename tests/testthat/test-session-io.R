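test_that("sensor_stream enforces its invariants", {
  t <- c(0, 0.1, 0.2)
  s <- sensor_stream(t, list(x = 1:3, y = 4:6), "A1", "gps", "gps", 10)
  expect_s3_class(s, "tf_stream")
  expect_equal(nrow(s), 3)
  expect_error(sensor_stream(c(0, 0.2, 0.1), list(x = 1:3), "A1", "g", "gps",
                             10),
               class = "tf_data_error")
  expect_error(sensor_stream(t, list(x = c(1, NA, 3)), "A1", "g", "gps", 10),
               class = "tf_data_error")
  # NA allowed under the dropout mask
  s2 <- sensor_stream(t, list(x = c(1, NA, 3)), "A1", "g", "gps", 10,
                      dropout = c(FALSE, TRUE, FALSE))
  expect_true(s2$dropout[2])
  expect_error(sensor_stream(t, list(x = 1:3), "A1", "g", "gps", 0),
               class = "tf_validation_error")
})

test_that("manifest validation rejects undeclared athletes and bad geometry", {
  toy <- toy_session()
  m <- toy$manifest
  expect_error(
    session_manifest("s", "soccer", c(-10, 10, -5, 5),
                     m$athletes,
                     dplyr::mutate(m$stream_index,
                                   athlete_id = c("A1", "ZZ"))),
    class = "tf_validation_error")
  expect_error(
    session_manifest("s", "soccer", c(10, -10, -5, 5), m$athletes,
                     m$stream_index),
    class = "tf_validation_error")
  expect_error(
    session_manifest("s", "badminton", c(-10, 10, -5, 5), m$athletes,
                     m$stream_index))
})

test_that("write_session/read_session round-trips a toy session", {
  toy <- toy_session()
  dir <- withr::local_tempdir()
  write_session(toy$manifest, toy$streams, toy$events, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # one CSV per stream
  expect_length(list.files(file.path(dir, "streams")), length(toy$streams))
  back <- read_session(file.path(dir, "manifest.json"))
  expect_setequal(names(back$streams), names(toy$streams))
  for (nm in names(toy$streams)) {
    a <- toy$streams[[nm]]; b <- back$streams[[nm]]
    expect_identical(b$t, a$t)
    expect_equal(b$x, a$x, tolerance = 1e-9)
    expect_identical(attr(b, "modality"), attr(a, "modality"))
  }
  expect_equal(nrow(back$events), 2)
  expect_identical(back$events$event_type, toy$events$event_type)
})

test_that("read/write round-trip holds for a simulator-written session", {
  sim <- simulate_session(sim_config(n_athletes_per_team = 2,
                                     duration_s = 6, seed = 42))
  expect_length(sim$streams, 2 * 2 * 5)  # athletes x modalities
  dir <- withr::local_tempdir()
  write_session(sim$manifest, sim$streams, sim$truth$events, dir)
  back <- read_session(file.path(dir, "manifest.json"))
  expect_length(back$streams, length(sim$streams))
  s0 <- sim$streams[["A1/imu"]]; s1 <- back$streams[["A1/imu"]]
  expect_identical(s1$t, s0$t)
  expect_equal(s1$gyro_z, s0$gyro_z, tolerance = 1e-9)
  expect_identical(s1$dropout, s0$dropout)
})

test_that("missing events file yields an empty event table", {
  toy <- toy_session()
  dir <- withr::local_tempdir()
  write_session(toy$manifest, toy$streams, NULL, dir)
  back <- read_session(file.path(dir, "manifest.json"))
  expect_s3_class(back$events, "tf_events")
  expect_equal(nrow(back$events), 0)
})

test_that("team trajectory output is wide with 4 columns per athlete", {
  team <- tibble::tibble(
    t = rep(seq(0, 0.4, 0.1), 4),
    athlete_id = rep(c("A1", "A2", "A3", "A4"), each = 5),
    team = "A",
    x = rnorm(20), y = rnorm(20), vx = rnorm(20), vy = rnorm(20))
  tt <- fuse_team(purrr::map(split(team, team$athlete_id), function(d) {
    structure(tibble::tibble(t = d$t, x = d$x, y = d$y, vx = d$vx, vy = d$vy),
              class = c("tf_record", class(tibble::tibble())),
              athlete_id = d$athlete_id[1])
  }))
  p <- file.path(withr::local_tempdir(), "team.csv")
  write_output(tt, p)
  out <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(dim(out), c(5, 1 + 4 * 4))
  back_x <- out$x_A2
  expect_equal(back_x, team$x[team$athlete_id == "A2"], tolerance = 1e-9)
})

test_that("indicator output round-trips and empty series is header-only", {
  empty <- structure(
    tibble::tibble(t = numeric(), ssi = numeric()),
    class = c("tf_indicators", class(tibble::tibble())))
  p <- file.path(withr::local_tempdir(), "ind.csv")
  write_output(empty, p)
  expect_identical(readLines(p), "t,ssi")
})

test_that("events require both athlete ids on passes", {
  expect_error(tf_events(1, "pass", "A1", NA), class = "tf_validation_error")
  expect_error(tf_events(1, "throw_in"), class = "tf_validation_error")
})
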