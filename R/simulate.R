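#' Simulation configuration
#'
#' Parameters of the synthetic multi-athlete session generator. Defaults
#' emulate the deployed sensor network: modality sampling rates of 200 Hz
#' (IMU), 10 Hz (GPS), 40 Hz (LPS) with nominal accuracies of +-0.5 m (GPS,
#' open field), +-0.1 m (LPS), +-0.02 g accelerometer, +-0.05 deg/s
#' gyroscope and +-1 bpm heart rate. Heart rate is generated directly in bpm
#' at 10 Hz through a first-order lag on running speed (tau = 30 s) rather
#' than as raw kHz ECG, and insole force as a 100 Hz per-step impulse train;
#' only cumulative load is consumed downstream.
#'
#' Team coordination is generated by coupled phase oscillators: each
#' athlete's oscillation phase follows Kuramoto dynamics
#' `dpsi_i = omega_i dt + (kappa/n) sum_j sin(psi_j - psi_i) dt + sigma dW`,
#' so `coupling_kappa` is the dial that stands in for tactical coordination
#' level: every downstream coordination indicator should increase with it.
#'
#' @param n_athletes_per_team athletes per team (two teams are generated).
#' @param duration_s session length, seconds.
#' @param frame_rate_hz ground-truth trajectory rate, Hz.
#' @param coupling_kappa Kuramoto coupling strength, dimensionless >= 0.
#' @param formation_spacing_m spacing of the formation grid, metres.
#' @param centroid_speed_mps typical speed of the team centroid, m/s.
#' @param osc_amplitude_m radius of individual oscillatory movement, metres.
#' @param base_freq_hz mean oscillation frequency, Hz.
#' @param freq_spread_hz athlete-to-athlete SD of natural frequency, Hz.
#' @param phase_noise intensity of phase diffusion, rad/sqrt(s).
#' @param pitch_extent pitch `c(x_min, x_max, y_min, y_max)`, metres.
#' @param noise_profile named list of per-modality noise SDs:
#'   gps_sigma_m, lps_sigma_m, imu_acc_sigma_g, gyro_sigma_dps, mag_sigma_deg,
#'   hr_sigma_bpm, insole_sigma_n.
#' @param latency_profile named list per modality, each `c(mean, jitter)` in
#'   seconds.
#' @param dropout_rate per-sample Bernoulli dropout probability in `[0, 1)`.
#' @param event_rates list: passes_per_min, perturbations_per_min.
#' @param perturbation_s duration of a coupling dip after a perturbation.
#' @param outcome_effect named numeric vector: shift (in within-class SDs)
#'   of indicator summaries between win and loss sessions, used by
#'   [make_outcome_dataset()].
#' @param modalities character subset of sensors to generate.
#' @param sport sport label for the manifest.
#' @param seed integer RNG seed; all randomness derives from it.
#' @return list of class `tf_sim_config`.
#' @export
sim_config <- function(n_athletes_per_team = 5,
                       duration_s = 120,
                       frame_rate_hz = 100,
                       coupling_kappa = 2,
                       formation_spacing_m = 8,
                       centroid_speed_mps = 0.5,
                       osc_amplitude_m = 2,
                       base_freq_hz = 0.4,
                       freq_spread_hz = 0.05,
                       phase_noise = 0.1,
                       pitch_extent = c(-20, 20, -15, 15),
                       noise_profile = list(),
                       latency_profile = list(),
                       dropout_rate = 0.01,
                       event_rates = list(passes_per_min = 6,
                                          perturbations_per_min = 1),
                       perturbation_s = 5,
                       outcome_effect = c(tcr = 1, cpr = -1, ssi = 1, icc = 1),
                       modalities = c("imu", "gps", "lps", "physio", "insole"),
                       sport = "soccer",
                       seed = 1L) {
  noise_defaults <- list(gps_sigma_m = 0.5, lps_sigma_m = 0.1,
                         imu_acc_sigma_g = 0.02, gyro_sigma_dps = 0.05,
                         mag_sigma_deg = 0.3, hr_sigma_bpm = 1,
                         insole_sigma_n = 1.2)
  latency_defaults <- list(imu = c(0.02, 0.005), gps = c(0.05, 0.01),
                           lps = c(0.01, 0.002), physio = c(0.1, 0.02),
                           insole = c(0.02, 0.005))
  cfg <- list(
    n_athletes_per_team = n_athletes_per_team, duration_s = duration_s,
    frame_rate_hz = frame_rate_hz, coupling_kappa = coupling_kappa,
    formation_spacing_m = formation_spacing_m,
    centroid_speed_mps = centroid_speed_mps,
    osc_amplitude_m = osc_amplitude_m, base_freq_hz = base_freq_hz,
    freq_spread_hz = freq_spread_hz, phase_noise = phase_noise,
    pitch_extent = pitch_extent,
    noise_profile = utils::modifyList(noise_defaults, noise_profile),
    latency_profile = utils::modifyList(latency_defaults, latency_profile),
    dropout_rate = dropout_rate, event_rates = event_rates,
    perturbation_s = perturbation_s, outcome_effect = outcome_effect,
    modalities = match.arg(modalities,
                           c("imu", "gps", "lps", "physio", "insole"),
                           several.ok = TRUE),
    sport = sport, seed = as.integer(seed))
  if (cfg$coupling_kappa < 0) {
    tf_validation_error("coupling_kappa must be >= 0", "coupling_kappa")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    tf_validation_error("dropout_rate must lie in [0, 1)", "dropout_rate")
  }
  if (cfg$duration_s <= 0 || cfg$frame_rate_hz <= 0) {
    tf_validation_error("duration_s and frame_rate_hz must be > 0", "duration_s")
  }
  structure(cfg, class = "tf_sim_config")
}

# Euler-Maruyama integration of Kuramoto phase dynamics; kappa may be a
# per-frame vector (perturbations dip it). Returns n_frames x n matrix.
kuramoto_phases <- function(n, t, omega, kappa, sigma, psi0) {
  nf <- length(t)
  dt <- if (nf > 1) t[2] - t[1] else 0
  psi <- matrix(0, nf, n)
  psi[1, ] <- psi0
  if (length(kappa) == 1) kappa <- rep(kappa, nf)
  sq <- sigma * sqrt(dt)
  noise <- matrix(rnorm((nf - 1) * n), nf - 1, n)
  for (k in seq_len(nf - 1)) {
    p <- psi[k, ]
    # mean-field form of the pairwise sine coupling
    zr <- mean(cos(p)); zi <- mean(sin(p))
    coupling <- kappa[k] * (zi * cos(p) - zr * sin(p))
    psi[k + 1, ] <- p + (omega + coupling) * dt + sq * noise[k, ]
  }
  psi
}

#' Simulate a multi-athlete session with ground truth
#'
#' Generates a full session: a manifest, per-athlete sensor streams for each
#' configured modality (truth resampled at the modality rate, delayed by
#' transmission latency, plus Gaussian noise at the modality accuracy, with
#' Bernoulli dropouts), and the ground truth the sensors observed.
#'
#' Athlete i's position is `centroid(t) + formation_slot_i +
#' a * (cos psi_i, sin psi_i)` with phases from Kuramoto dynamics; the team
#' centroid follows a smooth bounded path. Perturbation events temporarily
#' collapse the coupling, passes occur at Poisson times between nearby
#' teammates. Everything is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `manifest`, `streams` (named list of `tf_stream`) and
#'   `truth` (list: `team` — a `tf_team` at the frame rate, `orientation` —
#'   per-athlete heading series, `phases` — matrix of true phases, `events`,
#'   `outcome`, `config`).
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "tf_sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(child_seed(cfg$seed, "session"))
  n_team <- cfg$n_athletes_per_team
  n <- 2L * n_team
  ids <- c(paste0("A", seq_len(n_team)), paste0("B", seq_len(n_team)))
  teams <- rep(c("A", "B"), each = n_team)
  fr <- cfg$frame_rate_hz
  t <- seq(0, cfg$duration_s, by = 1 / fr)
  nf <- length(t)

  # events first: perturbations modulate coupling
  events <- simulate_events(cfg, ids, teams)
  kappa_t <- rep(cfg$coupling_kappa, nf)
  pert_t <- events$t[events$event_type == "perturbation"]
  for (pt in pert_t) {
    idx <- which(t >= pt & t < pt + cfg$perturbation_s)
    kappa_t[idx] <- kappa_t[idx] * 0.1
  }

  # phases per team (coupling acts within a team)
  omega0 <- 2 * pi * cfg$base_freq_hz
  phases <- matrix(0, nf, n)
  for (side in c("A", "B")) {
    set.seed(child_seed(cfg$seed, "phases", side))
    m <- which(teams == side)
    omega <- omega0 + 2 * pi * cfg$freq_spread_hz * rnorm(length(m))
    psi0 <- runif(length(m), 0, 2 * pi)
    phases[, m] <- kuramoto_phases(length(m), t, omega, kappa_t,
                                   cfg$phase_noise, psi0)
  }

  # centroid path: smooth bounded Lissajous-style drift inside the pitch
  px <- cfg$pitch_extent
  amp_x <- 0.25 * (px[2] - px[1]) / 2
  amp_y <- 0.25 * (px[4] - px[3]) / 2
  wx <- cfg$centroid_speed_mps / max(amp_x, 1e-9)
  wy <- cfg$centroid_speed_mps / max(amp_y, 1e-9) / 1.37  # incommensurate
  cent <- function(tt, side) {
    sgn <- if (side == "A") 1 else -1
    cbind(sgn * 0.3 * (px[2] - px[1]) / 2 * 0 + amp_x * sin(wx * tt) * sgn,
          amp_y * sin(wy * tt + sgn * 0.8))
  }

  # formation slots on a grid around the centroid
  slots <- formation_slots(n_team, cfg$formation_spacing_m)
  pos <- array(0, c(nf, n, 2))
  for (i in seq_len(n)) {
    side <- teams[i]
    k <- ((i - 1) %% n_team) + 1
    cc <- cent(t, side)
    pos[, i, 1] <- cc[, 1] + slots[k, 1] +
      cfg$osc_amplitude_m * cos(phases[, i])
    pos[, i, 2] <- cc[, 2] + slots[k, 2] +
      cfg$osc_amplitude_m * sin(phases[, i])
  }

  dt <- 1 / fr
  vel <- array(0, c(nf, n, 2))
  acc <- array(0, c(nf, n, 2))
  for (i in seq_len(n)) for (d in 1:2) {
    vel[, i, d] <- cgrad(pos[, i, d], dt)
    acc[, i, d] <- cgrad(vel[, i, d], dt)
  }

  team_tbl <- tibble(
    t = rep(t, n),
    athlete_id = rep(ids, each = nf),
    team = rep(teams, each = nf),
    x = as.vector(pos[, , 1]), y = as.vector(pos[, , 2]),
    vx = as.vector(vel[, , 1]), vy = as.vector(vel[, , 2]))
  truth_team <- new_team_trajectory(team_tbl)

  heading <- matrix(0, nf, n)
  for (i in seq_len(n)) {
    h <- atan2(vel[, i, 2], vel[, i, 1])
    heading[, i] <- signal::unwrap(h) * 180 / pi
  }

  streams <- list()
  stream_rows <- list()
  for (i in seq_len(n)) {
    sp <- athlete_streams(cfg, ids[i], t, pos[, i, ], vel[, i, ], acc[, i, ],
                          heading[, i], phases[, i])
    streams <- c(streams, sp)
  }
  names(streams) <- vapply(streams, stream_id, character(1))

  athletes <- tibble(
    athlete_id = ids, role = rep("field", n), team = teams,
    sensors = purrr::map(ids, function(id) {
      vapply(streams[vapply(streams, function(s)
        attr(s, "athlete_id") == id, logical(1))],
        function(s) attr(s, "sensor_id"), character(1), USE.NAMES = FALSE)
    }))
  idx <- purrr::map_dfr(streams, stream_meta)
  idx$path <- file.path("streams",
                        paste0(idx$athlete_id, "_", idx$sensor_id, ".csv"))
  manifest <- session_manifest(
    session_id = sprintf("sim-%d", cfg$seed), sport = cfg$sport,
    pitch_extent = cfg$pitch_extent, athletes = athletes,
    stream_index = idx[c("athlete_id", "sensor_id", "modality", "path",
                         "sample_rate_hz", "latency_s")])

  set.seed(child_seed(cfg$seed, "outcome"))
  outcome <- sample(c("win", "loss"), 1)

  orientation <- purrr::map(setNames(seq_len(n), ids), function(i) {
    tibble(t = t, heading_deg = heading[, i])
  })

  list(manifest = manifest, streams = streams,
       truth = list(team = truth_team, orientation = orientation,
                    phases = phases, phase_t = t, events = events,
                    outcome = outcome, config = cfg))
}

# centred finite-difference gradient with one-sided ends
cgrad <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  if (n < 2) return(g)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

formation_slots <- function(n, spacing) {
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  g <- expand.grid(col = seq_len(ncol_), row = seq_len(nrow_))[seq_len(n), ]
  cbind((g$col - (ncol_ + 1) / 2) * spacing,
        (g$row - (nrow_ + 1) / 2) * spacing)
}

simulate_events <- function(cfg, ids, teams) {
  set.seed(child_seed(cfg$seed, "events"))
  dur_min <- cfg$duration_s / 60
  tA <- ids[teams == "A"]
  n_pass <- rpois(1, cfg$event_rates$passes_per_min * dur_min)
  pass_t <- sort(runif(n_pass, 0, cfg$duration_s))
  from <- sample(tA, n_pass, replace = TRUE)
  to <- vapply(from, function(f) sample(setdiff(tA, f), 1), character(1))
  n_pert <- rpois(1, cfg$event_rates$perturbations_per_min * dur_min)
  pert_t <- sort(runif(n_pert, 0, max(cfg$duration_s - cfg$perturbation_s, 1)))
  n_dec <- rpois(1, 2 * dur_min)
  dec_t <- sort(runif(n_dec, 0, cfg$duration_s))
  dec_id <- sample(tA, n_dec, replace = TRUE)
  ev <- tf_events(
    t = c(pass_t, pert_t, dec_t),
    event_type = c(rep("pass", n_pass), rep("perturbation", n_pert),
                   rep("decisive_action", n_dec)),
    athlete_id = c(from, rep(NA, n_pert), dec_id),
    target_athlete_id = c(to, rep(NA, n_pert + n_dec)))
  ev
}

# truth sampled at sensor clocks: linear interpolation of the frame-rate
# series; exact whenever a sensor tick coincides with a truth frame.
sample_truth <- function(t_frame, x, t_query) {
  approx(t_frame, x, xout = t_query, rule = 2)$y
}

athlete_streams <- function(cfg, id, t, pos, vel, acc, heading, phase) {
  np <- cfg$noise_profile
  lp <- cfg$latency_profile
  dur <- cfg$duration_s
  mk <- function(sensor_id, modality, rate, channels, sigmas, units) {
    ts <- seq(0, dur, by = 1 / rate)
    lat <- lp[[modality]]
    set.seed(child_seed(cfg$seed, id, sensor_id))
    lat_samp <- lat[1] + lat[2] * abs(rnorm(length(ts)))
    if (lat[1] == 0 && lat[2] == 0) lat_samp <- rep(0, length(ts))
    t_eff <- pmax(t[1], ts - lat_samp)
    vals <- purrr::imap(channels, function(f, nm) {
      v <- f(t_eff)
      v + sigmas[[nm]] * rnorm(length(v))
    })
    dropout <- runif(length(ts)) < cfg$dropout_rate
    vals <- purrr::map(vals, function(v) { v[dropout] <- NA_real_; v })
    sensor_stream(ts, vals, id, sensor_id, modality, rate,
                  units = units,
                  accuracy = unlist(sigmas),
                  latency_s = lat[1], dropout = dropout)
  }
  g <- 9.80665
  out <- list()
  if ("gps" %in% cfg$modalities) {
    out$gps <- mk("gps", "gps", 10,
      list(x = function(tt) sample_truth(t, pos[, 1], tt),
           y = function(tt) sample_truth(t, pos[, 2], tt)),
      list(x = np$gps_sigma_m, y = np$gps_sigma_m),
      c(x = "m", y = "m"))
  }
  if ("lps" %in% cfg$modalities) {
    out$lps <- mk("lps", "lps", 40,
      list(x = function(tt) sample_truth(t, pos[, 1], tt),
           y = function(tt) sample_truth(t, pos[, 2], tt)),
      list(x = np$lps_sigma_m, y = np$lps_sigma_m),
      c(x = "m", y = "m"))
  }
  if ("imu" %in% cfg$modalities) {
    grate <- cgrad(heading, t[2] - t[1])
    out$imu <- mk("imu", "imu", 200,
      list(ax = function(tt) sample_truth(t, acc[, 1], tt),
           ay = function(tt) sample_truth(t, acc[, 2], tt),
           gyro_z = function(tt) sample_truth(t, grate, tt),
           incl_deg = function(tt) sample_truth(t, heading, tt)),
      list(ax = np$imu_acc_sigma_g * g, ay = np$imu_acc_sigma_g * g,
           gyro_z = np$gyro_sigma_dps, incl_deg = np$mag_sigma_deg),
      c(ax = "m/s^2", ay = "m/s^2", gyro_z = "deg/s", incl_deg = "deg"))
  }
  if ("physio" %in% cfg$modalities) {
    speed <- sqrt(vel[, 1]^2 + vel[, 2]^2)
    hr <- first_order_lag(60 + 12 * speed, t[2] - t[1], tau = 30)
    out$physio <- mk("hr", "physio", 10,
      list(hr = function(tt) sample_truth(t, hr, tt)),
      list(hr = np$hr_sigma_bpm), c(hr = "bpm"))
  }
  if ("insole" %in% cfg$modalities) {
    speed <- sqrt(vel[, 1]^2 + vel[, 2]^2)
    force <- pmax(0, sin(2 * phase))^3 * (600 + 60 * speed)
    out$insole <- mk("insole", "insole", 100,
      list(force = function(tt) sample_truth(t, force, tt)),
      list(force = np$insole_sigma_n), c(force = "N"))
  }
  unname(out)
}

first_order_lag <- function(x, dt, tau) {
  a <- dt / (tau + dt)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (k in 2:length(x)) y[k] <- y[k - 1] + a * (x[k] - y[k - 1])
  y
}

#' Inject amplitude-proportional Gaussian noise into a stream
#'
#' Adds zero-mean Gaussian noise with per-channel standard deviation
#' `amplitude_fraction` times the channel RMS — the robustness protocol used
#' to probe fusion degradation (up to 30% amplitude).
#'
#' @param stream a `tf_stream`.
#' @param amplitude_fraction fraction of channel RMS, in `[0, 1]`.
#' @param seed integer seed.
#' @return the corrupted `tf_stream`.
#' @export
inject_noise <- function(stream, amplitude_fraction, seed = 1L) {
  if (amplitude_fraction < 0 || amplitude_fraction > 1) {
    tf_validation_error("amplitude_fraction must lie in [0, 1]",
                        "amplitude_fraction")
  }
  if (amplitude_fraction == 0) return(stream)
  set.seed(child_seed(seed, "inject", stream_id(stream)))
  for (ch in stream_channels(stream)) {
    v <- stream[[ch]]
    sigma <- amplitude_fraction * rms(v)
    stream[[ch]] <- v + sigma * rnorm(length(v))
  }
  stream
}

#' Draw a labelled dataset of session-level indicator summaries
#'
#' Session summaries of the eight coordination indicators with a win/loss
#' label. Within each class the indicators are independent Gaussians; the
#' class means differ by `config$outcome_effect` (in within-class SD units),
#' so the Bayes-optimal held-out accuracy is `pnorm(norm(effect)/2)` —
#' a closed-form yardstick for the outcome classifier.
#'
#' @param config a [sim_config()]; `outcome_effect` and `seed` are used.
#' @param n_sessions number of sessions (balanced classes), >= 2.
#' @return tibble: session_id, outcome and one column per indicator.
#' @export
make_outcome_dataset <- function(config, n_sessions) {
  if (!inherits(config, "tf_sim_config")) config <- do.call(sim_config, config)
  if (n_sessions < 2) tf_validation_error("n_sessions must be >= 2",
                                          "n_sessions")
  set.seed(child_seed(config$seed, "outcomes"))
  base <- c(ssi = 0.5, tcr = 0.3, fsq = 0.6, tie = 0.7, cpr = 5,
            icc = 0.5, dms = 0.6, ldh = 0.8)
  sds <- c(ssi = 0.1, tcr = 0.08, fsq = 0.1, tie = 0.1, cpr = 1.5,
           icc = 0.1, dms = 0.1, ldh = 0.05)
  eff <- setNames(rep(0, length(base)), names(base))
  oe <- config$outcome_effect
  eff[names(oe)] <- oe
  y <- rep(c("win", "loss"), length.out = n_sessions)
  X <- purrr::map_dfc(names(base), function(k) {
    shift <- ifelse(y == "win", eff[k] / 2, -eff[k] / 2) * sds[k]
    tibble(!!k := base[k] + shift + sds[k] * rnorm(n_sessions))
  })
  bind_cols(tibble(session_id = sprintf("s%03d", seq_len(n_sessions)),
                   outcome = y), X)
}
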