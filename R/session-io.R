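#' Construct a sensor stream
#'
#' A sensor stream is one timestamped multi-channel signal from one device on
#' one athlete: a tibble with a strictly increasing time column `t` (seconds
#' on the session master clock), one column per channel and a logical
#' `dropout` column marking samples lost in transmission. Device metadata
#' (modality, nominal sample rate, per-channel units and accuracies, reported
#' transmission latency) travels as attributes.
#'
#' @param t numeric vector, strictly increasing, seconds on the master clock.
#' @param values data frame or named list of numeric channels (one column per
#'   channel), `length(t)` rows.
#' @param athlete_id,sensor_id character identifiers.
#' @param modality one of `"imu"`, `"gps"`, `"lps"`, `"physio"`, `"insole"`.
#' @param sample_rate_hz nominal sampling rate, Hz (> 0).
#' @param units named character vector of per-channel units (optional).
#' @param accuracy named numeric vector of nominal per-channel accuracies in
#'   the channel's units (optional).
#' @param latency_s reported transmission latency, seconds.
#' @param dropout logical vector marking missing samples; channel values may
#'   be `NA` only where `dropout` is `TRUE`.
#' @return a tibble of class `tf_stream`.
#' @export
sensor_stream <- function(t, values, athlete_id, sensor_id, modality,
                          sample_rate_hz, units = NULL, accuracy = NULL,
                          latency_s = 0, dropout = NULL) {
  modality <- match.arg(modality, c("imu", "gps", "lps", "physio", "insole"))
  values <- as_tibble(as.data.frame(values))
  if (nrow(values) != length(t)) {
    tf_validation_error("values must have one row per timestamp", "values")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    tf_data_error("timestamps must be strictly increasing",
                  paste(athlete_id, sensor_id, sep = "/"))
  }
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    tf_validation_error("sample_rate_hz must be > 0", "sample_rate_hz")
  }
  if (is.null(dropout)) dropout <- rep(FALSE, length(t))
  bad <- vapply(values, function(v) any(is.na(v) & !dropout), logical(1))
  if (any(bad)) {
    tf_data_error(
      paste0("NA outside dropout mask in channel(s): ",
             paste(names(values)[bad], collapse = ", ")),
      paste(athlete_id, sensor_id, sep = "/"))
  }
  out <- bind_cols(tibble(t = as.double(t)), values,
                   tibble(dropout = as.logical(dropout)))
  structure(out,
            class = c("tf_stream", class(tibble())),
            athlete_id = athlete_id, sensor_id = sensor_id,
            modality = modality, sample_rate_hz = sample_rate_hz,
            units = units, accuracy = accuracy, latency_s = latency_s)
}

#' Stream metadata as a one-row tibble
#' @param stream a `tf_stream`.
#' @return tibble with athlete_id, sensor_id, modality, sample_rate_hz,
#'   latency_s, n_samples.
#' @export
stream_meta <- function(stream) {
  tibble(
    athlete_id = attr(stream, "athlete_id"),
    sensor_id = attr(stream, "sensor_id"),
    modality = attr(stream, "modality"),
    sample_rate_hz = attr(stream, "sample_rate_hz"),
    latency_s = attr(stream, "latency_s") %||% 0,
    n_samples = nrow(stream)
  )
}

stream_channels <- function(stream) setdiff(names(stream), c("t", "dropout"))

stream_id <- function(stream) {
  paste(attr(stream, "athlete_id"), attr(stream, "sensor_id"), sep = "/")
}

#' Construct a session manifest
#'
#' The manifest declares the session (sport, pitch extent, master clock),
#' the athletes and which sensor streams belong to whom. Positions use a
#' pitch frame in metres, origin at the pitch centre, x toward team A's
#' attacking direction.
#'
#' @param session_id character.
#' @param sport one of basketball, soccer, volleyball, handball, generic.
#' @param pitch_extent numeric `c(x_min, x_max, y_min, y_max)` in metres.
#' @param athletes tibble with columns athlete_id, role, team ("A"/"B") and a
#'   list-column `sensors` of sensor ids.
#' @param stream_index tibble with columns athlete_id, sensor_id, modality,
#'   path, sample_rate_hz (and optionally latency_s).
#' @param master_clock_epoch numeric, seconds (e.g. UNIX epoch of t = 0).
#' @return list of class `tf_manifest`.
#' @export
session_manifest <- function(session_id, sport, pitch_extent, athletes,
                             stream_index, master_clock_epoch = 0) {
  sport <- match.arg(sport,
    c("basketball", "soccer", "volleyball", "handball", "generic"))
  pitch_extent <- as.double(pitch_extent)
  if (length(pitch_extent) != 4 ||
      pitch_extent[2] <= pitch_extent[1] || pitch_extent[4] <= pitch_extent[3]) {
    tf_validation_error("pitch_extent must be c(x_min,x_max,y_min,y_max), non-degenerate",
                        "pitch_extent")
  }
  athletes <- as_tibble(athletes)
  if (anyDuplicated(athletes$athlete_id)) {
    tf_validation_error("athlete_ids must be unique", "athletes.athlete_id")
  }
  if (any(lengths(athletes$sensors) == 0)) {
    tf_validation_error("every athlete needs a non-empty sensors list",
                        "athletes.sensors")
  }
  stream_index <- as_tibble(stream_index)
  if (!"latency_s" %in% names(stream_index)) stream_index$latency_s <- 0
  undeclared <- setdiff(stream_index$athlete_id, athletes$athlete_id)
  if (length(undeclared)) {
    tf_validation_error(
      paste0("stream references undeclared athlete(s): ",
             paste(undeclared, collapse = ", ")),
      "stream_index.athlete_id")
  }
  if (any(stream_index$sample_rate_hz <= 0)) {
    tf_validation_error("sample_rate_hz must be > 0",
                        "stream_index.sample_rate_hz")
  }
  structure(
    list(session_id = session_id, sport = sport, pitch_extent = pitch_extent,
         master_clock_epoch = master_clock_epoch, athletes = athletes,
         stream_index = stream_index),
    class = "tf_manifest")
}

#' Construct an event table
#'
#' Discrete annotated events: passes, possession changes, perturbations
#' (opposing-team interventions), decisive actions and shots.
#'
#' @param t numeric event times, seconds.
#' @param event_type character, one of pass, possession_change, perturbation,
#'   decisive_action, shot.
#' @param athlete_id,target_athlete_id,outcome optional character vectors.
#' @return tibble of class `tf_events`.
#' @export
tf_events <- function(t = numeric(), event_type = character(),
                      athlete_id = NA_character_,
                      target_athlete_id = NA_character_,
                      outcome = NA_character_) {
  allowed <- c("pass", "possession_change", "perturbation",
               "decisive_action", "shot")
  if (length(event_type) && !all(event_type %in% allowed)) {
    tf_validation_error(paste0("unknown event_type; allowed: ",
                               paste(allowed, collapse = ", ")), "event_type")
  }
  out <- tibble(t = as.double(t), event_type = as.character(event_type),
                athlete_id = rep_len(as.character(athlete_id), length(t)),
                target_athlete_id = rep_len(as.character(target_athlete_id),
                                            length(t)),
                outcome = rep_len(as.character(outcome), length(t)))
  is_pass <- out$event_type == "pass"
  if (any(is_pass & (is.na(out$athlete_id) | is.na(out$target_athlete_id)))) {
    tf_validation_error("pass events must carry both athlete ids", "athlete_id")
  }
  structure(arrange(out, .data$t), class = c("tf_events", class(tibble())))
}

# ---- reading ----------------------------------------------------------------

#' Read a session from disk
#'
#' Loads `manifest.json`, every stream CSV it indexes and (if present)
#' `events.csv` from the same directory.
#'
#' @param manifest_path path to `manifest.json`.
#' @return list with elements `manifest` (`tf_manifest`), `streams` (named
#'   list of `tf_stream`) and `events` (`tf_events`, empty if no file).
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    tf_validation_error("manifest file not found", manifest_path)
  }
  root <- dirname(manifest_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (field in c("session_id", "sport", "pitch_extent", "athletes", "streams")) {
    if (is.null(m[[field]])) {
      tf_validation_error(paste0("manifest missing required field '", field, "'"),
                          field)
    }
  }
  athletes <- as_tibble(m$athletes)
  if (!is.list(athletes$sensors)) athletes$sensors <- as.list(athletes$sensors)
  manifest <- session_manifest(
    session_id = m$session_id, sport = m$sport,
    pitch_extent = unlist(m$pitch_extent),
    athletes = athletes,
    stream_index = as_tibble(m$streams),
    master_clock_epoch = m$master_clock_epoch %||% 0)

  streams <- purrr::pmap(manifest$stream_index, function(athlete_id, sensor_id,
                                                         modality, path,
                                                         sample_rate_hz,
                                                         latency_s, ...) {
    f <- file.path(root, path)
    if (!file.exists(f)) tf_validation_error("stream file not found", path)
    # base parser: correctly rounded doubles, so timestamps round-trip
    # bit-exactly
    df <- as_tibble(utils::read.csv(f))
    dropout <- if ("dropout" %in% names(df)) as.logical(df$dropout) else NULL
    vals <- df[setdiff(names(df), c("t", "dropout"))]
    extra <- m$stream_meta[[paste(athlete_id, sensor_id, sep = "/")]]
    sensor_stream(df$t, vals, athlete_id, sensor_id, modality, sample_rate_hz,
                  units = unlist(extra$units), accuracy = unlist(extra$accuracy),
                  latency_s = latency_s, dropout = dropout)
  })
  names(streams) <- paste(manifest$stream_index$athlete_id,
                          manifest$stream_index$sensor_id, sep = "/")

  ev_path <- file.path(root, "events.csv")
  events <- if (file.exists(ev_path)) {
    df <- as_tibble(utils::read.csv(ev_path, colClasses = c(t = "numeric"),
                                    stringsAsFactors = FALSE))
    tf_events(df$t, df$event_type, df$athlete_id, df$target_athlete_id,
              df$outcome)
  } else {
    tf_events()
  }
  list(manifest = manifest, streams = streams, events = events)
}

# ---- writing ----------------------------------------------------------------

#' Write a session to disk
#'
#' Produces `manifest.json`, one CSV per stream under `streams/` and
#' `events.csv`. `read_session()` on the result reproduces the input exactly
#' on timestamps and ids and to <= 1e-9 relative error on values.
#'
#' @param manifest `tf_manifest`.
#' @param streams list of `tf_stream`.
#' @param events `tf_events` or NULL.
#' @param out_dir output directory (created if needed).
#' @return the path to the written `manifest.json`, invisibly.
#' @export
write_session <- function(manifest, streams, events = NULL, out_dir) {
  dir.create(file.path(out_dir, "streams"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) tf_abort("cannot create output directory",
                                     class = "tf_io_error")
  idx <- purrr::map_dfr(streams, stream_meta)
  idx$path <- file.path("streams",
                        paste0(idx$athlete_id, "_", idx$sensor_id, ".csv"))
  meta_extra <- list()
  for (s in streams) {
    sid <- stream_id(s)
    p <- file.path(out_dir, "streams",
                   paste0(attr(s, "athlete_id"), "_",
                          attr(s, "sensor_id"), ".csv"))
    df <- as.data.frame(s)
    df$dropout <- as.integer(df$dropout)
    readr::write_csv(df, p, progress = FALSE)
    meta_extra[[sid]] <- list(units = as.list(attr(s, "units") %||% list()),
                              accuracy = as.list(attr(s, "accuracy") %||% list()))
  }
  manifest$stream_index <- idx[c("athlete_id", "sensor_id", "modality", "path",
                                 "sample_rate_hz", "latency_s")]
  mj <- list(session_id = manifest$session_id, sport = manifest$sport,
             pitch_extent = manifest$pitch_extent,
             master_clock_epoch = manifest$master_clock_epoch,
             athletes = manifest$athletes,
             streams = manifest$stream_index,
             stream_meta = meta_extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(mj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(events) && nrow(events) > 0) {
    readr::write_csv(as.data.frame(events), file.path(out_dir, "events.csv"),
                     progress = FALSE)
  }
  invisible(path)
}

#' Write a pipeline output object to disk
#'
#' CSV for tabular results (deterministic column order, full precision),
#' JSON for the fusion-quality report.
#'
#' @param x an `tf_record`, `tf_team`, `tf_indicators` or `tf_quality`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_output <- function(x, path) UseMethod("write_output")

#' @export
write_output.tf_record <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}

#' @export
write_output.tf_indicators <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}

# team trajectory written wide: t then x,y,vx,vy per athlete (stable order)
#' @export
write_output.tf_team <- function(x, path) {
  wide <- tidyr::pivot_wider(
    as_tibble(x)[c("t", "athlete_id", "x", "y", "vx", "vy")],
    names_from = "athlete_id", values_from = c("x", "y", "vx", "vy"),
    names_glue = "{.value}_{athlete_id}")
  ids <- unique(as_tibble(x)$athlete_id)
  cols <- c("t", as.vector(t(outer(ids, c("x", "y", "vx", "vy"),
                                   function(a, v) paste0(v, "_", a)))))
  readr::write_csv(as.data.frame(wide[cols]), path, progress = FALSE)
  invisible(path)
}

#' @export
write_output.tf_quality <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
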