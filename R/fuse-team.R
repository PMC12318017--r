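new_team_trajectory <- function(tbl) {
  needed <- c("t", "athlete_id", "team", "x", "y", "vx", "vy")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    tf_validation_error(paste0("team trajectory missing column(s): ",
                               paste(missing, collapse = ", ")), "tbl")
  }
  structure(as_tibble(tbl), class = c("tf_team", class(tibble())))
}

#' Team-level fusion of individual records
#'
#' Integrates per-athlete fused records into a single team trajectory on
#' the shared analysis grid. Team-level weights are uniform: the centroid
#' is the arithmetic mean of member positions at every frame.
#'
#' @param records list of `tf_record` (>= 2 athletes, identical grids).
#' @param teams named character vector mapping athlete_id to "A"/"B";
#'   default assigns everyone to team "A".
#' @return long tibble of class `tf_team`: t, athlete_id, team, x, y, vx,
#'   vy.
#' @export
fuse_team <- function(records, teams = NULL) {
  if (length(records) < 2) {
    tf_abort("team fusion needs at least 2 athletes", class = "tf_error")
  }
  ids <- vapply(records, function(r) attr(r, "athlete_id"), character(1))
  grids <- purrr::map(records, "t")
  ref <- grids[[1]]
  same <- vapply(grids, function(g)
    length(g) == length(ref) && max(abs(g - ref)) < 1e-9, logical(1))
  if (!all(same)) {
    tf_abort("records are not on a common time grid", class = "tf_error")
  }
  if (is.null(teams)) teams <- setNames(rep("A", length(ids)), ids)
  tbl <- purrr::map2_dfr(records, ids, function(r, id) {
    tibble(t = r$t, athlete_id = id, team = unname(teams[id]),
           x = r$x, y = r$y, vx = r$vx, vy = r$vy)
  })
  new_team_trajectory(tbl)
}

#' Team centroid trajectory
#'
#' Arithmetic mean position (and velocity) of a team's athletes at every
#' frame.
#'
#' @param team a `tf_team`.
#' @param by_team if `TRUE` (default) one centroid per team label, else one
#'   over all athletes.
#' @return tibble: t, (team,) cx, cy, cvx, cvy.
#' @export
team_centroid <- function(team, by_team = TRUE) {
  g <- if (by_team) group_by(team, .data$t, .data$team) else
    group_by(team, .data$t)
  out <- summarise(g, cx = mean(.data$x), cy = mean(.data$y),
                   cvx = mean(.data$vx), cvy = mean(.data$vy),
                   .groups = "drop")
  out
}
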