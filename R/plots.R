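#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_path geom_point
#'   geom_raster facet_wrap labs theme_minimal scale_fill_viridis_c coord_fixed
NULL

#' @export
ggplot2::autoplot

#' Pitch map of a team trajectory
#' @param object a `tf_team`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tf_team <- function(object, ...) {
  cen <- team_centroid(object)
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$y,
                                group = .data$athlete_id,
                                colour = .data$team)) +
    geom_path(alpha = 0.6) +
    geom_path(data = cen, aes(x = .data$cx, y = .data$cy, group = .data$team),
              colour = "black", linewidth = 1) +
    coord_fixed() +
    labs(x = "x (m)", y = "y (m)",
         title = "Athlete trajectories and team centroid") +
    theme_minimal()
}

#' Faceted time series of the indicator system
#' @param object a `tf_indicators`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tf_indicators <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"t",
                              names_to = "indicator", values_to = "value")
  ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~indicator, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = "Collaborative-dynamics indicators") +
    theme_minimal()
}

#' Cross-recurrence plot
#' @param object a `tf_crqa`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tf_crqa <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_len(nrow(object$CR)),
                           j = seq_len(ncol(object$CR)))
  df$rec <- as.vector(object$CR)
  ggplot(df[df$rec == 1, ], aes(x = .data$i, y = .data$j)) +
    geom_point(shape = 15, size = 0.3) +
    coord_fixed() +
    labs(x = "athlete i time index", y = "athlete j time index",
         title = sprintf("Cross-recurrence plot (RR = %.3f, DET = %.3f)",
                         object$RR, object$DET)) +
    theme_minimal()
}

#' Per-source adaptive weight history of a fused record
#' @param object a `tf_record`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tf_record <- function(object, ...) {
  w <- attr(object, "weights")
  ggplot(w, aes(x = .data$block_t, y = .data$weight,
                colour = .data$source)) +
    geom_line() +
    labs(x = "time (s)", y = "fusion weight",
         title = paste0("Adaptive source weights: ",
                        attr(object, "athlete_id"))) +
    theme_minimal()
}

#' Fuser comparison: RMSE vs injected noise amplitude
#' @param object a `tf_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.tf_comparison <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$noise_amplitude, y = .data$rmse_pos_m,
             colour = .data$fuser)) +
    geom_line() + geom_point() +
    labs(x = "injected noise amplitude (fraction of RMS)",
         y = "position RMSE (m)",
         title = "Fusion robustness under noise injection") +
    theme_minimal()
}
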