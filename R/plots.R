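#' Compass plot of range displacement vectors
#'
#' Arrows from each species' current range median center to its future one,
#' colored by compass quadrant.
#'
#' @param records Range-change tibble from [compute_range_changes()].
#' @return A ggplot.
#' @export
plot_shift_vectors <- function(records) {
  df <- dplyr::filter(records, !is.na(.data$quadrant))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$center_current_lon,
                   y = .data$center_current_lat,
                   xend = .data$center_future_lon,
                   yend = .data$center_future_lat,
                   colour = .data$quadrant),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Quadrant",
                  title = "Range median-center displacement vectors")
}

#' Diversity change across elevation bands
#'
#' @param profile An `elevation_profile`.
#' @return A ggplot of per-band species diversity, current vs future.
#' @export
plot_elevation_profile <- function(profile) {
  df <- tidyr::pivot_longer(
    profile$profile, c("diversity_current", "diversity_future"),
    names_to = "scenario", values_to = "diversity",
    names_prefix = "diversity_"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$band,
                                        y = .data$diversity,
                                        fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Elevation band", y = "Species diversity",
                  fill = NULL)
  if (!is.na(profile$turning_point)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("turning point at %g m", profile$turning_point))
  }
  p
}

#' Histogram of per-species range changes
#'
#' @param records Range-change tibble from [compute_range_changes()].
#' @return A ggplot.
#' @export
plot_range_change <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$pct_change)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Range change (%)", y = "Species")
}

#' @method autoplot priority_ranking
#' @export
autoplot.priority_ranking <- function(object, ...) {
  autoplot(object$rank_grid) +
    ggplot2::labs(fill = "Priority rank")
}
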