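#' Plot a maximum-intensity projection with detected spots overlaid
#'
#' @param stack An [image_stack()].
#' @param spots Optional classified spot tibble; centroids are drawn
#'   coloured by class.
#' @param channel Channel role to project (default `"oligomer"`).
#' @return A ggplot object (x/y in um, intensity as fill).
#' @export
plot_field_mip <- function(stack, spots = NULL, channel = "oligomer") {
  chan <- get_channel(stack, channel)
  mip <- apply(chan, c(2, 3), max)
  sp <- stack$spacing
  df <- tidyr::expand_grid(y_um = (seq_len(nrow(mip)) - 0.5) * sp$dy,
                           x_um = (seq_len(ncol(mip)) - 0.5) * sp$dx)
  df$intensity <- as.vector(t(mip))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = channel, title = "Maximum-intensity projection")
  if (!is.null(spots) && nrow(spots) > 0) {
    p <- p + ggplot2::geom_point(
      data = spots,
      ggplot2::aes(.data$x_um, .data$y_um, colour = .data$class),
      shape = 1, size = 2.5, stroke = 0.9)
  }
  p
}

#' Plot per-field uptake metrics by group
#'
#' Jittered per-field values with group mean +/- SEM, one panel per metric.
#'
#' @param summaries Field-summary tibble with a grouping column.
#' @param group_col Grouping column name.
#' @param metrics Metric columns to show.
#' @return A ggplot object.
#' @export
plot_uptake_summary <- function(summaries, group_col = "group",
                                metrics = c("pct_internalizing",
                                            "mean_internalized_spots_per_neuron",
                                            "internalization_index",
                                            "mean_attached_spots_per_neuron")) {
  long <- tidyr::pivot_longer(
    dplyr::select(summaries, dplyr::all_of(c(group_col, metrics))),
    dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  stat <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data[[group_col]]),
    mean = mean(.data$value, na.rm = TRUE),
    sem = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data[[group_col]], .data$value)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(
      data = stat,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      colour = "red3", linewidth = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname compare_groups
#' @param object A `group_comparison`.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tibble::tibble(group = factor(object$labels, levels = object$labels),
                       mean = object$means, sem = object$sems)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.15) +
    ggplot2::labs(
      x = NULL, y = "mean ± SEM",
      subtitle = sprintf("t(%.3g) = %.3g, p = %.3g", object$df,
                         object$t_statistic, object$p_value))
}
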