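# ggplot2 visualisation helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.grid_map <- function(object, ...) {
  df <- tibble(
    x = rep(object$grid$x, times = length(object$grid$y)),
    y = rep(object$grid$y, each = length(object$grid$x)),
    value = as.vector(object$values)
  )
  df$value[!as.vector(object$mask)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
      na.value = "grey92", name = object$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = if (nzchar(object$component)) object$component else NULL,
      x = "x (mm)", y = "y (mm)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.polar_map <- function(object, ...) {
  xy <- polar_to_cartesian(object$grid)
  df <- tibble(
    x = as.vector(xy$x), y = as.vector(xy$y),
    value = as.vector(ifelse(object$valid, object$values, NA_real_))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
      high = "#b2182b", na.value = "grey92", name = object$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Bar chart of cohort band areas
#'
#' Mean +/- SD of the weak/moderate/strong area percentages per barometer,
#' per metric.
#'
#' @param summary a [cohort_summary()]
#' @param metric `"ncc"` or `"ssim"`
#' @return a ggplot object
#' @export
plot_band_areas <- function(summary, metric = c("ncc", "ssim")) {
  metric <- match.arg(metric)
  tab <- summary$table[summary$table$metric == metric, ]
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$component, y = .data$mean_pct, fill = .data$band
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean_pct - .data$sd_pct, 0),
        ymax = .data$mean_pct + .data$sd_pct
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "corneal area (%)",
      title = paste(toupper(metric), "band areas")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
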