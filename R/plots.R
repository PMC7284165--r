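#' Group-mean bar plot with standard-deviation error bars
#'
#' Per-region group means of one diffusion parameter, error bars showing
#' the standard deviation of the per-slice values (the usual presentation
#' for cohort comparisons of region-wise diffusion measures).
#'
#' @param roi_table ROI table from [run_cohort()] (or `tidy(x, "roi")`).
#' @param parameter Parameter to plot.
#' @return A ggplot object.
#' @export
plot_group_means <- function(roi_table, parameter = "FA") {
  df <- roi_table |>
    dplyr::filter(.data$parameter == !!parameter) |>
    dplyr::group_by(.data$roi, .data$group) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_minimal()
}

#' Rose plot of orientation distributions
#'
#' Axial orientation histograms per region and group on a polar axis
#' (angles shown over `[0, 180)` degrees from the left-right axis).
#'
#' @param orientations Orientation tibble from a cohort
#'   (`x$orientations`): columns `group`, `roi`, `theta`.
#' @param binwidth Histogram bin width in degrees.
#' @return A ggplot object.
#' @export
plot_orientation_rose <- function(orientations, binwidth = 10) {
  ggplot2::ggplot(orientations, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 150, 30)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$roi),
                        cols = ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "orientation (deg from left-right axis)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Raster view of a scalar map
#'
#' @param object A `scalar_maps` object.
#' @param map Which map: `"fa"`, `"md"` or `"theta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_maps <- function(object, map = c("fa", "md", "theta"), ...) {
  map <- match.arg(map)
  m <- object[[map]]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::labs(fill = toupper(map), x = "left-right (x)", y = "dorso-ventral (y)") +
    ggplot2::theme_minimal()
}

#' Overview plot of a cohort analysis
#'
#' @param object A `hippo_cohort`.
#' @param type `"group_means"` or `"orientations"`.
#' @param parameter Parameter for the group-mean panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hippo_cohort <- function(object, type = c("group_means", "orientations"),
                                  parameter = "FA", ...) {
  type <- match.arg(type)
  if (type == "group_means") {
    plot_group_means(object$roi_table, parameter)
  } else {
    plot_orientation_rose(object$orientations)
  }
}
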