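#' Plot an occupancy map
#'
#' Heatmap of percent residency on the top (x-y) or side (x-z) projection.
#'
#' @param object A `tv_occupancy` tibble from [occupancy_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tv_occupancy <- function(object, ...) {
  view <- attr(object, "view")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h, y = .data$v,
                                       fill = .data$pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "% residency") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (downwind, cm)",
                  y = if (view == "top") "y (cross-wind, cm)" else "z (cm)",
                  title = sprintf("Occupancy (%s view)", view)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted intensity-preference curve
#'
#' @param object A `tv_ll4fit`.
#' @param data Optional tibble of the underlying (x, y) points.
#' @param ... Unused.
#' @return A ggplot of the fitted sigmoid on a log-intensity axis.
#' @exportS3Method ggplot2::autoplot
autoplot.tv_ll4fit <- function(object, data = NULL, ...) {
  cur <- ll4_curve(object)
  p <- ggplot2::ggplot(cur, ggplot2::aes(x = .data$x, y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = c(object$c, object$d),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$e, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative intensity (vs tulle target)",
                  y = "preference index", title = object$group) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 alpha = 0.5)
  }
  p
}

#' Spectral preference curve with group means and run predictions
#'
#' @param means Group means from [estimate_group_means()] with a
#'   `test_channel` grouping (numeric wavelengths).
#' @param predictions Optional per-run predictions from
#'   [predict_run_effects()]; clusters are expected as
#'   `"<run> <channel> <intensity>"` labels, as produced by
#'   [prepare_preference_data()].
#' @return A ggplot of preference index against wavelength.
#' @export
plot_spectral_preference <- function(means, predictions = NULL) {
  means <- mutate(means,
                  wavelength = suppressWarnings(as.numeric(.data$test_channel)))
  p <- ggplot2::ggplot(means, ggplot2::aes(x = .data$wavelength,
                                           y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "wavelength (nm)", y = "preference index") +
    ggplot2::theme_minimal()
  if (!is.null(predictions)) {
    pts <- predictions %>%
      mutate(wavelength = suppressWarnings(
        as.numeric(vapply(strsplit(.data$cluster, " "), `[`, "", 2))))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$wavelength, y = .data$fitted_pi),
      alpha = 0.4, size = 0.8)
  }
  p
}
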