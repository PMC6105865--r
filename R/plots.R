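# ggplot2 views of the synthetic world, the sampling campaign and the
# fitted models.

#' Map the synthetic world
#'
#' DA polygons shaded by a covariate (or population), with optional user
#' points overlaid.
#'
#' @param das Tessellation tibble.
#' @param fill Column to shade by.
#' @param users Optional user tibble to overlay.
#' @return A ggplot object.
#' @export
plot_world <- function(das, fill = "pop_density", users = NULL) {
  poly <- purrr::map_dfr(seq_len(nrow(das)), function(i) {
    xy <- das$polygon[[i]]
    tibble::tibble(da_id = das$da_id[i], x = xy[, 1], y = xy[, 2],
                   .fill = das[[fill]][i])
  })
  p <- ggplot2::ggplot(poly, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$da_id,
                                       fill = .data$.fill),
                          colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_fill_viridis_c(name = fill, trans = "log10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "miles", y = "miles")
  if (!is.null(users)) {
    p <- p + ggplot2::geom_point(data = users, size = 0.2, alpha = 0.4,
                                 colour = "white")
  }
  p
}

#' Map buffer densities and outlier flags
#'
#' @param buffers Buffer observations.
#' @param outliers Optional outlier report; flagged buffers are ringed.
#' @param radius Buffer radius (miles).
#' @return A ggplot object.
#' @export
plot_buffers <- function(buffers, outliers = NULL, radius = 1) {
  p <- ggplot2::ggplot(buffers, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$density,
                                     colour = .data$density)) +
    ggplot2::scale_colour_viridis_c(name = "users / sq mi") +
    ggplot2::scale_size_area(max_size = 6, guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "miles", y = "miles")
  if (!is.null(outliers)) {
    flagged <- dplyr::inner_join(buffers,
                                 outliers[outliers$outlier, "point_id"],
                                 by = "point_id")
    if (nrow(flagged)) {
      p <- p + ggplot2::geom_point(data = flagged, shape = 21, size = 8,
                                   colour = "red", stroke = 1)
    }
  }
  p
}

#' Forest plot of incidence rate ratios
#'
#' @param object A `density_fit`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled IRR axis, unity line).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.density_fit <- function(object, ...) {
  tab <- irr_table(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$irr,
                                    stats::reorder(.data$term, .data$irr))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "incidence rate ratio (95% CI)", y = NULL)
}
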