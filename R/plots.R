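#' Plot a shape space projection
#'
#' PC1-PC2 scatter of every particle, coloured by ensemble, with optional
#' confidence ellipses and centers of gravity (larger black-bordered dots).
#'
#' @param projection a projection tibble from [project_ensemble()].
#' @param ellipses draw per-ensemble confidence ellipses?
#' @param level ellipse coverage probability.
#' @return A ggplot object.
#' @export
plot_shape_space <- function(projection, ellipses = TRUE, level = 0.95) {
  p <- ggplot2::ggplot(projection,
                       ggplot2::aes(.data$pc1, .data$pc2, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = ensemble_centroids(projection),
                        ggplot2::aes(fill = .data$label),
                        shape = 21, colour = "black", size = 3,
                        show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "ensemble") +
    ggplot2::theme_minimal()
  if (ellipses) {
    ell <- confidence_ellipse(projection, level = level)
    t <- seq(0, 2 * pi, length.out = 181)
    path <- ell |>
      dplyr::rowwise() |>
      dplyr::reframe(
        label = .data$label,
        pc1 = .data$center_pc1 +
          cos(.data$angle_rad) * .data$semi_major * cos(t) -
          sin(.data$angle_rad) * .data$semi_minor * sin(t),
        pc2 = .data$center_pc2 +
          sin(.data$angle_rad) * .data$semi_major * cos(t) +
          cos(.data$angle_rad) * .data$semi_minor * sin(t)
      )
    p <- p + ggplot2::geom_path(data = path, linewidth = 0.4)
  }
  p
}

#' @export
autoplot.shape_space <- function(object, n_components = 20, ...) {
  d <- tidy.shape_space(object)
  d <- d[seq_len(min(n_components, nrow(d))), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$component,
                                  .data$explained_variance_ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component", y = "explained variance ratio") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_result <- function(object, ...) {
  d <- tidy.overlap_result(object)
  shade <- tibble::tibble(x = object$grid,
                          density = pmin(object$pdf_a, object$pdf_b))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_area(data = shade, fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$label)) +
    ggplot2::labs(
      x = "projection onto inter-centroid axis",
      y = "density",
      subtitle = sprintf("OVL = %.3f", object$ovl),
      colour = "ensemble"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.distance_pdf <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(.data$distance, .data$density,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("distance to center of gravity (first %d PCs)",
                              object$m),
                  y = "density", colour = "ensemble") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.shape_trajectory <- function(object, ...) {
  r <- object$record
  ggplot2::ggplot(r, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$readout,
                                     shape = .data$action), size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "readout") +
    ggplot2::theme_minimal()
}

#' Plot contours as closed outlines
#'
#' @inheritParams contour_tbl
#' @param max_particles cap on the number of outlines drawn.
#' @return A ggplot object, faceted by particle.
#' @export
plot_contours <- function(contours, max_particles = 16) {
  ids <- utils::head(unique(contours$particle_id), max_particles)
  d <- contours[contours$particle_id %in% ids, ]
  closed <- d |>
    dplyr::group_by(.data$particle_id) |>
    dplyr::group_modify(~ dplyr::bind_rows(.x, .x[1, ])) |>
    dplyr::ungroup()
  ggplot2::ggplot(closed, ggplot2::aes(.data$x_nm, .data$y_nm)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~particle_id) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
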