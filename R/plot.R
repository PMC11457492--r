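## ggplot2 visualisations for the main result types.

image_df <- function(image) {
  m <- image$pixels
  tibble(x_nm = rep(index_to_nm(seq_len(ncol(m)), image$pixel_size_nm),
                    each = nrow(m)),
         y_nm = rep(index_to_nm(seq_len(nrow(m)), image$pixel_size_nm),
                    times = ncol(m)),
         intensity = as.vector(m))
}

#' Plot a calibrated image
#'
#' @param object A [tm_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tm_image <- function(object, ...) {
  ggplot2::ggplot(image_df(object),
                  ggplot2::aes(.data$x_nm, .data$y_nm,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "I")
}

#' Plot a point set with its neighbour graph
#'
#' Points coloured by neighbour degree over the optional edges of the
#' radius-bounded graph, the standard rendering of nearest-neighbour maps.
#'
#' @param points Tibble with `id`, `x_nm`, `y_nm`.
#' @param graph Optional edge tibble from [build_neighbor_graph()].
#' @return A ggplot.
#' @export
plot_neighbor_graph <- function(points, graph = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(.data$x_nm, .data$y_nm))
  if (!is.null(graph) && nrow(graph) > 0) {
    seg <- graph |>
      dplyr::left_join(dplyr::rename(points, x0 = "x_nm", y0 = "y_nm"),
                       by = c(i = "id")) |>
      dplyr::left_join(dplyr::rename(points, x1 = "x_nm", y1 = "y_nm"),
                       by = c(j = "id"))
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x0, y = .data$y0,
                               xend = .data$x1, yend = .data$y1),
      colour = "grey60")
    deg <- tibble(id = points$id,
                  degree = factor(graph_degrees(points, graph)))
    p <- p + ggplot2::geom_point(
      data = dplyr::left_join(points, deg, by = "id"),
      ggplot2::aes(colour = .data$degree), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Plot a power spectrum with detected reflections
#'
#' @param object A `tm_spectrum`.
#' @param reflections Optional `tm_reflections` overlay.
#' @param ... Unused.
#' @return A ggplot (log10 power).
#' @exportS3Method ggplot2::autoplot
autoplot.tm_spectrum <- function(object, reflections = NULL, ...) {
  nr <- nrow(object$power); nc <- ncol(object$power)
  df <- tibble(fx = rep(freq_axis_steps(nc) * object$freq_col_step,
                        each = nr),
               fy = rep(freq_axis_steps(nr) * object$freq_row_step,
                        times = nc),
               power = as.vector(object$power))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$fx, .data$fy,
                                        fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 P") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fx (1/nm)", y = "fy (1/nm)")
  if (!is.null(reflections) && nrow(reflections) > 0) {
    p <- p + ggplot2::geom_point(data = reflections,
                                 ggplot2::aes(.data$fx, .data$fy),
                                 inherit.aes = FALSE, shape = 1,
                                 colour = "red", size = 3)
  }
  p
}

#' Plot a profile fit over its data
#'
#' @param object A `tm_fit`.
#' @param ... Unused.
#' @return A ggplot of the raw profile (grey) and fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.tm_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$arclength_um), max(d$arclength_um), length.out = 200)
  curve <- tibble(arclength_um = xs, intensity = predict_tm_fit(object, xs))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$arclength_um,
                                       .data$intensity)) +
    ggplot2::geom_point(colour = "grey50", size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "magenta", linewidth = 1) +
    ggplot2::labs(x = "arclength (um)", y = "intensity",
                  title = sprintf("%s fit", object$model))
  if (!is.na(object$peak_position_um)) {
    p <- p + ggplot2::geom_vline(xintercept = object$peak_position_um,
                                 colour = "gold3", linetype = 2)
  }
  p
}

#' Plot area versus depth with fitted slopes
#'
#' @param object A `tm_depth_area`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tm_depth_area <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table, -"depth_um",
                              names_to = "what", values_to = "area_um2")
  ggplot2::ggplot(long, ggplot2::aes(.data$depth_um, .data$area_um2,
                                     colour = .data$what)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "depth below apical surface (um)",
                  y = expression(area ~ (mu * m^2)), colour = NULL)
}
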