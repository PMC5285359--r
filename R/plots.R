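#' @importFrom ggplot2 autoplot ggplot aes geom_polygon geom_point geom_line
#'   geom_path labs scale_fill_manual theme_minimal coord_equal
NULL

#' Plot a Voronoi tiling with its maximal nucleus clusters
#'
#' Draws the clipped region polygons, shades regions belonging to any
#' maximal nucleus cluster, and marks the generating points. The y axis is
#' reversed so the plot matches raster orientation (origin top-left).
#'
#' @param object A `voronoi_tiling`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voronoi_tiling
#' @export
autoplot.voronoi_tiling <- function(object, ...) {
  info <- tidy.voronoi_tiling(object)
  polys <- dplyr::bind_rows(lapply(seq_along(object$regions), function(i) {
    v <- object$regions[[i]]
    tibble(id = i, px = v[, 1], py = v[, 2], is_mnc = info$is_mnc[i])
  }))
  ggplot(polys, aes(x = .data$px, y = .data$py, group = .data$id,
                    fill = .data$is_mnc)) +
    geom_polygon(colour = "grey30", linewidth = 0.2) +
    geom_point(data = dplyr::mutate(info, px = .data$x, py = .data$y),
               aes(group = NULL, fill = NULL), size = 0.4) +
    scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "indianred"),
                      name = "in MNC") +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
}

#' Plot an entropy profile over the beta sweep
#'
#' One curve per region set (MNC vs non-MNC), entropy in bits against the
#' Renyi order beta.
#'
#' @param object An `entropy_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entropy_profile
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot(tidy.entropy_profile(object),
         aes(x = .data$beta, y = .data$entropy, colour = .data$set)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = expression(beta), y = "H (bits)", colour = NULL,
         title = sprintf("Rényi entropy profile (%s model)", object$model)) +
    theme_minimal()
}

#' Plot a principal-MNC centroid trajectory
#'
#' @param trajectory A [centroid_trajectory()] table.
#' @return A ggplot object with frames connected in time order.
#' @export
plot_trajectory <- function(trajectory) {
  ggplot(trajectory, aes(x = .data$centroid_x, y = .data$centroid_y)) +
    geom_path(colour = "grey50") +
    geom_point(aes(colour = .data$frame_index)) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "centroid x (px)", y = "centroid y (px)", colour = "frame") +
    theme_minimal()
}
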