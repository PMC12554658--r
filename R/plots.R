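# ggplot2 graphics for the main result types.

#' @describeIn classify_plant Rate-profile plot: height on the vertical
#'   axis, `|K'|` on the horizontal axis, with the classification
#'   intervals shaded.
#' @param object A `plant_type` object.
#' @method autoplot plant_type
#' @export
autoplot.plant_type <- function(object, ...) {
  iv <- object$intervals
  bands <- tibble::tibble(
    type = c("cylinder", "tower"),
    xmin = c(iv$cylinder[1], iv$tower[1]),
    xmax = c(iv$cylinder[2], iv$tower[2])
  )
  ggplot2::ggplot(object$samples) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.15) +
    ggplot2::geom_point(ggplot2::aes(x = .data$rate, y = .data$height),
                        alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(cylinder = "#2166ac",
                                          tower = "#b2182b")) +
    ggplot2::labs(x = "corner change rate |K'| (1/length)",
                  y = "height (normalized units)",
                  fill = "interval",
                  title = paste0("plant type: ", object$label)) +
    ggplot2::theme_minimal()
}

#' @describeIn quickhull Hull plot: input silhouette (if supplied via
#'   `points`) with the convex polygon and its left/right chains.
#' @param object A `hull2d` object.
#' @param points Optional background 2D point set.
#' @method autoplot hull2d
#' @export
autoplot.hull2d <- function(object, points = NULL, ...) {
  poly <- dplyr::bind_rows(object$vertices, object$vertices[1, ])
  chains <- split_chains(object)
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    m <- as_xy_matrix(points)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = m[, 1], y = m[, 2]),
      ggplot2::aes(x = .data$x, y = .data$y),
      color = "grey70", size = 0.3)
  }
  p +
    ggplot2::geom_path(data = poly,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       color = "grey40") +
    ggplot2::geom_point(data = chains,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$chain), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral", y = "height", color = "chain") +
    ggplot2::theme_minimal()
}

#' Plot a projected silhouette view
#'
#' @param view A single view (tibble with `u`, `v`), e.g. one angle of
#'   [project_views()].
#' @return A ggplot object.
#' @export
plot_view <- function(view) {
  ggplot2::ggplot(view, ggplot2::aes(x = .data$v, y = .data$u)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral", y = "height") +
    ggplot2::theme_minimal()
}
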