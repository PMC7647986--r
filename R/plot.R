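#' Plot ratio curves for a decomposition
#'
#' H3 and H2 preserved-node ratios against the decomposition level; a
#' crossing of the curves at high levels indicates that the network core
#' is enriched in 3-hinge patches.
#'
#' @param object A `ratio_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ratio_curves
#' @export
autoplot.ratio_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = c("ratio_h3", "ratio_h2"),
                              names_to = "class", values_to = "ratio")
  long$class <- ifelse(long$class == "ratio_h3", "3-hinge", "2-hinge")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$ratio,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "decomposition level s",
                  y = "ratio of preserved nodes",
                  colour = NULL,
                  title = sprintf("%s decomposition", object$method[1])) +
    ggplot2::theme_minimal()
}

#' Plot an H3 vs H2 group comparison
#'
#' Bar chart of class means with sd error bars, one facet-free panel per
#' metric on the x axis.
#'
#' @param object A `group_comparison` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  long <- tibble(
    metric = rep(object$metric, 2),
    class = rep(c("3-hinge", "2-hinge"), each = nrow(object)),
    mean = c(object$mean_h3, object$mean_h2),
    sd = c(object$sd_h3, object$sd_h2)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$mean,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "z-scored metric", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a surface altitude field with detected hinges
#'
#' Vertex scatter coloured by altitude with hinge locations overlaid;
#' intended for the synthetic sheets, which are single-valued over the
#' xy plane.
#'
#' @param mesh A [surface_mesh] with an altitude field.
#' @param crest Optional `crest_graph` whose hinges to overlay.
#' @return A ggplot object.
#' @export
plot_altitude <- function(mesh, crest = NULL) {
  if (is.null(mesh$altitude)) stop_hinge("mesh has no altitude field")
  df <- tibble(x = mesh$vertices[, 1], y = mesh$vertices[, 2],
               altitude = mesh$altitude)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$altitude)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "white",
                                    high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "altitude (mm)")
  if (!is.null(crest) && nrow(crest$hinges) > 0) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(crest$hinges), colour = "black", shape = 4,
      size = 3, stroke = 1.2,
      mapping = ggplot2::aes(x = .data$x, y = .data$y)
    )
  }
  p
}

#' @method tidy crest_graph
#' @export
tidy.crest_graph <- function(x, ...) {
  as_tibble(x$hinges)
}

#' @method glance crest_graph
#' @export
glance.crest_graph <- function(x, ...) {
  tibble(
    n_crest_vertices = length(x$nodes),
    n_edges = nrow(x$edges),
    n_hinges = nrow(x$hinges),
    n_3hinges = sum(x$hinges$arm_count == 3L),
    length_threshold = x$length_threshold
  )
}
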