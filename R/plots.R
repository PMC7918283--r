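# ggplot2 views of networks, polygon sets, maxent fits and the landscape.

#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_polygon
#'   geom_col geom_line coord_equal labs theme_minimal scale_fill_viridis_c
NULL

#' @export
ggplot2::autoplot

# segments of all edges with minimum-image unwrapping (drawn from u)
.edge_segments <- function(network) {
  e <- network$edges; nd <- network$nodes; L <- network$cell
  tibble::tibble(
    x = nd$x[e$u], y = nd$y[e$u],
    xend = nd$x[e$u] + (nd$x[e$v] + e$sx * L[1] - nd$x[e$u]),
    yend = nd$y[e$u] + (nd$y[e$v] + e$sy * L[2] - nd$y[e$u]))
}

#' Plot a network
#'
#' Edges as segments (periodic edges drawn unwrapped from one endpoint) and
#' nodes coloured by coordination number.
#'
#' @param object a `cw_network`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.cw_network <- function(object, ...) {
  segs <- .edge_segments(object)
  ggplot(object$nodes, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = segs,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey40", inherit.aes = FALSE) +
    geom_point(aes(colour = factor(.data$k)), size = 1.6) +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", colour = "k") +
    theme_minimal()
}

#' Plot a polygon set
#'
#' Faces filled by their edge count n, the standard colouring for ring
#' statistics figures.
#'
#' @param object a `cw_polygons`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.cw_polygons <- function(object, ...) {
  df <- purrr::imap_dfr(object$polygons, function(p, i)
    tibble::tibble(id = i, n = p$n, x = p$x, y = p$y))
  if (!nrow(df)) stop("no polygons to plot", call. = FALSE)
  ggplot(df, aes(x = .data$x, y = .data$y, group = .data$id,
                 fill = .data$n)) +
    geom_polygon(colour = "grey20", linewidth = 0.2) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", fill = "n") +
    theme_minimal()
}

#' Plot a maximum-entropy fit
#'
#' Observed polygon edge-count fractions as columns with the fitted
#' maximum-entropy distribution as a line.
#'
#' @param object a `cw_maxent_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.cw_maxent_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$n)) +
    geom_col(aes(y = .data$observed), fill = "steelblue", alpha = 0.7) +
    geom_line(aes(y = .data$fitted), colour = "red3", linetype = 2) +
    geom_point(aes(y = .data$fitted), colour = "red3") +
    labs(x = "polygon edge count n", y = "fraction of polygons p(n)") +
    theme_minimal()
}

#' Network landscape scatter
#'
#' Plots networks in the (mu2(k), r) plane - the "network landscape" in
#' which simulated, experimental and entropic reference networks are
#' compared. Points with undefined assortativity are dropped with a message.
#'
#' @param data tibble with columns mu2_k and assortativity (e.g. rows of
#'   [landscape_point()] or a scan aggregate), optionally a `label` column
#'   mapped to colour
#' @return a ggplot
#' @export
plot_landscape <- function(data) {
  bad <- !is.finite(data$assortativity)
  if (any(bad)) {
    message(sum(bad), " network(s) with undefined assortativity dropped")
    data <- data[!bad, ]
  }
  gg <- ggplot(data, aes(x = .data$mu2_k, y = .data$assortativity))
  if ("label" %in% names(data))
    gg <- gg + geom_point(aes(colour = .data$label), size = 2)
  else gg <- gg + geom_point(size = 2)
  gg + labs(x = expression(mu[2](k)), y = "assortativity r") +
    theme_minimal()
}
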