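# Per-network statistics: shape regularity, polygon distributions,
# assortativity, coordination moments, edge lengths and areas.

#' Shape regularity coefficient of a polygon
#'
#' `SRC = SO x Vxy x CO`, the product of
#' * solidity `SO`: polygon area / convex hull area,
#' * balanced repartition `Vxy`: min(sigma_x, sigma_y) / max(sigma_x,
#'   sigma_y) of the vertex coordinates, and
#' * convexity `CO`: convex hull perimeter / polygon perimeter.
#'
#' Regular shapes (square, regular n-gon) score exactly 1; elongated or
#' concave shapes score below 1. Each factor lies in (0, 1].
#'
#' By default the repartition factor is computed in the polygon's
#' principal-axes frame (the eigenvectors of the vertex covariance), which
#' makes the score invariant under rigid rotation - a rotated square still
#' scores 1, which is what "balanced repartition" is meant to capture. Set
#' `frame = "raw"` for the pose-dependent variant using raw x/y coordinates.
#'
#' @param polygon a polygon from a `cw_polygons` object, or a matrix/data
#'   frame of vertex coordinates (one vertex per row, unwrapped, no repeated
#'   closing vertex)
#' @param frame "principal" (default) or "raw" for the Vxy factor
#' @return SRC in (0, 1]
#' @export
#' @examples
#' src(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square: exactly 1
#' src(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)))  # 2:1 rectangle: 0.5
src <- function(polygon, frame = c("principal", "raw")) {
  frame <- match.arg(frame)
  if (is.list(polygon) && !is.null(polygon$x))
    polygon <- cbind(polygon$x, polygon$y)
  xy <- as.matrix(polygon)
  if (nrow(xy) < 3) stop("a polygon needs at least 3 vertices", call. = FALSE)
  area <- abs(.shoelace(xy[, 1], xy[, 2]))
  if (area <= 0) stop("degenerate (zero-area) polygon", call. = FALSE)
  hull <- chull(xy)
  hxy <- xy[hull, , drop = FALSE]
  hull_area <- abs(.shoelace(hxy[, 1], hxy[, 2]))
  per <- function(m) sum(sqrt(rowSums((m - m[c(2:nrow(m), 1), ])^2)))
  SO <- area / hull_area
  CO <- per(hxy) / per(xy)
  cv <- stats::cov(xy)
  if (frame == "principal") {
    ev <- eigen(cv, symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    Vxy <- sqrt(min(ev) / max(ev))
  } else {
    Vxy <- sqrt(min(diag(cv)) / max(diag(cv)))
  }
  SO * Vxy * CO
}

#' Polygon edge-count distribution
#'
#' Fractions `p_n` of polygons with `n` edges, normalised so that
#' `sum(p_n) = 1`, and the mean edge count `<n> = sum(n p_n)`.
#'
#' @param polygons a `cw_polygons` object or an integer vector of edge counts
#' @return tibble with columns n, count, p; the mean is attached as
#'   attribute `mean_n`
#' @export
pn_distribution <- function(polygons) {
  ns <- if (inherits(polygons, "cw_polygons"))
    vapply(polygons$polygons, function(p) p$n, numeric(1)) else
    as.numeric(polygons)
  if (!length(ns)) stop("empty polygon set", call. = FALSE)
  tb <- table(ns)
  out <- tibble::tibble(n = as.integer(names(tb)),
                        count = as.integer(tb),
                        p = as.integer(tb) / sum(tb))
  attr(out, "mean_n") <- sum(out$n * out$p)
  out
}

#' Polygon-size assortativity
#'
#' Pearson correlation of polygon edge counts across adjacent polygon pairs
#' (adjacency = a shared network edge), computed over the symmetrised pair
#' list: each shared edge contributes both ordered pairs (n_i, n_j) and
#' (n_j, n_i). Negative values mean unlike sizes neighbour each other; a
#' Poisson-Voronoi tessellation sits near -0.15.
#'
#' When every polygon has the same size the correlation is undefined and
#' `NA` is returned with attribute `defined = FALSE` (never silently 0).
#'
#' @param polygons a `cw_polygons` object, or a two-column matrix of
#'   already-symmetrised adjacent size pairs
#' @return the assortativity r in `[-1, 1]`, or flagged `NA`
#' @export
assortativity <- function(polygons) {
  pairs <- if (inherits(polygons, "cw_polygons"))
    .polygon_adjacency(polygons) else as.matrix(polygons)
  if (nrow(pairs) < 2)
    return(structure(NA_real_, defined = FALSE,
                     reason = "fewer than 2 adjacent polygon pairs"))
  if (var(pairs[, 1]) == 0 || var(pairs[, 2]) == 0)
    return(structure(NA_real_, defined = FALSE,
                     reason = "zero size variance"))
  r <- cor(pairs[, 1], pairs[, 2])
  structure(r, defined = TRUE)
}

#' Coordination-number statistics
#'
#' Mean node degree `<k>` and the second central moment `mu2(k)` (the
#' variance of the degree distribution, the "width" axis of the network
#' landscape).
#'
#' @param network a `cw_network`
#' @return tibble with mean_k and mu2_k
#' @export
coordination_stats <- function(network) {
  k <- network$nodes$k
  if (!length(k)) stop("empty network", call. = FALSE)
  tibble::tibble(mean_k = mean(k), mu2_k = mean((k - mean(k))^2))
}

#' Edge-length and polygon-area statistics
#'
#' Mean and standard deviation of the minimum-image node-to-node edge
#' lengths, and the mean polygon area (shoelace formula on unwrapped
#' vertices).
#'
#' @param network a `cw_network`
#' @param polygons optional matching `cw_polygons`
#' @return tibble with mean_l, sd_l (nm) and mean_area (nm^2, NA if no
#'   polygons supplied)
#' @export
edge_and_area_stats <- function(network, polygons = NULL) {
  e <- network$edges
  if (!nrow(e)) stop("network has no edges", call. = FALSE)
  nd <- network$nodes
  L <- network$cell
  dx <- nd$x[e$v] + e$sx * L[1] - nd$x[e$u]
  dy <- nd$y[e$v] + e$sy * L[2] - nd$y[e$u]
  len <- rep(sqrt(dx^2 + dy^2), e$mult)
  areas <- if (!is.null(polygons))
    vapply(polygons$polygons, function(p) p$area, numeric(1)) else numeric(0)
  tibble::tibble(mean_l = mean(len), sd_l = sd(len),
                 mean_area = if (length(areas)) mean(areas) else NA_real_)
}

#' Full per-network metrics record
#'
#' One row with every summary statistic: polygon count, `<n>`, `<k>`,
#' `mu2(k)`, assortativity, `<SRC>` with its sd, edge lengths, mean polygon
#' area and the dangling-edge percentage. Column names mirror the metrics
#' CSV contract.
#'
#' @param network a `cw_network`
#' @param polygons matching `cw_polygons` (computed if missing)
#' @param src_frame frame for the SRC repartition factor, see [src()]
#' @return a one-row tibble
#' @export
network_metrics <- function(network, polygons = NULL,
                            src_frame = "principal") {
  if (is.null(polygons)) polygons <- delaunay_polygons(network)
  ns <- vapply(polygons$polygons, function(p) p$n, numeric(1))
  srcs <- vapply(polygons$polygons, src, numeric(1), frame = src_frame)
  cs <- coordination_stats(network)
  ea <- edge_and_area_stats(network, polygons)
  r <- assortativity(polygons)
  de <- dangling_edges(network, polygons)
  tibble::tibble(
    Npolygon = length(ns),
    mean_n = if (length(ns)) mean(ns) else NA_real_,
    mean_k = cs$mean_k,
    mu2_k = cs$mu2_k,
    assortativity = as.numeric(r),
    mean_SRC = if (length(srcs)) mean(srcs) else NA_real_,
    sd_SRC = if (length(srcs) > 1) sd(srcs) else NA_real_,
    mean_l_nm = ea$mean_l,
    sd_l_nm = ea$sd_l,
    mean_area_nm2 = ea$mean_area,
    dangling_pct = de$percentage)
}

#' Coordinates of a network in the (mu2(k), r) landscape
#'
#' The "network landscape" locates a network by the width of its degree
#' distribution (x) and its polygon-size assortativity (y); simulated,
#' experimental and entropic reference networks can be compared in this
#' plane.
#'
#' @inheritParams network_metrics
#' @return one-row tibble with mu2_k, assortativity and a logical
#'   `r_defined` flag
#' @export
landscape_point <- function(network, polygons = NULL) {
  if (is.null(polygons)) polygons <- delaunay_polygons(network)
  cs <- coordination_stats(network)
  r <- assortativity(polygons)
  tibble::tibble(mu2_k = cs$mu2_k, assortativity = as.numeric(r),
                 r_defined = isTRUE(attr(r, "defined")))
}

#' Correlation between coordination number and head-pair energy
#'
#' Extracts the network from every stored snapshot of a trajectory, pairs the
#' mean coordination number `<k>(t)` with the head-head pair energy
#' `Upair(t)` from the scalar log, and reports their Pearson correlation.
#' During self-assembly the two are strongly anti-correlated: every new
#' head-head contact lowers `Upair` and raises `<k>`, which is what makes
#' `<k>` a convenient proxy for the internal energy.
#'
#' @param trajectory a `cw_trajectory` from [run_protocol()] with snapshots
#' @param stages stages to include (default the cooling ramp)
#' @param rc head-clustering cutoff (nm)
#' @return list with `data` (tibble: time_us, mean_k, upair_J) and
#'   `correlation`; the correlation carries a `defined` attribute and is
#'   flagged `NA` for constant series
#' @export
upair_k_correlation <- function(trajectory, stages = "cool", rc = 75) {
  idx <- which(vapply(trajectory$snapshots,
                      function(s) s$stage %in% stages, logical(1)))
  if (length(idx) < 2)
    stop("trajectory has fewer than 2 snapshots in the requested stage(s)",
         call. = FALSE)
  lg <- trajectory$log[trajectory$log$stage %in% stages, ]
  rows <- purrr::map_dfr(idx, function(i) {
    st <- .snapshot_state(trajectory, i)
    net <- build_network(st, rc)
    j <- which.min(abs(lg$time_us - st$time))
    tibble::tibble(time_us = st$time, mean_k = mean(net$nodes$k),
                   upair_J = lg$Upair_J[j])
  })
  if (var(rows$mean_k) == 0 || var(rows$upair_J) == 0)
    return(list(data = rows,
                correlation = structure(NA_real_, defined = FALSE)))
  list(data = rows,
       correlation = structure(cor(rows$mean_k, rows$upair_J),
                               defined = TRUE))
}
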