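# Polygon assignment by Delaunay merging.
#
# Starting from the triangles of the periodic Delaunay triangulation of the
# network nodes (a superset of the network edges, by assumption), every edge
# that exists only in the triangulation is removed one at a time; removing an
# edge merges the two faces it separates. What remains when all
# triangulation-only edges are gone is the set of faces of the periodic
# planar network: polygons, plus (possibly) non-disk faces whose boundary
# walks traverse dangling structures.
#
# Faces are held as circular linked lists of directed periodic edges
# ("next" pointers); removing an edge splices the two incident cycles
# together in O(1). This also handles the self-merge case (both sides of the
# removed edge already belong to one face), where the splice splits the walk.

#' Assign the polygon faces of a network
#'
#' Implements the Delaunay-merge construction. Pendant material is dealt
#' with first: degree-1 nodes are pruned iteratively, their edges recorded
#' as dangling - a pendant tree never separates two faces, so pruning cannot
#' change the polygon set, and lone molecule ends floating inside faces
#' would otherwise break the triangulation precondition below. The remaining
#' node set is triangulated on the periodic cell; the triangulation must
#' contain every remaining network edge (networks violating this are
#' rejected, mirroring the restriction under which the method is defined).
#' All triangulation-only edges are then removed, merging faces pairwise,
#' until only network edges remain. The resulting face set covers the entire
#' cell area and is independent of the removal order.
#'
#' A face is reported as a polygon when its (spur-pruned) boundary is a
#' simple closed cycle that does not wind around the torus and has positive
#' orientation; the complement region of a sparse network and pure tree
#' components are faces but not polygons. An edge is dangling when it does
#' not separate two distinct faces.
#'
#' @param network a `cw_network` (see [build_network()])
#' @param order optional permutation of the triangulation-only edge classes
#'   fixing the removal order (the result is invariant to it; exposed so the
#'   invariance can be asserted)
#' @param delaunay optionally, a precomputed [periodic_delaunay()] of the
#'   node coordinates
#' @return a `cw_polygons`: list with `polygons` (each an ordered node-id
#'   cycle with unwrapped vertex coordinates, edge count n, area, perimeter),
#'   `faces` (all boundary walks), `edge_faces` (face index left of each
#'   directed network edge), `dangling` (tibble of dangling edge classes),
#'   `n_edges` (network edge classes) and `cell`
#' @export
delaunay_polygons <- function(network, order = NULL, delaunay = NULL) {
  nodes <- network$nodes
  xy <- cbind(nodes$x, nodes$y)
  L <- network$cell
  pruned <- .prune_pendants(network)
  network <- pruned$network
  if (nrow(nodes) < 3 || nrow(network$edges) < 3 ||
      length(pruned$keep_nodes) < 3) {
    # degenerate network: no faces can close, every edge is dangling
    ne <- network$edges
    keys <- .undirected_key(ne$u, ne$v, ne$sx, ne$sy)
    keys <- unique(c(keys, pruned$dangling))
    return(structure(list(polygons = list(), faces = list(),
                          poly_of_face = integer(0),
                          face_of = new.env(parent = emptyenv()),
                          dangling = keys,
                          n_edges = pruned$n_edges_total,
                          net_keys = keys, cell = L),
                     class = "cw_polygons"))
  }
  if (is.null(delaunay))
    delaunay <- .periodic_delaunay_subset(xy, L, pruned$keep_nodes)
  ed <- delaunay$edges

  # periodic classes of the network edges (minimum image)
  ne <- network$edges
  net_keys <- .undirected_key(ne$u, ne$v, ne$sx, ne$sy)
  if (anyDuplicated(net_keys))
    net_keys <- unique(net_keys)
  del_dir <- ed$key
  del_un <- unique(.undirected_key(ed$u, ed$v, ed$sx, ed$sy))
  missing <- setdiff(net_keys, del_un)
  if (length(missing))
    stop("the Delaunay triangulation is not a superset of the network ",
         "edges; offending edge(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  # next-pointer cycles from the CCW triangles
  nxt <- new.env(parent = emptyenv(), size = length(del_dir))
  prv <- new.env(parent = emptyenv(), size = length(del_dir))
  nt <- nrow(delaunay$tri)
  k1 <- ed$key[seq_len(nt)]
  k2 <- ed$key[nt + seq_len(nt)]
  k3 <- ed$key[2 * nt + seq_len(nt)]
  for (t in seq_len(nt)) {
    assign(k1[t], k2[t], envir = nxt); assign(k2[t], k3[t], envir = nxt)
    assign(k3[t], k1[t], envir = nxt)
    assign(k2[t], k1[t], envir = prv); assign(k3[t], k2[t], envir = prv)
    assign(k1[t], k3[t], envir = prv)
  }

  remove_classes <- setdiff(del_un, net_keys)
  if (!is.null(order)) {
    stopifnot(length(order) == length(remove_classes))
    remove_classes <- remove_classes[order]
  }
  twin_of <- function(key) {
    m <- .parse_keys(key)
    .edge_key(m[, "v"], m[, "u"], -m[, "sx"], -m[, "sy"])
  }
  for (d in remove_classes) {
    dp <- twin_of(d)
    a <- get(d, envir = prv); b <- get(d, envir = nxt)
    ap <- get(dp, envir = prv); bp <- get(dp, envir = nxt)
    if (b == dp && bp == d) {
      # two-edge cycle: both removed, the face boundary vanishes
    } else if (b == dp) {        # d immediately followed by its twin
      assign(a, bp, envir = nxt); assign(bp, a, envir = prv)
    } else if (bp == d) {        # twin immediately followed by d
      assign(ap, b, envir = nxt); assign(b, ap, envir = prv)
    } else {
      assign(a, bp, envir = nxt); assign(bp, a, envir = prv)
      assign(ap, b, envir = nxt); assign(b, ap, envir = prv)
    }
    rm(list = c(d, dp), envir = nxt); rm(list = c(d, dp), envir = prv)
  }

  # extract boundary walks (orbits of the remaining next pointers)
  remaining <- ls(envir = nxt, sorted = TRUE)
  seen <- new.env(parent = emptyenv(), size = length(remaining))
  faces <- list()
  for (k in remaining) {
    if (!is.null(seen[[k]])) next
    walk <- character(0)
    cur <- k
    repeat {
      walk <- c(walk, cur)
      assign(cur, TRUE, envir = seen)
      cur <- get(cur, envir = nxt)
      if (cur == k) break
    }
    faces[[length(faces) + 1]] <- walk
  }

  out <- .assemble_polygons(network, faces, net_keys)
  out$dangling <- unique(c(out$dangling, pruned$dangling))
  out$n_edges <- pruned$n_edges_total
  out$net_keys <- unique(c(out$net_keys, pruned$dangling))
  out
}

# iteratively remove degree-1 nodes; their edges are dangling by definition
# (a pendant tree never separates two distinct faces), and removing them
# cannot change any polygon. Returns the pruned network, the dangling edge
# classes, the surviving node ids and the total edge-class count.
.prune_pendants <- function(network) {
  e <- network$edges
  keys <- .undirected_key(e$u, e$v, e$sx, e$sy)
  n_total <- length(unique(keys))
  repeat {
    deg <- tabulate(c(e$u, e$v), nbins = nrow(network$nodes))
    leaf <- which(deg == 1)
    drop <- e$u %in% leaf | e$v %in% leaf
    if (!any(drop)) break
    e <- e[!drop, , drop = FALSE]
  }
  kept_keys <- .undirected_key(e$u, e$v, e$sx, e$sy)
  net2 <- network
  net2$edges <- e
  deg <- tabulate(c(e$u, e$v), nbins = nrow(network$nodes))
  list(network = net2,
       dangling = setdiff(unique(keys), unique(kept_keys)),
       keep_nodes = which(deg > 0),
       n_edges_total = n_total)
}

# periodic Delaunay of a subset of the nodes, with edge keys expressed in
# the original node ids
.periodic_delaunay_subset <- function(xy, L, keep) {
  if (length(keep) == nrow(xy)) return(periodic_delaunay(xy, L))
  del <- periodic_delaunay(xy[keep, , drop = FALSE], L)
  # remap ids back to the full-network numbering
  del$tri[, c("v1", "v2", "v3")] <- matrix(keep[del$tri[, c("v1", "v2", "v3")]],
                                           ncol = 3)
  ed <- del$edges
  ed$u <- keep[ed$u]; ed$v <- keep[ed$v]
  ed$key <- .edge_key(ed$u, ed$v, ed$sx, ed$sy)
  ed$twin <- .edge_key(ed$v, ed$u, -ed$sx, -ed$sy)
  del$edges <- ed
  del$xy <- xy
  del
}

# turn face boundary walks into polygons + dangling bookkeeping
.assemble_polygons <- function(network, faces, net_keys) {
  nodes <- network$nodes
  xy <- cbind(nodes$x, nodes$y)
  L <- network$cell

  face_of <- new.env(parent = emptyenv())
  for (f in seq_along(faces))
    for (k in faces[[f]]) assign(k, f, envir = face_of)

  polygons <- list()
  poly_of_face <- rep(NA_integer_, length(faces))
  dangling_keys <- character(0)
  for (f in seq_along(faces)) {
    walk <- faces[[f]]
    m <- .parse_keys(walk)
    un <- .undirected_key(m[, "u"], m[, "v"], m[, "sx"], m[, "sy"])
    dup <- unique(un[duplicated(un)])   # traversed in both directions
    dangling_keys <- c(dangling_keys, dup)
    if (length(dup)) {
      keep <- !(un %in% dup)
      walk <- walk[keep]
      m <- m[keep, , drop = FALSE]
      if (!nrow(m)) next
      # after dropping spur edges the remainder must still be one closed
      # chain (tail of each edge = head of the next) to qualify as a polygon
      heads <- m[, "u"]; tails <- m[, "v"]
      if (!all(tails == heads[c(seq_len(nrow(m))[-1], 1)])) next
    }
    if (nrow(m) < 3) next
    if (sum(m[, "sx"]) != 0 || sum(m[, "sy"]) != 0) next # winds the torus
    ids <- m[, "u"]
    if (anyDuplicated(ids)) next                         # not simple
    # unwrap vertex coordinates along the walk
    cum_sx <- cumsum(c(0, m[-nrow(m), "sx"]))
    cum_sy <- cumsum(c(0, m[-nrow(m), "sy"]))
    px <- xy[ids, 1] + cum_sx * L[1]
    py <- xy[ids, 2] + cum_sy * L[2]
    # the first vertex fixes the reference image; shift consistency means
    # consecutive steps are the true edge vectors
    area <- .shoelace(px, py)
    if (area <= 0) next                                  # outer/complement walk
    per <- sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
    polygons[[length(polygons) + 1]] <-
      list(nodes = ids, x = px, y = py, n = length(ids),
           area = area, perimeter = per, face = f)
    poly_of_face[f] <- length(polygons)
  }
  dangling_keys <- unique(dangling_keys)

  structure(list(polygons = polygons, faces = faces,
                 poly_of_face = poly_of_face,
                 face_of = face_of,
                 dangling = dangling_keys,
                 n_edges = length(net_keys),
                 net_keys = net_keys,
                 cell = L),
            class = "cw_polygons")
}

.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' @export
print.cw_polygons <- function(x, ...) {
  ns <- vapply(x$polygons, function(p) p$n, numeric(1))
  cat(sprintf("<cw_polygons> %d polygons (n: %s), %d faces, %d/%d dangling edges\n",
              length(x$polygons),
              if (length(ns)) paste0(min(ns), "-", max(ns)) else "-",
              length(x$faces), length(x$dangling), x$n_edges))
  invisible(x)
}

#' Dangling edges of a network
#'
#' An edge is dangling when it does not separate two distinct faces of the
#' periodic planar network - bridges, trees and pendant chains whose boundary
#' walk traverses the edge twice. These are the edges that are not part of
#' any polygon.
#'
#' @param network a `cw_network`
#' @param polygons the matching [delaunay_polygons()] result (computed if
#'   missing)
#' @return list with `keys` (edge-class identifiers), `n_dangling`, `n_edges`
#'   and `percentage`
#' @export
dangling_edges <- function(network, polygons = NULL) {
  if (is.null(polygons)) polygons <- delaunay_polygons(network)
  nd <- length(polygons$dangling)
  ne <- polygons$n_edges
  list(keys = polygons$dangling, n_dangling = nd, n_edges = ne,
       percentage = if (ne > 0) 100 * nd / ne else NA_real_)
}

# adjacency pairs of polygon sizes across shared (non-dangling) edges;
# returns a two-column matrix of (n_i, n_j), one row per directed pairing
.polygon_adjacency <- function(polygons) {
  keys <- setdiff(polygons$net_keys, polygons$dangling)
  if (!length(keys)) return(matrix(numeric(), 0, 2))
  m <- .parse_keys(keys)
  twin <- .edge_key(m[, "v"], m[, "u"], -m[, "sx"], -m[, "sy"])
  f1 <- vapply(keys, function(k) {
    v <- polygons$face_of[[k]]; if (is.null(v)) NA_integer_ else v
  }, integer(1))
  f2 <- vapply(twin, function(k) {
    v <- polygons$face_of[[k]]; if (is.null(v)) NA_integer_ else v
  }, integer(1))
  p1 <- polygons$poly_of_face[f1]
  p2 <- polygons$poly_of_face[f2]
  ok <- !is.na(p1) & !is.na(p2)
  if (!any(ok)) return(matrix(numeric(), 0, 2))
  n1 <- vapply(polygons$polygons[p1[ok]], function(p) p$n, numeric(1))
  n2 <- vapply(polygons$polygons[p2[ok]], function(p) p$n, numeric(1))
  cbind(c(n1, n2), c(n2, n1))
}
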