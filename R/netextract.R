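# From bead snapshot to node/edge network.
#
# Nodes are single-linkage clusters of head beads (plus tangle beads, which
# are permanent crosslinks and enter as their own nodes); edges are the
# molecule strands joining two terminal sites.

#' Cluster head beads into network nodes
#'
#' Single-linkage clustering: two heads belong to the same cluster if they
#' are connected by a chain of head-head contacts shorter than `rc`
#' (minimum-image distances). The default cutoff `rc` = 1.5 `sigma_hh` =
#' 75 nm sits safely above the head-pair equilibrium distance
#' 2^(1/6) `sigma_hh` ~ 56 nm and below the body-bead scale.
#'
#' @param state a `cw_state`
#' @param rc linkage cutoff (nm)
#' @return list with `membership` (cluster index per head bead, named by bead
#'   index), `centroids` (periodic circular-mean centroid per cluster) and
#'   `sizes`
#' @export
cluster_heads <- function(state, rc = 75) {
  stopifnot(rc > 0)
  heads <- which(state$type == BEAD_HEAD)
  nh <- length(heads)
  if (nh == 0)
    return(list(membership = integer(0), centroids = matrix(numeric(), 0, 2),
                sizes = integer(0), heads = integer(0)))
  hp <- state$pos[heads, , drop = FALSE]
  L <- state$cell
  parent <- seq_len(nh)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  # grid bucketing keeps the pair search near-linear
  ngx <- max(1L, floor(L[1] / rc)); ngy <- max(1L, floor(L[2] / rc))
  gx <- pmin(ngx - 1L, floor(hp[, 1] / (L[1] / ngx)))
  gy <- pmin(ngy - 1L, floor(hp[, 2] / (L[2] / ngy)))
  cellid <- gx + ngx * gy
  buckets <- split(seq_len(nh), cellid)
  bkey <- function(cx, cy) (cx %% ngx) + ngx * (cy %% ngy)
  for (b in names(buckets)) {
    ids <- buckets[[b]]
    c0 <- as.numeric(b)
    cx <- c0 %% ngx; cy <- c0 %/% ngx
    neigh <- setdiff(unique(c(bkey(cx + 1, cy), bkey(cx + 1, cy + 1),
                              bkey(cx, cy + 1), bkey(cx - 1, cy + 1))), c0)
    nb_ids <- unlist(buckets[as.character(neigh)], use.names = FALSE)
    for (ii in seq_along(ids)) {
      i <- ids[ii]
      # half-stencil: each cross-bucket adjacency is visited exactly once,
      # so neighbour candidates must not be filtered by index order
      js <- c(ids[-seq_len(ii)], nb_ids)
      if (!length(js)) next
      d1 <- hp[js, 1] - hp[i, 1]; d1 <- d1 - L[1] * round(d1 / L[1])
      d2 <- hp[js, 2] - hp[i, 2]; d2 <- d2 - L[2] * round(d2 / L[2])
      hit <- js[d1 * d1 + d2 * d2 < rc * rc]
      for (j in hit) {
        a <- find(i); bb <- find(j)
        if (a != bb) parent[bb] <- a
      }
    }
  }
  roots <- vapply(seq_len(nh), find, integer(1))
  membership <- match(roots, unique(roots))
  nc <- max(membership)
  centroids <- t(vapply(seq_len(nc), function(k) {
    .periodic_centroid(hp[membership == k, , drop = FALSE], L)
  }, numeric(2)))
  list(membership = setNames(membership, heads),
       centroids = centroids,
       sizes = tabulate(membership, nc),
       heads = heads)
}

# decompose each molecule into arcs between terminal beads (heads/tangles)
.molecule_arcs <- function(state) {
  terminals <- state$type %in% c(BEAD_HEAD, BEAD_TANGLE)
  bonds <- state$bonds
  n <- nrow(state$pos)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  arcs <- list()
  visited <- new.env(parent = emptyenv())
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  for (t0 in which(terminals)) {
    for (nb in adj[[t0]]) {
      if (!is.null(visited[[ekey(t0, nb)]])) next
      path <- c(t0, nb)
      assign(ekey(t0, nb), TRUE, envir = visited)
      prev <- t0; cur <- nb
      while (!terminals[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) != 1) break # malformed body chain; drop arc
        assign(ekey(cur, nxt), TRUE, envir = visited)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      if (terminals[cur])
        arcs[[length(arcs) + 1]] <-
          list(from = t0, to = cur, mol = state$mol[t0], path = path)
    }
  }
  arcs
}

#' Build the node/edge network of a snapshot
#'
#' One node per head cluster (at its periodic centroid) and one node per
#' tangle bead; one edge per molecule strand whose two terminal sites map to
#' distinct nodes. Strands whose two ends fall in the same cluster are
#' recorded as self-loops and excluded from the edge set. Parallel strands
#' between the same node pair are collapsed into one edge whose multiplicity
#' is recorded; the node degree `k` counts strands (multiplicity included),
#' matching the coordination number of the head cluster.
#'
#' @param state a `cw_state`
#' @param rc head-clustering cutoff (nm), see [cluster_heads()]
#' @return a `cw_network`: list with `nodes` (tibble: id, x, y, k, kind,
#'   size), `edges` (tibble: u, v, sx, sy, mult - with (sx, sy) the
#'   minimum-image cell shift), `self_loops`, `cell`
#' @export
build_network <- function(state, rc = 75) {
  cl <- cluster_heads(state, rc)
  nc <- nrow(cl$centroids)
  tangles <- which(state$type == BEAD_TANGLE)
  node_xy <- rbind(cl$centroids,
                   state$pos[tangles, , drop = FALSE])
  node_xy[, 1] <- .wrap_cell(node_xy[, 1], state$cell[1])
  node_xy[, 2] <- .wrap_cell(node_xy[, 2], state$cell[2])
  kind <- c(rep("cluster", nc), rep("tangle", length(tangles)))
  size <- c(cl$sizes, rep(1L, length(tangles)))
  node_of_bead <- integer(nrow(state$pos))
  node_of_bead[cl$heads] <- cl$membership
  if (length(tangles)) node_of_bead[tangles] <- nc + seq_along(tangles)

  arcs <- .molecule_arcs(state)
  L <- state$cell
  eu <- integer(0); ev <- integer(0); emol <- integer(0)
  loops <- integer(0); loop_mol <- integer(0)
  for (a in arcs) {
    u <- node_of_bead[a$from]; v <- node_of_bead[a$to]
    if (u == v) { loops <- c(loops, u); loop_mol <- c(loop_mol, a$mol) }
    else { eu <- c(eu, u); ev <- c(ev, v); emol <- c(emol, a$mol) }
  }
  swap <- eu > ev
  tmp <- eu[swap]; eu[swap] <- ev[swap]; ev[swap] <- tmp
  dx <- node_xy[ev, 1] - node_xy[eu, 1]
  dy <- node_xy[ev, 2] - node_xy[eu, 2]
  sx <- -round(dx / L[1]); sy <- -round(dy / L[2])
  ek <- paste(eu, ev, sep = "|")
  mult <- as.integer(table(ek)[ek])
  keep <- !duplicated(ek)
  edges <- tibble::tibble(u = eu[keep], v = ev[keep],
                          sx = as.integer(sx[keep]), sy = as.integer(sy[keep]),
                          mult = mult[keep])
  k <- tabulate(c(eu, ev), nbins = nrow(node_xy))
  nodes <- tibble::tibble(id = seq_len(nrow(node_xy)),
                          x = node_xy[, 1], y = node_xy[, 2],
                          k = k, kind = kind, size = size)
  structure(list(nodes = nodes, edges = edges,
                 self_loops = tibble::tibble(node = loops, mol = loop_mol),
                 cell = L),
            class = "cw_network")
}

#' Construct a network object directly from node and edge tables
#'
#' Entry point for externally supplied networks (e.g. digitized micrographs
#' exported as node/edge CSVs) and for the lattice builders. Edge cell shifts
#' are taken as minimum image unless provided.
#'
#' @param nodes data frame with columns x, y (nm) and optionally id
#' @param edges data frame with columns u, v (node ids) and optionally
#'   sx, sy
#' @param cell c(Lx, Ly)
#' @return a `cw_network`
#' @export
as_network <- function(nodes, edges, cell) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!all(c("x", "y") %in% names(nodes)))
    stop("`nodes` needs columns x and y", call. = FALSE)
  n <- nrow(nodes)
  if (!"id" %in% names(nodes)) nodes$id <- seq_len(n)
  nodes$id <- as.integer(nodes$id)
  if (!all(nodes$id == seq_len(n)))
    stop("node ids must be 1..n in order", call. = FALSE)
  edges$u <- as.integer(edges$u); edges$v <- as.integer(edges$v)
  bad <- !(edges$u %in% nodes$id) | !(edges$v %in% nodes$id)
  if (any(bad))
    stop("edge row(s) ", paste(which(bad), collapse = ", "),
         " reference unknown node ids", call. = FALSE)
  L <- as.numeric(cell)
  nodes$x <- unname(.wrap_cell(as.numeric(nodes$x), L[1]))
  nodes$y <- unname(.wrap_cell(as.numeric(nodes$y), L[2]))
  swap <- edges$u > edges$v
  if (any(swap)) {
    tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
    if ("sx" %in% names(edges)) { edges$sx[swap] <- -edges$sx[swap]
                                  edges$sy[swap] <- -edges$sy[swap] }
  }
  if (!"sx" %in% names(edges)) {
    dx <- nodes$x[edges$v] - nodes$x[edges$u]
    dy <- nodes$y[edges$v] - nodes$y[edges$u]
    edges$sx <- as.integer(-round(dx / L[1]))
    edges$sy <- as.integer(-round(dy / L[2]))
  }
  ek <- paste(edges$u, edges$v, edges$sx, edges$sy)
  if (anyDuplicated(ek))
    stop("duplicate edge(s) at row(s) ",
         paste(which(duplicated(ek)), collapse = ", "), call. = FALSE)
  if (!"mult" %in% names(edges)) edges$mult <- 1L
  k <- tabulate(c(edges$u, edges$v), nbins = n)
  nodes$k <- as.integer(k)
  if (!"kind" %in% names(nodes)) nodes$kind <- "cluster"
  if (!"size" %in% names(nodes)) nodes$size <- 1L
  structure(list(nodes = nodes[, c("id", "x", "y", "k", "kind", "size")],
                 edges = edges[, c("u", "v", "sx", "sy", "mult")],
                 self_loops = tibble::tibble(node = integer(0),
                                             mol = integer(0)),
                 cell = L),
            class = "cw_network")
}

#' @export
print.cw_network <- function(x, ...) {
  cat(sprintf("<cw_network> %d nodes, %d edges (%d self-loops), <k> = %.3f\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$self_loops),
              mean(x$nodes$k)))
  invisible(x)
}
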