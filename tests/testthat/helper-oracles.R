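# Independent face-traversal oracle and fixture generators shared by the
# test files. The oracle enumerates the faces of a periodic planar graph by
# half-edge traversal (angular sorting at each node) and never touches the
# Delaunay-merge code path it is used to check.

# all face boundary walks of a periodic planar network
oracle_faces <- function(network) {
  nd <- network$nodes; L <- network$cell; e <- network$edges
  du <- c(e$u, e$v); dv <- c(e$v, e$u)
  dsx <- c(e$sx, -e$sx); dsy <- c(e$sy, -e$sy)
  key <- paste(du, dv, dsx, dsy, sep = "|")
  twin <- paste(dv, du, -dsx, -dsy, sep = "|")
  vx <- nd$x[dv] + dsx * L[1] - nd$x[du]
  vy <- nd$y[dv] + dsy * L[2] - nd$y[du]
  ang <- atan2(vy, vx)
  nxt <- setNames(character(length(key)), key)
  for (v in unique(du)) {
    out <- which(du == v)
    o <- out[order(ang[out])]
    # next(d) for d arriving at v: the outgoing edge immediately clockwise
    # of reverse(d) in the CCW angular order (faces keep interior on left)
    for (j in seq_along(o)) {
      prev_idx <- o[if (j == 1) length(o) else j - 1]
      nxt[twin[o[j]]] <- key[prev_idx]
    }
  }
  faces <- list(); seen <- character(0)
  for (k in names(nxt)) {
    if (k %in% seen) next
    walk <- character(0); cur <- k
    repeat {
      walk <- c(walk, cur); cur <- nxt[[cur]]
      if (cur == k) break
    }
    seen <- c(seen, walk)
    faces[[length(faces) + 1]] <- walk
  }
  faces
}

# canonical form of a set of face walks (rotation-invariant)
normalize_faces <- function(faces) {
  sort(vapply(faces, function(w) {
    i <- which(w == min(w))[1]
    paste(c(w[i:length(w)], w[seq_len(i - 1)]), collapse = ";")
  }, character(1)))
}

# random periodic planar fixture whose edges are by construction a subset of
# a Delaunay triangulation (so polygon assignment is well-defined)
random_planar_fixture <- function(n = 30, keep = 0.7, seed = 1, L = 1000) {
  set.seed(seed)
  xy <- cbind(runif(n) * L, runif(n) * L)
  del <- periodic_delaunay(xy, c(L, L))
  ed <- del$edges
  un <- !duplicated(colweb:::.undirected_key(ed$u, ed$v, ed$sx, ed$sy))
  edges <- tibble::tibble(u = ed$u[un], v = ed$v[un],
                          sx = ed$sx[un], sy = ed$sy[un])
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  edges$sx[swap] <- -edges$sx[swap]; edges$sy[swap] <- -edges$sy[swap]
  keep_rows <- runif(nrow(edges)) < keep
  as_network(tibble::tibble(x = xy[, 1], y = xy[, 2]),
             edges[keep_rows, ], c(L, L))
}

# empty bonded topology, for free-bead states
empty_bonds <- function()
  matrix(numeric(), 0, 3, dimnames = list(NULL, c("i", "j", "rest")))
empty_angles <- function()
  matrix(numeric(), 0, 4, dimnames = list(NULL, c("i", "j", "k", "theta0")))

# free beads on a sparse lattice (no conservative interactions in range)
free_bead_state <- function(n = 100, spacing = 400, T = 0, m = 1e-21,
                            seed = 1) {
  side <- ceiling(sqrt(n))
  g <- as.matrix(expand.grid(x = (1:side) * spacing,
                             y = (1:side) * spacing))[1:n, , drop = FALSE]
  st <- system_state(g, type = rep(2L, n), mol = 1:n,
                     bonds = empty_bonds(), angles = empty_angles(),
                     cell = c(side * spacing, side * spacing))
  if (T > 0) {
    set.seed(seed)
    st$vel <- matrix(rnorm(2 * n, sd = sqrt(1.380649e-23 * T / m) * 1e3),
                     n, 2)
  }
  st
}
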