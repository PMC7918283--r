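# Periodic Delaunay triangulation by ghost tiling.
#
# The triangulation of the infinite periodic point set is recovered from a
# triangulation of the primary cell plus a margin of ghost copies; a face is
# canonical iff its centroid lies in the primary cell. A consistency check
# (every directed periodic edge must have its twin) guards against an
# insufficient margin, in which case the margin is doubled up to the full
# 3x3 tiling.

# deterministic, index-based jitter used to break the exact cocircularity of
# lattice fixtures (honeycomb, square net); the same offset is applied to
# every periodic image of a node, so periodic consistency is preserved
.det_jitter <- function(n) {
  u <- ((seq_len(n) * 2654435761) %% 4294967296) / 4294967296
  v <- ((seq_len(n) * 1013904223 + 12345) %% 4294967296) / 4294967296
  cbind(u - 0.5, v - 0.5)
}

# wrap coordinates strictly into [0, L): the one canonical representation
# used by network construction and triangulation alike, so that cell-shift
# bookkeeping never disagrees between the two
.wrap_cell <- function(x, L) {
  y <- x %% L
  y[y >= L | y < 0] <- 0
  y
}

.edge_key <- function(u, v, sx, sy) paste(u, v, sx, sy, sep = "|")

.parse_keys <- function(keys) {
  m <- matrix(as.integer(unlist(strsplit(keys, "|", fixed = TRUE))),
              ncol = 4, byrow = TRUE)
  colnames(m) <- c("u", "v", "sx", "sy")
  m
}

# canonical (undirected) form of a periodic edge class
.undirected_key <- function(u, v, sx, sy) {
  swap <- u > v | (u == v & (sx < 0 | (sx == 0 & sy < 0)))
  ifelse(swap, .edge_key(v, u, -sx, -sy), .edge_key(u, v, sx, sy))
}

#' Delaunay triangulation of points in a periodic cell
#'
#' Triangulates the torus by tiling a margin of ghost images around the
#' primary cell, triangulating the tiled set and keeping each periodic face
#' exactly once (the copy whose centroid falls in the primary cell). Exactly
#' cocircular configurations (ideal lattices) are broken by a deterministic,
#' periodicity-preserving jitter of relative magnitude `jitter_rel`.
#'
#' @param xy n x 2 matrix of points inside the cell (nm)
#' @param cell c(Lx, Ly)
#' @param margin ghost-tile margin as a fraction of the cell; by default wide
#'   enough for Poisson-like point sets, and automatically doubled (up to the
#'   full 3x3 tiling) if the periodic consistency check fails
#' @param jitter_rel relative jitter amplitude; affects only which
#'   triangulation is chosen among degenerate ones, never the reported
#'   geometry (polygon coordinates always use the original positions)
#' @return a `cw_delaunay`: list with `tri` (integer matrix of canonical
#'   faces: node ids v1..v3 and per-vertex cell shifts, CCW), `edges`
#'   (directed periodic edge table with owner face and in-face position),
#'   `xy`, `cell`
#' @export
periodic_delaunay <- function(xy, cell, margin = NULL, jitter_rel = 1e-5) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 nodes to triangulate", call. = FALSE)
  L <- as.numeric(cell)
  xy[, 1] <- .wrap_cell(xy[, 1], L[1])
  xy[, 2] <- .wrap_cell(xy[, 2], L[2])
  base <- xy
  base[, 1] <- base[, 1] + .det_jitter(n)[, 1] * jitter_rel * L[1]
  base[, 2] <- base[, 2] + .det_jitter(n)[, 2] * jitter_rel * L[2]
  if (is.null(margin)) margin <- min(1, max(0.35, 8 / sqrt(n)))
  repeat {
    res <- tryCatch(.pd_attempt(base, xy, L, margin), error = identity)
    if (!inherits(res, "error")) return(res)
    if (margin >= 1)
      stop("periodic Delaunay triangulation failed: ",
           conditionMessage(res), call. = FALSE)
    margin <- min(1, margin * 2)
  }
}

.pd_attempt <- function(base, xy_orig, L, margin) {
  shifts <- as.matrix(expand.grid(sx = -1L:1L, sy = -1L:1L))
  n <- nrow(base)
  px <- numeric(0); py <- numeric(0)
  gid <- integer(0); gsx <- integer(0); gsy <- integer(0)
  for (k in seq_len(nrow(shifts))) {
    s <- shifts[k, ]
    qx <- base[, 1] + s[1] * L[1]
    qy <- base[, 2] + s[2] * L[2]
    keep <- if (s[1] == 0 && s[2] == 0) rep(TRUE, n) else
      qx > -margin * L[1] & qx < (1 + margin) * L[1] &
      qy > -margin * L[2] & qy < (1 + margin) * L[2]
    px <- c(px, qx[keep]); py <- c(py, qy[keep])
    gid <- c(gid, which(keep))
    gsx <- c(gsx, rep(s[1], sum(keep))); gsy <- c(gsy, rep(s[2], sum(keep)))
  }
  tm <- interp::tri.mesh(px, py)
  tr <- interp::triangles(tm)[, 1:3, drop = FALSE]
  cx <- (px[tr[, 1]] + px[tr[, 2]] + px[tr[, 3]]) / 3
  cy <- (py[tr[, 1]] + py[tr[, 2]] + py[tr[, 3]]) / 3
  canon <- cx >= 0 & cx < L[1] & cy >= 0 & cy < L[2]
  tr <- tr[canon, , drop = FALSE]
  if (nrow(tr) == 0) stop("no canonical faces found")
  # orient counter-clockwise
  det <- (px[tr[, 2]] - px[tr[, 1]]) * (py[tr[, 3]] - py[tr[, 1]]) -
         (py[tr[, 2]] - py[tr[, 1]]) * (px[tr[, 3]] - px[tr[, 1]])
  swap <- det < 0
  tmp <- tr[swap, 2]; tr[swap, 2] <- tr[swap, 3]; tr[swap, 3] <- tmp

  tri <- cbind(v1 = gid[tr[, 1]], v2 = gid[tr[, 2]], v3 = gid[tr[, 3]],
               s1x = gsx[tr[, 1]], s1y = gsy[tr[, 1]],
               s2x = gsx[tr[, 2]], s2y = gsy[tr[, 2]],
               s3x = gsx[tr[, 3]], s3y = gsy[tr[, 3]])
  nt <- nrow(tri)
  # directed edges of all canonical faces, in CCW in-face order
  eu <- c(tri[, "v1"], tri[, "v2"], tri[, "v3"])
  ev <- c(tri[, "v2"], tri[, "v3"], tri[, "v1"])
  esx <- c(tri[, "s2x"] - tri[, "s1x"], tri[, "s3x"] - tri[, "s2x"],
           tri[, "s1x"] - tri[, "s3x"])
  esy <- c(tri[, "s2y"] - tri[, "s1y"], tri[, "s3y"] - tri[, "s2y"],
           tri[, "s1y"] - tri[, "s3y"])
  # cell shift of the edge's tail vertex within its owner face copy
  etx <- c(tri[, "s1x"], tri[, "s2x"], tri[, "s3x"])
  ety <- c(tri[, "s1y"], tri[, "s2y"], tri[, "s3y"])
  keys <- .edge_key(eu, ev, esx, esy)
  twins <- .edge_key(ev, eu, -esx, -esy)
  if (anyDuplicated(keys))
    stop("duplicate directed periodic edge (margin too small)")
  if (!all(twins %in% keys))
    stop("periodic edge set is not twin-complete (margin too small)")
  edges <- list(u = eu, v = ev, sx = esx, sy = esy,
                tail_sx = etx, tail_sy = ety,
                key = keys, twin = twins,
                tri = rep(seq_len(nt), 3),
                slot = rep(1:3, each = nt))
  structure(list(tri = tri, edges = edges, xy = xy_orig, cell = L,
                 margin = margin),
            class = "cw_delaunay")
}

#' @export
print.cw_delaunay <- function(x, ...) {
  cat(sprintf("<cw_delaunay> %d nodes, %d periodic faces (margin %.2f)\n",
              nrow(x$xy), nrow(x$tri), x$margin))
  invisible(x)
}

# circumcenters of canonical faces, in unwrapped (face-copy) coordinates
.tri_circumcenters <- function(del) {
  tri <- del$tri; xy <- del$xy; L <- del$cell
  ax <- xy[tri[, "v1"], 1] + tri[, "s1x"] * L[1]
  ay <- xy[tri[, "v1"], 2] + tri[, "s1y"] * L[2]
  bx <- xy[tri[, "v2"], 1] + tri[, "s2x"] * L[1]
  by <- xy[tri[, "v2"], 2] + tri[, "s2y"] * L[2]
  cx <- xy[tri[, "v3"], 1] + tri[, "s3x"] * L[1]
  cy <- xy[tri[, "v3"], 2] + tri[, "s3y"] * L[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy)
}
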