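# Builders for structured inputs: idealised square/hexagonal nets built at
# their energy minima, and Poisson-Voronoi calibration tessellations.

# LJ pair minimum distance
.r_min <- function(sigma) 2^(1 / 6) * sigma

# optimal offset of the 4-head corner cluster of the square net: heads sit
# at distance o from the node along the 4 edge directions, so pairs are at
# sqrt(2) o (4x) and 2 o (2x)
.square_corner_offset <- function(params) {
  f <- function(o) 4 * head_head_energy(sqrt(2) * o, params) +
    2 * head_head_energy(2 * o, params)
  stats::optimize(f, c(0.4 * params$sigma_hh, 1.5 * params$sigma_hh))$minimum
}

# map (i, j, slot) lattice coordinates to node id + cell shift
.lat_id <- function(i, j, slot, nx, ny, nslot) {
  sx <- ifelse(i < 0, -1L, ifelse(i >= nx, 1L, 0L))
  sy <- ifelse(j < 0, -1L, ifelse(j >= ny, 1L, 0L))
  ii <- ((i %% nx) + nx) %% nx
  jj <- ((j %% ny) + ny) %% ny
  list(id = as.integer((jj * nx + ii) * nslot + slot), sx = sx, sy = sy)
}

#' Idealised periodic networks built at their energy minimum
#'
#' Constructs the two idealised reference structures: a honeycomb (nodes of
#' degree 3, one molecule per edge) and a "chain-link fence" square net
#' (corner nodes of degree 4, each edge two molecules long with a degree-2
#' node mid-edge). All bonds are at rest length and every head cluster sits
#' at its Lennard-Jones optimum: the hexagon edge is `l_eqm + 2 r_min /
#' sqrt(3)` so the three heads at each node form an equilateral triangle of
#' side `r_min`; the square-net corner offset minimises the 4-head cluster
#' energy. Because polygon edge counts are counted in nodes, the square-net
#' faces have n = 8 (4 corners + 4 mid-edge nodes).
#'
#' @param type "honeycomb" or "square_net"
#' @param cells number of unit cells per direction (scalar or c(nx, ny))
#' @param params [potential_params()]
#' @return list with `state` (a `cw_state` of placed molecules), `network`
#'   (the intended `cw_network`), `type`, `a` (lattice edge length, nm)
#' @export
build_ideal_net <- function(type = c("honeycomb", "square_net"), cells = 3,
                            params = potential_params()) {
  type <- match.arg(type)
  cells <- rep(cells, length.out = 2)
  nx <- cells[1]; ny <- cells[2]
  stopifnot(nx >= 2, ny >= 2)
  rmin <- .r_min(params$sigma_hh)
  lin <- molecule_template("linear", params)

  if (type == "honeycomb") {
    delta <- rmin / sqrt(3)
    a <- params$l_eqm + 2 * delta
    w <- sqrt(3) * a; h <- 3 * a
    cell <- c(nx * w, ny * h)
    # 4 nodes per unit cell (armchair column):
    base <- rbind(c(0, 0), c(0, a), c(sqrt(3) * a / 2, 1.5 * a),
                  c(sqrt(3) * a / 2, 2.5 * a))
    grid <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
    nodes_xy <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g)
      sweep(base, 2, c(grid$i[g] * w, grid$j[g] * h), "+")))
    # edge list in (i, j, slot) coordinates: from-slot, to (di, dj, slot)
    espec <- list(c(0, 0, 1, 0, 0, 2), c(0, 0, 2, 0, 0, 3),
                  c(0, 0, 2, -1, 0, 3), c(0, 0, 3, 0, 0, 4),
                  c(0, 0, 4, 0, 1, 1), c(0, 0, 4, 1, 1, 1))
    nslot <- 4L
  } else {
    o4 <- .square_corner_offset(params)
    a <- 2 * o4 + 2 * params$l_eqm + rmin
    cell <- c(nx * a, ny * a)
    # slots: 1 corner (0,0), 2 h-mid (a/2, 0), 3 v-mid (0, a/2)
    base <- rbind(c(0, 0), c(a / 2, 0), c(0, a / 2))
    grid <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
    nodes_xy <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g)
      sweep(base, 2, c(grid$i[g] * a, grid$j[g] * a), "+")))
    espec <- list(c(0, 0, 1, 0, 0, 2), c(0, 0, 2, 1, 0, 1),
                  c(0, 0, 1, 0, 0, 3), c(0, 0, 3, 0, 1, 1))
    nslot <- 3L
  }

  grid <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  eu <- integer(0); ev <- integer(0); esx <- integer(0); esy <- integer(0)
  for (g in seq_len(nrow(grid))) {
    i <- grid$i[g]; j <- grid$j[g]
    for (e in espec) {
      from <- .lat_id(i + e[1], j + e[2], e[3] - 1L, nx, ny, nslot)
      to <- .lat_id(i + e[4], j + e[5], e[6] - 1L, nx, ny, nslot)
      eu <- c(eu, from$id + 1L); ev <- c(ev, to$id + 1L)
      esx <- c(esx, to$sx - from$sx); esy <- c(esy, to$sy - from$sy)
    }
  }
  # node rows must be ordered by id
  ids <- unlist(lapply(seq_len(nrow(grid)), function(g)
    (grid$j[g] * nx + grid$i[g]) * nslot + seq_len(nslot)))
  nodes_xy <- nodes_xy[order(ids), , drop = FALSE]
  swap <- eu > ev
  tmp <- eu[swap]; eu[swap] <- ev[swap]; ev[swap] <- tmp
  esx[swap] <- -esx[swap]; esy[swap] <- -esy[swap]
  network <- as_network(
    tibble::tibble(x = nodes_xy[, 1] %% cell[1], y = nodes_xy[, 2] %% cell[2]),
    tibble::tibble(u = eu, v = ev, sx = esx, sy = esy), cell)

  # place molecules along the edges, heads offset into the node clusters
  nd <- network$nodes
  ms <- list(); ctr <- 0
  L <- cell
  if (type == "honeycomb") {
    for (r in seq_len(nrow(network$edges))) {
      e <- network$edges[r, ]
      p1 <- c(nd$x[e$u], nd$y[e$u])
      p2 <- c(nd$x[e$v] + e$sx * L[1], nd$y[e$v] + e$sy * L[2])
      u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
      ctr <- ctr + 1
      ms[[ctr]] <- list(tpl = lin, centre = (p1 + p2) / 2,
                        rot = atan2(u[2], u[1]))
    }
  } else {
    # two molecules per corner-to-corner edge: each recorded edge is
    # corner-to-mid or mid-to-corner; one molecule per edge, heads offset
    # o4 at corners and rmin/2 at mid nodes
    o4 <- .square_corner_offset(params)
    for (r in seq_len(nrow(network$edges))) {
      e <- network$edges[r, ]
      p1 <- c(nd$x[e$u], nd$y[e$u])
      p2 <- c(nd$x[e$v] + e$sx * L[1], nd$y[e$v] + e$sy * L[2])
      d <- p2 - p1; len <- sqrt(sum(d^2)); u <- d / len
      is_corner <- function(id) ((id - 1) %% 3) == 0  # slot 1 of each cell
      off1 <- if (is_corner(e$u)) o4 else rmin / 2
      off2 <- if (is_corner(e$v)) o4 else rmin / 2
      h1 <- p1 + off1 * u
      h2 <- p2 - off2 * u
      ctr <- ctr + 1
      ms[[ctr]] <- list(tpl = lin, centre = (h1 + h2) / 2,
                        rot = atan2(u[2], u[1]))
    }
  }
  templates <- lapply(ms, function(m) m$tpl)
  centres <- do.call(rbind, lapply(ms, function(m) m$centre))
  rots <- vapply(ms, function(m) m$rot, numeric(1))
  state <- .assemble(templates, centres, rots, params, cell)
  list(state = state, network = network, type = type, a = a, cells = cells)
}

#' Potential energy of an ideal network under affine scaling
#'
#' Scales positions and cell of an ideal-network state by a factor `s` in the
#' xy plane (bonds stretch, head-group distances change) and evaluates the
#' total potential energy per molecule, mimicking stretching simulations. At
#' `s = 1` the bond and angle terms are exactly zero by construction.
#'
#' @param net result of [build_ideal_net()]
#' @param s_range vector of scale factors (> 0)
#' @param params [potential_params()]
#' @return tibble with s, per-term energies (J) and energy per molecule;
#'   the minimum over `s` is attached as attribute `min_e_per_molecule`
#' @export
energy_vs_scale <- function(net, s_range = seq(0.9, 1.1, by = 0.005),
                            params = potential_params()) {
  stopifnot(all(s_range > 0))
  st <- net$state
  nmol <- length(unique(st$mol))
  rows <- purrr::map_dfr(s_range, function(s) {
    sc <- st
    sc$pos <- st$pos * s
    sc$cell <- st$cell * s
    tf <- suppressWarnings(total_forces(sc, params))
    tibble::tibble(s = s, e_bond = tf$energy$bond, e_angle = tf$energy$angle,
                   e_bb = tf$energy$body_body, e_hh = tf$energy$head_head,
                   e_total = tf$energy$total,
                   e_per_molecule = tf$energy$total / nmol)
  })
  attr(rows, "min_e_per_molecule") <- min(rows$e_per_molecule)
  rows
}

#' Poisson-Voronoi tessellation on the periodic cell
#'
#' Generates `n_seeds` uniform random points in the periodic cell and builds
#' their Voronoi tessellation via the dual of the periodic Delaunay
#' triangulation: Voronoi vertices are triangle circumcenters (network nodes,
#' generically of degree 3), Voronoi edges join circumcenters of adjacent
#' triangles, and the cells are the polygons. This is the random reference
#' structure whose polygon-size assortativity is about -0.15.
#'
#' @param n_seeds number of seed points (>= 10)
#' @param cell c(Lx, Ly); defaults to the unit-density square
#' @param seed RNG seed
#' @return list with `network` (the Voronoi graph as a `cw_network`),
#'   `cells` (list of polygons: x, y, n, area), `sizes` (edge count per
#'   cell), `adjacency` (two-column matrix of symmetrised adjacent-cell
#'   sizes), `seeds` (the point matrix)
#' @export
poisson_voronoi_network <- function(n_seeds, cell = NULL, seed = 1) {
  stopifnot(n_seeds >= 10)
  if (is.null(cell)) cell <- c(sqrt(n_seeds), sqrt(n_seeds)) * 100
  L <- as.numeric(cell)
  set.seed(seed)
  pts <- cbind(runif(n_seeds) * L[1], runif(n_seeds) * L[2])
  del <- periodic_delaunay(pts, L)
  tri <- del$tri
  nt <- nrow(tri)
  cc <- .tri_circumcenters(del)

  # Voronoi cells: triangles incident to each seed, ordered by angle
  slot_ids <- cbind(tri[, "v1"], tri[, "v2"], tri[, "v3"])
  slot_sx <- cbind(tri[, "s1x"], tri[, "s2x"], tri[, "s3x"])
  slot_sy <- cbind(tri[, "s1y"], tri[, "s2y"], tri[, "s3y"])
  inc_node <- as.vector(slot_ids)
  inc_tri <- rep(seq_len(nt), 3)
  inc_x <- cc[inc_tri, 1] - as.vector(slot_sx) * L[1]
  inc_y <- cc[inc_tri, 2] - as.vector(slot_sy) * L[2]
  ord <- order(inc_node)
  inc_node <- inc_node[ord]; inc_x <- inc_x[ord]; inc_y <- inc_y[ord]
  starts <- c(1, which(diff(inc_node) > 0) + 1, length(inc_node) + 1)
  cells_list <- vector("list", n_seeds)
  for (u in seq_len(n_seeds)) {
    idx <- starts[u]:(starts[u + 1] - 1)
    px <- inc_x[idx]; py <- inc_y[idx]
    ang <- atan2(py - pts[u, 2], px - pts[u, 1])
    o <- order(ang)
    px <- px[o]; py <- py[o]
    cells_list[[u]] <- list(x = px, y = py, n = length(px),
                            area = abs(.shoelace(px, py)))
  }
  sizes <- vapply(cells_list, function(c) c$n, numeric(1))

  # adjacency = Delaunay edges; symmetrised size pairs
  ed <- del$edges
  un <- !duplicated(.undirected_key(ed$u, ed$v, ed$sx, ed$sy))
  du <- ed$u[un]; dv <- ed$v[un]
  adjacency <- cbind(c(sizes[du], sizes[dv]), c(sizes[dv], sizes[du]))

  # Voronoi graph: node per triangle, edge per Delaunay edge (twin pair)
  wx <- floor(cc[, 1] / L[1]); wy <- floor(cc[, 2] / L[2])
  vx <- cc[, 1] - wx * L[1]; vy <- cc[, 2] - wy * L[2]
  pos_in <- match(ed$twin, ed$key)
  left <- ed$tri; right <- ed$tri[pos_in]
  # tail-vertex shift of u in the left and right owner copies
  a_u <- cbind(ed$tail_sx, ed$tail_sy)
  # in the twin (v,u,-s) the head is u, at shift tail(twin) + s(twin)
  b_u <- cbind(ed$sx + ed$tail_sx, ed$sy + ed$tail_sy)[pos_in, , drop = FALSE]
  delta <- a_u - b_u
  keep <- un
  evu <- left[keep]; evv <- right[keep]
  esx <- wx[evv] + delta[keep, 1] - wx[evu]
  esy <- wy[evv] + delta[keep, 2] - wy[evu]
  vor_nodes <- tibble::tibble(x = vx, y = vy)
  vswap <- evu > evv
  tmpu <- evu[vswap]; evu[vswap] <- evv[vswap]; evv[vswap] <- tmpu
  esx[vswap] <- -esx[vswap]; esy[vswap] <- -esy[vswap]
  network <- as_network(vor_nodes,
                        tibble::tibble(u = evu, v = evv,
                                       sx = as.integer(round(esx)),
                                       sy = as.integer(round(esy))), L)
  list(network = network, cells = cells_list, sizes = sizes,
       adjacency = adjacency, seeds = pts, delaunay = del)
}
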