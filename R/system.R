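# SystemState: beads in a periodic 2D cell, with molecule membership and
# bonded topology.

#' Construct a system state
#'
#' @param pos N x 2 matrix of positions (nm); wrapped into the cell
#' @param vel N x 2 matrix of velocities (nm/us)
#' @param type integer bead types (1 head, 2 body, 3 tangle)
#' @param mol integer molecule id per bead
#' @param bonds matrix with columns i, j, rest (1-based indices, nm)
#' @param angles matrix with columns i, j, k, theta0 (rad)
#' @param cell c(Lx, Ly) in nm
#' @param time simulation time (us)
#' @return an object of class `cw_state`
#' @export
system_state <- function(pos, vel = NULL, type, mol, bonds, angles,
                         cell, time = 0) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 2)
  vel <- as.matrix(vel)
  stopifnot(ncol(pos) == 2, all(dim(vel) == dim(pos)),
            length(type) == n, length(mol) == n,
            length(cell) == 2, all(cell > 0))
  dimnames(pos) <- NULL
  dimnames(vel) <- NULL
  pos[, 1] <- pos[, 1] %% cell[1]
  pos[, 2] <- pos[, 2] %% cell[2]
  st <- structure(
    list(pos = pos, vel = vel, type = as.integer(type), mol = as.integer(mol),
         bonds = bonds, angles = angles, cell = as.numeric(cell),
         time = time),
    class = "cw_state")
  st$excl <- .bonded_exclusions(st)
  st
}

#' @export
print.cw_state <- function(x, ...) {
  cat(sprintf(
    "<cw_state> %d beads / %d molecules in %.0f x %.0f nm cell, t = %.3g us\n",
    nrow(x$pos), length(unique(x$mol)), x$cell[1], x$cell[2], x$time))
  invisible(x)
}

# pairs of beads within the same molecule separated by <= 2 bonds, excluded
# from non-bonded interactions (without this, the intramolecular body pair at
# 100 nm < sigma_bb would strain every molecule)
.bonded_exclusions <- function(state) {
  n <- nrow(state$pos)
  adj <- vector("list", n)
  for (b in seq_len(nrow(state$bonds))) {
    i <- state$bonds[b, 1]; j <- state$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one], use.names = FALSE))
    nb <- setdiff(unique(c(one, two)), i)
    nb <- nb[nb > i]
    if (length(nb)) out[[i]] <- cbind(i, nb)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(), 0, 2)
  storage.mode(m) <- "integer"
  m
}

# place template instances at given centres/rotations and assemble a state
.assemble <- function(templates, centres, rots, params, cell, vel_T = NULL,
                      seed = NULL) {
  nmol <- length(templates)
  sizes <- vapply(templates, function(t) length(t$types), integer(1))
  off <- cumsum(c(0L, sizes))
  ntot <- off[nmol + 1]
  pos <- matrix(0, ntot, 2)
  type <- integer(ntot); mol <- integer(ntot)
  bonds <- vector("list", nmol); angles <- vector("list", nmol)
  for (m in seq_len(nmol)) {
    tpl <- templates[[m]]
    th <- rots[m]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    idx <- (off[m] + 1):(off[m] + sizes[m])
    pos[idx, ] <- sweep(tpl$xy %*% t(R), 2, centres[m, ], "+")
    type[idx] <- tpl$types
    mol[idx] <- m
    bonds[[m]] <- cbind(tpl$bonds[, 1:2, drop = FALSE] + off[m],
                        rest = tpl$bonds[, "rest"])
    if (!is.null(tpl$angles) && nrow(tpl$angles))
      angles[[m]] <- cbind(tpl$angles + off[m], theta0 = params$theta0)
  }
  bonds <- do.call(rbind, bonds)
  angles <- do.call(rbind, angles[!vapply(angles, is.null, logical(1))])
  if (is.null(angles)) angles <- matrix(numeric(), 0, 4,
                                        dimnames = list(NULL, c("i", "j", "k", "theta0")))
  vel <- matrix(0, ntot, 2)
  if (!is.null(vel_T)) {
    if (!is.null(seed)) set.seed(seed)
    vel <- .maxwell_velocities(ntot, vel_T, m_kg = 1e-21)
  }
  system_state(pos, vel, type, mol, bonds, angles, cell)
}

# Maxwell-Boltzmann velocities in nm/us for temperature T (K);
# 1 m/s = 1000 nm/us
.maxwell_velocities <- function(n, T, m_kg) {
  sd_nm_us <- sqrt(.kB * T / m_kg) * 1e3
  matrix(stats::rnorm(2 * n, sd = sd_nm_us), n, 2)
}

#' Place molecules on a square grid
#'
#' Builds the initial configuration of the self-assembly protocol: `nx` x
#' `ny` linear molecules laid horizontally on a square grid, with grid pitch
#' large enough that no two beads overlap.
#'
#' @param nx,ny grid dimensions (the production setting is 20 x 20)
#' @param params [potential_params()]
#' @param spacing grid pitch (nm); default `l_eqm + 100`
#' @param T initial Maxwell-Boltzmann temperature (K); 0 for beads at rest
#' @param seed RNG seed for the initial velocities
#' @return a `cw_state`
#' @export
#' @examples
#' st <- build_grid(5, 5)
#' st
build_grid <- function(nx, ny, params = potential_params(),
                       spacing = NULL, T = 0, seed = 1) {
  stopifnot(nx >= 1, ny >= 1)
  if (is.null(spacing)) spacing <- params$l_eqm + 100
  if (spacing <= params$l_eqm)
    stop("grid `spacing` must exceed the molecule length l_eqm: the cell is ",
         "too small for the molecules", call. = FALSE)
  cell <- c(nx * spacing, ny * spacing)
  tpl <- molecule_template("linear", params)
  centres <- as.matrix(expand.grid(
    x = (seq_len(nx) - 0.5) * spacing,
    y = (seq_len(ny) - 0.5) * spacing))
  .assemble(rep(list(tpl), nx * ny), centres, rep(0, nx * ny), params, cell,
            vel_T = if (T > 0) T else NULL, seed = seed)
}

#' Substitute linear molecules with pre-tangled composites
#'
#' Replaces a uniformly random subset of the linear molecules in `state` with
#' tangled templates (placed at the same centre and orientation), modelling
#' lateral 3D tangling interactions in the 2D simulation.
#'
#' @param state a `cw_state` whose molecules are linear
#' @param f_b,f_c fractions of molecules replaced by the one-site and
#'   two-site tangled templates (`f_b + f_c <= 1`)
#' @param seed RNG seed for the substituted subset
#' @param params [potential_params()]
#' @param arc head-to-tangle arc distance (nm)
#' @return a `cw_state` with consistent bead/molecule bookkeeping
#' @export
substitute_tangled <- function(state, f_b = 0, f_c = 0, seed = 1,
                               params = potential_params(), arc = 150) {
  tset <- make_tangled_templates(f_b, f_c, arc, params) # validates fractions
  if (f_b + f_c == 0) return(state)
  mols <- sort(unique(state$mol))
  nmol <- length(mols)
  n_b <- round(f_b * nmol); n_c <- round(f_c * nmol)
  set.seed(seed)
  chosen <- sample(mols, n_b + n_c)
  kind <- stats::setNames(rep("linear", nmol), mols)
  kind[as.character(chosen[seq_len(n_b)])] <- "tangle_b"
  if (n_c > 0) kind[as.character(chosen[n_b + seq_len(n_c)])] <- "tangle_c"

  lin <- molecule_template("linear", params)
  templates <- vector("list", nmol)
  centres <- matrix(0, nmol, 2)
  rots <- numeric(nmol)
  for (mi in seq_len(nmol)) {
    idx <- which(state$mol == mols[mi])
    ctr <- .periodic_centroid(state$pos[idx, , drop = FALSE], state$cell)
    centres[mi, ] <- ctr
    # orientation from the two heads (minimum image)
    heads <- idx[state$type[idx] == BEAD_HEAD]
    d <- state$pos[heads[2], ] - state$pos[heads[1], ]
    d <- d - state$cell * round(d / state$cell)
    rots[mi] <- atan2(d[2], d[1])
    templates[[mi]] <- switch(kind[as.character(mols[mi])],
                              linear = lin,
                              tangle_b = tset$tangle_b,
                              tangle_c = tset$tangle_c)
  }
  .assemble(templates, centres, rots, params, state$cell)
}

# periodic (circular-mean) centroid of a set of points in the cell
.periodic_centroid <- function(xy, cell) {
  vapply(1:2, function(d) {
    th <- xy[, d] / cell[d] * 2 * pi
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang / (2 * pi) * cell[d]) %% cell[d]
  }, numeric(1))
}
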