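# Potential energy terms of the force field. All functions are vectorised
# over their first argument and return energies in J.

#' Harmonic bond energy
#'
#' `U(r) = 1/2 kl (r - rest)^2`. The 1/2 convention matters: the printed
#' value of `kl` assumes it.
#'
#' @param r bead-bead separation (nm), `r >= 0`
#' @param params [potential_params()]
#' @param rest rest length (nm), defaulting to the per-bond rest length
#' @return energy in J
#' @export
bond_energy <- function(r, params = potential_params(),
                        rest = params$bond_rest) {
  if (any(r < 0)) stop("bond separation `r` must be non-negative", call. = FALSE)
  # kl [N/m] x (nm)^2 = 1e-18 J x [N/m numeric]
  0.5 * params$kl * ((r - rest) * 1e-9)^2
}

#' Harmonic angle energy
#'
#' `U(theta) = 1/2 k_theta (theta - theta0)^2`, zero at the straight-chain
#' rest angle `theta0 = pi`.
#'
#' @param theta bond angle (rad) in `[0, pi]`
#' @param params [potential_params()]
#' @return energy in J
#' @export
angle_energy <- function(theta, params = potential_params()) {
  if (any(theta < 0 | theta > pi))
    stop("`theta` must lie in [0, pi]", call. = FALSE)
  0.5 * params$k_theta * (theta - params$theta0)^2
}

#' Body-body excluded-volume energy
#'
#' The 12-6 Lennard-Jones form truncated (without energy shift) at
#' `r = sigma_bb`, where the bracket vanishes, so the term is continuous,
#' strictly positive and monotonically decreasing on `(0, sigma_bb)`:
#' a purely repulsive excluded-volume potential.
#'
#' @param r separation (nm), `r > 0`
#' @param params [potential_params()]
#' @return energy in J
#' @export
body_body_energy <- function(r, params = potential_params()) {
  if (any(r <= 0)) stop("`r` must be strictly positive", call. = FALSE)
  s6 <- (params$sigma_bb / r)^6
  ifelse(r < params$sigma_bb, 4 * params$eps_bb * (s6^2 - s6), 0)
}

#' Head-head attraction energy
#'
#' The full 12-6 Lennard-Jones potential between head beads, truncated
#' (unshifted) at `rc_hh` (3 `sigma_hh` by default). The minimum is `-eps_hh`
#' at `r = 2^(1/6) sigma_hh`.
#'
#' @param r separation (nm), `r > 0`
#' @param params [potential_params()]
#' @return energy in J
#' @export
head_head_energy <- function(r, params = potential_params()) {
  if (any(r <= 0)) stop("`r` must be strictly positive", call. = FALSE)
  s6 <- (params$sigma_hh / r)^6
  ifelse(r < params$rc_hh, 4 * params$eps_hh * (s6^2 - s6), 0)
}

#' Total forces and energy breakdown
#'
#' Evaluates the full force field on a system state: harmonic bonds, harmonic
#' angles, head-head attraction and body-body repulsion, with the minimum
#' image convention and intramolecular exclusions (bead pairs separated by at
#' most two bonds do not interact non-bondedly). Head-body cross terms are
#' identically zero. Forces are exact negative gradients of the implemented
#' energies.
#'
#' Bead pairs closer than the numerical floor 0.7 sigma (where the 12-6
#' barrier is ~256 eps, dynamically unreachable) are flagged: the pair is
#' evaluated at the floor distance, capping the force, and a warning is
#' issued.
#'
#' @param state a `cw_state`
#' @param params [potential_params()]
#' @return list with `forces` (N x 2 matrix, J/nm, i.e. the gradient with
#'   respect to nm displacements), `energy` (named list in J: bond, angle,
#'   body_body, head_head, total), `upair` (the head-head pair energy sum,
#'   J) and `virial` (J)
#' @export
total_forces <- function(state, params = potential_params()) {
  eng <- .engine_args(state, params)
  res <- .cw_energy_forces(eng$pos, eng$vel, eng$type, eng$mol, eng$bonds,
                           eng$bond_rest, eng$angles, eng$angle_theta0,
                           eng$excl, eng$cell, eng$pars, eng$m)
  if (res$energy$n_overlap > 0)
    warning(res$energy$n_overlap,
            " bead pair(s) below the 0.7 sigma overlap floor; forces capped",
            call. = FALSE)
  e <- lapply(res$energy[c("bond", "angle", "body_body", "head_head", "total")],
              function(z) z / .J2zJ)
  list(forces = res$forces / .J2zJ, # zJ/nm -> J/nm
       energy = e,
       upair = e$head_head,
       virial = res$energy$virial / .J2zJ)
}

# marshal a cw_state + cw_params into the 0-based engine arguments
.engine_args <- function(state, params, sim = NULL) {
  bonds <- state$bonds
  angles <- state$angles
  list(pos = state$pos,
       vel = state$vel / 1e3, # nm/us -> nm/ns
       type = state$type,
       mol = state$mol,
       bonds = matrix(as.integer(bonds[, 1:2, drop = FALSE] - 1L),
                      ncol = 2),
       bond_rest = as.numeric(bonds[, "rest"]),
       angles = matrix(as.integer(angles[, 1:3, drop = FALSE] - 1L),
                       ncol = 3),
       angle_theta0 = as.numeric(angles[, "theta0"]),
       excl = matrix(as.integer(state$excl - 1L), ncol = 2),
       cell = state$cell,
       pars = .pp_internal(params),
       m = if (is.null(sim)) 1 else sim$m * .kg2u)
}
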