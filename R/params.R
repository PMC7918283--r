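# Parameter containers and unit conversions.
#
# User-facing units follow the conventions of the coarse-grained collagen
# literature: lengths in nm, times in us, energies in J, bond force constants
# in N/m, temperatures in K, pressures in Pa. The compiled engine works in a
# self-consistent internal system (nm, ns, zJ = 1e-21 J, mass unit 1e-21 kg);
# conversions are centralised here.

#' Boltzmann constant in J/K
#' @keywords internal
.kB <- 1.380649e-23

# conversion factors: user unit -> internal engine unit
.J2zJ <- 1e21           # J -> zJ
.Nm2zJnm2 <- 1e3        # N/m -> zJ/nm^2
.us2ns <- 1e3           # us -> ns
.kg2u <- 1e21           # kg -> internal mass unit (1e-21 kg)
.Pa2zJnm3 <- 1e-6       # Pa -> zJ/nm^3

#' Force-field parameters for the coarse-grained collagen-like molecule
#'
#' Holds every symbol of the bead-spring force field: harmonic bond and angle
#' constants, the attractive head-head Lennard-Jones well, and the purely
#' repulsive body-body term (truncated at `sigma_bb`, so it acts as an
#' excluded-volume potential). Head-body cross interactions are identically
#' zero by construction; there is no parameter for them.
#'
#' Defaults are the values that most reliably self-assemble networks:
#' `kl` = 1.657e-4 N/m, `k_theta` = 200e-21 J, `eps_hh` = 4.142e-21 J,
#' `eps_bb` = 16.142e-21 J, `l_eqm` = 300 nm, `sigma_hh` = 50 nm,
#' `sigma_bb` = 137.5 nm. Note `eps_hh` equals kB x 300 K to three
#' significant figures, which is why the melt stage at 300 K dissociates
#' head-head bonds.
#'
#' Both harmonic terms use the 1/2 k (x - x0)^2 convention; the printed value
#' of `kl` is only meaningful together with this convention.
#'
#' @param kl bond force constant (N/m)
#' @param l_eqm equilibrium end-to-end molecule length (nm)
#' @param bond_rest per-bond rest length (nm). The default 60 nm
#'   discretises the 300 nm molecule into five bonds (H-B-B-B-B-H), which
#'   realises the intended coordination geometry: with heads bound at their
#'   pair minimum, the innermost body beads of arms sharing a node are
#'   ~160 nm apart for three arms (outside the sigma_bb = 137.5 nm
#'   repulsion, so k = 3 is easy), ~139 nm for four arms (marginal), and
#'   ~122 nm for five (strongly penalised) - the excluded volume favours
#'   k = 3 and caps coordination near 4
#' @param k_theta angle force constant (J/rad^2)
#' @param theta0 equilibrium angle (rad); pi is a straight chain. Intrinsic
#'   curvature can be explored by lowering it.
#' @param eps_hh head-head Lennard-Jones well depth (J)
#' @param sigma_hh head-head Lennard-Jones range (nm)
#' @param eps_bb body-body energy scale (J)
#' @param sigma_bb body-body range (nm); the body term is cut (untruncated
#'   12-6 bracket, no energy shift) at `r = sigma_bb`, making it purely
#'   repulsive
#' @param rc_hh head-head cutoff (nm); the head term is truncated, unshifted,
#'   at 3 `sigma_hh` by default, where the neglected tail is below 0.2% of
#'   `eps_hh`
#' @return an object of class `cw_params`
#' @export
#' @examples
#' p <- potential_params()
#' head_head_energy(2^(1/6) * 50, p) # the well minimum, -eps_hh
potential_params <- function(kl = 1.657e-4,
                             l_eqm = 300,
                             bond_rest = 60,
                             k_theta = 200e-21,
                             theta0 = pi,
                             eps_hh = 4.142e-21,
                             sigma_hh = 50,
                             eps_bb = 16.142e-21,
                             sigma_bb = 137.5,
                             rc_hh = 3 * sigma_hh) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    x
  }
  for (nm in c("kl", "l_eqm", "bond_rest", "k_theta", "eps_hh", "sigma_hh",
               "eps_bb", "sigma_bb", "rc_hh")) {
    v <- num1(get(nm), nm)
    if (v <= 0) stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  num1(theta0, "theta0")
  if (theta0 < 0 || theta0 > pi)
    stop("`theta0` must lie in [0, pi]", call. = FALSE)
  structure(
    list(kl = kl, l_eqm = l_eqm, bond_rest = bond_rest,
         k_theta = k_theta, theta0 = theta0,
         eps_hh = eps_hh, sigma_hh = sigma_hh,
         eps_bb = eps_bb, sigma_bb = sigma_bb, rc_hh = rc_hh),
    class = "cw_params")
}

#' @export
print.cw_params <- function(x, ...) {
  cat("<cw_params> coarse-grained collagen force field\n")
  cat(sprintf("  bonds : kl = %.4g N/m, rest = %g nm (l_eqm = %g nm)\n",
              x$kl, x$bond_rest, x$l_eqm))
  cat(sprintf("  angles: k_theta = %.4g J, theta0 = %.4g rad\n",
              x$k_theta, x$theta0))
  cat(sprintf("  heads : eps = %.4g J, sigma = %g nm, cutoff = %g nm\n",
              x$eps_hh, x$sigma_hh, x$rc_hh))
  cat(sprintf("  bodies: eps = %.4g J, sigma = %g nm (repulsive)\n",
              x$eps_bb, x$sigma_bb))
  invisible(x)
}

# internal-unit view of the force field, as the engine list
.pp_internal <- function(params) {
  stopifnot(inherits(params, "cw_params"))
  list(kl = params$kl * .Nm2zJnm2,
       ktheta = params$k_theta * .J2zJ,
       eps_hh = params$eps_hh * .J2zJ,
       sig_hh = params$sigma_hh,
       rc_hh = params$rc_hh,
       eps_bb = params$eps_bb * .J2zJ,
       sig_bb = params$sigma_bb,
       theta0 = params$theta0)
}

#' Integrator and thermostat parameters
#'
#' The bead mass, friction time and timestep are not physical observables of
#' the target system; they are chosen so that the printed microsecond-scale
#' protocol is integrable. The defaults follow from the bond period: with
#' `m` = 1e-21 kg and the default `kl`, one bond oscillation takes
#' 2 pi sqrt(m / kl) ~ 15.4 ns, the timestep resolves it 50x, and the
#' Langevin damping time is 100 timesteps so `dt` << `gamma`.
#'
#' @param m bead mass (kg)
#' @param dt timestep (us); default `2 pi sqrt(m / kl) / 50`
#' @param gamma Langevin damping time (us); default `100 dt`
#' @param tau_T coupling time of the deterministic velocity-rescale
#'   thermostat used during the constant-pressure stage (us); default `100 dt`
#' @param tau_p barostat coupling time (us)
#' @param p_target barostat target pressure (Pa)
#' @param lz0 nominal out-of-plane cell thickness (nm) used to convert the
#'   2D virial into a 3D pressure, mirroring the convention of treating a 2D
#'   system in a 3D cell. Fixed at 1.5 nm, the physical width of a collagen
#'   IV triple helix - the natural slab thickness of this quasi-2D system
#' @param scale_clamp maximum per-step fractional cell rescale of the
#'   weak-coupling barostat
#' @param max_disp displacement cap (nm per step) applied during
#'   pre-equilibration to stop overlapping initial states from exploding
#' @param kl bond force constant (N/m) used only to derive the default `dt`
#' @return an object of class `cw_sim_params`
#' @export
sim_params <- function(m = 1e-21,
                       kl = 1.657e-4,
                       dt = NULL,
                       gamma = NULL,
                       tau_T = NULL,
                       tau_p = 0.5,
                       p_target = 20,
                       lz0 = 1.5,
                       scale_clamp = 2e-4,
                       max_disp = 10) {
  tau_bond_ns <- 2 * pi * sqrt((m * .kg2u) / (kl * .Nm2zJnm2))
  if (is.null(dt)) dt <- tau_bond_ns / 50 / .us2ns
  if (is.null(gamma)) gamma <- 100 * dt
  if (is.null(tau_T)) tau_T <- 100 * dt
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (is.finite(gamma) && dt > gamma / 10)
    stop("`dt` must be much smaller than `gamma`", call. = FALSE)
  if (dt > tau_bond_ns / .us2ns / 10)
    stop("`dt` does not resolve the bond period 2*pi*sqrt(m/kl)",
         call. = FALSE)
  structure(
    list(m = m, dt = dt, gamma = gamma, tau_T = tau_T, tau_p = tau_p,
         p_target = p_target, lz0 = lz0, scale_clamp = scale_clamp,
         max_disp = max_disp),
    class = "cw_sim_params")
}

#' @export
print.cw_sim_params <- function(x, ...) {
  cat("<cw_sim_params>\n")
  cat(sprintf("  m = %.3g kg, dt = %.4g us, gamma = %.4g us\n",
              x$m, x$dt, x$gamma))
  cat(sprintf("  barostat: p = %g Pa, tau_p = %.3g us, Lz0 = %g nm\n",
              x$p_target, x$tau_p, x$lz0))
  invisible(x)
}
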