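# Langevin (NVT) dynamics, the constant-pressure relaxation stage, and
# instantaneous observables.

#' Kinetic temperature of a state
#'
#' `T = sum(m |v|^2) / (2 N kB)` - two translational degrees of freedom per
#' bead.
#'
#' @param state a `cw_state`
#' @param m bead mass (kg)
#' @return temperature (K)
#' @export
kinetic_temperature <- function(state, m = 1e-21) {
  n <- nrow(state$pos)
  if (n < 1) stop("empty state", call. = FALSE)
  v2 <- sum(state$vel^2) # (nm/us)^2 ; 1 nm/us = 1e-3 m/s
  m * v2 * 1e-6 / (2 * n * .kB)
}

#' Instantaneous virial pressure
#'
#' `P = (N kB T + W/2) / (Lx Ly Lz0)` with `W = sum r_ij . F_ij` over all
#' conservative interactions and a nominal out-of-plane thickness `Lz0`,
#' mirroring the convention of simulating a 2D system inside a 3D cell with
#' frozen z. The factor 1/2 is the 2D virial normalisation (1/d with d = 2).
#'
#' @param state a `cw_state`
#' @param params [potential_params()]
#' @param sim [sim_params()] (supplies `m` and `lz0`)
#' @return pressure (Pa)
#' @export
virial_pressure <- function(state, params = potential_params(),
                            sim = sim_params()) {
  if (prod(state$cell) <= 0) stop("zero cell area", call. = FALSE)
  tf <- total_forces(state, params)
  Tk <- kinetic_temperature(state, sim$m)
  n <- nrow(state$pos)
  vol_m3 <- state$cell[1] * state$cell[2] * sim$lz0 * 1e-27 # nm^3 -> m^3
  (n * .kB * Tk + 0.5 * tf$virial) / vol_m3 # virial is J already (J/nm . nm)
}

# shared low-level stage runner; durations in us, temperatures in K
.run_stage <- function(state, params, sim, duration, T_start, T_end = T_start,
                       thermostat = c("langevin", "rescale", "none"),
                       barostat = FALSE, max_disp = 0, seed = 1,
                       n_samples = 40, keep_snapshots = FALSE,
                       stage = "stage") {
  thermostat <- match.arg(thermostat)
  dt_ns <- sim$dt * .us2ns
  n_steps <- max(1L, as.integer(round(duration / sim$dt)))
  sample_every <- max(1L, n_steps %/% n_samples)
  eng <- .engine_args(state, params, sim)
  res <- tryCatch(
    .cw_run_stage(eng$pos, eng$vel, eng$type, eng$mol, eng$bonds, eng$bond_rest,
                  eng$angles, eng$angle_theta0, eng$excl, eng$cell, eng$pars,
                  eng$m, dt_ns,
                  if (is.finite(sim$gamma)) sim$gamma * .us2ns else -1,
                  n_steps, T_start, T_end,
                  switch(thermostat, langevin = 1L, rescale = 2L, none = 0L),
                  sim$tau_T * .us2ns,
                  barostat, sim$p_target * .Pa2zJnm3, sim$tau_p * .us2ns,
                  sim$lz0, sim$scale_clamp,
                  max_disp, as.integer(seed %% .Machine$integer.max),
                  sample_every, keep_snapshots),
    error = function(e) stop("stage '", stage, "' aborted: ",
                             conditionMessage(e), call. = FALSE))
  new_state <- state
  new_state$pos <- res$pos
  new_state$vel <- res$vel * 1e3 # nm/ns -> nm/us
  new_state$cell <- res$cell
  new_state$time <- state$time + n_steps * sim$dt
  log <- tibble::as_tibble(res$log)
  log <- tibble::tibble(
    stage = stage,
    time_us = state$time + log$t_ns / .us2ns,
    T_target = log$T_target, T_kin = log$T_kin,
    U_total_J = log$U_total / .J2zJ, Upair_J = log$U_pair / .J2zJ,
    P_Pa = log$P / .Pa2zJnm3,
    Lx = log$Lx, Ly = log$Ly, area_nm2 = log$Lx * log$Ly)
  snaps <- lapply(res$snapshots, function(s)
    list(time_us = state$time + s$t_ns / .us2ns, stage = stage, pos = s$pos))
  list(state = new_state, log = log, snapshots = snaps,
       n_overlap = res$n_overlap)
}

#' Advance a state by Langevin dynamics
#'
#' Velocity-Verlet integration of the Langevin equation: at each force
#' evaluation the conservative forces are supplemented by a drag `-(m/gamma)
#' v` and a Brownian force `sqrt(2 kB T m / (gamma dt)) xi` with `xi` a fresh
#' standard Gaussian per step and component - the unique prefactor satisfying
#' fluctuation-dissipation for this drag, so the stationary kinetic
#' temperature equals `T`. With `gamma = Inf` the dynamics reduce to NVE.
#'
#' @param state a `cw_state`
#' @param duration time to integrate (us)
#' @param T thermostat temperature (K); a length-2 vector ramps linearly
#' @param params [potential_params()]
#' @param sim [sim_params()]
#' @param seed RNG seed for the Brownian force
#' @param max_disp per-step displacement cap in nm (0 = off)
#' @param keep_snapshots record bead positions at the sampling cadence
#' @return list with `state`, `log` (tibble of scalars) and `snapshots`
#' @export
langevin_step <- function(state, duration, T = 30, params = potential_params(),
                          sim = sim_params(), seed = 1, max_disp = 0,
                          keep_snapshots = FALSE) {
  Tv <- rep(T, length.out = 2)
  .run_stage(state, params, sim, duration, Tv[1], Tv[2],
             thermostat = if (is.finite(sim$gamma)) "langevin" else "none",
             max_disp = max_disp, seed = seed,
             keep_snapshots = keep_snapshots, stage = "langevin")
}

#' Constant-pressure cell relaxation
#'
#' Relaxes the periodic cell toward the target pressure with a weak-coupling
#' (Berendsen-type) isotropic barostat: the cell and all positions are
#' rescaled affinely each step, with the per-step rescale clamped. During
#' this stage temperature is controlled by a deterministic velocity-rescale
#' coupling rather than the Langevin thermostat (the implicit solvent is
#' switched off while the density equilibrates).
#'
#' @inheritParams langevin_step
#' @param T thermostat temperature (K)
#' @return list with `state` (relaxed, fixed final cell), `log`, `snapshots`
#' @export
npt_stage <- function(state, duration, T = 30, params = potential_params(),
                      sim = sim_params(), seed = 1, keep_snapshots = FALSE) {
  .run_stage(state, params, sim, duration, T, T, thermostat = "rescale",
             barostat = TRUE, seed = seed, keep_snapshots = keep_snapshots,
             stage = "npt")
}

#' Simulation protocol configuration
#'
#' Bundles the force field, integrator settings, system size and the
#' melt-cool schedule. Stage durations default to the production protocol:
#' 4 us capped-displacement pre-equilibration + 36 us equilibration at 30 K,
#' 40 us constant-pressure relaxation at 30 K and 20 Pa, cell freeze, linear
#' heating 30 K to 300 K over 100 us (which melts the proto-network), then
#' linear cooling back to 30 K over `t_cool`. `duration_scale` shortens every
#' stage proportionally for desk-scale runs.
#'
#' @param nx,ny molecules per grid side
#' @param params [potential_params()]
#' @param sim [sim_params()]
#' @param t_preeq,t_equil,t_npt,t_heat,t_hold,t_cool stage durations (us)
#' @param T_low,T_high protocol temperatures (K)
#' @param f_b,f_c tangled-molecule substitution fractions
#' @param arc head-to-tangle arc distance (nm)
#' @param duration_scale multiplier applied to every stage duration
#' @param seed base RNG seed (controls velocities, substitution and every
#'   stage's Brownian forces)
#' @param keep_snapshots stages for which bead snapshots are kept
#' @return a `cw_config`
#' @export
run_config <- function(nx = 20, ny = 20,
                       params = potential_params(), sim = NULL,
                       t_preeq = 4, t_equil = 36, t_npt = 40,
                       t_heat = 100, t_hold = 0, t_cool = 100,
                       T_low = 30, T_high = 300,
                       f_b = 0, f_c = 0, arc = 150,
                       duration_scale = 1, seed = 1,
                       keep_snapshots = c("heat", "cool")) {
  if (is.null(sim)) sim <- sim_params(kl = params$kl)
  structure(list(nx = nx, ny = ny, params = params, sim = sim,
                 t_preeq = t_preeq, t_equil = t_equil, t_npt = t_npt,
                 t_heat = t_heat, t_hold = t_hold, t_cool = t_cool,
                 T_low = T_low, T_high = T_high,
                 f_b = f_b, f_c = f_c, arc = arc,
                 duration_scale = duration_scale, seed = seed,
                 keep_snapshots = keep_snapshots),
            class = "cw_config")
}

#' @export
print.cw_config <- function(x, ...) {
  cat(sprintf("<cw_config> %dx%d molecules, t_cool = %g us (scale %g), seed %d\n",
              x$nx, x$ny, x$t_cool, x$duration_scale, x$seed))
  invisible(x)
}

#' Run the full melt-cool self-assembly protocol
#'
#' Executes, in order: square-grid initialisation (with optional tangled
#' substitution), capped-displacement pre-equilibration, Langevin
#' equilibration at `T_low`, constant-pressure relaxation at `T_low` and
#' `p_target`, cell freeze, linear heating to `T_high` (melting the
#' proto-network down to isolated molecules), an optional hold, and linear
#' cooling back to `T_low` over `t_cool` during which the network
#' self-assembles.
#'
#' @param config a [run_config()]
#' @return a `cw_trajectory`: list with `final` (the final `cw_state`), `log`
#'   (tibble of per-sample scalars with stage labels), `snapshots` (list of
#'   bead positions for the requested stages) and `config`
#' @export
run_protocol <- function(config) {
  stopifnot(inherits(config, "cw_config"))
  p <- config$params; sim <- config$sim
  ds <- config$duration_scale
  st <- build_grid(config$nx, config$ny, p, T = config$T_low,
                   seed = config$seed)
  if (config$f_b + config$f_c > 0) {
    st <- substitute_tangled(st, config$f_b, config$f_c,
                             seed = config$seed, params = p, arc = config$arc)
    set.seed(config$seed)
    st$vel <- .maxwell_velocities(nrow(st$pos), config$T_low, sim$m)
  }
  stages <- list(
    list(name = "preeq", dur = config$t_preeq, T0 = config$T_low,
         T1 = config$T_low, thermo = "langevin", baro = FALSE,
         cap = sim$max_disp),
    list(name = "equil", dur = config$t_equil, T0 = config$T_low,
         T1 = config$T_low, thermo = "langevin", baro = FALSE, cap = 0),
    list(name = "npt", dur = config$t_npt, T0 = config$T_low,
         T1 = config$T_low, thermo = "rescale", baro = TRUE, cap = 0),
    list(name = "heat", dur = config$t_heat, T0 = config$T_low,
         T1 = config$T_high, thermo = "langevin", baro = FALSE, cap = 0),
    list(name = "hold", dur = config$t_hold, T0 = config$T_high,
         T1 = config$T_high, thermo = "langevin", baro = FALSE, cap = 0),
    list(name = "cool", dur = config$t_cool, T0 = config$T_high,
         T1 = config$T_low, thermo = "langevin", baro = FALSE, cap = 0))
  logs <- list(); snaps <- list()
  for (i in seq_along(stages)) {
    sg <- stages[[i]]
    if (sg$dur <= 0) next
    res <- .run_stage(st, p, sim, sg$dur * ds, sg$T0, sg$T1,
                      thermostat = sg$thermo, barostat = sg$baro,
                      max_disp = sg$cap,
                      seed = (config$seed + 7919 * i) %% 2147483647,
                      keep_snapshots = sg$name %in% config$keep_snapshots,
                      stage = sg$name)
    st <- res$state
    logs[[length(logs) + 1]] <- res$log
    snaps <- c(snaps, res$snapshots)
  }
  structure(list(final = st, log = dplyr::bind_rows(logs),
                 snapshots = snaps, config = config),
            class = "cw_trajectory")
}

#' @export
print.cw_trajectory <- function(x, ...) {
  cat(sprintf("<cw_trajectory> %d log samples, %d snapshots, final t = %.3g us\n",
              nrow(x$log), length(x$snapshots), x$final$time))
  invisible(x)
}

# rebuild a cw_state for a stored snapshot (positions only; zero velocities)
.snapshot_state <- function(traj, i) {
  s <- traj$snapshots[[i]]
  st <- traj$final
  st$pos <- s$pos
  st$pos[, 1] <- st$pos[, 1] %% st$cell[1]
  st$pos[, 2] <- st$pos[, 2] %% st$cell[2]
  st$vel <- matrix(0, nrow(s$pos), 2)
  st$time <- s$time_us
  st
}
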