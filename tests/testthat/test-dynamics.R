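# Integrator and thermostat physics: drag, fluctuation-dissipation, NVE
# limit, virial pressure, barostat behaviour, determinism.

test_that("kinetic temperature follows its definition", {
  st <- free_bead_state(10)
  expect_equal(kinetic_temperature(st), 0)
  # one bead at speed v: T = m v^2 / (2 kB)
  st1 <- free_bead_state(1)
  st1$vel[1, ] <- c(1000, 0) # nm/us = 1 m/s
  expect_equal(kinetic_temperature(st1, m = 1e-21),
               1e-21 * 1^2 / (2 * 1.380649e-23))
  expect_error(kinetic_temperature(system_state(
    matrix(numeric(), 0, 2), type = integer(0), mol = integer(0),
    bonds = empty_bonds(), angles = empty_angles(), cell = c(1, 1))),
    "empty")
})

test_that("Maxwell-distributed velocities read back their temperature", {
  set.seed(5)
  n <- 4000
  st <- free_bead_state(n, T = 300, seed = 5)
  est <- kinetic_temperature(st)
  se <- 300 * sqrt(2 / (2 * n)) # sd of the chi^2-based estimator
  expect_lt(abs(est - 300), 3 * se)
})

test_that("pure drag decays velocities geometrically at T = 0", {
  p <- potential_params(); sim <- sim_params()
  st <- free_bead_state(25)
  st$vel <- matrix(1000, 25, 2)
  nsteps <- 2000
  r <- langevin_step(st, duration = sim$dt * nsteps, T = 0, params = p,
                     sim = sim, seed = 1)
  expect_equal(mean(abs(r$state$vel)), 1000 * exp(-nsteps * sim$dt / sim$gamma),
               tolerance = 1e-10)
})

test_that("gamma -> Inf at T = 0 reduces to NVE with tiny energy drift", {
  p <- potential_params()
  sim <- sim_params(dt = sim_params()$dt / 10)
  sim$gamma <- Inf
  osc <- system_state(matrix(c(100, 100, 165, 100), 2, 2, byrow = TRUE),
                      type = c(2L, 2L), mol = c(1L, 1L),
                      bonds = matrix(c(1, 2, 60), 1, 3,
                                     dimnames = list(NULL, c("i", "j", "rest"))),
                      angles = empty_angles(), cell = c(400, 400))
  r <- langevin_step(osc, duration = sim$dt * 10000, T = 0, params = p,
                     sim = sim)
  ek <- 2 * 1.380649e-23 * r$log$T_kin # 2 beads, 2 dof each
  etot <- r$log$U_total_J + ek
  e0 <- bond_energy(65, p, rest = 60) # initial stretch sets the energy scale
  expect_lt((max(etot) - min(etot)) / e0, 1e-4)
})

test_that("Langevin thermostat satisfies equipartition at a plateau", {
  p <- potential_params(); sim <- sim_params()
  # free beads
  st <- free_bead_state(144, T = 30, seed = 2)
  r <- langevin_step(st, duration = sim$dt * 30000, T = 30, params = p,
                     sim = sim, seed = 7)
  lg <- r$log
  expect_equal(mean(lg$T_kin[-(1:5)]), 30, tolerance = 0.02)
  # bonded molecules (stiff modes included), out of interaction range so
  # no aggregation heat disturbs the stationary state
  stm <- build_grid(5, 5, p, spacing = 1500, T = 30, seed = 3)
  rm <- langevin_step(stm, duration = 10, T = 30, params = p, sim = sim,
                      seed = 8)
  lgm <- rm$log
  expect_equal(mean(lgm$T_kin[lgm$time_us > 3]), 30, tolerance = 0.02)
})

test_that("virial pressure reproduces the ideal gas and repulsion signs", {
  p <- potential_params(); sim <- sim_params()
  # non-interacting beads: P V = N kB T
  set.seed(9)
  st <- free_bead_state(400, T = 300, seed = 9)
  P <- virial_pressure(st, p, sim)
  n <- nrow(st$pos)
  vol <- prod(st$cell) * sim$lz0 * 1e-27
  expect_equal(P * vol / (n * 1.380649e-23 * kinetic_temperature(st)), 1,
               tolerance = 1e-9)
  # T = 0, no interactions: exactly zero
  st0 <- free_bead_state(50)
  expect_equal(virial_pressure(st0, p, sim), 0)
  # two body beads inside the repulsive range: positive virial
  st2 <- free_bead_state(2, spacing = 4000)
  st2$pos[2, ] <- st2$pos[1, ] + c(110, 0)
  expect_gt(virial_pressure(st2, p, sim), 0)
})

test_that("barostat relaxes toward the target pressure", {
  p <- potential_params()
  sim <- sim_params()
  sim$p_target <- 300 # a moderate compression of the lattice-gas fixture
  st <- free_bead_state(100, spacing = 160, T = 300, seed = 4)
  r <- npt_stage(st, duration = 3, T = 300, params = p, sim = sim, seed = 5)
  lg <- r$log
  second_half <- lg[lg$time_us > max(lg$time_us) / 2, ]
  expect_equal(mean(second_half$P_Pa), sim$p_target, tolerance = 0.25)
  # cell freeze contract: langevin stages never change the cell
  r2 <- langevin_step(r$state, duration = 0.2, T = 300, params = p,
                      sim = sim, seed = 6)
  expect_identical(r2$state$cell, r$state$cell)
})

test_that("trajectories are deterministic given config and seed", {
  cfg <- run_config(nx = 3, ny = 3, t_preeq = 0.2, t_equil = 0.3,
                    t_npt = 0.3, t_heat = 0.5, t_cool = 0.5, seed = 42)
  t1 <- run_protocol(cfg)
  t2 <- run_protocol(cfg)
  expect_identical(t1$final$pos, t2$final$pos)
  expect_identical(t1$log, t2$log)
  cfg2 <- cfg; cfg2$seed <- 43
  t3 <- run_protocol(cfg2)
  expect_false(identical(t1$final$pos, t3$final$pos))
})

test_that("protocol stages appear in order with the configured durations", {
  cfg <- run_config(nx = 3, ny = 3, t_preeq = 0.2, t_equil = 0.4,
                    t_npt = 0.3, t_heat = 0.6, t_cool = 0.5, seed = 1)
  traj <- run_protocol(cfg)
  lg <- traj$log
  expect_identical(unique(lg$stage),
                   c("preeq", "equil", "npt", "heat", "cool"))
  ends <- tapply(lg$time_us, lg$stage, max)
  expect_equal(as.numeric(ends[c("preeq", "equil", "npt", "heat", "cool")]),
               cumsum(c(0.2, 0.4, 0.3, 0.6, 0.5)), tolerance = 2e-3)
  # temperature schedule endpoints
  expect_equal(lg$T_target[lg$stage == "heat"][sum(lg$stage == "heat")], 300)
  expect_equal(lg$T_target[nrow(lg)], 30)
  # cell frozen after the npt stage
  post <- lg[lg$stage %in% c("heat", "cool"), ]
  expect_equal(length(unique(post$Lx)), 1L)
})

test_that("non-finite states abort with a stage label", {
  p <- potential_params()
  sim <- sim_params()
  st <- build_grid(2, 2, p)
  st$vel <- matrix(Inf, nrow(st$pos), 2)
  expect_error(langevin_step(st, duration = sim$dt * 2000, T = 30,
                             params = p, sim = sim), "non-finite")
})
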