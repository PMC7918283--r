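# Force-field terms: closed-form values, symmetry, continuity, exact
# gradients.

test_that("harmonic bond energy matches closed form and is symmetric", {
  p <- potential_params()
  expect_equal(bond_energy(p$bond_rest, p), 0)
  expect_equal(bond_energy(p$bond_rest + 10, p),
               bond_energy(p$bond_rest - 10, p))
  # 10 nm extension at rest 100: 1/2 * 1.657e-4 N/m * (1e-8 m)^2
  expect_equal(bond_energy(110, p, rest = 100), 8.285e-21, tolerance = 1e-12)
  expect_error(bond_energy(-1, p), "non-negative")
})

test_that("harmonic angle energy matches closed form on [0, pi]", {
  p <- potential_params()
  expect_equal(angle_energy(p$theta0, p), 0)
  expect_equal(angle_energy(pi - 0.2, p), angle_energy(pi - 0.2, p))
  d <- 0.15
  pp <- potential_params(theta0 = pi / 2)
  expect_equal(angle_energy(pi / 2 + d, pp), angle_energy(pi / 2 - d, pp))
  # K = 200e-21 J, theta = pi - 0.1: 1/2 * 200e-21 * 0.01
  expect_equal(angle_energy(pi - 0.1, p), 1.0e-21, tolerance = 1e-12)
  expect_error(angle_energy(-0.1, p), "\\[0, pi\\]")
  expect_error(angle_energy(3.5, p), "\\[0, pi\\]")
})

test_that("body-body term is repulsive, continuous and zero beyond sigma", {
  p <- potential_params()
  expect_equal(body_body_energy(p$sigma_bb, p), 0)
  expect_equal(body_body_energy(2 * p$sigma_bb, p), 0)
  # value at the would-be LJ minimum equals the bracket evaluated directly
  r <- p$sigma_bb / 2^(1 / 6)
  s6 <- (p$sigma_bb / r)^6
  expect_equal(body_body_energy(r, p), 4 * p$eps_bb * (s6^2 - s6))
  expect_equal(body_body_energy(r, p), 8 * p$eps_bb)
  # continuity at the cutoff and monotone decrease below it
  eps <- 1e-9
  expect_lt(body_body_energy(p$sigma_bb - eps, p), 1e-28)
  rs <- seq(0.7, 1, by = 0.01) * p$sigma_bb
  expect_true(all(diff(body_body_energy(rs, p)) < 0))
  expect_true(all(body_body_energy(rs[-length(rs)], p) > 0))
  expect_error(body_body_energy(0, p), "positive")
})

test_that("head-head term has the LJ minimum and unshifted cutoff", {
  p <- potential_params()
  expect_equal(head_head_energy(p$sigma_hh, p), 0)
  expect_equal(head_head_energy(2^(1 / 6) * p$sigma_hh, p), -p$eps_hh)
  # independent evaluation at r = 100 nm
  s6 <- (50 / 100)^6
  expect_equal(head_head_energy(100, p), 4 * p$eps_hh * (s6^2 - s6))
  expect_equal(head_head_energy(p$rc_hh, p), 0)
  expect_equal(head_head_energy(p$rc_hh + 1, p), 0)
  expect_error(head_head_energy(-5, p), "positive")
})

test_that("head-head well depth matches thermal energy at the melt temperature", {
  # eps_HH = kB * 300 K to 3 significant figures: the melt stage at 300 K
  # sits exactly at the head-bond energy scale, which is what dissociates it
  p <- potential_params()
  expect_equal(p$eps_hh / (1.380649e-23 * 300), 1, tolerance = 5e-4)
})

test_that("parameter validation rejects non-physical values", {
  expect_error(potential_params(kl = -1), "strictly positive")
  expect_error(potential_params(sigma_hh = 0), "strictly positive")
  expect_error(potential_params(theta0 = 4), "\\[0, pi\\]")
})

test_that("forces are exact negative gradients of the total energy", {
  p <- potential_params()
  set.seed(11)
  errs <- c()
  for (rep in 1:10) {
    st <- build_grid(2, 2, p)
    st$pos <- st$pos + matrix(rnorm(length(st$pos), sd = 12), ncol = 2)
    st$pos[, 1] <- st$pos[, 1] %% st$cell[1]
    st$pos[, 2] <- st$pos[, 2] %% st$cell[2]
    tf <- suppressWarnings(total_forces(st, p))
    h <- 1e-4
    for (i in sample(nrow(st$pos), 3)) {
      for (d in 1:2) {
        sp <- st; sp$pos[i, d] <- sp$pos[i, d] + h
        sm <- st; sm$pos[i, d] <- sm$pos[i, d] - h
        fd <- -(suppressWarnings(total_forces(sp, p))$energy$total -
                  suppressWarnings(total_forces(sm, p))$energy$total) / (2 * h)
        scale <- max(abs(fd), abs(tf$forces[i, d]), 1e-24)
        errs <- c(errs, abs(fd - tf$forces[i, d]) / scale)
      }
    }
  }
  expect_lt(max(errs), 1e-6)
})

test_that("net force vanishes and energy splits into the expected terms", {
  p <- potential_params()
  # isolated straight molecule at rest geometry: zero force, zero energy
  st1 <- build_grid(1, 1, p, spacing = 2000)
  tf1 <- total_forces(st1, p)
  expect_lt(max(abs(tf1$forces)), 1e-30)
  expect_equal(tf1$energy$total, 0)
  # random configuration: Newton's third law for the conservative forces
  set.seed(3)
  st <- build_grid(3, 3, p)
  st$pos <- st$pos + matrix(rnorm(length(st$pos), sd = 20), ncol = 2)
  tf <- suppressWarnings(total_forces(st, p))
  expect_lt(max(abs(colSums(tf$forces))), 1e-22 * nrow(st$pos))
  expect_identical(tf$upair, tf$energy$head_head)
})

test_that("overlapping beads are flagged and the force stays finite", {
  p <- potential_params()
  st <- free_bead_state(4, spacing = 500)
  st$pos[2, ] <- st$pos[1, ] + c(0.1, 0)
  expect_warning(tf <- total_forces(st, p), "overlap")
  expect_true(all(is.finite(tf$forces)))
})
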