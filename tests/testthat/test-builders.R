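# Builders: grids, tangled templates and substitution, ideal nets and their
# scaling energetics, Poisson-Voronoi fixtures.

test_that("build_grid places the requested molecules without overlaps", {
  p <- potential_params()
  st <- build_grid(5, 4, p)
  n_beads_mol <- length(molecule_template("linear", p)$types)
  expect_equal(length(unique(st$mol)), 20L)
  expect_equal(nrow(st$pos), 20L * n_beads_mol)
  # minimum interbead distance comfortably above the numerical floor
  d <- as.matrix(dist(st$pos))
  diag(d) <- Inf
  expect_gt(min(d), 5)
  # single molecule at rest: zero conservative energy
  st1 <- build_grid(1, 1, p, spacing = 1500)
  expect_equal(total_forces(st1, p)$energy$total, 0)
  expect_error(build_grid(2, 2, p, spacing = 200), "too small")
})

test_that("tangled templates have the advertised branch structure", {
  p <- potential_params()
  tb <- molecule_template("tangle_b", p)
  tc <- molecule_template("tangle_c", p)
  br_b <- colweb:::template_branches(tb)
  br_c <- colweb:::template_branches(tc)
  expect_equal(sum(br_b == 3 & tb$types == 3L), 1L) # one 3-branch tangle bead
  expect_equal(sum(br_c == 3 & tc$types == 3L), 2L) # two of them
  # head-to-tangle arc distance along bonds is 150 nm (3 x 50 nm)
  for (tpl in list(tb, tc)) {
    rests <- tpl$bonds[, "rest"]
    expect_true(all(abs(rests - 50) < 1e-9))
  }
  expect_equal(sum(tb$types == 1L), 3L)
  expect_equal(sum(tc$types == 1L), 4L)
  expect_error(make_tangled_templates(f_b = 0.7, f_c = 0.5), "f_b \\+ f_c")
})

test_that("tangled substitution replaces the right number of molecules", {
  p <- potential_params()
  st <- build_grid(5, 5, p)
  expect_identical(substitute_tangled(st, 0, 0, params = p), st)
  st2 <- substitute_tangled(st, f_b = 0.2, f_c = 0.2, seed = 4, params = p)
  types_by_mol <- split(st2$type, st2$mol)
  n_tangle <- vapply(types_by_mol, function(t) sum(t == 3L), integer(1))
  expect_equal(sum(n_tangle == 1), 5L)
  expect_equal(sum(n_tangle == 2), 5L)
  expect_equal(sum(n_tangle == 0), 15L)
  # reproducible under the same seed
  st3 <- substitute_tangled(st, f_b = 0.2, f_c = 0.2, seed = 4, params = p)
  expect_identical(st2$pos, st3$pos)
  expect_error(substitute_tangled(st, f_b = 0.9, f_c = 0.2), "f_b \\+ f_c")
})

test_that("ideal nets are built at their bonded energy minimum", {
  p <- potential_params()
  for (type in c("honeycomb", "square_net")) {
    net <- build_ideal_net(type, 3, p)
    tf <- total_forces(net$state, p)
    expect_equal(tf$energy$bond, 0, tolerance = 1e-30)
    expect_equal(tf$energy$angle, 0, tolerance = 1e-30)
    expect_lt(tf$energy$head_head, 0) # bound head clusters
  }
})

test_that("ideal-net extraction reproduces the intended topology", {
  p <- potential_params()
  hc <- build_ideal_net("honeycomb", 3, p)
  net_h <- build_network(hc$state)
  expect_equal(unique(net_h$nodes$k), 3L)
  expect_equal(pn_distribution(delaunay_polygons(net_h))$p, 1)
  expect_equal(pn_distribution(delaunay_polygons(net_h))$n, 6L)
  sq <- build_ideal_net("square_net", 3, p)
  net_s <- build_network(sq$state)
  expect_setequal(unique(net_s$nodes$k), c(2L, 4L))
  pol_s <- delaunay_polygons(net_s)
  ns <- vapply(pol_s$polygons, function(q) q$n, numeric(1))
  expect_true(all(ns == 8)) # 4 corners + 4 mid-edge nodes per square
  # square cell area: polygons tile the cell
  expect_equal(mean(vapply(pol_s$polygons, function(q) q$area, numeric(1))),
               prod(sq$network$cell) / length(pol_s$polygons),
               tolerance = 1e-9)
})

test_that("hexagonal nets beat square nets across kl and eps_hh", {
  # minimum-over-scale energy per molecule, scanned over a 3x3 grid of
  # bond strengths and head well depths
  for (fk in c(0.5, 1, 2)) {
    for (fe in c(0.5, 1, 2)) {
      p <- potential_params(kl = 1.657e-4 * fk, eps_hh = 4.142e-21 * fe)
      hc <- build_ideal_net("honeycomb", 2, p)
      sq <- build_ideal_net("square_net", 2, p)
      s_range <- seq(0.97, 1.03, by = 0.01)
      e_h <- attr(energy_vs_scale(hc, s_range, p), "min_e_per_molecule")
      e_s <- attr(energy_vs_scale(sq, s_range, p), "min_e_per_molecule")
      expect_lt(e_h, e_s)
    }
  }
})

test_that("scaling an ideal net moves it off its energy minimum", {
  p <- potential_params()
  hc <- build_ideal_net("honeycomb", 2, p)
  ev <- energy_vs_scale(hc, c(0.95, 1, 1.05), p)
  expect_equal(ev$e_bond[ev$s == 1], 0, tolerance = 1e-28)
  expect_gt(ev$e_bond[ev$s == 1.05], 0)
  expect_gt(ev$e_bond[ev$s == 0.95], 0)
  # head energy at s = 1 is the sum over bound clusters
  expect_lt(ev$e_hh[ev$s == 1], 0)
})

test_that("Poisson-Voronoi fixtures satisfy the structural identities", {
  vor <- poisson_voronoi_network(150, seed = 9)
  expect_true(all(vor$network$nodes$k == 3L))          # generic positions
  expect_equal(mean(vor$sizes), 6, tolerance = 1e-12)  # Euler on the torus
  V <- nrow(vor$network$nodes); E <- nrow(vor$network$edges)
  F <- length(vor$cells)
  expect_equal(V - E + F, 0L)
  # cells tile the cell area
  expect_equal(sum(vapply(vor$cells, function(c) c$area, numeric(1))),
               prod(vor$network$cell), tolerance = 1e-6)
  # seed determinism
  vor2 <- poisson_voronoi_network(150, seed = 9)
  expect_identical(vor$sizes, vor2$sizes)
  expect_error(poisson_voronoi_network(5), "n_seeds")
})

test_that("Poisson-Voronoi assortativity is mildly disassortative", {
  rs <- vapply(1:3, function(s)
    as.numeric(assortativity(poisson_voronoi_network(600, seed = s)$adjacency)),
    numeric(1))
  expect_lt(mean(rs), -0.05)
  expect_gt(mean(rs), -0.3)
})
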