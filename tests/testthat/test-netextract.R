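# Head clustering, network building, and the Delaunay-merge polygon
# assignment checked against the independent half-edge traversal oracle.

two_head_state <- function(d, L = 2000) {
  # two isolated head beads a distance d apart
  system_state(rbind(c(500, 500), c(500 + d, 500)),
               type = c(1L, 1L), mol = c(1L, 2L),
               bonds = empty_bonds(), angles = empty_angles(),
               cell = c(L, L))
}

test_that("single-linkage head clustering honours the cutoff", {
  expect_equal(length(cluster_heads(two_head_state(56), rc = 75)$sizes), 1L)
  expect_equal(length(cluster_heads(two_head_state(80), rc = 75)$sizes), 2L)
  # chain a-b-c with |ab| = |bc| = 70, |ac| = 140: one cluster by transitivity
  st <- system_state(rbind(c(500, 500), c(570, 500), c(640, 500)),
                     type = rep(1L, 3), mol = 1:3,
                     bonds = empty_bonds(), angles = empty_angles(),
                     cell = c(2000, 2000))
  cl <- cluster_heads(st, rc = 75)
  expect_equal(length(cl$sizes), 1L)
  expect_equal(cl$sizes, 3L)
  # periodic wrap: heads on opposite sides of the boundary still link
  stp <- system_state(rbind(c(10, 500), c(1990, 500)),
                      type = c(1L, 1L), mol = 1:2,
                      bonds = empty_bonds(), angles = empty_angles(),
                      cell = c(2000, 2000))
  expect_equal(length(cluster_heads(stp, rc = 75)$sizes), 1L)
  # empty input
  st0 <- free_bead_state(3)
  expect_equal(length(cluster_heads(st0)$membership), 0L)
})

# three molecules arranged as a triangle with fused head pairs
triangle_state <- function(params = potential_params()) {
  tpl <- molecule_template("linear", params)
  a <- 360
  centres <- rbind(c(0, 0), c(a, 0), c(a / 2, a * sqrt(3) / 2))
  mids <- rbind((centres[1, ] + centres[2, ]) / 2,
                (centres[2, ] + centres[3, ]) / 2,
                (centres[3, ] + centres[1, ]) / 2)
  dirs <- rbind(centres[2, ] - centres[1, ], centres[3, ] - centres[2, ],
                centres[1, ] - centres[3, ])
  rots <- atan2(dirs[, 2], dirs[, 1])
  colweb:::.assemble(rep(list(tpl), 3), mids + 1000, rots, params,
                     cell = c(3000, 3000))
}

test_that("build_network maps molecules to nodes and edges", {
  net <- build_network(triangle_state())
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$nodes$k, rep(2L, 3))
  # isolated molecule: two k=1 nodes, one edge
  st1 <- build_grid(1, 1, spacing = 1500)
  net1 <- build_network(st1)
  expect_equal(nrow(net1$nodes), 2L)
  expect_equal(net1$nodes$k, c(1L, 1L))
  expect_equal(nrow(net1$edges), 1L)
})

test_that("tangle beads become fixed degree-3 nodes", {
  p <- potential_params()
  st <- build_grid(4, 4, p, spacing = 500)
  st2 <- substitute_tangled(st, f_b = 0.25, seed = 3, params = p)
  net <- build_network(st2)
  tangles <- net$nodes[net$nodes$kind == "tangle", ]
  expect_equal(nrow(tangles), 4L) # 25% of 16 molecules
  expect_true(all(tangles$k == 3L))
})

test_that("Delaunay-merge reproduces elementary polygon fixtures", {
  # 3 nodes, 3 edges: a single triangle
  tri <- as_network(tibble::tibble(x = c(100, 500, 300),
                                   y = c(100, 100, 400)),
                    tibble::tibble(u = c(1, 2, 1), v = c(2, 3, 3)),
                    cell = c(1000, 1000))
  pol <- delaunay_polygons(tri)
  expect_equal(length(pol$polygons), 1L)
  expect_equal(pol$polygons[[1]]$n, 3)
  # 4 nodes in a square, perimeter edges only: the diagonal exists only in
  # the triangulation and its removal merges the two triangles
  sq <- as_network(tibble::tibble(x = c(100, 500, 500, 100),
                                  y = c(100, 100, 500, 500)),
                   tibble::tibble(u = c(1, 2, 3, 1), v = c(2, 3, 4, 4)),
                   cell = c(1000, 1000))
  pols <- delaunay_polygons(sq)
  expect_equal(length(pols$polygons), 1L)
  expect_equal(pols$polygons[[1]]$n, 4)
  expect_equal(pols$polygons[[1]]$area, 400^2)
})

test_that("a network edge missing from the triangulation is an error", {
  # a long crossing edge that Delaunay cannot contain
  set.seed(2)
  xy <- cbind(runif(12) * 1000, runif(12) * 1000)
  del <- periodic_delaunay(xy, c(1000, 1000))
  ed <- del$edges
  un <- !duplicated(colweb:::.undirected_key(ed$u, ed$v, ed$sx, ed$sy))
  edges <- tibble::tibble(u = ed$u[un], v = ed$v[un],
                          sx = ed$sx[un], sy = ed$sy[un])
  # add the pair with the largest separation as a non-Delaunay edge
  dmat <- as.matrix(dist(xy))
  far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  bad <- tibble::tibble(u = min(far), v = max(far), sx = 0L, sy = 0L)
  # keep the full triangulation so no node is pendant-pruned; the far edge
  # cannot be Delaunay and must trigger the precondition error
  net <- as_network(tibble::tibble(x = xy[, 1], y = xy[, 2]),
                    dplyr::bind_rows(edges, bad), c(1000, 1000))
  expect_error(delaunay_polygons(net), "superset")
})

test_that("merge result is invariant to the removal order", {
  net <- random_planar_fixture(n = 40, keep = 0.75, seed = 11)
  p1 <- delaunay_polygons(net)
  pr <- colweb:::.prune_pendants(net)
  del <- colweb:::.periodic_delaunay_subset(cbind(net$nodes$x, net$nodes$y),
                                            net$cell, pr$keep_nodes)
  del_un <- unique(colweb:::.undirected_key(del$edges$u, del$edges$v,
                                            del$edges$sx, del$edges$sy))
  net_un <- colweb:::.undirected_key(pr$network$edges$u, pr$network$edges$v,
                                     pr$network$edges$sx, pr$network$edges$sy)
  n_rm <- length(setdiff(del_un, net_un))
  set.seed(99)
  p2 <- delaunay_polygons(net, order = sample(n_rm))
  expect_identical(normalize_faces(p1$faces), normalize_faces(p2$faces))
  expect_setequal(p1$dangling, p2$dangling)
})

test_that("merge faces equal the half-edge traversal oracle on random fixtures", {
  n_match <- 0
  for (seed in 1:40) {
    net <- random_planar_fixture(n = 25 + (seed %% 3) * 10,
                                 keep = 0.55 + 0.15 * (seed %% 4), seed = seed)
    if (nrow(net$edges) < 3) next
    pol <- delaunay_polygons(net)
    # faces are assigned on the pendant-pruned graph: pruning cannot change
    # any polygon, and the oracle must see the same graph
    pruned <- colweb:::.prune_pendants(net)$network
    expect_identical(normalize_faces(pol$faces),
                     normalize_faces(oracle_faces(pruned)),
                     info = paste("fixture seed", seed))
    n_match <- n_match + 1
  }
  expect_gte(n_match, 35)
})

test_that("Euler relation and area conservation hold on dangling-free networks", {
  for (fix in list(build_ideal_net("honeycomb", 3)$network,
                   build_ideal_net("square_net", 3)$network,
                   poisson_voronoi_network(60, seed = 3)$network)) {
    pol <- tryCatch(delaunay_polygons(fix), error = function(e) NULL)
    if (is.null(pol)) next # Voronoi vertex graphs may violate the precondition
    V <- nrow(fix$nodes); E <- nrow(fix$edges)
    F <- length(pol$faces)
    expect_equal(V - E + F, 0L)
    expect_equal(length(pol$dangling), 0L)
    expect_equal(sum(vapply(pol$polygons, function(q) q$area, numeric(1))),
                 prod(fix$cell), tolerance = 1e-6)
  }
})

test_that("dangling edges are the edges that bound no two distinct faces", {
  hc <- build_ideal_net("honeycomb", 3)$network
  expect_equal(dangling_edges(hc)$percentage, 0)
  # single isolated molecule: its one edge borders only the outer face
  iso <- build_network(build_grid(1, 1, spacing = 1500))
  expect_equal(dangling_edges(iso)$percentage, 100)
  # hexagon with one pendant edge: 1 of 7 edges dangling
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hx <- tibble::tibble(x = 500 + 150 * cos(th), y = 500 + 150 * sin(th))
  nodes <- dplyr::bind_rows(hx, tibble::tibble(x = 880, y = 500))
  edges <- tibble::tibble(u = c(1:6, 1), v = c(2:6, 1, 7))
  net <- as_network(nodes, edges, cell = c(1000, 1000))
  de <- dangling_edges(net)
  expect_equal(de$n_dangling, 1L)
  expect_equal(de$percentage, 100 / 7, tolerance = 1e-12)
})

test_that("self-loop molecules are excluded from edges but recorded", {
  p <- potential_params()
  tpl <- molecule_template("linear", p)
  # bend a molecule so both heads share one cluster
  th <- seq(0, 1.8 * pi, length.out = nrow(tpl$xy))
  bent <- cbind(64 * cos(th), 64 * sin(th)) + 500
  st <- system_state(bent, type = tpl$types, mol = rep(1L, nrow(bent)),
                     bonds = tpl$bonds, angles = cbind(tpl$angles, theta0 = pi),
                     cell = c(1000, 1000))
  net <- build_network(st, rc = 75)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(nrow(net$self_loops), 1L)
})
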