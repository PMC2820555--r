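test_that("degenerate construction inputs are rejected", {
  expect_error(build_dome_geometry(n_layers = 1), "n_layers")
  expect_error(build_dome_geometry(n_layers = 4,
                                   cells_per_layer_profile = c(8, 5, 0, 1)),
               "degenerate layer profile")
  expect_error(build_dome_geometry(n_layers = 4, competent_depth = 4),
               "competent_depth")
  g <- toy_dome(1)
  expect_error(ablate(g, seq_len(g$n)), "every cell")
  expect_error(ablate(g, 99L), "outside")
})

test_that("construction is deterministic for a fixed seed", {
  a <- build_dome_geometry(seed = 7)
  b <- build_dome_geometry(seed = 7)
  expect_identical(a$centres, b$centres)
  expect_identical(a$edges, b$edges)
  c <- build_dome_geometry(seed = 8)
  expect_false(identical(a$centres, c$centres))
})

test_that("toy dome adjacency matches a brute-force Voronoi oracle", {
  g <- toy_dome(1)
  expect_equal(g$n, 12L)
  oracle <- grid_voronoi_oracle(g$centres)
  expect_setequal(edge_set(g$edges), edge_set(oracle))
})

test_that("cell graph is symmetric, irreflexive and connected", {
  for (seed in 1:3) {
    g <- build_dome_geometry(seed = seed)
    expect_true(all(g$edges[, 1] != g$edges[, 2]))
    expect_equal(anyDuplicated(edge_set(g$edges)), 0L)
    expect_true(samsim:::graph_connected(g))
    # competent cells lie within competent_depth layers of the boundary
    d_bound <- suppressWarnings(apply(
      igraph::distances(samsim:::cell_graph(g), v = which(g$boundary)), 2, min))
    expect_true(all(d_bound[g$competent] < g$meta$competent_depth))
  }
})

test_that("anchoring peaks at the tip and decays monotonically", {
  g <- build_dome_geometry(seed = 2)
  a <- g$anchoring
  expect_true(all(a >= 0))
  expect_equal(which.max(a), g$tip_cell)
  d <- samsim:::graph_distance_from(g, g$tip_cell)
  # equal geodesic distance implies equal anchoring; larger distance never
  # increases it
  expect_true(all(tapply(a, d, function(x) diff(range(x))) < 1e-12))
  by_d <- tapply(a, d, unique)
  expect_true(all(diff(unlist(by_d)) <= 0))
  const <- build_anchoring(g, mode = "constant", level = 0.4)
  expect_true(all(const == 0.4))
})

test_that("ablation restricts the geometry without dangling references", {
  g <- toy_dome(1)
  expect_identical(ablate(g, integer(0)), g)

  # remove one interior cell: each former neighbour loses exactly one edge
  victim <- which(g$layer == 2L)[2L]
  nbrs <- union(g$edges[g$edges[, 1] == victim, 2],
                g$edges[g$edges[, 2] == victim, 1])
  g2 <- ablate(g, victim)
  deg <- function(geom, ids) {
    vapply(ids, function(i) sum(geom$edges == i), integer(1))
  }
  old_ids <- setdiff(seq_len(g$n), victim)
  expect_equal(deg(g2, match(g$cell_ids[nbrs], g2$cell_ids)),
               deg(g, nbrs) - 1L)
  expect_equal(deg(g2, match(g$cell_ids[setdiff(old_ids, nbrs)], g2$cell_ids)),
               deg(g, setdiff(old_ids, nbrs)))

  # property: random removals leave a consistent, simulatable geometry
  set.seed(42)
  for (i in 1:5) {
    drop <- sample(g$n, sample(1:6, 1))
    ga <- ablate(g, drop)
    expect_true(all(ga$edges >= 1 & ga$edges <= ga$n))
    expect_equal(length(ga$anchoring), ga$n)
    expect_equal(length(ga$competent), ga$n)
    L <- graph_laplacian(ga)
    expect_equal(max(abs(rowSums(L))), 0)
    p <- sam_params()
    noise <- sample_anchoring_noise(ga, p, 1)
    tr <- run_stage(initial_state(ga), ga, p, sam_scenario(), noise,
                    duration = 10, dt = 0.5)
    expect_true(all(is.finite(tr$final)))
  }
})

test_that("geometry survives a plain-text round trip", {
  g <- toy_dome(3)
  dir <- withr::local_tempdir()
  write_geometry(g, dir)
  g2 <- read_geometry(dir)
  expect_equal(g2$n, g$n)
  expect_equal(unname(g2$centres), unname(g$centres))
  expect_setequal(edge_set(g2$edges), edge_set(g$edges))
  expect_equal(g2$competent, g$competent)
  expect_equal(g2$anchoring, g$anchoring)
  expect_equal(g2$tip_cell, g$tip_cell)
})
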