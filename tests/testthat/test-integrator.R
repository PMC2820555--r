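test_that("graph Laplacian realises zero-flux diffusion", {
  g <- toy_dome(1)
  L <- graph_laplacian(g)
  expect_equal(max(abs(rowSums(L))), 0)
  expect_equal(L, t(L))
  expect_equal(as.vector(L %*% rep(3.7, g$n)), rep(0, g$n))

  # 3-cell path stencil, evaluated by hand
  path <- single_cell_geometry()
  path$n <- 3L; path$cell_ids <- 1:3
  path$centres <- cbind(x = 0:2, y = c(0, 0, 0))
  path$edges <- rbind(c(1L, 2L), c(2L, 3L))
  path$layer <- rep(1L, 3); path$boundary <- rep(TRUE, 3)
  path$competent <- rep(TRUE, 3); path$anchoring <- rep(1, 3)
  Lp <- graph_laplacian(path)
  expect_equal(as.vector(Lp %*% c(1, 0, 0)), c(-1, 1, 0))
})

test_that("pure diffusion conserves tracer mass over many steps", {
  g <- toy_dome(2)
  p <- sam_params()
  sc <- sam_scenario(wus_scale = 0, clv3_endogenous_scale = 0)
  p0 <- sam_params(rho = 0, nu_f = 0, r_y = 0, r_st = 0, r_c = 0, b_w = 0,
                   d_w = 0, d_f = 0, d_y = 0, d_st = 0, d_c = 0)
  ops <- samsim:::make_imex_operators(g, p0, dt = 0.5)
  set.seed(5)
  U <- matrix(runif(g$n * 5), ncol = 5, dimnames = list(NULL, samsim:::SPECIES))
  mass0 <- colSums(U)
  rp <- NULL
  for (i in 1:10000) {
    st <- imex_step(U, ops, p0, sc, g, 0, rp)
    U <- st$state; rp <- st$rhs
  }
  expect_equal(colSums(U), mass0, tolerance = 1e-12)
  # unconditional stability: 10x the default step, no blow-up
  ops10 <- samsim:::make_imex_operators(g, p0, dt = 5)
  U2 <- U; rp <- NULL
  for (i in 1:500) {
    st <- imex_step(U2, ops10, p0, sc, g, 0, rp)
    U2 <- st$state; rp <- st$rhs
  }
  expect_true(all(is.finite(U2)))
  expect_lt(max(U2), max(U) + 1)
})

test_that("zero diffusion and zero reactions leave the state unchanged", {
  g <- single_cell_geometry()
  p <- sam_params(rho = 0, nu_f = 0, r_y = 0, r_st = 0, r_c = 0, b_w = 0,
                  d_w = 0, d_f = 0, d_y = 0, d_st = 0, d_c = 0)
  ops <- samsim:::make_imex_operators(g, p, dt = 1)
  U <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list(NULL, samsim:::SPECIES))
  st <- imex_step(U, ops, p, sam_scenario(), g, 0, NULL)
  expect_equal(st$state, U)
  expect_equal(st$clips, 0)
})

test_that("linear decay converges at second order against the closed form", {
  g <- single_cell_geometry()
  sc <- sam_scenario()
  # only facX decays: d[F]/dt = -d_f F with everything else switched off
  p <- sam_params(rho = 0, nu_f = 0, r_y = 0, r_st = 0, r_c = 0, b_w = 0,
                  d_w = 0, d_f = 0.05, d_y = 0, d_st = 0, d_c = 0)
  err_at <- function(dt) {
    ops <- samsim:::make_imex_operators(g, p, dt)
    U <- initial_state(g, facx0 = 1)
    rp <- NULL
    for (i in seq_len(100 / dt)) {
      st <- imex_step(U, ops, p, sc, g, 0, rp)
      U <- st$state; rp <- st$rhs
    }
    ref <- single_cell_decay_problem(0.05, 1, 100)$value
    abs(U[1, "facX"] - ref)
  }
  e1 <- err_at(1); e05 <- err_at(0.5); e025 <- err_at(0.25)
  expect_lt(e1, 1e-3)
  expect_gt(e1 / e05, 3.3) # ~4x per halving for a 2nd-order scheme
  expect_gt(e05 / e025, 3.3)
})

test_that("IMEX solution tracks a fine-step explicit RK4 reference", {
  g <- toy_dome(1)
  p <- sam_params()
  sc <- sam_scenario()
  noise <- sample_anchoring_noise(g, p, 1)
  # start from a mid-trajectory state so all terms are active
  ops <- samsim:::make_imex_operators(g, p, dt = 0.5)
  U <- initial_state(g); rp <- NULL
  for (i in 1:2000) {
    st <- imex_step(U, ops, p, sc, g, noise, rp); U <- st$state; rp <- st$rhs
  }
  U0 <- U
  rp <- NULL
  for (i in 1:200) {
    st <- imex_step(U, ops, p, sc, g, noise, rp); U <- st$state; rp <- st$rhs
  }
  ref <- rk4_reference(U0, g, p, sc, noise, dt = 0.005, n_steps = 20000)
  rel <- max(abs(U - ref) / (abs(ref) + 1e-8))
  expect_lt(rel, 1e-4)
})

test_that("trajectories are bitwise reproducible for fixed seeds", {
  g <- toy_dome(4)
  p <- sam_params()
  noise <- sample_anchoring_noise(g, p, 9)
  run <- function() run_stage(initial_state(g), g, p, sam_scenario(), noise,
                              duration = 500, dt = 0.5)
  expect_identical(run()$final, run()$final)
  expect_identical(sample_anchoring_noise(g, p, 9), noise)
})

test_that("run_stage enforces preconditions and reports equilibrium", {
  g <- toy_dome(1)
  p <- sam_params()
  noise <- sample_anchoring_noise(g, p, 1)
  expect_error(run_stage(initial_state(g), g, p, sam_scenario(), noise,
                         duration = 0), "duration")
  tr <- run_stage(initial_state(g), g, p, sam_scenario(), noise,
                  duration = 500, dt = 0.5, snapshot_every = 100)
  expect_equal(tr$times[1], 0)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$snapshots[[1]], initial_state(g))
  expect_equal(tr$snapshots[[length(tr$snapshots)]], tr$final)
})

test_that("the two-stage protocol starts canonically and is consistent", {
  g <- toy_dome(1)
  p <- sam_params()
  res <- two_stage_protocol(g, p, sam_scenario(), durations = c(12000, 600),
                            dt = 0.5, seed = 3, equilibrium_tol = 1e-6)
  s10 <- res$stage1$snapshots[[1]]
  expect_equal(unique(s10[, "facX"]), 0.01)
  expect_equal(max(abs(s10[, colnames(s10) != "facX"])), 0)
  # an identity stage 2 stays at the stage-1 end state
  drift <- max(abs(res$stage2$final - res$stage1$final))
  expect_lt(drift, 0.05)
})

test_that("a reached equilibrium persists under further integration", {
  ctx <- wt_context()
  expect_true(ctx$cache$trajectory$equilibrium_reached)
  tr <- run_stage(ctx$state, ctx$geometry, ctx$params, sam_scenario(),
                  ctx$cache$noise, duration = 1000, dt = 0.5)
  expect_lt(max(abs(tr$final - ctx$state)), 1e-3)
})
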