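test_that("default parameters match the canonical parameter file", {
  tab <- read.table(system.file("extdata", "default_parameters.tsv",
                                package = "samsim"),
                    header = TRUE, sep = "\t")
  p <- sam_params()
  expect_setequal(names(p), tab$name)
  expect_equal(unlist(p[tab$name]), setNames(tab$value, tab$name))
  expect_error(sam_params(nope = 1), "unknown parameter")
  expect_error(sam_params(d_w = -1), "nonnegative")
  expect_error(sam_params(n_hill = 0.5), "Hill exponent")
  expect_error(sam_params(D_w = 0.5), "leakage")
})

test_that("pure decay state is a fixed point when all sources vanish", {
  g <- single_cell_geometry()
  p <- sam_params(nu_f = 0)
  state <- initial_state(g, facx0 = 0) # everything zero
  rhs <- reaction_rhs(state, p, sam_scenario(), g, noise = 0)
  expect_equal(unname(rhs), matrix(0, 1, 5))
})

test_that("stemness production is gated by competence", {
  g <- single_cell_geometry()
  g$competent <- FALSE
  state <- initial_state(g)
  state[, "WUS_signal"] <- 50 # far above any half-max
  p <- sam_params()
  rhs <- reaction_rhs(state, p, sam_scenario(), g, noise = 0)
  expect_equal(rhs[1, "stemness"], 0)
  g$competent <- TRUE
  rhs2 <- reaction_rhs(state, p, sam_scenario(), g, noise = 0)
  expect_gt(rhs2[1, "stemness"], 0)
})

test_that("single-cell reaction terms match an independent hand evaluation", {
  g <- single_cell_geometry()
  p <- sam_params()
  sc <- sam_scenario(clv3_exogenous = 0.2, clv3_endogenous_scale = 1.3,
                     receptor_background = 0.25, wus_scale = 0.7)
  state <- matrix(c(0.8, 0.3, 0.6, 0.4, 0.9), nrow = 1,
                  dimnames = list(NULL, samsim:::SPECIES))
  noise <- 0.01
  got <- reaction_rhs(state, p, sc, g, noise = noise)

  # transcribed independently, term by term
  W <- 0.8; Fx <- 0.3; Y <- 0.6; St <- 0.4; C <- 0.9
  rho_eff <- p$rho * (1 + noise)
  fsat <- Fx / (p$K_f + Fx)
  auto <- W^2 / (1 + p$kappa_w * W^2) + p$b_w
  act <- (p$k_rep * (1 - 0.25) * (C + 0.2))^p$n_rep
  prod_w <- 0.7 * rho_eff * fsat * auto / (1 + act)
  expected <- c(
    prod_w - p$d_w * W,
    p$nu_f - prod_w - p$d_f * Fx,
    p$r_y * W - p$d_y * Y,
    p$r_st * Y^p$n_hill / (p$K_y^p$n_hill + Y^p$n_hill) - p$d_st * St,
    1.3 * p$r_c * St - p$d_c * C
  )
  expect_equal(unname(got[1, ]), expected, tolerance = 1e-12)

  # activating CLV3 action mirrors the bounded repressive factor
  sc2 <- sam_scenario(clv3_effect_sign = "activating")
  got2 <- reaction_rhs(state, p, sc2, g, noise = noise)
  act2 <- (p$k_rep * (C))^p$n_rep
  prod2 <- rho_eff * fsat * auto * (2 - 1 / (1 + act2))
  expect_equal(got2[1, "WUS"], prod2 - p$d_w * W, tolerance = 1e-12)
})

test_that("reactions are local and scale linearly in the CLV3 knob", {
  g <- toy_dome(1)
  p <- sam_params()
  set.seed(1)
  state <- matrix(runif(g$n * 5, 0, 1), ncol = 5,
                  dimnames = list(NULL, samsim:::SPECIES))
  noise <- sample_anchoring_noise(g, p, 1)
  base <- reaction_rhs(state, p, sam_scenario(), g, noise)
  state2 <- state
  state2[3, ] <- state2[3, ] * 2 + 0.1
  pert <- reaction_rhs(state2, p, sam_scenario(), g, noise)
  expect_equal(pert[-3, ], base[-3, ])

  lam <- 2.7
  scaled <- reaction_rhs(state, p, sam_scenario(clv3_endogenous_scale = lam),
                         g, noise)
  prod_term <- base[, "CLV3"] + p$d_c * state[, "CLV3"]
  expect_equal(scaled[, "CLV3"] + p$d_c * state[, "CLV3"], lam * prod_term)

  state3 <- state
  state3[1, 2] <- -0.01
  expect_error(reaction_rhs(state3, p, sam_scenario(), g, noise),
               "negative concentration")
})

test_that("scenario presets carry the published knob settings", {
  expect_equal(scenario_preset("wild_type")$clv3_exogenous, 0)
  expect_equal(scenario_preset("wild_type")$clv3_endogenous_scale, 1)
  ko <- scenario_preset("clv3_knockout")
  expect_equal(c(ko$clv3_exogenous, ko$clv3_endogenous_scale), c(0, 0))
  expect_equal(scenario_preset("clv3_knockdown_gradual")$clv3_endogenous_scale,
               0.2)
  expect_equal(scenario_preset("clv3_overexpression_medium")$clv3_exogenous, 1)
  expect_equal(scenario_preset("clv3_overexpression_strong")$clv3_exogenous,
               1.5)
  expect_equal(scenario_preset("clv3_overexpression_low")$clv3_exogenous, 0.7)
  expect_equal(scenario_preset("clv1_background")$receptor_background, 0.2)
  expect_equal(scenario_preset("wus_knockdown_mild")$wus_scale, 0.6)
  expect_equal(scenario_preset("wus_knockdown_intermediate")$wus_scale, 0.4)
  expect_equal(scenario_preset("wus_knockout")$wus_scale, 0)
  expect_equal(scenario_preset("clv3_promoter_wus")$clv3_effect_sign,
               "activating")
  expect_false(scenario_preset("no_facx_feedback")$facx_feedback)
  expect_equal(scenario_preset("constant_anchoring")$anchoring_mode,
               "constant")
  expect_error(scenario_preset("frobnicate"), "wild_type")
})
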