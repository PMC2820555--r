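#' Canonical initial state
#'
#' The simulation protocol starts every run from facX homogeneously at 0.01
#' in all cells and every other species at 0.
#'
#' @param geometry A \code{meristem_geometry}.
#' @param facx0 Initial facX concentration.
#' @return An n x 5 state matrix with columns \code{WUS, facX, WUS_signal,
#'   stemness, CLV3}.
#' @export
initial_state <- function(geometry, facx0 = 0.01) {
  U <- matrix(0, nrow = geometry$n, ncol = length(SPECIES),
              dimnames = list(NULL, SPECIES))
  U[, "facX"] <- facx0
  U
}

#' Sample the frozen anchoring perturbation
#'
#' A small uniform random value per cell, added to the (normalised) anchoring
#' profile once at initialisation; it breaks the symmetry that the
#' activator-substrate subsystem needs to pattern, and is frozen for the whole
#' run so simulations are deterministic given the seed.
#'
#' @param geometry A \code{meristem_geometry}.
#' @param params A [sam_params()] (uses \code{xi_amp}).
#' @param seed Integer seed.
#' @return Numeric vector, one perturbation per cell.
#' @export
sample_anchoring_noise <- function(geometry, params, seed) {
  with_seed(seed, stats::runif(geometry$n, -params$xi_amp, params$xi_amp))
}

#' Reaction right-hand side (reactions only, no diffusion)
#'
#' Evaluates, cell by cell, the non-diffusive part of the five model
#' equations (see [sam_params()] for the algebra): the activator-substrate
#' WUS/facX pair modulated by the perturbed anchoring rate and by local total
#' CLV3, the WUS-signal relay, the competence-gated sigmoidal stemness
#' response, and stemness-driven endogenous CLV3 production. Scenario knobs
#' (exogenous CLV3, endogenous scale, receptor background, wus_scale, CLV3
#' sign, facX feedback) enter exactly as documented in [sam_scenario()].
#'
#' @param state n x 5 state matrix (columns in \code{SPECIES} order).
#' @param params A [sam_params()].
#' @param scenario A [sam_scenario()].
#' @param geometry A \code{meristem_geometry} with the same live cells.
#' @param noise Per-cell frozen anchoring perturbation
#'   (see [sample_anchoring_noise()]); 0 disables it.
#' @param check Validate inputs (negative concentrations are rejected as an
#'   integrator-bug signal). Internal callers disable this on the hot path.
#' @return n x 5 matrix of time derivatives.
#' @export
reaction_rhs <- function(state, params, scenario, geometry, noise = 0,
                         check = TRUE) {
  if (check) {
    if (nrow(state) != geometry$n) {
      stop("state and geometry disagree on the number of live cells.")
    }
    if (any(state < 0)) {
      stop("negative concentration in state: the integrator contract ",
           "(nonnegativity floor) was violated upstream.")
    }
  }
  W <- state[, 1L]; Fx <- state[, 2L]; Y <- state[, 3L]
  St <- state[, 4L]; C <- state[, 5L]

  rho_eff <- params$rho * (geometry$anchoring + noise)
  fsat <- Fx / (params$K_f + Fx)
  auto <- W * W / (1 + params$kappa_w * W * W) + params$b_w
  ctot <- C + scenario$clv3_exogenous
  act <- (params$k_rep * max(0, 1 - scenario$receptor_background) *
            ctot)^params$n_rep
  # repressive: multiply production by R in (0, 1]; activating (WUS driven
  # from the CLV3 promoter): mirror the same bounded response upward, 2 - R.
  repf <- if (scenario$clv3_effect_sign == "repressive") 1 / (1 + act)
          else 2 - 1 / (1 + act)
  prod_w <- scenario$wus_scale * rho_eff * fsat * auto * repf

  dW <- prod_w - params$d_w * W
  dF <- params$nu_f - (if (scenario$facx_feedback) prod_w else 0) -
    params$d_f * Fx
  dY <- params$r_y * W - params$d_y * Y
  yn <- Y^params$n_hill
  dS <- geometry$competent * params$r_st * yn / (params$K_y^params$n_hill + yn) -
    params$d_st * St
  dC <- scenario$clv3_endogenous_scale * params$r_c * St - params$d_c * C

  out <- cbind(dW, dF, dY, dS, dC)
  colnames(out) <- SPECIES
  out
}

#' Homogeneous steady state of the WUS/facX subsystem
#'
#' Solves the spatially homogeneous activator-substrate pair (no CLV3, no
#' competence) at a constant anchoring level for its nontrivial steady state,
#' by 1-D root finding: at steady state the facX balance gives
#' \code{F = (nu_f - d_w W) / d_f}, leaving one equation in W.
#'
#' @param params A [sam_params()].
#' @param rho_level Constant anchoring value (default 1, the tip level).
#' @return List with components \code{W}, \code{F}.
#' @export
wusfacx_steady_state <- function(params, rho_level = 1) {
  rho <- params$rho * rho_level
  g <- function(W) {
    Fx <- (params$nu_f - params$d_w * W) / params$d_f
    auto <- W * W / (1 + params$kappa_w * W * W) + params$b_w
    rho * Fx / (params$K_f + Fx) * auto - params$d_w * W
  }
  # The pair is typically bistable: a basal-expression state and the
  # self-activated (spot interior) state. Scan for every sign change and
  # return the largest root -- the activated branch whose lateral instability
  # drives patterning.
  upper <- params$nu_f / params$d_w * (1 - 1e-9)
  grid <- seq(1e-9, upper, length.out = 2000L)
  gv <- vapply(grid, g, numeric(1))
  flips <- which(gv[-1] * gv[-length(gv)] < 0)
  if (length(flips) == 0L) stop("no homogeneous steady state found.")
  i <- flips[length(flips)]
  root <- stats::uniroot(g, c(grid[i], grid[i + 1L]), tol = 1e-12)$root
  list(W = root, F = (params$nu_f - params$d_w * root) / params$d_f)
}

# Jacobian of the homogeneous WUS/facX pair at a state (W, F).
wusfacx_jacobian <- function(params, ss, rho_level = 1) {
  rho <- params$rho * rho_level
  W <- ss$W; Fx <- ss$F
  auto <- W * W / (1 + params$kappa_w * W * W) + params$b_w
  dauto <- 2 * W / (1 + params$kappa_w * W * W)^2
  fsat <- Fx / (params$K_f + Fx)
  dfsat <- params$K_f / (params$K_f + Fx)^2
  matrix(c(rho * fsat * dauto - params$d_w, rho * dfsat * auto,
           -rho * fsat * dauto, -rho * dfsat * auto - params$d_f),
         nrow = 2L, byrow = TRUE)
}

#' Dispersion relation of the WUS/facX subsystem on the cell graph
#'
#' Linearises the homogeneous activator-substrate steady state and, for every
#' eigenvalue of the graph Laplacian (the graph analogue of the spatial
#' wavenumbers), computes the largest real part of the linearised growth-rate
#' matrix. A band of positive growth at nonzero Laplacian modes while the
#' homogeneous (zero) mode decays is the Turing signature that lets the pair
#' form a confined WUS spot.
#'
#' @param params A [sam_params()].
#' @param geometry A \code{meristem_geometry}.
#' @param rho_level Constant anchoring level for the linearisation.
#' @return Data frame with \code{laplacian_eigenvalue} (<= 0) and
#'   \code{growth_rate}.
#' @export
dispersion_relation <- function(params, geometry, rho_level = 1) {
  ss <- wusfacx_steady_state(params, rho_level)
  J <- wusfacx_jacobian(params, ss, rho_level)
  L <- graph_laplacian(geometry)
  lam <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  Dm <- diag(c(params$D_w, params$D_f))
  growth <- vapply(lam, function(l) {
    max(Re(eigen(J + l * Dm, only.values = TRUE)$values))
  }, numeric(1))
  data.frame(laplacian_eigenvalue = lam, growth_rate = growth)
}
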