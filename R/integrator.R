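#' Unweighted graph Laplacian of the cell graph
#'
#' For a per-cell field u, \code{(L u)(c) = sum_{n ~ c} (u(n) - u(c))}: each
#' shared Voronoi wall contributes equally (cell surfaces and volumes are
#' neglected). Boundary cells simply have fewer neighbours, which realises the
#' zero-flux condition without ghost cells; consequently every row and column
#' of L sums to zero and pure diffusion conserves total mass.
#'
#' @param geometry A \code{meristem_geometry}.
#' @return Dense n x n symmetric matrix.
#' @export
graph_laplacian <- function(geometry) {
  n <- geometry$n
  L <- matrix(0, n, n)
  e <- geometry$edges
  if (nrow(e)) {
    L[e] <- 1
    L[e[, c(2L, 1L), drop = FALSE]] <- 1
    diag(L) <- -rowSums(L)
  }
  L
}

# Precompute the per-species Crank-Nicolson operators for a fixed geometry
# and time step: P = (I - dt/2 D L)^-1 (I + dt/2 D L) applied to the state,
# Ainv = (I - dt/2 D L)^-1 applied to the (explicit) reaction increment.
make_imex_operators <- function(geometry, params, dt) {
  stopifnot(dt > 0)
  L <- graph_laplacian(geometry)
  Dv <- diffusion_rates(params)
  I <- diag(geometry$n)
  ops <- lapply(Dv, function(D) {
    A <- I - (dt * D / 2) * L
    Ainv <- solve(A)
    list(P = Ainv %*% (I + (dt * D / 2) * L), Ainv = Ainv)
  })
  list(ops = ops, L = L, D = Dv, dt = dt)
}

#' One IMEX time step (Crank-Nicolson diffusion + Adams-Bashforth reactions)
#'
#' Advances the state by one constant time step: diffusion is treated with the
#' trapezoidal (Crank-Nicolson) implicit rule, one linear solve per species
#' (factorised once per stage in \code{operators}); reactions with the
#' explicit two-step second-order Adams-Bashforth rule,
#' \code{1.5 f(t) - 0.5 f(t - dt)}. On the first step of a stage (no reaction
#' history) a single explicit-Euler reaction substep bootstraps the method.
#' The result is floored at zero; floor events are counted.
#'
#' @param state n x 5 state matrix.
#' @param operators Result of the internal operator factory (built by
#'   [run_stage()]; exposed for testing via \code{samsim:::make_imex_operators}).
#' @param params,scenario,geometry,noise As in [reaction_rhs()].
#' @param rhs_prev Reaction evaluation at the previous step, or \code{NULL} on
#'   the first step.
#' @return List: \code{state} (new state), \code{rhs} (reaction RHS at the old
#'   state, to pass as \code{rhs_prev} next step), \code{clips} (number of
#'   negative entries floored).
#' @export
imex_step <- function(state, operators, params, scenario, geometry, noise,
                      rhs_prev = NULL) {
  R <- reaction_rhs(state, params, scenario, geometry, noise, check = FALSE)
  Reff <- if (is.null(rhs_prev)) R else 1.5 * R - 0.5 * rhs_prev
  dt <- operators$dt
  new <- state
  for (s in seq_along(SPECIES)) {
    op <- operators$ops[[s]]
    new[, s] <- op$P %*% state[, s] + dt * (op$Ainv %*% Reff[, s])
  }
  if (!all(is.finite(new))) {
    stop("non-finite state encountered during time stepping.")
  }
  clips <- sum(new < 0)
  if (clips) new[new < 0] <- 0
  list(state = new, rhs = R, clips = clips)
}

#' Integrate one simulation stage
#'
#' Runs the IMEX scheme for \code{duration} model time units at constant step
#' \code{dt}, storing snapshots every \code{snapshot_every} time units plus
#' the final state. Every \code{check_every} units the full instantaneous
#' derivative (reactions + diffusion) is evaluated; when its maximum absolute
#' value stays below \code{equilibrium_tol} for \code{consecutive_checks}
#' consecutive checks the stage stops early and is flagged as equilibrated.
#'
#' @param initial n x 5 initial state.
#' @param geometry,params,scenario,noise Model context (see [reaction_rhs()]).
#' @param duration Stage length in model time units (> 0).
#' @param dt Constant time step.
#' @param snapshot_every Snapshot cadence in time units.
#' @param equilibrium_tol Max |du/dt| defining "reasonably close to zero".
#' @param check_every Cadence of the equilibrium check, in time units.
#' @param consecutive_checks Checks that must pass in a row.
#' @param stage Label stored in the trajectory.
#' @return An object of class \code{sam_trajectory}: snapshot times and
#'   states, the final state, equilibrium diagnostics, step and clip counts.
#' @export
run_stage <- function(initial, geometry, params, scenario, noise,
                      duration = 30000, dt = 0.5, snapshot_every = 1000,
                      equilibrium_tol = 1e-8, check_every = 50,
                      consecutive_checks = 10, stage = "stage") {
  if (duration <= 0) stop("duration must be positive.")
  if (dt <= 0) stop("dt must be positive.")
  operators <- make_imex_operators(geometry, params, dt)
  LD <- lapply(seq_along(SPECIES),
               function(s) operators$D[s] * operators$L)

  n_steps <- ceiling(duration / dt)
  snap_steps <- max(1L, round(snapshot_every / dt))
  check_steps <- max(1L, round(check_every / dt))

  U <- initial
  rhs_prev <- NULL
  times <- 0
  snapshots <- list(U)
  clips <- 0L
  streak <- 0L
  equilibrated <- FALSE
  final_max_deriv <- rep(NA_real_, length(SPECIES))

  full_deriv <- function(U) {
    R <- reaction_rhs(U, params, scenario, geometry, noise, check = FALSE)
    for (s in seq_along(SPECIES)) R[, s] <- R[, s] + LD[[s]] %*% U[, s]
    R
  }

  step_i <- 0L
  while (step_i < n_steps) {
    step_i <- step_i + 1L
    res <- imex_step(U, operators, params, scenario, geometry, noise, rhs_prev)
    U <- res$state
    rhs_prev <- res$rhs
    clips <- clips + res$clips
    if (step_i %% snap_steps == 0L && step_i < n_steps) {
      times <- c(times, step_i * dt)
      snapshots <- c(snapshots, list(U))
    }
    if (step_i %% check_steps == 0L) {
      dU <- full_deriv(U)
      final_max_deriv <- apply(abs(dU), 2L, max)
      if (max(final_max_deriv) < equilibrium_tol) {
        streak <- streak + 1L
        if (streak >= consecutive_checks) {
          equilibrated <- TRUE
          break
        }
      } else {
        streak <- 0L
      }
    }
  }
  if (!equilibrated) {
    final_max_deriv <- apply(abs(full_deriv(U)), 2L, max)
    if (max(final_max_deriv) < equilibrium_tol) equilibrated <- TRUE
  }
  t_end <- step_i * dt
  if (times[length(times)] < t_end) {
    times <- c(times, t_end)
    snapshots <- c(snapshots, list(U))
  }
  structure(
    list(stage = stage, times = times, snapshots = snapshots, final = U,
         equilibrium_reached = equilibrated,
         final_max_derivative = stats::setNames(final_max_deriv, SPECIES),
         n_steps = step_i, dt = dt, clip_events = clips,
         duration_requested = duration),
    class = "sam_trajectory"
  )
}

#' @export
print.sam_trajectory <- function(x, ...) {
  cat("sam_trajectory [", x$stage, "]: ", x$n_steps, " steps of dt = ", x$dt,
      " (t = ", max(x$times), "), ", length(x$times), " snapshots; ",
      if (x$equilibrium_reached) "equilibrated" else "NOT equilibrated",
      " (max |du/dt| = ", signif(max(x$final_max_derivative), 3), "); ",
      x$clip_events, " clip events\n", sep = "")
  invisible(x)
}

#' Two-stage simulation protocol
#'
#' Stage 1 equilibrates the wild-type parameterisation from the canonical
#' initial condition (facX = 0.01 everywhere, all other species 0). Stage 2
#' starts from the stage-1 end state, applies the scenario parameters (and,
#' for ablation scenarios, the edited geometry) and integrates further.
#' Structural model-variant flags (\code{facx_feedback},
#' \code{anchoring_mode}) apply to both stages since they define the model,
#' not a perturbation. If stage 1 fails to equilibrate a warning is issued
#' and stage 2 still runs (some structural variants never equilibrate).
#'
#' @param geometry A \code{meristem_geometry}.
#' @param params A [sam_params()].
#' @param scenario_stage2 A [sam_scenario()] applied in stage 2.
#' @param durations Stage lengths in model time units.
#' @param dt Constant time step (same in both stages).
#' @param seed Seed for the frozen anchoring perturbation.
#' @param geometry_edit Optional function \code{(geometry, state, params) ->
#'   integer cell indices to ablate} applied between the stages.
#' @param params_stage2 Optional [sam_params()] used in stage 2 (defaults to
#'   \code{params}); lets scenarios sweep kinetic constants such as the facX
#'   basal production rate.
#' @param stage1_cache Optional precomputed stage-1 result (a list with
#'   elements \code{trajectory} and \code{noise} from an identical stage-1
#'   setup) to skip re-equilibration, e.g. across the points of a sweep.
#' @param ... Further arguments passed to [run_stage()].
#' @return List with elements \code{stage1}, \code{stage2} (both
#'   \code{sam_trajectory}), \code{geometry_stage2}, \code{noise}.
#' @export
two_stage_protocol <- function(geometry, params = sam_params(),
                               scenario_stage2 = sam_scenario(),
                               durations = c(30000, 15000), dt = 0.5,
                               seed = 1L, geometry_edit = NULL,
                               params_stage2 = NULL, stage1_cache = NULL,
                               ...) {
  if (scenario_stage2$anchoring_mode == "constant") {
    geometry$anchoring <- build_anchoring(geometry, mode = "constant")
  }
  noise <- sample_anchoring_noise(geometry, params, seed)
  stage1_scenario <- sam_scenario(
    facx_feedback = scenario_stage2$facx_feedback,
    anchoring_mode = scenario_stage2$anchoring_mode
  )
  if (!is.null(stage1_cache)) {
    s1 <- stage1_cache$trajectory
    noise <- stage1_cache$noise
  } else {
    s1 <- run_stage(initial_state(geometry), geometry, params,
                    stage1_scenario, noise, duration = durations[1L],
                    dt = dt, stage = "stage1", ...)
  }
  if (!s1$equilibrium_reached) {
    warning("stage 1 did not reach equilibrium (max |du/dt| = ",
            signif(max(s1$final_max_derivative), 3),
            "); stage 2 runs from the final state anyway.")
  }

  geometry2 <- geometry
  U2 <- s1$final
  noise2 <- noise
  if (!is.null(geometry_edit)) {
    drop <- geometry_edit(geometry, s1$final, params)
    if (length(drop) == 0L) {
      warning("geometry edit selected no cells; geometry unchanged.")
    } else {
      keep <- setdiff(seq_len(geometry$n), drop)
      geometry2 <- ablate(geometry, drop)
      U2 <- s1$final[keep, , drop = FALSE]
      noise2 <- noise[keep]
    }
  }
  s2 <- run_stage(U2, geometry2, params_stage2 %||% params, scenario_stage2,
                  noise2, duration = durations[2L], dt = dt, stage = "stage2",
                  ...)
  list(stage1 = s1, stage2 = s2, geometry_stage2 = geometry2, noise = noise)
}

#' Explicit fourth-order Runge-Kutta reference integrator
#'
#' A fully explicit RK4 integration of the complete right-hand side
#' (reactions plus graph diffusion), used as an independent accuracy reference
#' for the production IMEX scheme at much smaller time steps. Not intended for
#' production runs.
#'
#' @param initial n x 5 initial state.
#' @param geometry,params,scenario,noise Model context.
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param floor_negative Floor the state at zero after each step, matching the
#'   IMEX nonnegativity contract.
#' @return Final n x 5 state matrix.
#' @export
rk4_reference <- function(initial, geometry, params, scenario, noise, dt,
                          n_steps, floor_negative = TRUE) {
  L <- graph_laplacian(geometry)
  Dv <- diffusion_rates(params)
  f <- function(U) {
    R <- reaction_rhs(U, params, scenario, geometry, noise, check = FALSE)
    for (s in seq_along(SPECIES)) R[, s] <- R[, s] + Dv[s] * (L %*% U[, s])
    R
  }
  U <- initial
  for (i in seq_len(n_steps)) {
    k1 <- f(U)
    k2 <- f(U + dt / 2 * k1)
    k3 <- f(U + dt / 2 * k2)
    k4 <- f(U + dt * k3)
    U <- U + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (floor_negative && any(U < 0)) U[U < 0] <- 0
  }
  U
}
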