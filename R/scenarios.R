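#' Catalogue of published in-silico experiments
#'
#' Every simulated perturbation of the meristem model as a named, concrete run
#' recipe over the two-stage protocol: conditional clv3 knockout and gradual
#' knockdown, clv1 receptor background and knockout, the three levels of
#' uniform CLV3 overexpression, the endogenous-CLV3 robustness sweep, graded
#' WUS knockdown, WUS misexpression from the CLV3 promoter, virtual laser
#' ablation of all WUS/CLV3-expressing cells, facX level variation, and the
#' two structural model variants (no WUS-on-facX feedback; constant
#' anchoring). Each recipe carries a machine-checkable expected-outcome
#' descriptor, so the catalogue doubles as the regression suite.
#'
#' @return Named list of \code{sam_recipe} objects.
#' @export
scenario_catalogue <- function() {
  recipe <- function(name, scenario, expected, geometry_edit = NULL,
                     sweep = NULL, notes = "") {
    structure(list(name = name, scenario = scenario, expected = expected,
                   geometry_edit = geometry_edit, sweep = sweep,
                   notes = notes),
              class = "sam_recipe")
  }
  out <- list(
    wild_type = recipe("wild_type", scenario_preset("wild_type"),
                       outcome_descriptor("patterned_wild_type"),
                       notes = "identity recipe; stage 2 equals stage 1"),
    clv3_knockout = recipe("clv3_knockout", scenario_preset("clv3_knockout"),
                           outcome_descriptor("oc_expansion")),
    clv3_knockdown_gradual = recipe(
      "clv3_knockdown_gradual", scenario_preset("clv3_knockdown_gradual"),
      outcome_descriptor("oc_expansion", strict = FALSE)),
    clv1_background = recipe("clv1_background",
                             scenario_preset("clv1_background"),
                             outcome_descriptor("oc_expansion", strict = FALSE)),
    clv1_knockout = recipe("clv1_knockout", scenario_preset("clv1_knockout"),
                           outcome_descriptor("oc_expansion")),
    clv3_overexpression_low = recipe(
      "clv3_overexpression_low", scenario_preset("clv3_overexpression_low"),
      outcome_descriptor("shrunken_equilibrium")),
    clv3_overexpression_medium = recipe(
      "clv3_overexpression_medium",
      scenario_preset("clv3_overexpression_medium"),
      outcome_descriptor("collapse_recovery")),
    clv3_overexpression_strong = recipe(
      "clv3_overexpression_strong",
      scenario_preset("clv3_overexpression_strong"),
      outcome_descriptor("collapse_no_recovery")),
    clv3_endogenous_sweep = recipe(
      "clv3_endogenous_sweep", scenario_preset("wild_type"), NULL,
      sweep = list(knob = "clv3_endogenous_scale",
                   values = seq(0.1, 6.2, by = 0.1)),
      notes = "stemness-driven CLV3 production varied 10%-620% in 10% steps"),
    wus_knockdown_mild = recipe("wus_knockdown_mild",
                                scenario_preset("wus_knockdown_mild"),
                                outcome_descriptor("domains_shrink")),
    wus_knockdown_intermediate = recipe(
      "wus_knockdown_intermediate",
      scenario_preset("wus_knockdown_intermediate"),
      outcome_descriptor("domains_shrink")),
    wus_knockout = recipe("wus_knockout", scenario_preset("wus_knockout"),
                          outcome_descriptor("domains_lost")),
    clv3_promoter_wus = recipe("clv3_promoter_wus",
                               scenario_preset("clv3_promoter_wus"),
                               outcome_descriptor("coalescence")),
    laser_ablation = recipe("laser_ablation",
                            scenario_preset("laser_ablation"),
                            outcome_descriptor("regeneration"),
                            geometry_edit = select_expressing_cells,
                            notes = "removes all WUS- or CLV3-expressing cells
                                     at the stage-1 equilibrium"),
    facx_variation = recipe(
      "facx_variation", scenario_preset("wild_type"), NULL,
      sweep = list(knob = "nu_f_scale", values = c(0.75, 1, 1.5, 2)),
      notes = "facX basal production swept; OC and SCD sizes grow together"),
    no_facx_feedback = recipe("no_facx_feedback",
                              scenario_preset("no_facx_feedback"),
                              outcome_descriptor("overproliferation")),
    constant_anchoring = recipe("constant_anchoring",
                                scenario_preset("constant_anchoring"),
                                outcome_descriptor("patterned"))
  )
  out
}

#' @export
print.sam_recipe <- function(x, ...) {
  cat("sam_recipe:", x$name,
      if (!is.null(x$sweep)) paste0("(sweep over ", x$sweep$knob, ")"), "\n")
  invisible(x)
}

#' Cells counted as WUS- or CLV3-expressing for the ablation scenario
#'
#' Applies the domain-analysis thresholds to the stage-1 equilibrium itself:
#' cells at or above \code{0.31 * max(WUS)} or, for stem-cell identity read
#' from the endogenous CLV3 reporter, at or above \code{0.21 * max(CLV3)}.
#'
#' @param geometry,state,params Stage-1 context as passed by
#'   [two_stage_protocol()].
#' @param delta_wus,delta_clv3 Threshold fractions.
#' @return Integer cell indices to ablate.
#' @export
select_expressing_cells <- function(geometry, state, params,
                                    delta_wus = 0.31, delta_clv3 = 0.21) {
  which(state[, "WUS"] >= delta_wus * max(state[, "WUS"]) |
          state[, "CLV3"] >= delta_clv3 * max(state[, "CLV3"]))
}

recipe_uses_wt_stage1 <- function(recipe) {
  sc <- recipe$scenario
  sc$facx_feedback && sc$anchoring_mode == "distribution"
}

#' Execute one scenario recipe
#'
#' Runs the two-stage protocol with the recipe's parameter edits (and, for
#' ablation, geometry edit), labels OC/SCD domains at every stage-2 snapshot
#' against the wild-type stage-1 equilibrium, and evaluates the recipe's
#' expected-outcome descriptor.
#'
#' @param recipe A \code{sam_recipe} from [scenario_catalogue()] (or
#'   user-built). Sweep recipes must go through [run_sweep()].
#' @param geometry A \code{meristem_geometry}.
#' @param params A [sam_params()].
#' @param seed Seed for the frozen anchoring perturbation.
#' @param stage1_cache Optional cached wild-type stage 1 (list with
#'   \code{trajectory}, \code{noise}) produced with the same geometry, params,
#'   seed and dt; ignored for structural variants, which re-run stage 1 under
#'   the variant model.
#' @param ... Passed to [two_stage_protocol()] (e.g. \code{durations},
#'   \code{dt}, \code{equilibrium_tol}).
#' @return An object of class \code{sam_run}: the two trajectories, stage-2
#'   geometry, per-snapshot labelings, species totals, the wild-type
#'   reference labeling and totals, and the outcome-check result.
#' @export
run_scenario <- function(recipe, geometry, params = sam_params(), seed = 1L,
                         stage1_cache = NULL, ...) {
  if (!is.null(recipe$sweep)) {
    stop("recipe '", recipe$name, "' is a sweep; use run_sweep().")
  }
  if (!recipe_uses_wt_stage1(recipe)) stage1_cache <- NULL
  res <- two_stage_protocol(geometry, params,
                            scenario_stage2 = recipe$scenario,
                            seed = seed, geometry_edit = recipe$geometry_edit,
                            stage1_cache = stage1_cache, ...)
  wt_state <- res$stage1$final
  ref <- c(WUS = max(wt_state[, "WUS"]),
           stemness = max(wt_state[, "stemness"]))
  wt_lab <- label_domains(wt_state, wt_state, geometry = geometry)
  labelings <- lapply(res$stage2$snapshots, label_domains,
                      wildtype_reference = ref,
                      geometry = res$geometry_stage2)
  names(labelings) <- res$stage2$times
  run <- structure(
    list(recipe = recipe, stage1 = res$stage1, stage2 = res$stage2,
         geometry = res$geometry_stage2, geometry_stage1 = geometry,
         noise = res$noise, labelings = labelings,
         totals = trajectory_totals(res$stage2),
         wt = wt_lab, wt_totals = colSums(wt_state), seed = seed),
    class = "sam_run"
  )
  run$outcome <- if (!is.null(recipe$expected)) {
    check_outcome(recipe$expected, run)
  }
  run
}

#' @export
print.sam_run <- function(x, ...) {
  final <- x$labelings[[length(x$labelings)]]
  cat("sam_run:", x$recipe$name, "| final OC", final$oc_count, "SCD",
      final$scd_count, "overlap", length(final$overlap_cells))
  if (!is.null(x$outcome)) {
    cat(" | expected", x$outcome$type, ":",
        if (x$outcome$pass) "PASS" else "FAIL")
  }
  cat("\n")
  invisible(x)
}

#' Run a knob sweep over the two-stage protocol
#'
#' Each sweep point runs an independent stage 2 from the shared wild-type
#' stage-1 equilibrium; points are order-invariant. Supported knobs:
#' \code{clv3_endogenous_scale} (scenario knob) and \code{nu_f_scale}
#' (multiplier on the facX basal production rate in stage 2).
#'
#' @param values Numeric knob values.
#' @param knob Knob name.
#' @param geometry,params,seed,stage1_cache,... As in [run_scenario()].
#' @return List with \code{table} (from [summarize_sweep()]), \code{labelings}
#'   (final stage-2 labeling per point) and \code{stage1_cache} (for reuse).
#' @export
run_sweep <- function(values, knob = c("clv3_endogenous_scale", "nu_f_scale"),
                      geometry, params = sam_params(), seed = 1L,
                      stage1_cache = NULL, ...) {
  knob <- match.arg(knob)
  if (is.null(stage1_cache)) {
    stage1_cache <- wildtype_stage1(geometry, params, seed = seed, ...)
  }
  wt_state <- stage1_cache$trajectory$final
  ref <- c(WUS = max(wt_state[, "WUS"]),
           stemness = max(wt_state[, "stemness"]))
  labelings <- lapply(values, function(v) {
    scenario <- sam_scenario()
    params2 <- NULL
    if (knob == "clv3_endogenous_scale") {
      scenario <- sam_scenario(clv3_endogenous_scale = v)
    } else {
      params2 <- do.call(sam_params, stats::setNames(list(params$nu_f * v),
                                                     "nu_f"))
    }
    res <- two_stage_protocol(geometry, params, scenario_stage2 = scenario,
                              seed = seed, params_stage2 = params2,
                              stage1_cache = stage1_cache, ...)
    label_domains(res$stage2$final, ref, geometry = geometry)
  })
  names(labelings) <- values
  list(table = summarize_sweep(labelings, values), labelings = labelings,
       stage1_cache = stage1_cache)
}

#' Equilibrate (and cache) the wild-type stage 1
#'
#' @param geometry,params,seed As in [run_scenario()].
#' @param durations,dt,... As in [two_stage_protocol()]/[run_stage()]; only
#'   the stage-1 duration is used.
#' @return List with \code{trajectory} and \code{noise}, usable as
#'   \code{stage1_cache} in [run_scenario()] and [run_sweep()].
#' @export
wildtype_stage1 <- function(geometry, params = sam_params(), seed = 1L,
                            durations = c(30000, 15000), dt = 0.5, ...) {
  noise <- sample_anchoring_noise(geometry, params, seed)
  tr <- run_stage(initial_state(geometry), geometry, params, sam_scenario(),
                  noise, duration = durations[1L], dt = dt, stage = "stage1",
                  ...)
  list(trajectory = tr, noise = noise)
}
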