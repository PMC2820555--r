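# Species ordering used everywhere: columns of a state matrix.
SPECIES <- c("WUS", "facX", "WUS_signal", "stemness", "CLV3")

.samsim_cache <- new.env(parent = emptyenv())

default_parameter_table <- function() {
  if (is.null(.samsim_cache$param_table)) {
    path <- system.file("extdata", "default_parameters.tsv", package = "samsim")
    if (path == "") { # not yet installed (devtools load)
      path <- file.path("inst", "extdata", "default_parameters.tsv")
    }
    .samsim_cache$param_table <- utils::read.table(path, header = TRUE,
                                                   sep = "\t",
                                                   stringsAsFactors = FALSE)
  }
  .samsim_cache$param_table
}

#' Model parameters
#'
#' Returns the full set of kinetic constants of the five-species model with
#' their dimensionless default values, read from the canonical parameter file
#' \code{inst/extdata/default_parameters.tsv} (which documents each constant,
#' the equation term it enters, and its provenance). Any constant can be
#' overridden by name.
#'
#' The constants, by equation:
#' \describe{
#'   \item{WUS}{\code{d[W] = wus_scale * rho_eff * [facX] * autoW * repC - d_w [W]}
#'     with \code{rho_eff = rho * (anchoring + xi)},
#'     \code{autoW = [W]^2 / (1 + kappa_w [W]^2) + b_w}, and
#'     \code{repC = 1 / (1 + k_rep * (1 - receptor_background) * CLV3tot)}
#'     (sign flipped to \code{1 + ...} under activating CLV3 action).}
#'   \item{facX}{\code{d[facX] = nu_f - consumption - d_f [facX]}, consumption
#'     equal to the WUS production term (activator-substrate coupling), dropped
#'     in the no-feedback variant.}
#'   \item{WUS-signal}{\code{d[Y] = r_y [W] - d_y [Y]}.}
#'   \item{stemness}{\code{d[st] = I(c) * r_st * [Y]^n / (K_y^n + [Y]^n) - d_st [st]}
#'     with the competence indicator \code{I(c)} and a large Hill exponent
#'     \code{n_hill} for a sharp stem-cell transition.}
#'   \item{CLV3}{\code{d[C] = clv3_endogenous_scale * r_c [st] - d_c [C]};
#'     the state variable is endogenous CLV3, the stem-cell reporter.}
#' }
#' Diffusion \code{D_s * L} is added by the integrator on the cell graph;
#' \code{D_w} and \code{D_st} are weak leakage rates, facX, WUS-signal and
#' CLV3 diffuse freely.
#'
#' @param ... Named overrides, e.g. \code{sam_params(rho = 0.2)}.
#' @return An object of class \code{sam_params} (named list of numerics).
#' @export
sam_params <- function(...) {
  tab <- default_parameter_table()
  p <- as.list(stats::setNames(tab$value, tab$name))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
  structure(p, class = "sam_params")
}

validate_params <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("all model parameters must be finite and nonnegative.")
  }
  if (p$n_hill < 1) stop("Hill exponent n_hill must be >= 1.")
  free <- c(p$D_f, p$D_y, p$D_c)
  if (!(p$D_w < min(free) && p$D_st < min(free))) {
    stop("leakage diffusion (D_w, D_st) must be smaller than free diffusion ",
         "(D_f, D_y, D_c).")
  }
  invisible(p)
}

# Per-species diffusion rates, in SPECIES order.
diffusion_rates <- function(params) {
  c(params$D_w, params$D_f, params$D_y, params$D_st, params$D_c)
}

#' @export
print.sam_params <- function(x, ...) {
  cat("sam_params:\n")
  print(unlist(x))
  invisible(x)
}

#' Scenario parameters
#'
#' The knobs that distinguish the published in-silico experiments from the
#' wild type. Defaults are the wild-type setting ([CLV3_ext] = 0,
#' endogenous scale = 1, no receptor background, full WUS expression,
#' repressive CLV3 action, facX feedback on, tip-anchored production).
#'
#' @param clv3_exogenous Held uniform concentration of exogenous CLV3 present
#'   in every cell ([CLV3_ext]); enters WUS repression, not the endogenous pool.
#' @param clv3_endogenous_scale Multiplier on stemness-driven CLV3 production
#'   (1 wild type, 0 knockout, 0.2 gradual knockdown, >1 overexpression).
#' @param receptor_background Graded loss of CLV3 perception: 0 is wild type,
#'   1 removes CLV3 action entirely (clv1 knockout style).
#' @param wus_scale Multiplier on WUS production (w_ko; 1 wild type, 0 knockout).
#' @param clv3_effect_sign "repressive" (wild type) or "activating"
#'   (WUS expressed from the CLV3 promoter).
#' @param facx_feedback Logical; drop the WUS-on-facX consumption term when
#'   FALSE (structural variant).
#' @param anchoring_mode "distribution" (tip-peaked) or "constant"
#'   (no positional information).
#' @return An object of class \code{sam_scenario}.
#' @export
sam_scenario <- function(clv3_exogenous = 0,
                         clv3_endogenous_scale = 1,
                         receptor_background = 0,
                         wus_scale = 1,
                         clv3_effect_sign = c("repressive", "activating"),
                         facx_feedback = TRUE,
                         anchoring_mode = c("distribution", "constant")) {
  clv3_effect_sign <- match.arg(clv3_effect_sign)
  anchoring_mode <- match.arg(anchoring_mode)
  knobs <- c(clv3_exogenous, clv3_endogenous_scale, receptor_background,
             wus_scale)
  if (any(!is.finite(knobs)) || any(knobs < 0)) {
    stop("scenario knobs must be finite and nonnegative.")
  }
  structure(
    list(clv3_exogenous = clv3_exogenous,
         clv3_endogenous_scale = clv3_endogenous_scale,
         receptor_background = receptor_background,
         wus_scale = wus_scale,
         clv3_effect_sign = clv3_effect_sign,
         facx_feedback = facx_feedback,
         anchoring_mode = anchoring_mode),
    class = "sam_scenario"
  )
}

#' @export
print.sam_scenario <- function(x, ...) {
  cat("sam_scenario: [CLV3_ext] =", x$clv3_exogenous,
      "| endo scale =", x$clv3_endogenous_scale,
      "| receptor bg =", x$receptor_background,
      "| w_ko =", x$wus_scale,
      "| CLV3 action", x$clv3_effect_sign,
      "| facX feedback", x$facx_feedback,
      "| anchoring", x$anchoring_mode, "\n")
  invisible(x)
}

# name -> sam_scenario, the published knob settings
SCENARIO_PRESETS <- list(
  wild_type                   = list(),
  laser_ablation              = list(),
  clv3_knockout               = list(clv3_exogenous = 0, clv3_endogenous_scale = 0),
  clv3_knockdown_gradual      = list(clv3_exogenous = 0, clv3_endogenous_scale = 0.2),
  clv1_background             = list(receptor_background = 0.2),
  clv1_knockout               = list(receptor_background = 1),
  clv3_overexpression_low     = list(clv3_exogenous = 0.7, clv3_endogenous_scale = 1),
  clv3_overexpression_medium  = list(clv3_exogenous = 1, clv3_endogenous_scale = 1),
  clv3_overexpression_strong  = list(clv3_exogenous = 1.5, clv3_endogenous_scale = 1),
  clv3_promoter_wus           = list(clv3_exogenous = 0, clv3_endogenous_scale = 1,
                                     clv3_effect_sign = "activating"),
  wus_knockdown_mild          = list(wus_scale = 0.6),
  wus_knockdown_intermediate  = list(wus_scale = 0.4),
  wus_knockout                = list(wus_scale = 0),
  no_facx_feedback            = list(facx_feedback = FALSE),
  constant_anchoring          = list(anchoring_mode = "constant")
)

#' Published scenario parameter presets
#'
#' @param name One of \code{names(samsim:::SCENARIO_PRESETS)}; unknown names
#'   raise an error listing the valid presets.
#' @return A [sam_scenario()].
#' @export
scenario_preset <- function(name) {
  if (!name %in% names(SCENARIO_PRESETS)) {
    stop("unknown scenario preset '", name, "'. Valid presets: ",
         paste(names(SCENARIO_PRESETS), collapse = ", "))
  }
  do.call(sam_scenario, SCENARIO_PRESETS[[name]])
}
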