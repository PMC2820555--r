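#' Tiny deterministic test geometry
#'
#' A 12-cell, 3-layer dome (6/4/2 cells per layer) used as an oracle-sized
#' fixture: small enough that its Voronoi neighbour graph can be verified by
#' brute force, yet shaped like the production dome.
#'
#' @param seed Integer seed for the (small) centre jitter.
#' @return A \code{meristem_geometry} with 12 cells.
#' @export
toy_dome <- function(seed = 1L) {
  build_dome_geometry(n_layers = 3L, cells_per_layer_profile = c(6L, 4L, 2L),
                      competent_depth = 2L, seed = seed, jitter = 0.04)
}

#' Analytic single-cell decay reference
#'
#' Closed-form solution \code{u(t) = u0 * exp(-rate * t)} of pure linear decay
#' in one cell, the reference problem for integrator accuracy and
#' convergence-order measurements.
#'
#' @param rate Decay rate (>= 0).
#' @param u0 Initial value.
#' @param times Numeric vector of evaluation times.
#' @return Data frame with columns \code{time} and \code{value}.
#' @export
single_cell_decay_problem <- function(rate, u0 = 1, times = seq(0, 100, by = 1)) {
  if (rate < 0) stop("rate must be nonnegative.")
  data.frame(time = times, value = u0 * exp(-rate * times))
}

#' Single-cell geometry for integrator unit problems
#'
#' One isolated cell (no walls, competent, unit anchoring): diffusion vanishes
#' and the model reduces to its reaction ODEs.
#'
#' @return A \code{meristem_geometry} with a single cell.
#' @export
single_cell_geometry <- function() {
  structure(
    list(
      n = 1L, cell_ids = 1L,
      centres = cbind(x = 0, y = 0),
      edges = matrix(integer(0), ncol = 2L),
      layer = 1L, boundary = TRUE, competent = TRUE,
      anchoring = 1, tip_cell = 1L,
      meta = list(fixture = "single_cell")
    ),
    class = "meristem_geometry"
  )
}

#' Materialise the standard fixtures into a directory
#'
#' Writes the toy dome and the default production geometry as plain-text
#' tables, plus the analytic decay reference as a CSV, so external tools can
#' consume them. All content regenerates identically for a fixed seed.
#'
#' @param dir Target directory.
#' @param seed Integer seed.
#' @return \code{dir}, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geometry(toy_dome(seed), file.path(dir, "toy_dome"))
  write_geometry(build_dome_geometry(seed = seed),
                 file.path(dir, "default_dome"))
  utils::write.csv(single_cell_decay_problem(0.05, 1, seq(0, 200, by = 5)),
                   file.path(dir, "decay_reference.csv"), row.names = FALSE)
  invisible(dir)
}
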