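#' Threshold concentration fields into OC and SCD domains
#'
#' Discretises a state into the organizing centre (OC: cells whose WUS level
#' reaches \code{delta_wus} times the wild-type maximum) and the stem cell
#' domain (SCD: competent cells whose stemness reaches \code{delta_st} times
#' the wild-type maximum), with connected components on the cell graph,
#' centroids, the OC/SCD overlap, and a flag for whether the two domains touch
#' across at least one cell wall without being the same cells.
#'
#' Thresholds are relative to the wild-type equilibrium; the default fractions
#' are \code{delta_st = 0.21} and \code{delta_wus = 0.31}. The maximum
#' wild-type concentration is used as the reference level.
#'
#' @param state n x 5 state matrix on \code{geometry}.
#' @param wildtype_reference Either a state matrix on the same geometry (its
#'   per-species maxima are the reference levels; a different cell count is
#'   rejected), or a named numeric vector with elements \code{WUS} and
#'   \code{stemness} (needed e.g. on ablated geometries where the wild-type
#'   reference lives on the full geometry).
#' @param delta_st,delta_wus Threshold fractions.
#' @param geometry The \code{meristem_geometry} that \code{state} lives on.
#' @return An object of class \code{domain_labeling}.
#' @export
label_domains <- function(state, wildtype_reference, delta_st = 0.21,
                          delta_wus = 0.31, geometry) {
  if (nrow(state) != geometry$n) {
    stop("state and geometry disagree on the number of cells.")
  }
  if (is.matrix(wildtype_reference)) {
    if (nrow(wildtype_reference) != geometry$n) {
      stop("wildtype_reference lives on a different geometry; pass named ",
           "reference levels instead (c(WUS = ..., stemness = ...)).")
    }
    ref <- c(WUS = max(wildtype_reference[, "WUS"]),
             stemness = max(wildtype_reference[, "stemness"]))
  } else {
    ref <- wildtype_reference[c("WUS", "stemness")]
  }
  oc <- which(state[, "WUS"] >= delta_wus * ref[["WUS"]])
  scd <- which(geometry$competent &
                 state[, "stemness"] >= delta_st * ref[["stemness"]])
  centroid <- function(cells) {
    if (!length(cells)) return(NULL)
    colMeans(geometry$centres[cells, , drop = FALSE])
  }
  e <- geometry$edges
  touch <- any((e[, 1L] %in% oc & e[, 2L] %in% scd) |
                 (e[, 2L] %in% oc & e[, 1L] %in% scd))
  structure(
    list(
      oc_cells = oc, scd_cells = scd,
      oc_count = length(oc), scd_count = length(scd),
      oc_components = graph_components(geometry, oc),
      scd_components = graph_components(geometry, scd),
      oc_centroid = centroid(oc), scd_centroid = centroid(scd),
      overlap_cells = intersect(oc, scd),
      adjacency_flag = touch && !setequal(oc, scd),
      thresholds = c(delta_st = delta_st, delta_wus = delta_wus),
      reference = ref
    ),
    class = "domain_labeling"
  )
}

# Connected components of a cell subset on the cell graph, as a list of
# integer vectors (cell indices), largest first.
graph_components <- function(geometry, cells) {
  if (!length(cells)) return(list())
  sub <- igraph::induced_subgraph(cell_graph(geometry), cells)
  comp <- igraph::components(sub)
  out <- split(cells, comp$membership)
  out[order(-vapply(out, length, integer(1)))]
}

#' @export
print.domain_labeling <- function(x, ...) {
  cat("domain_labeling: OC", x$oc_count, "cells in",
      length(x$oc_components), "component(s); SCD", x$scd_count, "cells in",
      length(x$scd_components), "component(s); overlap",
      length(x$overlap_cells), "; adjacent:", x$adjacency_flag, "\n")
  invisible(x)
}

#' Summarise a parameter sweep of domain labelings
#'
#' @param labelings Named list of \code{domain_labeling}, one per sweep point;
#'   names are the knob values.
#' @param knob_values Numeric knob values (defaults to parsed names).
#' @return Data frame with one row per sweep point (\code{knob},
#'   \code{oc_count}, \code{scd_count}) carrying attributes
#'   \code{oc_constant} (all OC counts identical) and \code{scd_monotone}
#'   (SCD counts non-increasing or non-decreasing in the knob).
#' @export
summarize_sweep <- function(labelings, knob_values = NULL) {
  if (is.null(knob_values)) knob_values <- as.numeric(names(labelings))
  tab <- data.frame(
    knob = knob_values,
    oc_count = vapply(labelings, function(l) l$oc_count, integer(1)),
    scd_count = vapply(labelings, function(l) l$scd_count, integer(1)),
    row.names = NULL
  )
  tab <- tab[order(tab$knob), ]
  rownames(tab) <- NULL
  d <- diff(tab$scd_count)
  attr(tab, "oc_constant") <- length(unique(tab$oc_count)) == 1L
  attr(tab, "scd_monotone") <- all(d <= 0) || all(d >= 0)
  tab
}

# Per-snapshot species totals of a trajectory, as a time x species matrix.
trajectory_totals <- function(trajectory) {
  tot <- t(vapply(trajectory$snapshots, colSums, numeric(length(SPECIES))))
  rownames(tot) <- trajectory$times
  tot
}

#' Evaluate a qualitative outcome descriptor against a run
#'
#' Machine-checks the qualitative claims attached to the scenario catalogue:
#' domain expansion, transient collapse with recovery, permanent collapse,
#' OC/SCD coalescence, regeneration after ablation, overproliferation, and
#' wild-type patterning. Each check consumes only quantities computed by this
#' module (domain counts, centroids, components, species totals).
#'
#' @param descriptor A list with a \code{type} element (see
#'   [outcome_descriptor()]) and type-specific bounds.
#' @param analysis A \code{sam_run} (from [run_scenario()]) or a compatible
#'   list with elements \code{labelings} (time series of labelings for
#'   stage 2), \code{totals} (stage-2 species-total matrix),
#'   \code{wt} (wild-type reference labeling), \code{wt_totals},
#'   \code{geometry} (stage-2 geometry).
#' @return List with \code{pass} (logical), \code{type} and \code{evidence}
#'   (named numerics backing the verdict).
#' @export
check_outcome <- function(descriptor, analysis) {
  if (is.null(descriptor$type)) stop("descriptor needs a 'type' element.")
  labs <- analysis$labelings
  if (length(labs) == 0L) {
    return(list(pass = FALSE, type = descriptor$type,
                evidence = c(reason = "no data")))
  }
  final <- labs[[length(labs)]]
  wt <- analysis$wt
  g <- analysis$geometry
  ev <- c()
  pass <- switch(
    descriptor$type,
    patterned_wild_type = {
      scd_in_comp <- all(g$competent[final$scd_cells])
      tip_excluded <- !(g$tip_cell %in% final$oc_cells)
      scd_above <- !is.null(final$oc_centroid) && !is.null(final$scd_centroid) &&
        tip_distance(g, final$scd_centroid) < tip_distance(g, final$oc_centroid)
      ev <- c(oc_components = length(final$oc_components),
              scd_components = length(final$scd_components),
              overlap = length(final$overlap_cells),
              adjacent = final$adjacency_flag, scd_in_competent = scd_in_comp,
              tip_excluded = tip_excluded, scd_tipward = scd_above)
      length(final$oc_components) == 1L && length(final$scd_components) == 1L &&
        length(final$overlap_cells) == 0L && final$adjacency_flag &&
        scd_in_comp && tip_excluded && scd_above
    },
    patterned = {
      ev <- c(oc_components = length(final$oc_components),
              scd_components = length(final$scd_components),
              adjacent = final$adjacency_flag)
      length(final$oc_components) == 1L && length(final$scd_components) == 1L &&
        final$adjacency_flag
    },
    oc_expansion = {
      strict <- !isFALSE(descriptor$strict)
      shift <- tip_distance(g, wt$oc_centroid) -
        (if (is.null(final$oc_centroid)) Inf else tip_distance(g, final$oc_centroid))
      ev <- c(oc = final$oc_count, wt_oc = wt$oc_count,
              scd = final$scd_count, wt_scd = wt$scd_count,
              centroid_shift_tipward = shift)
      if (strict) {
        final$oc_count > wt$oc_count && shift > 0 &&
          final$scd_count > wt$scd_count
      } else {
        # tolerate sub-cell centroid jitter in the "no contraction" reading
        final$oc_count >= wt$oc_count && shift >= -0.05 &&
          final$scd_count >= wt$scd_count
      }
    },
    collapse_no_recovery = {
      frac <- descriptor$collapse_fraction %||% 0.05
      st_end <- analysis$totals[nrow(analysis$totals), "stemness"]
      w_end <- analysis$totals[nrow(analysis$totals), "WUS"]
      ev <- c(stemness_end_frac = st_end / analysis$wt_totals[["stemness"]],
              wus_end_frac = w_end / analysis$wt_totals[["WUS"]])
      all(ev < frac)
    },
    collapse_recovery = {
      lo <- descriptor$collapse_fraction %||% 0.2
      hi <- descriptor$recovery_fraction %||% 0.6
      st <- analysis$totals[, "stemness"] / analysis$wt_totals[["stemness"]]
      i_min <- which.min(st)
      ev <- c(stemness_min_frac = st[i_min],
              stemness_end_frac = st[length(st)])
      st[i_min] < lo && any(st[i_min:length(st)] > hi)
    },
    shrunken_equilibrium = {
      ev <- c(oc = final$oc_count, wt_oc = wt$oc_count,
              scd = final$scd_count, wt_scd = wt$scd_count)
      final$oc_count > 0L && final$scd_count > 0L &&
        final$oc_count < wt$oc_count && final$scd_count < wt$scd_count
    },
    coalescence = {
      bound <- descriptor$overlap_bound %||% 0.5
      joint <- union(final$oc_cells, final$scd_cells)
      ov_frac <- length(final$overlap_cells) /
        max(1L, min(final$oc_count, final$scd_count))
      ev <- c(overlap_fraction = ov_frac, joint = length(joint),
              wt_scd = wt$scd_count)
      ov_frac > bound && length(joint) > wt$scd_count
    },
    regeneration = {
      ev <- c(oc = final$oc_count, scd = final$scd_count)
      final$oc_count > 0L && final$scd_count > 0L
    },
    domains_shrink = {
      ev <- c(oc = final$oc_count, wt_oc = wt$oc_count,
              scd = final$scd_count, wt_scd = wt$scd_count)
      final$oc_count > 0L && final$scd_count > 0L &&
        final$oc_count <= wt$oc_count && final$scd_count <= wt$scd_count
    },
    domains_lost = {
      ev <- c(oc = final$oc_count, scd = final$scd_count)
      final$oc_count == 0L && final$scd_count == 0L
    },
    overproliferation = {
      majority <- descriptor$majority %||% 0.5
      all_comp <- all(which(g$competent) %in% final$scd_cells)
      ev <- c(all_competent_stem = all_comp,
              oc_fraction = final$oc_count / g$n)
      all_comp && final$oc_count > majority * g$n
    },
    stop("unknown descriptor type '", descriptor$type, "'.")
  )
  list(pass = isTRUE(pass), type = descriptor$type, evidence = ev)
}

#' Construct an outcome descriptor
#'
#' @param type One of \code{patterned_wild_type}, \code{patterned},
#'   \code{oc_expansion}, \code{collapse_no_recovery},
#'   \code{collapse_recovery}, \code{shrunken_equilibrium},
#'   \code{coalescence}, \code{regeneration}, \code{domains_shrink},
#'   \code{domains_lost}, \code{overproliferation}.
#' @param ... Type-specific bounds (e.g. \code{collapse_fraction},
#'   \code{recovery_fraction}, \code{overlap_bound}, \code{strict}).
#' @return A descriptor list.
#' @export
outcome_descriptor <- function(type, ...) {
  c(list(type = type), list(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
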