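# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched so package functions never perturb user code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build the static dome-shaped meristem section
#'
#' Constructs the two-dimensional artificial longitudinal section through a
#' shoot apical meristem used by the simulator: cell centres placed on
#' concentric semicircular layers over a half-disc (the flat base is the cut
#' through the stem), a Voronoi-wall adjacency graph, the outer-rim boundary
#' set, a competence mask marking the outermost layers, and a tip-peaked
#' anchoring profile. Centres are jittered so that the tessellation is generic;
#' the construction is deterministic for a fixed \code{seed}.
#'
#' Layers are counted from the outside in: layer 1 is the dome surface (radius
#' \code{n_layers - 1} in cell-spacing units) and layer \code{n_layers} is the
#' single central cell at the origin. The default profile places
#' \code{round(pi * r) + 1} cells on the layer of radius \code{r}, giving
#' roughly unit spacing everywhere.
#'
#' @param n_layers Number of concentric layers (>= 3).
#' @param cells_per_layer_profile Integer vector of cell counts per layer,
#'   outermost first. \code{NULL} (default) uses the arc-length profile above.
#' @param competent_depth Number of outermost layers whose cells are competent
#'   to acquire stemness (>= 1, < \code{n_layers}).
#' @param seed Integer seed for the centre jitter.
#' @param jitter Standard deviation of the isotropic Gaussian jitter applied to
#'   every centre except the tip and central cells, in cell-spacing units.
#' @param anchoring_shape Shape parameters passed to [build_anchoring()].
#' @return An object of class \code{meristem_geometry}; see
#'   [meristem_geometry] fields in the package vignette.
#' @export
build_dome_geometry <- function(n_layers = 9L,
                                cells_per_layer_profile = NULL,
                                competent_depth = 2L,
                                seed = 1L,
                                jitter = 0.08,
                                anchoring_shape = list()) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 3L) {
    stop("n_layers must be >= 3 (got ", n_layers, "): the dome needs at ",
         "least competent surface layers plus an interior.")
  }
  competent_depth <- as.integer(competent_depth)
  if (competent_depth < 1L || competent_depth >= n_layers) {
    stop("competent_depth must satisfy 1 <= competent_depth < n_layers.")
  }
  radii <- (n_layers - 1L):0L
  if (is.null(cells_per_layer_profile)) {
    cells_per_layer_profile <- pmax(1L, as.integer(round(pi * radii)) + 1L)
  }
  profile <- as.integer(cells_per_layer_profile)
  if (length(profile) != n_layers) {
    stop("cells_per_layer_profile must have one count per layer (",
         n_layers, " layers).")
  }
  if (any(profile < 1L)) {
    stop("degenerate layer profile: every layer needs at least one cell.")
  }

  layer <- rep.int(seq_len(n_layers), profile)
  x <- numeric(sum(profile))
  y <- numeric(sum(profile))
  angle <- numeric(sum(profile))
  idx <- 1L
  for (l in seq_len(n_layers)) {
    r <- radii[l]
    nl <- profile[l]
    if (r == 0L && nl > 1L) r <- 0.5 # spread a multi-cell innermost layer
    th <- if (nl == 1L) pi / 2 else seq(0, pi, length.out = nl)
    sel <- idx:(idx + nl - 1L)
    angle[sel] <- th
    x[sel] <- r * cos(th)
    y[sel] <- r * sin(th)
    idx <- idx + nl
  }
  n <- length(x)

  # tip: layer-1 cell nearest the apex angle, identified before jitter
  tip_cell <- which(layer == 1L)[which.min(abs(angle[layer == 1L] - pi / 2))]
  on_base <- abs(y) < 1e-9

  jit <- with_seed(seed, matrix(stats::rnorm(2L * n, sd = jitter), ncol = 2L))
  keep_fixed <- on_base | seq_len(n) == tip_cell
  jit[keep_fixed, ] <- 0
  centres <- cbind(x = x + jit[, 1L], y = y + jit[, 2L])

  edges <- voronoi_adjacency(centres)
  boundary <- layer == 1L | on_base
  # Stemness competence is restricted to the outer layers of the dome
  # surface; the flat base is the cut through the stem (rib tissue), so its
  # cells are never competent even where they touch layers 1-2.
  competent <- layer <= competent_depth & !on_base

  geom <- structure(
    list(
      n = n,
      cell_ids = seq_len(n),
      centres = centres,
      edges = edges,
      layer = layer,
      boundary = boundary,
      competent = competent,
      anchoring = rep(1, n),
      tip_cell = tip_cell,
      meta = list(n_layers = n_layers, profile = profile,
                  competent_depth = competent_depth, seed = as.integer(seed),
                  jitter = jitter)
    ),
    class = "meristem_geometry"
  )
  geom$anchoring <- do.call(build_anchoring, c(list(geom), anchoring_shape))
  if (!graph_connected(geom)) {
    stop("internal error: generated cell graph is not connected.")
  }
  geom
}

#' Voronoi-wall adjacency of a set of cell centres
#'
#' Two cells are adjacent when their Voronoi regions share a wall of positive
#' length. The wall between centres i and j lies on their perpendicular
#' bisector; parameterising that line, every third centre k contributes one
#' linear inequality, so the wall is a 1-D interval intersection and the test
#' is exact. Degenerate slivers shorter than \code{min_wall} (which arise from
#' nearly collinear centres along the flat base) are not counted as contacts.
#'
#' @param centres n x 2 matrix of cell centre coordinates.
#' @param min_wall Minimum wall length for a contact.
#' @param prefilter Centre pairs farther apart than this are skipped.
#' @return Two-column integer matrix of edges (i < j).
#' @export
voronoi_adjacency <- function(centres, min_wall = 0.05, prefilter = 3.0) {
  n <- nrow(centres)
  out <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    acc <- integer(0)
    for (j in (i + 1L):n) {
      dij <- centres[j, ] - centres[i, ]
      if (sum(dij^2) > prefilter^2) next
      if (voronoi_wall_length(centres, i, j) > min_wall) acc <- c(acc, j)
    }
    if (length(acc)) out[[i]] <- cbind(i, acc)
  }
  edges <- do.call(rbind, out)
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  dimnames(edges) <- NULL
  storage.mode(edges) <- "integer"
  edges
}

# Length of the Voronoi wall between centres i and j (0 when absent, Inf when
# unbounded). Points on the bisector are m + t*d with d the unit normal of
# (p_j - p_i); the condition |p - p_i| <= |p - p_k| is linear in t.
voronoi_wall_length <- function(centres, i, j) {
  pi_ <- centres[i, ]
  pj <- centres[j, ]
  m <- (pi_ + pj) / 2
  v <- pj - pi_
  d <- c(-v[2L], v[1L]) / sqrt(sum(v^2))
  lo <- -Inf
  hi <- Inf
  for (k in seq_len(nrow(centres))) {
    if (k == i || k == j) next
    pk <- centres[k, ]
    a <- 2 * sum(d * (pk - pi_))
    b <- sum(pk^2) - sum(pi_^2) - 2 * sum(m * (pk - pi_))
    if (abs(a) < 1e-12) {
      if (b < 0) return(0)
    } else if (a > 0) {
      hi <- min(hi, b / a)
    } else {
      lo <- max(lo, b / a)
    }
    if (lo >= hi) return(0)
  }
  hi - lo
}

#' Tip-anchored production-rate profile
#'
#' Returns the per-cell anchoring field that biases WUS/facX production toward
#' the meristem tip: a Gaussian decay in Euclidean distance from the tip cell,
#' lifted by a floor so every cell retains some production competence, and
#' normalised to 1 at the tip. With \code{mode = "constant"} every cell gets
#' the same value \code{level} (the no-anchoring model variant).
#'
#' @param geometry A [build_dome_geometry()] result.
#' @param mode \code{"gaussian"} (default) or \code{"constant"}.
#' @param width Gaussian width, in cell-spacing units.
#' @param floor Far-field fraction of the tip value, in [0, 1).
#' @param level Constant value used when \code{mode = "constant"}.
#' @param distance \code{"geodesic"} (graph distance from the tip cell,
#'   i.e. along the tissue; default) or \code{"euclidean"}.
#' @return Numeric vector, one nonnegative rate multiplier per cell.
#' @export
build_anchoring <- function(geometry, mode = c("gaussian", "constant"),
                            width = 3, floor = 0.05, level = 0.4,
                            distance = c("geodesic", "euclidean")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  if (mode == "constant") {
    return(rep(level, geometry$n))
  }
  d <- if (distance == "geodesic") {
    graph_distance_from(geometry, geometry$tip_cell)
  } else {
    tip <- geometry$centres[geometry$tip_cell, ]
    sqrt((geometry$centres[, 1L] - tip[1L])^2 +
           (geometry$centres[, 2L] - tip[2L])^2)
  }
  floor + (1 - floor) * exp(-d^2 / (2 * width^2))
}

#' Remove cells from a geometry (virtual laser ablation)
#'
#' Returns a new geometry containing only the surviving cells. Adjacency,
#' competence, anchoring and boundary markers are restricted; nothing is
#' re-normalised, so the hole left by the ablation simply has no cells and the
#' zero-flux condition applies along its rim. If the tip cell is removed, the
#' surviving cell nearest the old tip position becomes the distance reference.
#'
#' @param geometry A \code{meristem_geometry}.
#' @param cells_to_remove Integer indices (into the current cell ordering) of
#'   cells to ablate. May be empty.
#' @return A new \code{meristem_geometry}.
#' @export
ablate <- function(geometry, cells_to_remove) {
  cells_to_remove <- unique(as.integer(cells_to_remove))
  if (length(cells_to_remove) == 0L) return(geometry)
  if (!all(cells_to_remove %in% seq_len(geometry$n))) {
    stop("cells_to_remove contains indices outside the geometry.")
  }
  keep <- setdiff(seq_len(geometry$n), cells_to_remove)
  if (length(keep) == 0L) {
    stop("cannot ablate every cell: the remaining tissue would be empty.")
  }
  remap <- integer(geometry$n)
  remap[keep] <- seq_along(keep)
  e <- geometry$edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  storage.mode(e) <- "integer"

  new_tip <- if (geometry$tip_cell %in% keep) {
    remap[geometry$tip_cell]
  } else {
    old_tip <- geometry$centres[geometry$tip_cell, ]
    d2 <- (geometry$centres[keep, 1L] - old_tip[1L])^2 +
      (geometry$centres[keep, 2L] - old_tip[2L])^2
    which.min(d2)
  }

  structure(
    list(
      n = length(keep),
      cell_ids = geometry$cell_ids[keep],
      centres = geometry$centres[keep, , drop = FALSE],
      edges = e,
      layer = geometry$layer[keep],
      boundary = geometry$boundary[keep],
      competent = geometry$competent[keep],
      anchoring = geometry$anchoring[keep],
      tip_cell = new_tip,
      meta = c(geometry$meta, list(ablated = geometry$cell_ids[cells_to_remove]))
    ),
    class = "meristem_geometry"
  )
}

#' @export
print.meristem_geometry <- function(x, ...) {
  cat("meristem_geometry:", x$n, "cells,", nrow(x$edges), "walls,",
      max(x$layer), "layers;", sum(x$competent), "competent,",
      sum(x$boundary), "boundary; tip cell", x$tip_cell, "\n")
  invisible(x)
}

# igraph view of the cell graph (keeps isolated cells as vertices)
cell_graph <- function(geometry) {
  g <- igraph::make_empty_graph(n = geometry$n, directed = FALSE)
  igraph::add_edges(g, t(geometry$edges))
}

graph_connected <- function(geometry) {
  igraph::is_connected(cell_graph(geometry))
}

# Graph-geodesic distance (edge count) from one cell to all cells.
graph_distance_from <- function(geometry, from) {
  as.vector(igraph::distances(cell_graph(geometry), v = from))
}

#' Euclidean distance of points from the meristem tip
#'
#' @param geometry A \code{meristem_geometry}.
#' @param points Matrix (k x 2) of coordinates; defaults to all cell centres.
#' @return Numeric vector of distances from the tip cell centre.
#' @export
tip_distance <- function(geometry, points = geometry$centres) {
  points <- rbind(points)
  tip <- geometry$centres[geometry$tip_cell, ]
  sqrt((points[, 1L] - tip[1L])^2 + (points[, 2L] - tip[2L])^2)
}

#' Write / read a geometry as plain-text tables
#'
#' The geometry is stored as two tab-separated tables in \code{dir}:
#' \code{cells.tsv} (id, x, y, layer, competent, boundary, anchoring, is_tip)
#' and \code{edges.tsv} (id_a, id_b).
#'
#' @param geometry A \code{meristem_geometry}.
#' @param dir Directory (created if needed).
#' @return \code{write_geometry}: the directory, invisibly.
#'   \code{read_geometry}: the reconstructed \code{meristem_geometry}.
#' @export
write_geometry <- function(geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- data.frame(
    id = geometry$cell_ids,
    x = geometry$centres[, 1L],
    y = geometry$centres[, 2L],
    layer = geometry$layer,
    competent = as.integer(geometry$competent),
    boundary = as.integer(geometry$boundary),
    anchoring = geometry$anchoring,
    is_tip = as.integer(seq_len(geometry$n) == geometry$tip_cell)
  )
  edges <- data.frame(id_a = geometry$cell_ids[geometry$edges[, 1L]],
                      id_b = geometry$cell_ids[geometry$edges[, 2L]])
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(dir) {
  cells <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                             sep = "\t")
  edges <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                             sep = "\t")
  idx <- match(c(edges$id_a, edges$id_b), cells$id)
  e <- matrix(idx, ncol = 2L)
  storage.mode(e) <- "integer"
  structure(
    list(
      n = nrow(cells),
      cell_ids = cells$id,
      centres = cbind(x = cells$x, y = cells$y),
      edges = e,
      layer = cells$layer,
      boundary = cells$boundary == 1L,
      competent = cells$competent == 1L,
      anchoring = cells$anchoring,
      tip_cell = which(cells$is_tip == 1L)[1L],
      meta = list(source = dir)
    ),
    class = "meristem_geometry"
  )
}
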