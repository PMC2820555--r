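# Shared fixtures and a lazily computed wild-type equilibrium so the
# expensive stage-1 run happens at most once per test session.

.test_cache <- new.env(parent = emptyenv())

default_dome <- function() {
  if (is.null(.test_cache$dome)) .test_cache$dome <- build_dome_geometry(seed = 1)
  .test_cache$dome
}

# Wild-type stage-1 equilibrium at the package defaults, seed 1.
wt_context <- function() {
  if (is.null(.test_cache$wt)) {
    g <- default_dome()
    p <- sam_params()
    cache <- wildtype_stage1(g, p, seed = 1, equilibrium_tol = 1e-6)
    .test_cache$wt <- list(geometry = g, params = p, cache = cache,
                           state = cache$trajectory$final)
  }
  .test_cache$wt
}

run_catalogue_scenario <- function(name, seed = 1, ...) {
  ctx <- wt_context()
  run_scenario(scenario_catalogue()[[name]], ctx$geometry, ctx$params,
               seed = seed, stage1_cache = ctx$cache,
               equilibrium_tol = 1e-6, snapshot_every = 250, ...)
}

# Independent Voronoi-adjacency oracle: assign a dense grid of sample points
# to their nearest centre; two cells are neighbours when four-connected
# sample pixels map to the two different centres. Used on tiny geometries.
grid_voronoi_oracle <- function(centres, h = 0.02, pad = 1.5) {
  xs <- seq(min(centres[, 1]) - pad, max(centres[, 1]) + pad, by = h)
  ys <- seq(min(centres[, 2]) - pad, max(centres[, 2]) + pad, by = h)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  d2 <- outer(grid[, 1], centres[, 1], "-")^2 +
    outer(grid[, 2], centres[, 2], "-")^2
  lab <- matrix(max.col(-d2, ties.method = "first"),
                nrow = length(xs), ncol = length(ys))
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ])),
    cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  counts <- table(paste(pairs[, 1], pairs[, 2]))
  # a genuine wall produces many boundary pixels; corner contacts only a few
  keep <- names(counts)[counts >= 4]
  do.call(rbind, lapply(strsplit(keep, " "), as.integer))
}

edge_set <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

# Brute-force flood fill for connected components of a cell subset.
flood_components <- function(geometry, cells) {
  remaining <- cells
  nbrs <- lapply(seq_len(geometry$n), function(i) {
    e <- geometry$edges
    c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
  })
  comps <- list()
  while (length(remaining)) {
    frontier <- remaining[1]
    comp <- integer(0)
    while (length(frontier)) {
      comp <- union(comp, frontier)
      frontier <- setdiff(
        intersect(unique(unlist(nbrs[frontier])), remaining), comp)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(-vapply(comps, length, integer(1)))]
}
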