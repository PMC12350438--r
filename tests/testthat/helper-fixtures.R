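# Shared fixtures and the independent shortest-path oracle.

# Brute-force multi-source cost distance over the explicit 8-neighbour
# graph, via igraph. Edge weight L * (cost_a + cost_b) / 2 with L = 1
# (orthogonal) or sqrt(2) (diagonal). Independent of the package's own
# Dijkstra implementation.
oracleCostDistance <- function(values, sources) {
  nr <- nrow(values); nc <- ncol(values)
  idx <- function(r, c) (c - 1L) * nr + r
  edges <- list(); weights <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.finite(values[r, c])) next
    for (dr in -1:1) for (dc in 0:1) {
      # enumerate each undirected edge once
      if (dc == 0 && dr != 1) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.finite(values[r2, c2])) next
      L <- if (dr != 0 && dc != 0) sqrt(2) else 1
      edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r2, c2))
      weights <- c(weights, L * (values[r, c] + values[r2, c2]) / 2)
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))),
                           weight = weights)
  src <- idx(sources$row, sources$col)
  dmat <- igraph::distances(g, v = src, algorithm = "dijkstra")
  d <- apply(dmat, 2L, min)
  out <- matrix(d, nr, nc)
  out[!is.finite(values)] <- Inf
  out
}

# Random cost raster with random NoData cells; sources guaranteed passable.
randomRasterCase <- function(seed, maxDim = 7L) {
  set.seed(seed)
  nr <- sample(2:maxDim, 1); nc <- sample(2:maxDim, 1)
  v <- matrix(runif(nr * nc), nr, nc)
  n_nodata <- sample(0:floor(nr * nc / 4), 1)
  if (n_nodata > 0) v[sample(nr * nc, n_nodata)] <- Inf
  passable <- which(is.finite(v), arr.ind = TRUE)
  if (nrow(passable) < 2) return(NULL)
  ns <- sample(1:min(3, nrow(passable)), 1)
  pick <- passable[sample(nrow(passable), ns), , drop = FALSE]
  list(raster = costRaster(v),
       sources = data.frame(row = pick[, 1], col = pick[, 2]))
}

octile <- function(dr, dc) pmax(abs(dr), abs(dc)) +
  (sqrt(2) - 1) * pmin(abs(dr), abs(dc))

# Run snapping + dedup + tracing + delineation on a generated invasion.
runSyntheticPipeline <- function(sim, threshold, robustDef = 10) {
  snapping <- snapRecords(sim$records, sim$cost)
  cells <- dedupeRecords(sim$records, snapping)
  paths <- runSequential(sim$cost, cells[!cells$impassable, , drop = FALSE])
  partition <- delineate(paths, sim$records, snapping,
                         threshold = threshold, robustDef = robustDef)
  list(snapping = snapping, cells = cells, paths = paths,
       partition = partition,
       rates = populationRates(partition, sim$records))
}
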