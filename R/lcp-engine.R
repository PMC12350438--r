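# Sequential least-cost path engine: accumulated-cost surfaces, path
# traceback, and the annual time-step loop.

.SQRT2 <- sqrt(2)

#' Distance-weighted step cost between two neighbouring cells
#'
#' The landscape graph uses "geometric" accumulation: the cost of moving
#' between adjacent cells is the mean of the two cell costs, weighted by the
#' step length -- 1 cell unit for orthogonal moves, sqrt(2) for diagonal
#' moves. Step lengths are in cell units, not metres, so accumulated costs
#' are dimensionless (cost x cell units).
#'
#' @param cost_a,cost_b the two cell costs (non-negative; `Inf` =
#'   impassable)
#' @param move `"orthogonal"` or `"diagonal"`
#' @return the step cost; `Inf` if either cell is impassable
#' @examples
#' stepCost(1, 1, "diagonal")       # sqrt(2)
#' stepCost(0.2, 0.6, "orthogonal") # 0.4
#' @export
stepCost <- function(cost_a, cost_b, move = c("orthogonal", "diagonal")) {
  move <- match.arg(move)
  if (any(c(cost_a, cost_b) < 0)) stop("negative cell cost")
  L <- if (move == "diagonal") .SQRT2 else 1
  L * (cost_a + cost_b) / 2
}

#' Accumulated-cost surface from a set of source cells
#'
#' Multi-source shortest-path (Dijkstra) over the 8-connected grid graph
#' with [stepCost()] edge weights: for every cell, the minimum summed step
#' cost over all paths from any source. Source cells have cost 0; cells
#' unreachable without crossing an impassable cell have `Inf`.
#'
#' One optimal path per cell can be reconstructed from the returned surface
#' with [tracePath()]; no explicit predecessor grid is stored because the
#' surface determines the (tie-broken) traceback.
#'
#' @param cost a [CostRaster-class]
#' @param sources matrix/data.frame with columns `row`, `col` (1-based), all
#'   on passable cells
#' @return numeric matrix of accumulated costs, same shape as the raster
#' @examples
#' r <- costRaster(matrix(1, 5, 5))
#' acc <- accumulate(r, data.frame(row = 1, col = 1))
#' acc[1, 4]  # 3 orthogonal steps -> 3
#' acc[3, 3]  # 2 diagonal steps -> 2 * sqrt(2)
#' @export
accumulate <- function(cost, sources) {
  stopifnot(is(cost, "CostRaster"))
  sources <- as.data.frame(sources)
  if (!nrow(sources)) stop("no source cells")
  d <- dim(cost@values)
  if (any(sources$row < 1 | sources$row > d[1] |
          sources$col < 1 | sources$col > d[2]))
    stop("source cell outside raster")
  idx <- .cellIndex(sources$row, sources$col, d[1])
  passable <- is.finite(cost@values)[idx]
  if (!any(passable)) stop("all source cells are impassable")
  .gridDijkstra(cost@values, as.integer(unique(idx[passable])))
}

#' Trace one least-cost path back through an accumulated-cost surface
#'
#' Walks from the target to a source cell along optimal-predecessor edges:
#' a neighbour `p` of cell `c` is an optimal predecessor when
#' `acc[p] + stepCost(p, c) == acc[c]` (within tolerance). When several
#' optimal predecessors exist, the one with strictly smaller accumulated
#' cost and then the smallest `(row, col)` lexicographic index is tried
#' first, which makes geometries reproducible. Dead ends -- possible only
#' inside zero-cost plateaus, where optimal-predecessor edges can form
#' cycles -- are resolved by backtracking (depth-first search), so a path
#' is found whenever one exists.
#'
#' @param cost a [CostRaster-class]
#' @param acc accumulated-cost surface from [accumulate()]
#' @param target length-2 integer vector `(row, col)` with finite
#'   accumulated cost
#' @param sources optional matrix/data.frame of the source cells used for
#'   `acc`; the walk terminates on any of them. Default: all cells with
#'   accumulated cost 0 (equivalent except on zero-cost corridors, where
#'   naming the sources explicitly is required for a correct endpoint).
#' @param tol relative tolerance for recognising an optimal predecessor
#' @return integer matrix with columns `row`, `col`, ordered from the
#'   source cell to the target cell
#' @export
tracePath <- function(cost, acc, target, sources = NULL, tol = 1e-9) {
  stopifnot(is(cost, "CostRaster"))
  v <- cost@values
  d <- dim(v)
  r0 <- as.integer(target[1]); c0 <- as.integer(target[2])
  if (!is.finite(acc[r0, c0]))
    stop("target cell is unreachable; no path exists")
  if (is.null(sources)) {
    src_idx <- which(acc == 0)
  } else {
    sources <- as.data.frame(sources)
    src_idx <- .cellIndex(sources$row, sources$col, d[1])
  }
  is_source <- logical(length(v))
  is_source[src_idx] <- TRUE

  predecessors <- function(r, c) {
    nr_ <- r + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    nc_ <- c + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    keep <- nr_ >= 1L & nr_ <= d[1] & nc_ >= 1L & nc_ <= d[2]
    nr_ <- nr_[keep]; nc_ <- nc_[keep]
    L <- ifelse(nr_ != r & nc_ != c, .SQRT2, 1)
    ni <- .cellIndex(nr_, nc_, d[1])
    w <- L * (v[r, c] + v[ni]) / 2
    ok <- is.finite(acc[ni]) & acc[ni] <= acc[r, c] &
      abs(acc[ni] + w - acc[r, c]) <= tol * max(1, acc[r, c])
    cand <- which(ok)
    # strictly closer predecessors first, then lexicographic (row, col)
    cand <- cand[order(acc[ni[cand]] >= acc[.cellIndex(r, c, d[1])],
                       nr_[cand], nc_[cand])]
    ni[cand]
  }

  start <- .cellIndex(r0, c0, d[1])
  visited <- logical(length(v))
  visited[start] <- TRUE
  # DFS with explicit stack of (cell, candidate list, position)
  stack <- list(list(cell = start, cand = NULL, pos = 0L))
  if (is_source[start]) stack[[1]]$done <- TRUE
  repeat {
    top <- stack[[length(stack)]]
    if (isTRUE(top$done)) break
    if (is.null(top$cand)) {
      rc <- .indexToCell(top$cell, d[1])
      top$cand <- predecessors(rc$row, rc$col)
      top$pos <- 0L
    }
    advanced <- FALSE
    while (top$pos < length(top$cand)) {
      top$pos <- top$pos + 1L
      nxt <- top$cand[top$pos]
      if (visited[nxt]) next
      visited[nxt] <- TRUE
      stack[[length(stack)]] <- top
      stack[[length(stack) + 1L]] <-
        list(cell = nxt, cand = NULL, pos = 0L, done = is_source[nxt])
      advanced <- TRUE
      break
    }
    if (!advanced) {
      stack[[length(stack)]] <- NULL  # dead end: backtrack
      if (!length(stack))
        stop("traceback failed at cell (", r0, ", ", c0,
             "); inconsistent surface")
    }
  }
  cells <- rev(vapply(stack, function(s) s$cell, integer(1)))
  path <- as.matrix(.indexToCell(cells, d[1]))
  colnames(path) <- c("row", "col")
  path
}

.emptyPathsDF <- function() {
  data.frame(path_id = integer(0), year = integer(0),
             source_row = integer(0), source_col = integer(0),
             source_year = integer(0),
             target_row = integer(0), target_col = integer(0),
             accumulated_cost = numeric(0))
}

.emptyIsolatedDF <- function() {
  data.frame(row = integer(0), col = integer(0), year = integer(0),
             reason = character(0))
}

#' Trace least-cost paths for one annual time step
#'
#' Given the cell records already known before year `t` and the records new
#' in year `t`, accumulates costs from all known (passable) cells at once
#' and then extracts the least-cost path for each new record individually.
#' A new record's path therefore always ends at the nearest (lowest
#' accumulated cost) previously known record. Records whose cell is
#' impassable or cut off by barriers yield no path and are reported as
#' isolated -- an outcome, not an error.
#'
#' @param cost a [CostRaster-class]
#' @param known data.frame of cell records with `row`, `col`, `year`, all
#'   strictly earlier than `year`
#' @param new data.frame of cell records with `row`, `col`, `year == year`
#' @param year the time step (the new records' observation year)
#' @return list with `paths` (data.frame as in [PathSet-class]), `geometry`
#'   (list of cell matrices) and `isolated` (data.frame)
#' @export
traceYear <- function(cost, known, new, year) {
  stopifnot(is(cost, "CostRaster"))
  known <- as.data.frame(known); new <- as.data.frame(new)
  if (nrow(known) && any(known$year >= year))
    stop("known records must predate the time step")
  if (nrow(new) && any(new$year != year))
    stop("new records must carry the time-step year")
  d <- dim(cost@values)
  iso <- .emptyIsolatedDF()
  paths <- .emptyPathsDF()
  geoms <- list()
  kpass <- is.finite(cost@values)[.cellIndex(known$row, known$col, d[1])]
  if (!nrow(known) || !any(kpass)) {
    if (nrow(new))
      iso <- data.frame(row = new$row, col = new$col, year = year,
                        reason = "no passable earlier record")
    return(list(paths = paths, geometry = geoms, isolated = iso))
  }
  ksub <- known[kpass, , drop = FALSE]
  acc <- accumulate(cost, ksub[, c("row", "col")])
  # nearest known record per cell: map source cell -> earliest year there
  kidx <- .cellIndex(ksub$row, ksub$col, d[1])
  kyear <- vapply(split(ksub$year, kidx), min, numeric(1))
  # deterministic target order: by cell index
  new <- new[order(.cellIndex(new$row, new$col, d[1])), , drop = FALSE]
  for (i in seq_len(nrow(new))) {
    r <- new$row[i]; c <- new$col[i]
    if (is.infinite(cost@values[r, c])) {
      iso <- rbind(iso, data.frame(row = r, col = c, year = year,
                                   reason = "impassable cell"))
      next
    }
    if (!is.finite(acc[r, c])) {
      iso <- rbind(iso, data.frame(row = r, col = c, year = year,
                                   reason = "surrounded by barrier"))
      next
    }
    g <- tracePath(cost, acc, c(r, c), sources = ksub[, c("row", "col")])
    src <- g[1, ]
    paths <- rbind(paths, data.frame(
      path_id = NA_integer_, year = year,
      source_row = src[1], source_col = src[2],
      source_year = as.integer(kyear[[as.character(.cellIndex(src[1], src[2], d[1]))]]),
      target_row = r, target_col = c,
      accumulated_cost = acc[r, c]))
    geoms[[length(geoms) + 1L]] <- g
  }
  list(paths = paths, geometry = geoms, isolated = iso)
}

#' Sequential least-cost modelling over annual time steps
#'
#' Iterates observation years in ascending order. For each year `t`, the
#' sources are all cell records observed before `t` and the targets are the
#' records new in `t`; each target is traced back to its nearest earlier
#' record via [traceYear()]. Records of the globally earliest year are
#' seeds and receive no incoming path. The result is the complete dispersal
#' network -- deliberately unfiltered, including paths with extremely high
#' accumulated cost, which are only removed during population delineation.
#'
#' By default records of the same year never connect to each other, which
#' makes the output invariant to record ordering within a year. With
#' `chainWithinYear = TRUE` each traced target immediately becomes a source
#' for the remaining targets of its year (an alternative, order-dependent
#' reading).
#'
#' @param cost a [CostRaster-class]
#' @param cellRecords deduplicated cell records from [dedupeRecords()]
#' @param chainWithinYear logical; see Details
#' @param verbose log per-year path counts via `message()`
#' @return a [PathSet-class]
#' @export
runSequential <- function(cost, cellRecords, chainWithinYear = FALSE,
                          verbose = FALSE) {
  stopifnot(is(cost, "CostRaster"))
  cr <- as.data.frame(cellRecords)
  if (!nrow(cr)) stop("no cell records")
  d <- dim(cost@values)
  years <- sort(unique(cr$year))
  seed_year <- years[1]
  seeds <- cr[cr$year == seed_year, c("row", "col", "year")]
  rownames(seeds) <- NULL
  all_paths <- .emptyPathsDF()
  all_geoms <- list()
  all_iso <- .emptyIsolatedDF()
  # seeds on impassable cells can never connect to anything
  seed_imp <- is.infinite(cost@values)[.cellIndex(seeds$row, seeds$col, d[1])]
  if (any(seed_imp))
    all_iso <- rbind(all_iso, data.frame(
      row = seeds$row[seed_imp], col = seeds$col[seed_imp],
      year = seed_year, reason = "impassable cell"))
  for (t in years[-1]) {
    known <- cr[cr$year < t, c("row", "col", "year"), drop = FALSE]
    new <- cr[cr$year == t, , drop = FALSE]
    if (chainWithinYear) {
      new <- new[order(.cellIndex(new$row, new$col, d[1])), , drop = FALSE]
      res <- list(paths = .emptyPathsDF(), geometry = list(),
                  isolated = .emptyIsolatedDF())
      for (i in seq_len(nrow(new))) {
        one <- traceYear(cost, known, new[i, , drop = FALSE], t)
        res$paths <- rbind(res$paths, one$paths)
        res$geometry <- c(res$geometry, one$geometry)
        res$isolated <- rbind(res$isolated, one$isolated)
        # traced target becomes a source for the rest of its year; it is
        # recorded as year t - 1 so the strictly-earlier precondition holds
        known <- rbind(known,
                       data.frame(row = new$row[i], col = new$col[i],
                                  year = t - 1L))
      }
    } else {
      res <- traceYear(cost, known, new, t)
    }
    if (verbose)
      message("year ", t, ": ", nrow(res$paths), " path(s), ",
              nrow(res$isolated), " isolated")
    all_paths <- rbind(all_paths, res$paths)
    all_geoms <- c(all_geoms, res$geometry)
    all_iso <- rbind(all_iso, res$isolated)
  }
  if (nrow(all_paths)) all_paths$path_id <- seq_len(nrow(all_paths))
  rownames(all_paths) <- NULL
  rownames(all_iso) <- NULL
  new("PathSet", paths = all_paths, geometry = all_geoms,
      isolated = all_iso, seeds = seeds)
}

#' Re-derive a path's accumulated cost from its geometry
#'
#' Sums [stepCost()] over consecutive cells of the geometry;
#' self-consistency check for traced paths.
#'
#' @param cost a [CostRaster-class]
#' @param geometry integer matrix with columns `row`, `col`
#' @return numeric accumulated cost
#' @export
recostPath <- function(cost, geometry) {
  stopifnot(is(cost, "CostRaster"))
  v <- cost@values
  if (nrow(geometry) < 2L) return(0)
  total <- 0
  for (i in seq_len(nrow(geometry) - 1L)) {
    a <- geometry[i, ]; b <- geometry[i + 1L, ]
    dr <- abs(a[1] - b[1]); dc <- abs(a[2] - b[2])
    if (max(dr, dc) != 1L) stop("geometry cells are not 8-neighbours")
    move <- if (dr == 1L && dc == 1L) "diagonal" else "orthogonal"
    total <- total + stepCost(v[a[1], a[2]], v[b[1], b[2]], move)
  }
  total
}
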