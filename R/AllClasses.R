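#' CostRaster: a traversal-cost grid with georeferencing
#'
#' A single-band raster of per-cell traversal costs in a projected
#' (equal-distance) coordinate reference system. Impassable cells (NoData in
#' the source raster, e.g. ocean) are stored as `Inf` so that the
#' path-finding algorithm can never enter them. Row 1 is the top of the
#' grid; cells are square with side `cellsize` metres. Cell `(r, c)` covers
#' the half-open box `[xmin + (c-1)*cs, xmin + c*cs) x (ymax - r*cs,
#' ymax - (r-1)*cs]` so that a point on a shared edge belongs to the cell to
#' its right/below in index space.
#'
#' After standard preparation ([invertRescale()]) all finite costs lie in
#' `[0, 1]`; user-supplied pre-made cost rasters may hold any non-negative
#' finite values. Costs of exactly 0 are allowed (zero-cost corridors), so a
#' path may accumulate zero cost over a nonzero distance.
#'
#' @slot values numeric matrix of non-negative costs, `Inf` = impassable.
#' @slot xmin x coordinate of the left edge of the grid (metres).
#' @slot ymax y coordinate of the top edge of the grid (metres).
#' @slot cellsize cell side length (metres), strictly positive.
#' @slot crs free-text identifier of the projected CRS (e.g. "ESRI:102031");
#'   purely descriptive, never parsed.
#'
#' @seealso [costRaster()], [loadCost()], [invertRescale()], [accumulate()]
#' @name CostRaster-class
#' @rdname CostRaster-class
#' @exportClass CostRaster
setClass("CostRaster",
  representation(
    values   = "matrix",
    xmin     = "numeric",
    ymax     = "numeric",
    cellsize = "numeric",
    crs      = "character"
  ),
  prototype(
    values = matrix(numeric(0), 0, 0),
    xmin = 0, ymax = 0, cellsize = 1, crs = NA_character_
  )
)

setValidity("CostRaster", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
  if (anyNA(v)) msgs <- c(msgs, "'values' must not contain NA; encode impassable cells as Inf")
  if (is.numeric(v) && !anyNA(v) && length(v) && any(v < 0))
    msgs <- c(msgs, "costs must be non-negative")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) || object@cellsize <= 0)
    msgs <- c(msgs, "'cellsize' must be a single positive number")
  if (length(object@xmin) != 1L || length(object@ymax) != 1L)
    msgs <- c(msgs, "'xmin' and 'ymax' must be single numbers")
  if (length(msgs)) msgs else TRUE
})

#' PathSet: the dispersal network of sequential least-cost paths
#'
#' The result of [runSequential()] (or a single [traceYear()] step): one
#' least-cost path per non-seed, reachable cell record, tracing the record
#' back to the nearest previously known record on the cost surface. The set
#' is unfiltered -- it deliberately includes paths with extremely high
#' accumulated cost, which are only removed later by [filterPaths()] during
#' population delineation.
#'
#' @slot paths data.frame with one row per path: `path_id`, `year` (the
#'   target's observation year, i.e. the time step), `source_row`,
#'   `source_col`, `source_year`, `target_row`, `target_col`,
#'   `accumulated_cost` (dimensionless, cost x cell units).
#' @slot geometry list of integer matrices (columns `row`, `col`), the cell
#'   sequence from source to target; consecutive cells are 8-neighbours.
#' @slot isolated data.frame of cell records for which no path could be
#'   traced (impassable cell or surrounded by a barrier): `row`, `col`,
#'   `year`, `reason`.
#' @slot seeds data.frame of earliest-year cell records, which have no
#'   incoming path by construction: `row`, `col`, `year`.
#'
#' @seealso [runSequential()], [pathTable()], [pathCosts()], [delineate()]
#' @name PathSet-class
#' @rdname PathSet-class
#' @exportClass PathSet
setClass("PathSet",
  representation(
    paths    = "data.frame",
    geometry = "list",
    isolated = "data.frame",
    seeds    = "data.frame"
  )
)

setValidity("PathSet", function(object) {
  p <- object@paths
  need <- c("path_id", "year", "source_row", "source_col", "source_year",
            "target_row", "target_col", "accumulated_cost")
  msgs <- character(0)
  if (!all(need %in% names(p)))
    msgs <- c(msgs, paste0("'paths' must have columns: ", paste(need, collapse = ", ")))
  if (length(object@geometry) != nrow(p))
    msgs <- c(msgs, "one geometry per path required")
  if (nrow(p)) {
    if (any(p$accumulated_cost < 0)) msgs <- c(msgs, "accumulated costs must be non-negative")
    if (any(p$source_year >= p$year)) msgs <- c(msgs, "source_year must precede the path year")
  }
  if (length(msgs)) msgs else TRUE
})

#' PopulationPartition: assignment of paths and records to populations
#'
#' The result of [delineate()]: paths retained under the accumulated-cost
#' threshold are grouped into connected components by shared endpoint cells;
#' records inherit the population of any retained path endpoint in their
#' cell, or remain unassigned. Populations are classified `robust` or
#' `sparse` by the median raw-observation count per calendar year.
#'
#' @slot pathPopulation integer vector, one per path in the originating
#'   [PathSet-class]; `NA` for paths removed by the threshold.
#' @slot recordPopulation data.frame `record_id`, `population` (`NA` =
#'   unassigned).
#' @slot populations data.frame with one row per population: `population`,
#'   `name`, `label`, `first_year`, `latest_year`, `n_records`,
#'   `median_per_year`, `status` ("robust"/"sparse").
#' @slot cellPopulation data.frame `row`, `col`, `population` for every
#'   retained path endpoint cell.
#' @slot threshold numeric, the accumulated-cost threshold applied.
#' @slot robustDef numeric, the robust-population definition (minimum median
#'   observations per year).
#'
#' @seealso [delineate()], [populationTable()], [recordAssignments()]
#' @name PopulationPartition-class
#' @rdname PopulationPartition-class
#' @exportClass PopulationPartition
setClass("PopulationPartition",
  representation(
    pathPopulation   = "integer",
    recordPopulation = "data.frame",
    populations      = "data.frame",
    cellPopulation   = "data.frame",
    threshold        = "numeric",
    robustDef        = "numeric"
  )
)

setValidity("PopulationPartition", function(object) {
  msgs <- character(0)
  pops <- object@populations
  need <- c("population", "name", "first_year", "latest_year",
            "n_records", "median_per_year", "status")
  if (!all(need %in% names(pops)))
    msgs <- c(msgs, paste0("'populations' must have columns: ", paste(need, collapse = ", ")))
  if (nrow(pops) && !all(pops$status %in% c("robust", "sparse")))
    msgs <- c(msgs, "status must be 'robust' or 'sparse'")
  rp <- object@recordPopulation
  if (!all(c("record_id", "population") %in% names(rp)))
    msgs <- c(msgs, "'recordPopulation' must have columns record_id, population")
  if (length(msgs)) msgs else TRUE
})
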