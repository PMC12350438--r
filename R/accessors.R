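# Accessors and show methods for the S4 containers.

#' @describeIn CostRaster-class number of rows / columns of the grid
#' @param x,object a `CostRaster`
#' @export
setMethod("dim", "CostRaster", function(x) dim(x@values))

#' Cost values of a CostRaster
#'
#' Returns the cost matrix (`Inf` marks impassable cells). Row 1 is the top
#' of the grid.
#'
#' @param x a [CostRaster-class]
#' @return numeric matrix
#' @export
costValues <- function(x) {
  stopifnot(is(x, "CostRaster"))
  x@values
}

#' Cell size of a CostRaster in metres
#' @param x a [CostRaster-class]
#' @return single numeric
#' @export
cellSize <- function(x) {
  stopifnot(is(x, "CostRaster"))
  x@cellsize
}

#' CRS identifier of a CostRaster
#' @param x a [CostRaster-class]
#' @return character scalar (may be `NA` when unknown)
#' @export
crsId <- function(x) {
  stopifnot(is(x, "CostRaster"))
  x@crs
}

#' Logical mask of impassable cells
#' @param x a [CostRaster-class]
#' @return logical matrix, `TRUE` where the cell cannot be traversed
#' @export
impassableMask <- function(x) {
  stopifnot(is(x, "CostRaster"))
  is.infinite(x@values)
}

setMethod("show", "CostRaster", function(object) {
  d <- dim(object@values)
  fin <- object@values[is.finite(object@values)]
  cat(sprintf("CostRaster: %d x %d cells, cellsize %g m, crs %s\n",
              d[1], d[2], object@cellsize,
              ifelse(is.na(object@crs), "<unknown>", object@crs)))
  cat(sprintf("  origin (xmin, ymax): (%g, %g)\n", object@xmin, object@ymax))
  if (length(fin)) {
    cat(sprintf("  finite cost range: [%g, %g]; impassable cells: %d\n",
                min(fin), max(fin), sum(is.infinite(object@values))))
  } else {
    cat("  all cells impassable\n")
  }
  invisible(NULL)
})

#' Path table of a PathSet
#'
#' One row per traced least-cost path, with endpoints, year (time step) and
#' accumulated cost.
#'
#' @param x a [PathSet-class]
#' @return data.frame
#' @export
pathTable <- function(x) {
  stopifnot(is(x, "PathSet"))
  x@paths
}

#' Accumulated costs of all paths in a PathSet
#' @param x a [PathSet-class]
#' @return numeric vector (dimensionless, cost x cell units)
#' @export
pathCosts <- function(x) {
  stopifnot(is(x, "PathSet"))
  x@paths$accumulated_cost
}

#' Number of paths in a PathSet
#' @param x a [PathSet-class]
#' @return integer
#' @export
nPaths <- function(x) {
  stopifnot(is(x, "PathSet"))
  nrow(x@paths)
}

#' Path geometries of a PathSet
#'
#' @param x a [PathSet-class]
#' @return list of integer matrices with columns `row`, `col`; each runs
#'   from the path's source cell to its target cell through 8-neighbouring
#'   cells
#' @export
pathGeometry <- function(x) {
  stopifnot(is(x, "PathSet"))
  x@geometry
}

#' Isolated cell records of a PathSet
#'
#' Cell records for which no least-cost path could be traced: records on
#' impassable cells or cut off from all earlier records by a barrier.
#'
#' @param x a [PathSet-class]
#' @return data.frame with columns `row`, `col`, `year`, `reason`
#' @export
isolatedRecords <- function(x) {
  stopifnot(is(x, "PathSet"))
  x@isolated
}

#' Seed cell records of a PathSet
#'
#' Records of the globally earliest observation year; they have no incoming
#' path by construction (there is nothing earlier to trace back to).
#'
#' @param x a [PathSet-class]
#' @return data.frame with columns `row`, `col`, `year`
#' @export
seedRecords <- function(x) {
  stopifnot(is(x, "PathSet"))
  x@seeds
}

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet: %d least-cost paths over years %s\n",
              nrow(object@paths),
              if (nrow(object@paths))
                paste(range(object@paths$year), collapse = "-") else "<none>"))
  if (nrow(object@paths))
    cat(sprintf("  accumulated cost range: [%g, %g]\n",
                min(object@paths$accumulated_cost),
                max(object@paths$accumulated_cost)))
  cat(sprintf("  seeds: %d; isolated records: %d\n",
              nrow(object@seeds), nrow(object@isolated)))
  invisible(NULL)
})

#' Population summary table of a PopulationPartition
#'
#' One row per delineated population: name, first and latest observation
#' year, raw-record count, median raw observations per calendar year and the
#' robust/sparse status.
#'
#' @param x a [PopulationPartition-class]
#' @return data.frame
#' @export
populationTable <- function(x) {
  stopifnot(is(x, "PopulationPartition"))
  x@populations
}

#' Per-record population assignments
#' @param x a [PopulationPartition-class]
#' @return data.frame with columns `record_id`, `population` (`NA` =
#'   unassigned)
#' @export
recordAssignments <- function(x) {
  stopifnot(is(x, "PopulationPartition"))
  x@recordPopulation
}

#' Record ids left unassigned by the delineation
#' @param x a [PopulationPartition-class]
#' @return vector of record ids whose cell is touched by no retained path
#'   endpoint
#' @export
unassignedRecords <- function(x) {
  stopifnot(is(x, "PopulationPartition"))
  rp <- x@recordPopulation
  rp$record_id[is.na(rp$population)]
}

#' Number of delineated populations
#' @param x a [PopulationPartition-class]
#' @return integer
#' @export
nPopulations <- function(x) {
  stopifnot(is(x, "PopulationPartition"))
  nrow(x@populations)
}

#' Per-path population membership
#' @param x a [PopulationPartition-class]
#' @return integer vector parallel to the originating PathSet's paths; `NA`
#'   for paths removed by the accumulated-cost threshold
#' @export
pathPopulations <- function(x) {
  stopifnot(is(x, "PopulationPartition"))
  x@pathPopulation
}

setMethod("show", "PopulationPartition", function(object) {
  pops <- object@populations
  n_un <- sum(is.na(object@recordPopulation$population))
  cat(sprintf("PopulationPartition: %d populations (threshold %g, robust definition %g)\n",
              nrow(pops), object@threshold, object@robustDef))
  cat(sprintf("  robust: %d, sparse: %d; unassigned records: %d\n",
              sum(pops$status == "robust"), sum(pops$status == "sparse"), n_un))
  if (nrow(pops)) {
    print(head(pops[, c("name", "first_year", "latest_year", "n_records",
                        "median_per_year", "status")], 10), row.names = FALSE)
    if (nrow(pops) > 10) cat(sprintf("  ... and %d more\n", nrow(pops) - 10))
  }
  invisible(NULL)
})
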