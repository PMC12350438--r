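# End-to-end orchestration: prepare -> snap/dedupe -> sequential tracing ->
# delineation -> expansion rates (-> sensitivity sweep), with all stage
# outputs written to disk plus a reproducibility manifest.

#' Write a PathSet as GeoJSON LineStrings
#'
#' One feature per path with properties `path_id`, `year`, `source_year`,
#' `accumulated_cost`, endpoint cells and, when available, `population`.
#' Coordinates are the projected cell-centre coordinates of the path's cell
#' sequence.
#'
#' @param paths a [PathSet-class]
#' @param cost the [CostRaster-class] the paths were traced on (for the
#'   cell-to-coordinate transform)
#' @param path output file path
#' @param population optional integer vector of population ids per path
#'   (`NA` = removed/unassigned)
#' @return `path`, invisibly
#' @export
writePathsGeoJSON <- function(paths, cost, path, population = NULL) {
  stopifnot(is(paths, "PathSet"), is(cost, "CostRaster"))
  df <- pathTable(paths)
  geoms <- pathGeometry(paths)
  feats <- lapply(seq_len(nrow(df)), function(i) {
    xy <- cellCenters(cost, geoms[[i]])
    props <- list(path_id = df$path_id[i], year = df$year[i],
                  source_year = df$source_year[i],
                  source_row = df$source_row[i], source_col = df$source_col[i],
                  target_row = df$target_row[i], target_col = df$target_col[i],
                  accumulated_cost = df$accumulated_cost[i])
    if (!is.null(population)) props$population <- population[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = unname(as.matrix(xy))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a PathSet written by [writePathsGeoJSON()]
#'
#' Reconstructs the path table and cell geometries from the GeoJSON
#' feature properties and the raster transform. Seed and isolated-record
#' tables are not stored in GeoJSON and come back empty.
#'
#' @param path GeoJSON file path
#' @param cost the [CostRaster-class] the paths were traced on
#' @return a [PathSet-class]
#' @export
readPathsGeoJSON <- function(path, cost) {
  stopifnot(is(cost, "CostRaster"))
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  rows <- lapply(feats, function(f) as.data.frame(
    f$properties[c("path_id", "year", "source_year", "source_row",
                   "source_col", "target_row", "target_col",
                   "accumulated_cost")]))
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- .emptyPathsDF()
  for (col in c("path_id", "year", "source_year", "source_row", "source_col",
                "target_row", "target_col"))
    df[[col]] <- as.integer(df[[col]])
  geoms <- lapply(feats, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(p) c(p[[1]], p[[2]])))
    g <- as.matrix(.pointToCell(cost, xy[, 1], xy[, 2]))
    colnames(g) <- c("row", "col")
    g
  })
  new("PathSet", paths = df, geometry = geoms,
      isolated = .emptyIsolatedDF(),
      seeds = data.frame(row = integer(0), col = integer(0),
                         year = integer(0)))
}

#' Read a pipeline configuration file
#'
#' YAML key-value file mirroring the arguments of [runPipeline()]:
#' `cost`, `mode`, `observations`, `threshold` or `quantile`, `robust_def`,
#' `breakpoints` (a mapping population name -> list of years), `sweep`
#' (`step`, `robust_defs`), `out`, `seed`.
#'
#' @param path YAML file path
#' @return named list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$threshold) && !is.null(cfg$quantile))
    stop("config sets both 'threshold' and 'quantile'; choose one")
  if (!is.null(cfg$robust_def) && cfg$robust_def < 1)
    stop("'robust_def' must be >= 1")
  cfg
}

#' Run the full sequential least-cost workflow
#'
#' Executes cost preparation, record snapping/deduplication, sequential
#' least-cost path tracing, population delineation and expansion-rate
#' estimation, optionally followed by the sensitivity sweep. When `outDir`
#' is given, every stage result is written there (`cells.csv`,
#' `paths.geojson`, `populations.csv`, `assignments.csv`, `rates.csv`,
#' `sweep.csv`, `manifest.json`); outputs are regenerated deterministically
#' from the inputs and parameters recorded in the manifest.
#'
#' @param cost a [CostRaster-class], or path to an ASCII-grid raster file
#' @param records data.frame of observation records, or path to a CSV read
#'   via [readObservations()]
#' @param mode raster interpretation when `cost` is a file path (see
#'   [loadCost()])
#' @param threshold,quantile accumulated-cost threshold for the
#'   delineation, or the path-cost quantile at which to place it (exactly
#'   one)
#' @param robustDef robust-population definition (default 10)
#' @param breakpoints named list of per-population breakpoint years (see
#'   [populationRates()])
#' @param sweep `NULL`, or a list with `step` (threshold grid step) and
#'   `robustDefs` to run the sensitivity sweep
#' @param maxIsolationKm optional pre-filter: drop records farther than
#'   this from every other record (off by default)
#' @param chainWithinYear see [runSequential()]
#' @param outDir optional output directory, created if needed
#' @return list with `cost`, `records`, `snapping`, `cellRecords`,
#'   `paths`, `partition`, `rates`, and `sweep` (when requested)
#' @export
runPipeline <- function(cost, records, mode = c("suitability", "cost"),
                        threshold = NULL, quantile = NULL, robustDef = 10,
                        breakpoints = list(), sweep = NULL,
                        maxIsolationKm = NULL, chainWithinYear = FALSE,
                        outDir = NULL) {
  mode <- match.arg(mode)
  inputs <- list()
  if (is.character(cost)) {
    inputs$cost_file <- cost
    cost <- loadCost(cost, mode = mode)
  }
  if (is.character(records)) {
    inputs$observations_file <- records
    records <- readObservations(records)
  }
  if (!is.null(maxIsolationKm))
    records <- filterIsolated(records, maxIsolationKm)
  snapping <- snapRecords(records, cost)
  cellRecords <- dedupeRecords(records, snapping)
  paths <- runSequential(cost, cellRecords[!cellRecords$impassable, ,
                                           drop = FALSE],
                         chainWithinYear = chainWithinYear)
  partition <- delineate(paths, records, snapping, threshold = threshold,
                         quantile = quantile, robustDef = robustDef)
  rates <- populationRates(partition, records, breakpoints = breakpoints)
  res <- list(cost = cost, records = records, snapping = snapping,
              cellRecords = cellRecords, paths = paths,
              partition = partition, rates = rates)
  if (!is.null(sweep)) {
    step <- if (is.null(sweep$step)) 0.01 else sweep$step
    rdefs <- if (is.null(sweep$robustDefs)) 5:15 else sweep$robustDefs
    grid <- defaultThresholdGrid(paths, step)
    res$sweep <- sensitivitySweep(paths, records, snapping, grid, rdefs)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCellRecords(cellRecords, file.path(outDir, "cells.csv"))
    writePathsGeoJSON(paths, cost, file.path(outDir, "paths.geojson"),
                      population = pathPopulations(partition))
    write.csv(populationTable(partition),
              file.path(outDir, "populations.csv"), row.names = FALSE)
    write.csv(recordAssignments(partition),
              file.path(outDir, "assignments.csv"), row.names = FALSE)
    write.csv(rates, file.path(outDir, "rates.csv"), row.names = FALSE)
    if (!is.null(res$sweep))
      write.csv(res$sweep, file.path(outDir, "sweep.csv"), row.names = FALSE)
    manifest <- list(
      package = "seqlcp",
      version = as.character(utils::packageVersion("seqlcp")),
      parameters = list(mode = mode, threshold = partition@threshold,
                        quantile = quantile, robust_def = robustDef,
                        chain_within_year = chainWithinYear,
                        max_isolation_km = maxIsolationKm,
                        breakpoints = breakpoints),
      inputs = inputs,
      input_checksums = if (length(inputs))
        as.list(tools::md5sum(unlist(inputs))) else list(),
      n_records = nrow(records), n_cells = nrow(cellRecords),
      n_paths = nPaths(paths),
      n_populations = nPopulations(partition))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  res
}
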