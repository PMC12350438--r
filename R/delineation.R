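# Population delineation: threshold filtering of the dispersal network,
# connectivity components over shared path endpoints, record assignment and
# robust/sparse classification.

.costsOf <- function(paths) {
  if (is(paths, "PathSet")) pathCosts(paths) else as.numeric(paths)
}

#' Empirical quantile of an accumulated-cost threshold
#'
#' Fraction of paths with accumulated cost at or below the threshold
#' (empirical CDF, no interpolation).
#'
#' @param paths a [PathSet-class] or numeric vector of path costs
#' @param threshold accumulated-cost threshold
#' @return fraction in `[0, 1]`
#' @export
quantileOfThreshold <- function(paths, threshold) {
  costs <- .costsOf(paths)
  if (!length(costs)) stop("empty path set")
  mean(costs <= threshold)
}

#' Accumulated-cost threshold of an empirical quantile
#'
#' The smallest observed path cost `c` such that the fraction of paths with
#' cost `<= c` is at least `q`.
#'
#' @param paths a [PathSet-class] or numeric vector of path costs
#' @param q quantile in `[0, 1]`
#' @return a path cost
#' @export
thresholdOfQuantile <- function(paths, q) {
  costs <- .costsOf(paths)
  if (!length(costs)) stop("empty path set")
  if (q < 0 || q > 1) stop("'q' must be in [0, 1]")
  s <- sort(costs)
  s[max(1L, ceiling(q * length(s)))]
}

#' Remove high-cost paths from the dispersal network
#'
#' Paths that exceed the accumulated-cost threshold are removed; paths at
#' exactly the threshold are retained. The threshold represents the maximum
#' cost-distance the species can cover in one year of dispersal.
#'
#' @param paths a [PathSet-class]
#' @param threshold accumulated-cost threshold (>= 0)
#' @return logical vector: which paths are retained
#' @export
filterPaths <- function(paths, threshold) {
  if (threshold < 0) stop("'threshold' must be non-negative")
  .costsOf(paths) <= threshold
}

# Rank that orders cells lexicographically by (row, col).
.cellRank <- function(row, col) as.numeric(row) * 1e7 + as.numeric(col)

#' Connected components of retained paths by shared endpoints
#'
#' Builds the undirected graph whose vertices are path endpoint cells and
#' whose edges are the retained paths, and labels each path with its
#' connected component. Population identifiers are assigned
#' deterministically: components are numbered by earliest member record
#' year, ties broken by the smallest endpoint cell in `(row, col)`
#' lexicographic order.
#'
#' @param paths data.frame of retained paths (columns as in
#'   [PathSet-class]), or a [PathSet-class] whose full path table is used
#' @return list with `pathPopulation` (integer per path) and
#'   `cellPopulation` (data.frame `row`, `col`, `population` for every
#'   endpoint cell)
#' @export
pathComponents <- function(paths) {
  df <- if (is(paths, "PathSet")) pathTable(paths) else as.data.frame(paths)
  if (!nrow(df))
    return(list(pathPopulation = integer(0),
                cellPopulation = data.frame(row = integer(0), col = integer(0),
                                            population = integer(0))))
  skey <- paste(df$source_row, df$source_col)
  tkey <- paste(df$target_row, df$target_col)
  g <- igraph::graph_from_data_frame(
    data.frame(from = skey, to = tkey, stringsAsFactors = FALSE),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  path_comp <- memb[skey]  # source and target are in the same component
  # deterministic renumbering: earliest member record year, then smallest
  # endpoint cell
  first_year <- tapply(pmin(df$source_year, df$year), path_comp, min)
  vname <- names(memb)
  vrc <- do.call(rbind, strsplit(vname, " ", fixed = TRUE))
  vrow <- as.integer(vrc[, 1]); vcol <- as.integer(vrc[, 2])
  min_rank <- tapply(.cellRank(vrow, vcol), memb, min)
  comp_ids <- as.integer(names(first_year))
  ord <- order(first_year, min_rank[as.character(comp_ids)])
  renum <- setNames(seq_along(comp_ids), comp_ids[ord])
  pathPopulation <- as.integer(renum[as.character(path_comp)])
  cellPopulation <- data.frame(
    row = vrow, col = vcol,
    population = as.integer(renum[as.character(memb)]))
  cellPopulation <- cellPopulation[order(cellPopulation$population,
                                         .cellRank(cellPopulation$row,
                                                   cellPopulation$col)), ]
  rownames(cellPopulation) <- NULL
  list(pathPopulation = pathPopulation, cellPopulation = cellPopulation)
}

#' Assign observation records to populations
#'
#' A record joins the population of any retained path starting or ending in
#' its raster cell. Records in cells touched by no retained path endpoint
#' (isolated by barriers or by the removal of high-cost paths) remain
#' unassigned (`NA`). All raw records of a cell inherit the cell's
#' assignment. By construction a cell belongs to at most one component; a
#' violation indicates a corrupted partition and fails loudly.
#'
#' @param snapping result of [snapRecords()] for the raw records
#' @param cellPopulation endpoint-cell table from [pathComponents()]
#' @return data.frame `record_id`, `row`, `col`, `population` (`NA` =
#'   unassigned)
#' @export
assignRecords <- function(snapping, cellPopulation) {
  key <- paste(cellPopulation$row, cellPopulation$col)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    pops <- unique(cellPopulation$population[key == dup])
    if (length(pops) > 1L)
      stop("internal error: endpoint cell (", dup,
           ") touched by two populations: ", paste(pops, collapse = ", "))
  }
  lut <- setNames(cellPopulation$population, key)
  rkey <- paste(snapping$row, snapping$col)
  data.frame(
    record_id = snapping$id,
    row = snapping$row, col = snapping$col,
    population = as.integer(lut[rkey])
  )
}

# Median raw-observation count per calendar year for one population.
# Years without records inside [first, latest] count as zero unless
# occupiedYearsOnly.
.medianPerYear <- function(years, occupiedYearsOnly = FALSE) {
  span <- seq(min(years), max(years))
  counts <- as.numeric(table(factor(years, levels = span)))
  if (occupiedYearsOnly) counts <- counts[counts > 0]
  median(counts)
}

#' Classify populations as robust or sparse
#'
#' For each population, the raw (pre-deduplication) record count per
#' calendar year is computed over the population's observed span
#' (first to latest year inclusive, zero-filling years without records) and
#' summarised by its median -- a measure of spatio-temporal data coverage.
#' Populations whose median reaches the robust definition are classified
#' `robust` (high confidence in their existence), the rest `sparse`.
#' A population whose median equals the definition exactly is robust.
#'
#' Population names follow the pattern `"<label> <first year>"`, with
#' `a`/`b`/`c`... suffixes on collisions; the label comes from the earliest
#' member record's `label` attribute when present, else the population id.
#'
#' @param assignments data.frame `record_id`, `population` as returned by
#'   [assignRecords()], joined with the records' `year` (and optional
#'   `label`)
#' @param robustDef minimum median observations per year for robust status
#'   (> 0)
#' @param occupiedYearsOnly if `TRUE`, the median is taken over years with
#'   at least one record instead of the full zero-filled span (alternative
#'   reading; default `FALSE`)
#' @return data.frame with one row per population: `population`, `name`,
#'   `label`, `first_year`, `latest_year`, `n_records`, `median_per_year`,
#'   `status`; sorted by population id
#' @export
classifyPopulations <- function(assignments, robustDef = 10,
                                occupiedYearsOnly = FALSE) {
  if (robustDef <= 0) stop("'robustDef' must be positive")
  a <- assignments[!is.na(assignments$population), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(population = integer(0), name = character(0),
                      label = character(0), first_year = integer(0),
                      latest_year = integer(0), n_records = integer(0),
                      median_per_year = numeric(0), status = character(0)))
  has_label <- "label" %in% names(a) && !all(is.na(a$label))
  rows <- lapply(split(seq_len(nrow(a)), a$population), function(ix) {
    yrs <- a$year[ix]
    lab <- if (has_label) as.character(a$label[ix][which.min(yrs)])
           else NA_character_
    data.frame(
      population = a$population[ix][1],
      label = lab,
      first_year = min(yrs), latest_year = max(yrs),
      n_records = length(ix),
      median_per_year = .medianPerYear(yrs, occupiedYearsOnly)
    )
  })
  pops <- do.call(rbind, rows)
  pops <- pops[order(pops$population), ]
  pops$label[is.na(pops$label)] <-
    sprintf("pop%02d", pops$population[is.na(pops$label)])
  base <- paste(pops$label, pops$first_year)
  name <- base
  for (b in unique(base[duplicated(base)])) {
    ix <- which(base == b)
    name[ix] <- paste0(b, letters[seq_along(ix)])
  }
  pops$name <- name
  pops$status <- ifelse(pops$median_per_year >= robustDef, "robust", "sparse")
  rownames(pops) <- NULL
  pops[, c("population", "name", "label", "first_year", "latest_year",
           "n_records", "median_per_year", "status")]
}

#' Delineate populations from the dispersal network
#'
#' The four-step delineation: (1) remove paths whose accumulated cost
#' exceeds the threshold, (2) group the remaining paths into connected
#' components by shared endpoint cells, (3) assign every raw observation
#' record to the population of any retained path endpoint in its cell
#' (records in untouched cells stay unassigned), (4) classify each
#' population as robust or sparse by its median raw-observation count per
#' calendar year.
#'
#' @param paths a [PathSet-class] from [runSequential()]
#' @param records raw observation records (`id`, `x`, `y`, `year`, optional
#'   `label`)
#' @param snapping result of [snapRecords()] for `records`
#' @param threshold accumulated-cost threshold; exactly one of `threshold`
#'   and `quantile` must be given
#' @param quantile alternatively, the empirical quantile of path costs at
#'   which to place the threshold (e.g. 0.947)
#' @param robustDef robust-population definition: minimum median raw
#'   observations per calendar year (default 10)
#' @param occupiedYearsOnly see [classifyPopulations()]
#' @return a [PopulationPartition-class]
#' @export
delineate <- function(paths, records, snapping, threshold = NULL,
                      quantile = NULL, robustDef = 10,
                      occupiedYearsOnly = FALSE) {
  stopifnot(is(paths, "PathSet"))
  if (is.null(threshold) == is.null(quantile))
    stop("supply exactly one of 'threshold' and 'quantile'")
  if (!is.null(quantile)) threshold <- thresholdOfQuantile(paths, quantile)
  df <- pathTable(paths)
  keep <- if (nrow(df)) filterPaths(paths, threshold) else logical(0)
  comp <- pathComponents(df[keep, , drop = FALSE])
  pathPopulation <- rep(NA_integer_, nrow(df))
  pathPopulation[keep] <- comp$pathPopulation
  assignments <- assignRecords(snapping, comp$cellPopulation)
  records <- as.data.frame(records)
  assignments$year <- records$year[match(assignments$record_id, records$id)]
  if ("label" %in% names(records))
    assignments$label <- records$label[match(assignments$record_id, records$id)]
  pops <- classifyPopulations(assignments, robustDef = robustDef,
                              occupiedYearsOnly = occupiedYearsOnly)
  new("PopulationPartition",
      pathPopulation = pathPopulation,
      recordPopulation = assignments[, c("record_id", "population")],
      populations = pops,
      cellPopulation = comp$cellPopulation,
      threshold = as.numeric(threshold),
      robustDef = as.numeric(robustDef))
}
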