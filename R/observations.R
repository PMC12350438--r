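# Occurrence records: reading, snapping to raster cells, deduplication.
#
# Coordinate convention (used everywhere): rows increase downward, columns
# rightward, 1-based indices, half-open cells -- a point on a shared edge
# belongs to the cell to its right/below in index space.

#' Read occurrence records from CSV
#'
#' Expects a header with at least `id`, `x`, `y`, `year`; an optional
#' `label` column (e.g. country) is carried through and used for population
#' naming. Coordinates must be projected metres in the CRS of the cost
#' raster.
#'
#' @param path CSV file path
#' @param yearRange plausible calendar-year range; records outside it are an
#'   error (guards against date-parsing accidents upstream)
#' @return data.frame with columns `id`, `x`, `y`, `year` (+ `label` if
#'   present)
#' @export
readObservations <- function(path, yearRange = c(1900L, 2100L)) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("observations CSV missing column(s): ", paste(miss, collapse = ", "))
  df$year <- as.integer(df$year)
  if (anyNA(df$year)) stop("non-integer year in observations")
  bad <- df$year < yearRange[1] | df$year > yearRange[2]
  if (any(bad))
    stop("observation year(s) outside plausible range [", yearRange[1], ", ",
         yearRange[2], "]: ", paste(unique(df$year[bad]), collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate record ids in observations")
  df
}

#' Snap occurrence records to cost-raster cells
#'
#' Maps each point to the cell containing it under the affine transform of
#' the cost raster (half-open cell convention). Records that fall on
#' impassable (NoData) cells are kept but flagged: they can never be path
#' endpoints and will end up unassigned, which surfaces data problems
#' instead of hiding them.
#'
#' @param records data.frame with columns `id`, `x`, `y`, `year`
#' @param cost a [CostRaster-class] sharing the records' CRS
#' @return data.frame with columns `id`, `row`, `col`, `cell` (column-major
#'   linear index), `impassable`
#' @export
snapRecords <- function(records, cost) {
  stopifnot(is(cost, "CostRaster"))
  records <- as.data.frame(records)
  stopifnot(all(c("id", "x", "y") %in% names(records)))
  d <- dim(cost@values)
  rc <- .pointToCell(cost, records$x, records$y)
  oob <- rc$row < 1L | rc$row > d[1] | rc$col < 1L | rc$col > d[2]
  if (any(oob))
    stop("record(s) outside raster bounds: ",
         paste(records$id[oob], collapse = ", "))
  cell <- .cellIndex(rc$row, rc$col, d[1])
  data.frame(
    id = records$id,
    row = rc$row, col = rc$col, cell = cell,
    impassable = is.infinite(cost@values)[cell]
  )
}

#' Deduplicate records to one cell record per occupied cell
#'
#' The path-finding algorithm operates at the resolution of the cost
#' surface, so multiple records in one cell would create duplicated or
#' zero-length paths. Deduplication retains one record per cell with the
#' earliest observation year; all raw record ids snapped to the cell are
#' kept as members (input order preserved).
#'
#' @param records data.frame with columns `id`, `year` (+ optional `label`)
#' @param snapping result of [snapRecords()] covering all of `records`
#' @return data.frame with one row per occupied cell: `row`, `col`, `cell`,
#'   `year` (minimum member year), `n_members`, `member_ids` (list column),
#'   `impassable`, and `label` of the earliest member when present. Sorted
#'   by cell index.
#' @export
dedupeRecords <- function(records, snapping) {
  records <- as.data.frame(records)
  if (!all(records$id %in% snapping$id))
    stop("snapping does not cover all records")
  m <- merge(records, snapping, by = "id", sort = FALSE)
  # merge() keeps input order here because ids are unique; rely on order of
  # 'records' for member and tie ordering
  m <- m[match(records$id, m$id), ]
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), m$cell), function(ix) {
    yrs <- m$year[ix]
    first <- ix[which.min(yrs)]  # earliest year, ties broken by input order
    data.frame(
      row = m$row[first], col = m$col[first], cell = m$cell[first],
      year = min(yrs), n_members = length(ix),
      impassable = m$impassable[first],
      label = if ("label" %in% names(m)) m$label[first] else NA_character_
    )
  }))
  out$member_ids <- lapply(split(seq_len(nrow(m)), m$cell), function(ix) m$id[ix])
  out <- out[order(out$cell), ]
  rownames(out) <- NULL
  out
}

#' Drop spatially isolated records
#'
#' Optional pre-filter removing records farther than `maxKm` from every
#' other record (planar distance). Mirrors the manual exclusion of extreme
#' outliers that would otherwise bloat the study area. Off by default in all
#' pipelines.
#'
#' @param records data.frame with columns `id`, `x`, `y`
#' @param maxKm isolation distance in kilometres
#' @return the filtered data.frame; dropped ids are reported via a message
#' @export
filterIsolated <- function(records, maxKm) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n < 2L) return(records)
  dm <- as.matrix(stats::dist(records[, c("x", "y")]))
  diag(dm) <- Inf
  nearest <- apply(dm, 1L, min)
  drop <- nearest > maxKm * 1000
  if (any(drop))
    message("dropping ", sum(drop), " isolated record(s): ",
            paste(records$id[drop], collapse = ", "))
  records[!drop, , drop = FALSE]
}

#' Write cell records to CSV
#'
#' Member ids are joined with `;`. The list column is restored by
#' [readCellRecords()].
#'
#' @param cellRecords result of [dedupeRecords()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeCellRecords <- function(cellRecords, path) {
  df <- cellRecords
  df$member_ids <- vapply(df$member_ids, paste, "", collapse = ";")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cell records written by [writeCellRecords()]
#' @param path CSV path
#' @return data.frame in the layout of [dedupeRecords()]
#' @export
readCellRecords <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$member_ids <- strsplit(as.character(df$member_ids), ";", fixed = TRUE)
  df
}
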