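# Cost surface preparation: suitability -> cost inversion, ASCII-grid I/O,
# and cell <-> coordinate conversion.

#' Construct a CostRaster
#'
#' @param values numeric matrix of costs; `NA` entries are converted to
#'   `Inf` (impassable), matching the treatment of NoData cells.
#' @param xmin,ymax projected coordinates of the top-left corner of the grid
#'   (left edge / top edge), metres.
#' @param cellsize cell side length in metres (cells are square).
#' @param crs optional CRS identifier string, descriptive only.
#' @return a [CostRaster-class]
#' @examples
#' r <- costRaster(matrix(0.5, 4, 5), cellsize = 10000)
#' dim(r)
#' @export
costRaster <- function(values, xmin = 0, ymax = nrow(values) * cellsize,
                       cellsize = 1, crs = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[is.na(values)] <- Inf
  new("CostRaster", values = values, xmin = as.numeric(xmin),
      ymax = as.numeric(ymax), cellsize = as.numeric(cellsize),
      crs = as.character(crs))
}

#' Invert and rescale a suitability raster into a cost raster
#'
#' Environmental suitability is assumed to facilitate dispersal, so high
#' suitability must become low traversal cost. Each finite suitability value
#' `v` maps to `(vmax - v) / (vmax - vmin)`, which sends `vmax` to cost 0,
#' `vmin` to cost 1, and is strictly monotone decreasing in between. NoData
#' (`NA`) cells become `Inf` (impassable).
#'
#' @param x numeric matrix of suitability values (`NA` = NoData), or a
#'   [CostRaster-class] whose finite values are to be re-inverted.
#' @param vmin,vmax optional explicit value range; default is the observed
#'   finite range of `x`. When supplied, every finite value must lie within
#'   `[vmin, vmax]`.
#' @param xmin,ymax,cellsize,crs georeferencing, used when `x` is a bare
#'   matrix (ignored when `x` is a `CostRaster`, whose georeferencing is
#'   kept).
#' @return a [CostRaster-class] with finite costs in `[0, 1]`
#' @examples
#' s <- matrix(c(33.04, 938.572, NA, 500), 2, 2)
#' costValues(invertRescale(s))
#' @export
invertRescale <- function(x, vmin = NULL, vmax = NULL,
                          xmin = 0, ymax = NULL, cellsize = 1,
                          crs = NA_character_) {
  if (is(x, "CostRaster")) {
    georef <- list(xmin = x@xmin, ymax = x@ymax, cellsize = x@cellsize, crs = x@crs)
    m <- x@values
    m[is.infinite(m)] <- NA
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    if (is.null(ymax)) ymax <- nrow(m) * cellsize
    georef <- list(xmin = xmin, ymax = ymax, cellsize = cellsize, crs = crs)
  }
  fin <- m[is.finite(m)]
  if (!length(fin))
    stop("suitability raster has no finite values")
  user_bounds <- !is.null(vmin) || !is.null(vmax)
  if (is.null(vmin)) vmin <- min(fin)
  if (is.null(vmax)) vmax <- max(fin)
  if (vmax == vmin)
    stop("degenerate suitability range: vmax == vmin (", vmin,
         "); a constant raster cannot be rescaled")
  if (vmax < vmin) stop("'vmax' must exceed 'vmin'")
  if (user_bounds) {
    bad <- fin[fin < vmin | fin > vmax]
    if (length(bad))
      stop("suitability value ", format(bad[1]), " outside supplied range [",
           vmin, ", ", vmax, "]")
  }
  out <- (vmax - m) / (vmax - vmin)
  out[is.na(m)] <- Inf
  costRaster(out, xmin = georef$xmin, ymax = georef$ymax,
             cellsize = georef$cellsize, crs = georef$crs)
}

# -- ESRI ASCII grid I/O -------------------------------------------------
# Plain-text single-band raster format: 6 header lines (ncols, nrows,
# xllcorner|xllcenter, yllcorner|yllcenter, cellsize, NODATA_value)
# followed by nrows lines of ncols values, top row first.

.readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  body_start <- 1L
  for (i in seq_len(min(6L, length(lines)))) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    body_start <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing '", k, "': ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = lines[body_start:length(lines)], what = double(),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xmin <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xmin <- hdr$xllcenter - cs / 2
  else stop("ASCII grid header missing xllcorner/xllcenter")
  if (!is.null(hdr$yllcorner)) ymax <- hdr$yllcorner + nr * cs
  else if (!is.null(hdr$yllcenter)) ymax <- hdr$yllcenter - cs / 2 + nr * cs
  else stop("ASCII grid header missing yllcorner/yllcenter")
  list(values = m, xmin = xmin, ymax = ymax, cellsize = cs)
}

.writeAsciiGrid <- function(values, xmin, ymax, cellsize, path,
                            nodata = -9999) {
  nr <- nrow(values); nc <- ncol(values)
  if (any(is.finite(values) & values == nodata))
    stop("a finite cell value collides with the nodata sentinel ", nodata)
  out <- values
  out[!is.finite(out)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(xmin, digits = 17)),
    paste("yllcorner", format(ymax - nr * cellsize, digits = 17)),
    paste("cellsize", format(cellsize, digits = 17)),
    paste("NODATA_value", nodata)
  ), con)
  body <- apply(out, 1L, function(rw) paste(format(rw, digits = 17, trim = TRUE,
                                                   scientific = FALSE),
                                            collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Load a cost or suitability raster from an ESRI ASCII grid
#'
#' Reads a single-band plain-text raster (`.asc`). In mode `"suitability"`
#' the observed finite value range is inverted and rescaled to `[0, 1]` via
#' [invertRescale()]; in mode `"cost"` finite values pass through unchanged
#' (they may exceed 1). In both modes NoData cells become `Inf`
#' (impassable barriers such as the ocean).
#'
#' The raster must be in a projected, equal-distance CRS; reprojection and
#' resampling are out of scope and must happen upstream. If `crs` looks
#' geographic (degrees), loading is refused.
#'
#' @param path path to an ESRI ASCII grid file.
#' @param mode `"suitability"` (invert + rescale, the standard preparation)
#'   or `"cost"` (pre-made cost raster, passed through).
#' @param crs optional CRS identifier recorded on the result. Values
#'   indicating a geographic CRS (e.g. "EPSG:4326", "longlat") are rejected.
#' @param vmin,vmax optional explicit suitability range for mode
#'   `"suitability"`.
#' @return a [CostRaster-class]
#' @seealso [writeCost()], [invertRescale()]
#' @export
loadCost <- function(path, mode = c("suitability", "cost"),
                     crs = NA_character_, vmin = NULL, vmax = NULL) {
  mode <- match.arg(mode)
  if (!is.na(crs) && grepl("4326|longlat|latlong|CRS84|WGS\\s*84$", crs,
                           ignore.case = TRUE))
    stop("'", crs, "' looks like a geographic (unprojected) CRS; ",
         "supply the raster in a projected equal-distance CRS ",
         "(e.g. an Equidistant Conic projection)")
  g <- .readAsciiGrid(path)
  if (mode == "suitability") {
    invertRescale(g$values, vmin = vmin, vmax = vmax, xmin = g$xmin,
                  ymax = g$ymax, cellsize = g$cellsize, crs = crs)
  } else {
    if (any(g$values[is.finite(g$values)] < 0))
      stop("pre-made cost raster contains negative values")
    costRaster(g$values, xmin = g$xmin, ymax = g$ymax,
               cellsize = g$cellsize, crs = crs)
  }
}

#' Write a CostRaster to an ESRI ASCII grid
#'
#' Impassable (`Inf`) cells are written as the nodata sentinel; a
#' [loadCost()] round-trip in mode `"cost"` reproduces values, transform and
#' nodata mask exactly.
#'
#' @param x a [CostRaster-class]
#' @param path output file path
#' @param nodata nodata sentinel written to the file (must not collide with
#'   a finite cost)
#' @return `path`, invisibly
#' @export
writeCost <- function(x, path, nodata = -9999) {
  stopifnot(is(x, "CostRaster"))
  .writeAsciiGrid(x@values, x@xmin, x@ymax, x@cellsize, path, nodata = nodata)
}

# -- cell <-> coordinate conversion --------------------------------------

#' Projected coordinates of cell centres
#'
#' @param x a [CostRaster-class]
#' @param cells integer matrix or data.frame with columns `row`, `col`
#'   (1-based)
#' @return data.frame with columns `x`, `y` (metres)
#' @export
cellCenters <- function(x, cells) {
  stopifnot(is(x, "CostRaster"))
  cells <- as.data.frame(cells)
  data.frame(
    x = x@xmin + (cells$col - 0.5) * x@cellsize,
    y = x@ymax - (cells$row - 0.5) * x@cellsize
  )
}

# Point -> cell under the half-open convention: a point on a shared edge
# belongs to the cell to its right/below in index space. Returns row/col
# possibly outside [1, nrow]x[1, ncol]; callers validate.
.pointToCell <- function(x, px, py) {
  col <- floor((px - x@xmin) / x@cellsize) + 1L
  row <- floor((x@ymax - py) / x@cellsize) + 1L
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Column-major linear cell index used throughout the package.
.cellIndex <- function(row, col, nr) (as.integer(col) - 1L) * nr + as.integer(row)

.indexToCell <- function(idx, nr) {
  idx <- as.integer(idx)
  data.frame(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}
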