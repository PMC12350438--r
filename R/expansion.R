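# Expansion-rate estimation by distance regression: per-population OLS of
# the yearly cumulative maximum Euclidean distance from the first
# observation against calendar year.

#' Euclidean distances of a population's records to its first observation
#'
#' The reference point `p0` is the record with the earliest observation
#' year; ties are broken by input order (and reported via `attr(,
#' "p0_ties")` so the arbitrary choice is visible -- it shifts all
#' distances).
#'
#' @param records data.frame with columns `x`, `y`, `year` (projected
#'   metres)
#' @return numeric vector of planar distances in metres, one per record;
#'   `attr(, "p0")` holds the reference record's index
#' @examples
#' d <- distancesToFirst(data.frame(x = c(0, 3000), y = c(0, 4000),
#'                                  year = c(2008, 2009)))
#' d  # 0, 5000
#' @export
distancesToFirst <- function(records) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no records")
  i0 <- which.min(records$year)  # first match = input order tie-break
  d <- sqrt((records$x - records$x[i0])^2 + (records$y - records$y[i0])^2)
  attr(d, "p0") <- i0
  attr(d, "p0_ties") <- sum(records$year == records$year[i0]) > 1L
  d
}

#' Per-year cumulative maximum distance
#'
#' For each calendar year of the span: the maximum distance among all
#' records observed in or before that year. Years without records carry the
#' previous value forward, so the series has exactly one value per calendar
#' year and is non-decreasing.
#'
#' @param distances numeric vector of distances (metres)
#' @param years integer vector of observation years, parallel to
#'   `distances`
#' @param span length-2 integer vector `[first, last]`; defaults to the
#'   observed year range. Must cover all observation years.
#' @return data.frame with columns `year`, `cummax` (metres)
#' @export
cummaxByYear <- function(distances, years, span = range(years)) {
  if (length(distances) != length(years)) stop("length mismatch")
  if (min(years) < span[1] || max(years) > span[2])
    stop("'span' must cover all observation years")
  yr <- seq(span[1], span[2])
  ymax <- vapply(yr, function(t) {
    v <- distances[years == t]
    if (length(v)) max(v) else -Inf  # silent year: carried forward below
  }, numeric(1))
  cm <- cummax(ymax)
  if (any(is.infinite(cm)))
    stop("no records at or before the start of the span")
  data.frame(year = yr, cummax = cm)
}

#' Fit an expansion rate by distance regression
#'
#' Ordinary least squares of the cumulative maximum distance (metres)
#' against calendar year, with intercept. The slope, divided by 1000, is
#' the expansion rate in km/year; since the response is non-decreasing in
#' time, the slope is never negative. A zero-variance (constant) response
#' gives rate 0 with undefined R-squared (`NA`).
#'
#' @param years integer vector of calendar years (>= 2 distinct)
#' @param cummax numeric vector of cumulative maximum distances in metres,
#'   parallel to `years`
#' @param phase phase label stored on the result (default `"overall"`)
#' @param from,until first/last year of the fit window (default the data
#'   range)
#' @return one-row data.frame: `phase`, `from`, `until`,
#'   `rate_km_per_year`, `r2`, `n_years`
#' @examples
#' fitRate(2008:2012, seq(0, 20000, 5000))  # 5 km/year, r2 = 1
#' @export
fitRate <- function(years, cummax, phase = "overall",
                    from = min(years), until = max(years)) {
  if (length(years) < 2L)
    stop("need at least 2 years to fit an expansion rate (phase '",
         phase, "')")
  if (length(years) != length(cummax)) stop("length mismatch")
  if (stats::var(cummax) == 0) {
    slope <- 0
    r2 <- NA_real_
  } else {
    fit <- lm(cummax ~ years)
    slope <- unname(coef(fit)[2])
    # exact piecewise-linear constructions trigger the "essentially perfect
    # fit" note in summary.lm; such fits are expected here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (slope < 0) {
      # a non-decreasing response cannot yield a negative OLS slope
      # (Chebyshev's sum inequality); anything below rounding noise is a bug
      if (slope < -1e-9 * max(abs(cummax), 1))
        stop("negative expansion-rate slope from a non-decreasing response")
      slope <- 0
    }
  }
  data.frame(phase = phase, from = from, until = until,
             rate_km_per_year = slope / 1000, r2 = r2,
             n_years = length(years))
}

#' Fit expansion rates for manually chosen phases
#'
#' Splits the yearly series at the given breakpoint years and fits each
#' phase independently with [fitRate()]. Breakpoint years belong to both
#' adjacent phases: with breakpoints `b1 < b2` the phases are
#' `[first, b1]`, `[b1, b2]`, `[b2, last]` -- e.g. a lag phase 2008--2011,
#' an expansion phase 2011--2021 and a final phase 2021--2024. Breakpoints
#' are supplied manually (the one-point-per-year series is too short for
#' statistical breakpoint detection).
#'
#' @param series data.frame `year`, `cummax` from [cummaxByYear()]
#' @param breakpoints strictly increasing years inside the span; empty for
#'   a single overall fit
#' @param phaseNames optional labels, one per phase; defaults to
#'   `"lag phase"`, `"expansion phase"`, `"final phase"` for three phases,
#'   else `"phase 1"`, ...
#' @return data.frame with one row per phase (columns as [fitRate()])
#' @export
fitPhases <- function(series, breakpoints = integer(0), phaseNames = NULL) {
  yr <- series$year
  if (!length(breakpoints))
    return(fitRate(yr, series$cummax))
  breakpoints <- sort(as.integer(breakpoints))
  if (any(duplicated(breakpoints)))
    stop("duplicate breakpoint years")
  if (min(breakpoints) <= min(yr) || max(breakpoints) >= max(yr))
    stop("breakpoints must lie strictly inside the year span")
  bounds <- c(min(yr), breakpoints, max(yr))
  k <- length(bounds) - 1L
  if (is.null(phaseNames))
    phaseNames <- if (k == 3L) c("lag phase", "expansion phase", "final phase")
                  else paste("phase", seq_len(k))
  if (length(phaseNames) != k) stop("need one phase name per phase")
  out <- lapply(seq_len(k), function(i) {
    sel <- yr >= bounds[i] & yr <= bounds[i + 1L]
    if (sum(sel) < 2L)
      stop("phase '", phaseNames[i], "' [", bounds[i], ", ", bounds[i + 1L],
           "] has fewer than 2 years")
    fitRate(yr[sel], series$cummax[sel], phase = phaseNames[i],
            from = bounds[i], until = bounds[i + 1L])
  })
  do.call(rbind, out)
}

#' Expansion rates for all populations of a partition
#'
#' For each delineated population: compute distances of its raw records to
#' the population's first observation, the per-year cumulative maximum over
#' the population's observed span (silent years carried forward), and the
#' OLS expansion rate -- overall, plus per-phase fits where breakpoints are
#' configured. Populations with a single observation year are skipped (no
#' rate is defined).
#'
#' @param partition a [PopulationPartition-class]
#' @param records the raw observation records used for the delineation
#' @param breakpoints named list: population name (or id as character) ->
#'   integer vector of breakpoint years
#' @param observedYearsOnly if `TRUE`, regress only on years with at least
#'   one record instead of the full carried-forward yearly series
#'   (alternative reading; default `FALSE`)
#' @param robustOnly fit only robust populations (default `FALSE`)
#' @return data.frame with columns `population`, `name`, `status`, `phase`,
#'   `from`, `until`, `rate_km_per_year`, `r2`, `n_years`
#' @export
populationRates <- function(partition, records, breakpoints = list(),
                            observedYearsOnly = FALSE, robustOnly = FALSE) {
  stopifnot(is(partition, "PopulationPartition"))
  records <- as.data.frame(records)
  rp <- recordAssignments(partition)
  pops <- populationTable(partition)
  if (robustOnly) pops <- pops[pops$status == "robust", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pops))) {
    pid <- pops$population[i]
    ids <- rp$record_id[!is.na(rp$population) & rp$population == pid]
    sub <- records[match(ids, records$id), , drop = FALSE]
    if (length(unique(sub$year)) < 2L) next
    d <- distancesToFirst(sub)
    series <- cummaxByYear(d, sub$year)
    if (observedYearsOnly)
      series <- series[series$year %in% sub$year, , drop = FALSE]
    bp <- breakpoints[[pops$name[i]]]
    if (is.null(bp)) bp <- breakpoints[[as.character(pid)]]
    if (is.null(bp)) bp <- integer(0)
    fits <- if (length(bp)) rbind(fitPhases(series), fitPhases(series, bp))
            else fitPhases(series)
    fits <- cbind(data.frame(population = pid, name = pops$name[i],
                             status = pops$status[i]), fits)
    out[[length(out) + 1L]] <- fits
  }
  if (!length(out))
    return(data.frame(population = integer(0), name = character(0),
                      status = character(0), phase = character(0),
                      from = integer(0), until = integer(0),
                      rate_km_per_year = numeric(0), r2 = numeric(0),
                      n_years = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
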