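# Two-parameter sensitivity sweep: accumulated-cost threshold x robust
# population definition, recording the average overall expansion rate
# across robust populations at each grid point.

#' Default threshold grid for the sensitivity sweep
#'
#' Arithmetic grid from 0 to the maximum observed path cost (inclusive)
#' with the given step; the maximum is appended when it does not fall on
#' the grid.
#'
#' @param paths a [PathSet-class] or numeric vector of path costs
#' @param step grid step (> 0), e.g. 0.01
#' @return numeric vector of thresholds
#' @export
defaultThresholdGrid <- function(paths, step = 0.01) {
  if (step <= 0) stop("'step' must be positive")
  costs <- .costsOf(paths)
  if (!length(costs)) stop("empty path set")
  mx <- max(costs)
  g <- seq(0, mx, by = step)
  if (g[length(g)] < mx) g <- c(g, mx)
  g
}

#' Sensitivity sweep over threshold and robust-population definition
#'
#' The dispersal network is computed once (path tracing does not depend on
#' either parameter); for every combination of accumulated-cost threshold
#' and robust definition the delineation, classification and overall
#' distance regressions are re-run and the unweighted arithmetic mean of
#' the expansion rates across robust populations is recorded. Each grid
#' point evaluates exactly the same code path as a direct
#' [delineate()] + [populationRates()] run, so a single-point sweep
#' reproduces the main pipeline bit-for-bit.
#'
#' Phase-wise rates are not used here; only overall per-population rates
#' enter the mean.
#'
#' @param paths a [PathSet-class]
#' @param records raw observation records
#' @param snapping result of [snapRecords()] for `records`
#' @param thresholds numeric vector of accumulated-cost thresholds
#' @param robustDefs numeric vector of robust definitions (e.g. `5:15`)
#' @param occupiedYearsOnly,observedYearsOnly passed through to the
#'   delineation and regression steps
#' @return data.frame with one row per `(threshold, robust_def)`
#'   combination: `threshold`, `robust_def`, `n_populations`, `n_robust`,
#'   `n_unassigned`, `mean_rate_km_per_year` (`NA` when no robust
#'   population with a fittable rate exists)
#' @export
sensitivitySweep <- function(paths, records, snapping, thresholds,
                             robustDefs = 5:15,
                             occupiedYearsOnly = FALSE,
                             observedYearsOnly = FALSE) {
  stopifnot(is(paths, "PathSet"))
  if (!length(thresholds)) stop("empty threshold grid")
  rows <- vector("list", length(thresholds) * length(robustDefs))
  k <- 0L
  for (th in thresholds) {
    for (rd in robustDefs) {
      part <- delineate(paths, records, snapping, threshold = th,
                        robustDef = rd, occupiedYearsOnly = occupiedYearsOnly)
      rates <- populationRates(part, records, robustOnly = TRUE,
                               observedYearsOnly = observedYearsOnly)
      overall <- rates[rates$phase == "overall", , drop = FALSE]
      pops <- populationTable(part)
      k <- k + 1L
      rows[[k]] <- data.frame(
        threshold = th, robust_def = rd,
        n_populations = nrow(pops),
        n_robust = sum(pops$status == "robust"),
        n_unassigned = length(unassignedRecords(part)),
        mean_rate_km_per_year = if (nrow(overall))
          mean(overall$rate_km_per_year) else NA_real_
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
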