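---
title: "Sequential least-cost modelling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential least-cost modelling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqlcp)
```

## The model

`seqlcp` reconstructs the spread of a multiply-introduced invasive species
from two inputs: a raster cost surface describing how strongly the
landscape impedes dispersal, and dated point occurrences. The central
assumption is that a record observed in year *t* descends, directly or
indirectly, from some record already known before *t*, and that dispersal
preferentially follows permeable (low-cost) landscape. Three further
assumptions matter in practice:

* **Annual time steps.** The species is treated as univoltine: one
  generation, and hence one dispersal episode, per year. Records are
  therefore connected across years, never within a year (but see
  `chainWithinYear` below).
* **Suitability proxies permeability.** When the input is a habitat
  suitability map, cost is its linear inversion
  `(vmax - v) / (vmax - vmin)` onto [0, 1]. This is a proxy, not a
  measured resistance; the `mode = "cost"` path of `loadCost()` accepts a
  pre-made resistance raster instead.
* **An optimal-path view of connectivity.** Each new record is linked by a
  single deterministic least-cost path to the *nearest* earlier record in
  cost-distance. Paths are used to establish spatio-temporal relations
  between records, not as literal flight tracks.

The grid graph is 8-connected with geometric step costs
`L * (c_a + c_b) / 2`, `L = 1` orthogonal, `sqrt(2)` diagonal, in cell
units. Accumulated path cost is therefore dimensionless (cost × cell
units): on a uniform surface of cost *c* the accumulated cost from a
single source is exactly *c* times the octile distance
`max(|dr|, |dc|) + (sqrt(2) - 1) * min(|dr|, |dc|)`, a closed form the
test suite checks at machine precision. NoData cells carry infinite cost
and are impassable; ocean thereby becomes a hard barrier, while high-cost
land (mountain ranges) impedes paths without forbidding them.

Delineation removes every path whose accumulated cost exceeds a threshold
*T* (paths at exactly *T* are retained), takes connected components of the
remaining paths over shared endpoint cells, and assigns each record to the
component of any retained path endpoint in its raster cell. *T* has a
direct biological reading: the largest cost-distance the species can
plausibly cover in one year. Records touched by no retained endpoint stay
unassigned — deliberately, since silently attaching them would hide both
barriers and data gaps.

Expansion rates use the distance-regression estimator, the method most
robust to small samples among the classical rate estimators: per
population, the OLS slope (in km/year, slope/1000) of the yearly
cumulative maximum Euclidean distance from the population's first record
against calendar year. Because the response is non-decreasing, the slope
is provably non-negative; the implementation asserts this on every fit.
Phase-wise fits (lag / expansion / final) use manually supplied breakpoint
years; with one point per year the series is far too short for statistical
breakpoint detection, so none is attempted. Breakpoint years belong to
both adjacent phases.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `threshold` (or `quantile`) | maximum accumulated cost of a retained path, i.e. maximum yearly dispersal cost-distance | cost × cell units | none — must be chosen, ideally on a sweep plateau |
| `robustDef` | minimum median raw observations per calendar year for a robust population | records/year | 10 |
| `mode` | whether the raster is suitability (invert + rescale) or ready-made cost | — | `"suitability"` |
| `chainWithinYear` | allow same-year records to chain as sources | — | `FALSE` |
| `occupiedYearsOnly` | median over occupied years only, instead of zero-filled span | — | `FALSE` |
| `observedYearsOnly` | regress on observed years only, instead of carry-forward series | — | `FALSE` |
| `maxIsolationKm` | optional pre-filter dropping records isolated by more than this distance | km | off |

The threshold should be read off the sensitivity sweep
(`sensitivitySweep()`, `defaultThresholdGrid()` with step 0.01): as *T*
grows from 0, rates first rise while artificially fragmented populations
merge, then sit on a plateau across which the partition is stable, and
finally jump when a handful of extreme paths fuse distant populations
into implausible super-populations. A *T* at the start of the plateau,
together with a `robustDef` inside its own insensitive range, is the
recommended operating point. The sweep reuses the path set — tracing does
not depend on either parameter — and each grid point runs exactly the
same delineation and regression code as the main pipeline, so a
single-point sweep reproduces it bit for bit.

## Numerical and representational choices

* **Indices.** Rows increase downward, columns rightward, 1-based (the R
  convention), half-open cells: a point on a shared cell edge belongs to
  the cell to its right/below in index space. Stated once, used
  everywhere.
* **Tie-breaking in traceback.** The accumulated-cost surface fixes path
  *costs* uniquely, but not geometries. The traceback walks
  optimal-predecessor edges (`acc[p] + step(p, c) == acc[c]` within a
  relative tolerance of 1e-9), preferring strictly closer predecessors and
  then the smallest `(row, col)` lexicographic index; inside zero-cost
  plateaus, where optimal edges can form cycles, it backtracks
  depth-first. Geometries are thus reproducible, and re-costing a
  geometry recovers its accumulated cost to 1e-9.
* **Zero costs.** Costs of exactly 0 are legal (zero-cost corridors); a
  path may accumulate zero cost over a nonzero distance. On such
  surfaces the source set must be passed to `tracePath()` explicitly,
  which `traceYear()` does.
* **Threshold comparison.** "Exceeds" is strict: paths at exactly *T*
  are retained. Quantiles are plain empirical-CDF fractions with no
  interpolation, so `quantileOfThreshold()` and `thresholdOfQuantile()`
  invert each other on the observed cost set.
* **Median per year.** Raw (pre-deduplication) record counts over the
  population's full first-to-latest span with silent years counted as 0.
  Zero-filling penalises gappy coverage, which is the point of the
  robust/sparse distinction; `occupiedYearsOnly = TRUE` gives the milder
  reading. A median exactly at `robustDef` counts as robust.
* **Regression series.** One point per calendar year with carry-forward
  for silent years; omitting silent years would re-weight the fit toward
  well-observed periods (`observedYearsOnly = TRUE` gives that variant).
  Distances use raw records; `p0` ties (several records in the earliest
  year) are broken by input order and flagged on the result, since the
  choice shifts all distances.
* **Seeds.** All records of the globally earliest year are seeds with no
  incoming path; they may be merged into one population by later paths.
* **Within-year chaining.** Off by default: with strictly-earlier sources
  the output is invariant to record order within a year (the suite checks
  this). `chainWithinYear = TRUE` makes each traced target immediately a
  source for the rest of its year — order-dependent, provided for
  comparison.
* **Degenerate inputs.** Constant suitability rasters cannot be rescaled
  (error); records on NoData cells are kept but flagged and can never be
  path endpoints; records unreachable behind barriers are reported
  isolated rather than erroring; single-record populations yield no rate.
* **File formats.** Rasters are plain-text ESRI ASCII grids (bit-faithful
  round trip via `writeCost()`/`loadCost()`), paths GeoJSON, tables CSV —
  all text, all diffable. Reprojection and resampling are deliberately
  out of scope: all inputs must already share one projected
  equal-distance CRS, which keeps results deterministic and the
  geospatial surface minimal.

The shortest-path core is a multi-source Dijkstra in C++ (Rcpp); the test
suite verifies it against an independent brute-force Dijkstra over the
explicitly constructed 8-neighbour graph (via igraph) on random rasters
with random NoData, to 1e-9.

## The synthetic generator: what it does and does not emulate

`generateInvasion()` spreads each introduction in the pipeline's own
metric: every year, the next cohort is sampled uniformly (with
replacement, so cells can be re-reported) from the cells within a
cost-distance *budget* `b` of the label's current footprint, computed with
the same `accumulate()` the tracer uses. This makes ground truth
expressible in threshold units — within-population paths can never cost
more than `b`, and in the two-basin scenarios any barrier-crossing path
costs at least ~50 — so the threshold plateau `[b, barrier-crossing cost)`
exists *by construction* and recovery can be asserted exactly, not just
approximately.

Default study conditions (chosen once, as plausible desk-scale analogues
of a continental invasion dataset): 10 km cells on grids of roughly
36 × 56 cells, introductions staggered a few years apart (2008 and 2011 in
the two-basin scenario, horizon 2016), a yearly budget of 1.0 cost × cell
units over basins of cost 0.2 (a front of ~5 cells ≈ 50 km per year),
and cohorts of 12 records per year — comfortably above the robust
definition of 10 — or uneven counts (8–25) in the plateau scenario to
emulate fluctuating Citizen-Science effort. Validation uses 20 seeds for
the recovery and thinning experiments and 100-point threshold grids for
the monotonicity checks; these sizes keep the full suite in tens of
seconds while leaving no property vacuous.

What the simulator does *not* model — and what passing tests therefore do
not show about real data: spatially biased reporting (language borders,
project focus areas), geocoding error, human-mediated jump dispersal,
wind-assisted anisotropic spread, or mechanistic behaviour of any
particular species. The generator's observation bias is purely temporal
(uneven yearly counts). Real cost surfaces also carry model error that the
simulator's clean basins do not; a perfect adjusted-Rand recovery in the
two-basin experiment validates the machinery, not any particular
ecological inference.

## Known limitations

* Grid paths distort geometry: movement is restricted to 8 directions, so
  path shapes (not costs) depend on the raster orientation; the 16-way
  "knight's move" neighbourhood is not implemented.
* The single deterministic optimal path is an optimistic connectivity
  model; probabilistic ensembles and circuit-theory current maps are out
  of scope.
* Coarse rasters average away fine barriers; a 10 km alpine cell can look
  crossable even where no corridor exists.
* The delineation quality degrades gracefully but visibly with sparse
  data: thin coverage fragments populations and leaves records
  unassigned, which is informative about survey gaps but limits rate
  estimation there.
* The sensitivity sweep re-runs delineation per grid point; at the
  published step of 0.01 over a large cost range this is minutes, not
  seconds — use a coarser grid for exploration.

## A minimal run

```{r example, eval = FALSE}
sim   <- generateInvasion(twoBasinScenario(seed = 1))
snap  <- snapRecords(sim$records, sim$cost)
cells <- dedupeRecords(sim$records, snap)
paths <- runSequential(sim$cost, cells)
part  <- delineate(paths, sim$records, snap, threshold = 1.0)
populationRates(part, sim$records)
recoveryReport(sim$records, part)
```
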