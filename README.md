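# seqlcp — sequential least-cost modelling of invasive species spread

Estimates of how fast an invading species spreads usually assume that all
observations descend from a single introduction. When a species has in fact
been introduced several times — as is common for hitch-hiking insects — a
single regression over all records mixes independent invasion fronts and
biases the expansion rate. `seqlcp` infers the population structure directly
from dated occurrence records and a landscape cost surface, with no genetic
information, and then estimates an expansion rate per population.

The package is written for spatial ecologists working with gridded
suitability/resistance maps and point occurrence data (e.g. Citizen-Science
records of an expanding insect), in a projected, equal-distance CRS.

## Method

1. **Cost surface.** An environmental-suitability raster is inverted and
   rescaled, v ↦ (v_max − v)/(v_max − v_min), so that high suitability means
   low traversal cost in [0, 1]; NoData cells (ocean) become infinitely
   costly, i.e. impassable.
2. **Sequential least-cost paths.** Occurrences are snapped to raster cells
   and deduplicated (one record per cell, earliest year). In annual time
   steps — one step per generation of a univoltine species — every record
   new in year *t* is linked to the nearest record known before *t* by a
   least-cost path on the 8-connected grid graph. The edge weight between
   neighbouring cells *a*, *b* is the geometric (distance-weighted) step
   cost L·(c_a + c_b)/2 with L = 1 for orthogonal and √2 for diagonal moves;
   a path's *accumulated cost* is the sum of its step costs (multi-source
   Dijkstra). The union of all paths is the dispersal network.
3. **Population delineation.** Paths whose accumulated cost exceeds a
   threshold — interpretable as the maximum cost-distance covered in one
   year of dispersal — are removed; connected components of the remaining
   paths (nodes: endpoint cells) define populations; records inherit the
   population of any retained path endpoint in their cell, or stay
   unassigned. Populations are *robust* when the median raw-observation
   count per calendar year (zero-filling silent years) reaches a second
   threshold (default 10), else *sparse*.
4. **Expansion rates.** Per population, the distance-regression estimator:
   Euclidean distances d(p_i, p_0) to the population's first record, the
   per-year cumulative maximum of those distances (silent years carried
   forward), and the OLS slope of that series against year, in km/year —
   overall and, where configured, for manually chosen phases
   (lag / expansion / final).
5. **Sensitivity.** Both critical parameters — the accumulated-cost
   threshold and the robust-population definition — are swept on a grid,
   recording the mean overall rate across robust populations; a plateau in
   that surface identifies an insensitive operating range.

A synthetic invasion simulator (`generateInvasion()`) produces cost
surfaces and multi-introduction occurrence data with known ground truth in
the same cost-distance units, so the whole pipeline is testable end to end.

## Worked example

```r
library(seqlcp)

sim  <- generateInvasion(twoBasinScenario(seed = 1))  # two introductions, barrier between
snap <- snapRecords(sim$records, sim$cost)
cells <- dedupeRecords(sim$records, snap)
paths <- runSequential(sim$cost, cells)
paths
#> PathSet: 145 least-cost paths over years 2009-2016
#>   accumulated cost range: [0.2, 54.9657]
#>   seeds: 1; isolated records: 0

part <- delineate(paths, sim$records, snap, threshold = 1.0)
part
#> PopulationPartition: 2 populations (threshold 1, robust definition 10)
#>   robust: 2, sparse: 0; unassigned records: 0
#>    name first_year latest_year n_records median_per_year status
#>  A 2008       2008        2016        97              12 robust
#>  B 2011       2011        2016        61              12 robust

populationRates(part, sim$records)[, c("name", "phase", "rate_km_per_year", "r2")]
#>     name   phase rate_km_per_year        r2
#> 1 A 2008 overall         18.23977 0.8704815
#> 2 B 2011 overall         31.07376 0.9717842
```

The single path with accumulated cost ≈ 55 crosses the high-cost barrier
(it links the second introduction's first record back to the first
population); the threshold of 1.0 — the simulated yearly dispersal
budget — removes it, which is exactly how independent introductions are
revealed. The two populations then carry their own rates: the fronts
advance at ≈ 18 and ≈ 31 km/year and match the rates computed from the
simulator's ground-truth labels exactly (`recoveryReport()`).

A command-line front end with subcommands `prepare-cost`, `snap`, `run`,
`delineate`, `rates`, `sweep`, `simulate`, `all` ships in
`inst/scripts/seqlcp`. Rasters are exchanged as plain-text ESRI ASCII
grids, paths as GeoJSON, tables as CSV.

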