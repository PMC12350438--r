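# Threshold filtering, endpoint-connectivity components, record assignment
# and robust/sparse classification.

# minimal hand-built path table: endpoints A(1,1)-B(1,5), B(1,5)-C(4,4),
# D(9,9)-E(9,12)
fakePaths <- function(costs = c(1, 2, 3)) {
  data.frame(
    path_id = 1:3, year = c(2009, 2010, 2010),
    source_row = c(1, 1, 9), source_col = c(1, 5, 9),
    source_year = c(2008, 2009, 2009),
    target_row = c(1, 4, 9), target_col = c(5, 4, 12),
    accumulated_cost = costs)
}

test_that("threshold quantiles follow the empirical CDF without interpolation", {
  costs <- c(1, 2, 3, 4)
  expect_equal(quantileOfThreshold(costs, 2), 0.5)
  expect_equal(quantileOfThreshold(costs, 0.5), 0)
  expect_equal(thresholdOfQuantile(costs, 1), 4)
  expect_equal(thresholdOfQuantile(costs, 0), 1)
  expect_equal(thresholdOfQuantile(costs, 0.5), 2)
  # the two directions pair up on ties-free data
  set.seed(8)
  cs <- runif(97)
  q <- quantileOfThreshold(cs, thresholdOfQuantile(cs, 0.947))
  expect_gte(q, 0.947)
  expect_lt(q, 0.947 + 1 / length(cs) + 1e-12)
  expect_error(thresholdOfQuantile(numeric(0), 0.5), "empty")
})

test_that("filtering removes exactly the paths that exceed the threshold", {
  costs <- c(1.0, 4.4, 4.41)
  expect_identical(filterPaths(costs, 4.4), c(TRUE, TRUE, FALSE))
  expect_identical(filterPaths(costs, 10), rep(TRUE, 3))
  expect_identical(filterPaths(costs, 0), rep(FALSE, 3))
})

test_that("shared endpoints define population components deterministically", {
  comp <- pathComponents(fakePaths())
  expect_equal(comp$pathPopulation, c(1, 1, 2))  # A-B-C first (year 2008)
  expect_equal(sort(unique(comp$cellPopulation$population)), 1:2)
  # empty input: zero populations
  empty <- pathComponents(fakePaths()[0, ])
  expect_length(empty$pathPopulation, 0)
  expect_equal(nrow(empty$cellPopulation), 0)
})

test_that("records inherit the population of retained endpoint cells", {
  comp <- pathComponents(fakePaths())
  snapping <- data.frame(id = c("a", "b", "c", "lost"),
                         row = c(1, 1, 1, 20), col = c(5, 5, 1, 20),
                         cell = NA, impassable = FALSE)
  a <- assignRecords(snapping, comp$cellPopulation)
  expect_equal(a$population[1:3], c(1, 1, 1))  # cell-mates inherit together
  expect_true(is.na(a$population[4]))
})

test_that("classification zero-fills silent years and honours the boundary", {
  # counts {2019: 3, 2021: 5} -> series [3, 0, 5], median 3 -> sparse at 10
  a <- data.frame(record_id = 1:8, population = 1,
                  year = c(rep(2019, 3), rep(2021, 5)))
  pops <- classifyPopulations(a, robustDef = 10)
  expect_equal(pops$median_per_year, 3)
  expect_equal(pops$status, "sparse")
  # occupied-years-only alternative: median of [3, 5] = 4
  expect_equal(classifyPopulations(a, robustDef = 10,
                                   occupiedYearsOnly = TRUE)$median_per_year, 4)

  # median exactly at the definition is robust
  a2 <- data.frame(record_id = 1:20, population = 1,
                   year = rep(2019:2020, each = 10))
  expect_equal(classifyPopulations(a2, robustDef = 10)$status, "robust")
  expect_equal(classifyPopulations(a2, robustDef = 10.5)$status, "sparse")
})

test_that("population names combine label, first year and collision suffixes", {
  a <- data.frame(record_id = 1:6, population = c(1, 1, 2, 2, 3, 3),
                  year = c(2009, 2010, 2009, 2012, 2017, 2018),
                  label = c("Italy", "Italy", "Italy", "Italy",
                            "Austria", "Austria"))
  pops <- classifyPopulations(a, robustDef = 10)
  expect_identical(pops$name, c("Italy 2009a", "Italy 2009b", "Austria 2017"))
})

test_that("raising the threshold only merges populations", {
  sim <- generateInvasion(plateauScenario(2))
  pl <- runSyntheticPipeline(sim, threshold = 1.0)
  costs <- sort(unique(pathCosts(pl$paths)))
  t1 <- costs[floor(length(costs) * 0.3)]
  t2 <- costs[floor(length(costs) * 0.9)]
  p1 <- delineate(pl$paths, sim$records, pl$snapping, threshold = t1)
  p2 <- delineate(pl$paths, sim$records, pl$snapping, threshold = t2)
  a1 <- recordAssignments(p1)$population
  a2 <- recordAssignments(p2)$population
  # assigned records stay assigned...
  expect_true(all(!is.na(a2[!is.na(a1)])))
  expect_lte(length(unassignedRecords(p2)), length(unassignedRecords(p1)))
  # ...and every finer population maps into exactly one coarser population
  for (pop in unique(a1[!is.na(a1)]))
    expect_length(unique(a2[!is.na(a1) & a1 == pop]), 1)
})

test_that("record counts plus unassigned account for every raw record", {
  sim <- generateInvasion(twoBasinScenario(3))
  pl <- runSyntheticPipeline(sim, threshold = 1.0)
  pops <- populationTable(pl$partition)
  expect_equal(sum(pops$n_records) + length(unassignedRecords(pl$partition)),
               nrow(sim$records))
})

test_that("delineate requires exactly one of threshold and quantile", {
  sim <- generateInvasion(onePopulationScenario(1))
  pl <- runSyntheticPipeline(sim, threshold = 1.0)
  expect_error(delineate(pl$paths, sim$records, pl$snapping), "exactly one")
  expect_error(delineate(pl$paths, sim$records, pl$snapping,
                         threshold = 1, quantile = 0.9), "exactly one")
  pq <- delineate(pl$paths, sim$records, pl$snapping, quantile = 1.0)
  expect_equal(pq@threshold, max(pathCosts(pl$paths)))
})
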