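# The least-cost engine: geometric step costs, accumulated-cost surfaces,
# traceback and the annual sequential loop.

test_that("step costs are distance-weighted means of the two cell costs", {
  expect_equal(stepCost(1, 1, "orthogonal"), 1)
  expect_equal(stepCost(1, 1, "diagonal"), sqrt(2))
  expect_equal(stepCost(0.2, 0.6, "orthogonal"), 0.4)
  expect_equal(stepCost(0.2, 0.6, "diagonal"), 0.4 * sqrt(2))
  expect_identical(stepCost(Inf, 1, "orthogonal"), Inf)
  expect_error(stepCost(-0.1, 1, "orthogonal"), "negative")
})

test_that("uniform-cost accumulation equals octile distance times cost", {
  r <- costRaster(matrix(1, 6, 6))
  acc <- accumulate(r, data.frame(row = 1, col = 1))
  expect_equal(acc[1, 1], 0)
  expect_equal(acc[1, 4], 3)
  expect_equal(acc[3, 3], 2 * sqrt(2))
  expect_equal(acc[2, 3], 1 + sqrt(2))

  # non-unit cost scales the whole surface
  r2 <- costRaster(matrix(0.3, 8, 9))
  acc2 <- accumulate(r2, data.frame(row = 3, col = 7))
  for (rr in seq_len(8)) for (cc in seq_len(9))
    expect_equal(acc2[rr, cc], 0.3 * octile(rr - 3, cc - 7), tolerance = 1e-12)
})

test_that("accumulation agrees with the explicit-graph oracle", {
  done <- 0
  for (seed in 1:12) {
    case <- randomRasterCase(seed)
    if (is.null(case)) next
    acc <- accumulate(case$raster, case$sources)
    expect_equal(acc, oracleCostDistance(costValues(case$raster),
                                         case$sources),
                 tolerance = 1e-9)
    done <- done + 1
  }
  expect_gte(done, 8)
})

test_that("multi-source accumulation takes the minimum over sources", {
  r <- costRaster(matrix(1, 5, 9))
  acc <- accumulate(r, data.frame(row = c(3, 3), col = c(1, 9)))
  one <- accumulate(r, data.frame(row = 3, col = 1))
  other <- accumulate(r, data.frame(row = 3, col = 9))
  expect_equal(acc, pmin(one, other))
  expect_error(accumulate(costRaster(matrix(Inf, 3, 3)),
                          data.frame(row = 1, col = 1)), "impassable")
})

test_that("traced geometries are valid and reproduce their accumulated cost", {
  set.seed(21)
  v <- matrix(runif(48, 0.1, 1), 6, 8)
  v[c(5, 17, 30)] <- Inf
  r <- costRaster(v)
  acc <- accumulate(r, data.frame(row = 1, col = 1))
  for (target in list(c(6, 8), c(2, 7), c(6, 1))) {
    g <- tracePath(r, acc, target)
    expect_equal(unname(g[1, ]), c(1, 1))
    expect_equal(unname(g[nrow(g), ]), target)
    steps <- diff(g)
    expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))
    expect_equal(recostPath(r, g), acc[target[1], target[2]],
                 tolerance = 1e-9)
  }
})

test_that("traceback terminates and is deterministic on zero-cost corridors", {
  r <- costRaster(matrix(0, 5, 5))
  src <- data.frame(row = 3, col = 1)
  acc <- accumulate(r, src)
  g1 <- tracePath(r, acc, c(3, 5), sources = src)
  g2 <- tracePath(r, acc, c(3, 5), sources = src)
  expect_identical(g1, g2)
  expect_equal(unname(g1[1, ]), c(3, 1))
  expect_equal(unname(g1[nrow(g1), ]), c(3, 5))
  expect_equal(recostPath(r, g1), 0)
})

test_that("a year's targets connect to the nearest earlier record", {
  r <- costRaster(matrix(1, 7, 11))
  known <- data.frame(row = c(4, 4), col = c(1, 11), year = c(2008, 2009))
  new <- data.frame(row = 4, col = 4, year = 2010)
  res <- traceYear(r, known, new, 2010)
  expect_equal(nrow(res$paths), 1)
  expect_equal(res$paths$source_col, 1)  # closer of the two sources
  expect_equal(res$paths$accumulated_cost, 3)
  expect_equal(res$paths$source_year, 2008)
})

test_that("records surrounded by a barrier are reported isolated, not traced", {
  v <- matrix(1, 5, 5)
  v[2:4, 2:4] <- 1; v[c(2, 4), 2:4] <- Inf; v[3, c(2, 4)] <- Inf
  r <- costRaster(v)  # cell (3,3) is an island
  known <- data.frame(row = 1, col = 1, year = 2008)
  new <- data.frame(row = c(3, 5), col = c(3, 5), year = 2010)
  res <- traceYear(r, known, new, 2010)
  expect_equal(nrow(res$paths), 1)
  expect_equal(res$paths$target_row, 5)
  expect_equal(nrow(res$isolated), 1)
  expect_equal(res$isolated$row, 3)
  expect_match(res$isolated$reason, "barrier")
})

test_that("the sequential loop links each year to strictly earlier years", {
  r <- costRaster(matrix(1, 3, 8))
  # seed in 2008 plus one record per year 2009-2012, one cell apart
  cells <- data.frame(row = 2, col = 1:5, year = 2008:2012)
  ps <- runSequential(r, cells)
  expect_s4_class(ps, "PathSet")
  expect_equal(nPaths(ps), 4)
  expect_equal(pathCosts(ps), rep(1, 4))
  expect_equal(pathTable(ps)$source_col, 1:4)
  expect_equal(nrow(seedRecords(ps)), 1)

  # a single-year data set yields no paths at all
  ps0 <- runSequential(r, data.frame(row = 2, col = c(1, 5), year = 2010))
  expect_equal(nPaths(ps0), 0)
  expect_equal(nrow(seedRecords(ps0)), 2)
})

test_that("path counts satisfy n = records - seeds - isolated", {
  sim <- generateInvasion(twoBasinScenario(4))
  snapping <- snapRecords(sim$records, sim$cost)
  cells <- dedupeRecords(sim$records, snapping)
  ps <- runSequential(sim$cost, cells)
  expect_equal(nPaths(ps),
               nrow(cells) - nrow(seedRecords(ps)) - nrow(isolatedRecords(ps)))
})

test_that("output is invariant to record ordering within a year", {
  sim <- generateInvasion(onePopulationScenario(9))
  snapping <- snapRecords(sim$records, sim$cost)
  cells <- dedupeRecords(sim$records, snapping)
  ps1 <- runSequential(sim$cost, cells)
  set.seed(1)
  shuffled <- cells[sample(nrow(cells)), ]
  ps2 <- runSequential(sim$cost, shuffled)
  expect_equal(pathTable(ps1), pathTable(ps2))
  expect_identical(pathGeometry(ps1), pathGeometry(ps2))
})
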