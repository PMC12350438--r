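# Suitability-to-cost conversion and ASCII-grid round trips.

test_that("invertRescale maps the value range onto [0, 1] reversed", {
  s <- matrix(c(10, 20, 15, NA), 2, 2)
  cr <- invertRescale(s)
  v <- costValues(cr)
  expect_equal(v[1, 1], 1)    # minimum suitability -> maximum cost
  expect_equal(v[2, 1], 0)    # maximum suitability -> zero cost
  expect_equal(v[1, 2], 0.5)  # midpoint symmetry
  expect_identical(v[2, 2], Inf)  # NoData -> impassable

  # the documented preparation range of a 10 km suitability map
  cr2 <- invertRescale(matrix(c(33.04, 938.572), 1, 2),
                       vmin = 33.04, vmax = 938.572)
  expect_equal(costValues(cr2)[1, 1], 1)
  expect_equal(costValues(cr2)[1, 2], 0)
})

test_that("invertRescale is strictly monotone decreasing and involutive on [0,1]", {
  set.seed(42)
  s <- matrix(sort(runif(30, 5, 50)), 5, 6)
  v <- costValues(invertRescale(s))
  expect_true(all(diff(as.vector(v)) < 0))

  u <- matrix(runif(20), 4, 5)
  twice <- costValues(invertRescale(costValues(invertRescale(u, vmin = 0, vmax = 1)),
                                    vmin = 0, vmax = 1))
  expect_equal(twice, u, tolerance = 1e-12)
})

test_that("invertRescale rejects degenerate and out-of-range inputs", {
  expect_error(invertRescale(matrix(5, 3, 3)), "degenerate")
  expect_error(invertRescale(matrix(c(1, 60), 1, 2), vmin = 10, vmax = 50),
               "outside supplied range")
  expect_error(invertRescale(matrix(c(1, 2), 1, 2), vmin = 5, vmax = 3),
               "vmax")
})

test_that("loadCost passes pre-made costs through and inverts suitability", {
  tmp <- tempfile(fileext = ".asc")
  m <- matrix(5, 3, 3); m[2, 2] <- NA
  .asc <- costRaster(m, xmin = 1000, ymax = 9000, cellsize = 2000)
  writeCost(.asc, tmp)

  cr <- loadCost(tmp, mode = "cost")
  expect_equal(sum(costValues(cr) == 5), 8)
  expect_identical(costValues(cr)[2, 2], Inf)
  expect_equal(cellSize(cr), 2000)

  expect_error(loadCost(tmp, mode = "suitability"), "degenerate")
  expect_error(loadCost(tmp, mode = "cost", crs = "EPSG:4326"), "geographic")
})

test_that("write/read round trip preserves values, transform and nodata mask", {
  set.seed(7)
  m <- matrix(runif(35), 5, 7)
  m[c(3, 11, 30)] <- Inf
  r <- costRaster(m, xmin = -250000.5, ymax = 1750000.25, cellsize = 10000)
  tmp <- tempfile(fileext = ".asc")
  writeCost(r, tmp)
  back <- loadCost(tmp, mode = "cost")
  expect_identical(costValues(back), costValues(r))
  expect_identical(back@xmin, r@xmin)
  expect_identical(back@ymax, r@ymax)
  expect_identical(cellSize(back), cellSize(r))
  expect_identical(impassableMask(back), impassableMask(r))
})

test_that("the impassable set is preserved by preparation", {
  s <- matrix(runif(24, 1, 9), 4, 6)
  s[c(2, 9, 17)] <- NA
  cr <- invertRescale(s)
  expect_identical(which(is.infinite(costValues(cr))), c(2L, 9L, 17L))
  rr <- invertRescale(cr)  # re-inversion keeps the mask too
  expect_identical(which(is.infinite(costValues(rr))), c(2L, 9L, 17L))
})
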