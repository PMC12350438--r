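# Distance regression: distances to the first record, yearly cumulative
# maxima, overall and phase-wise OLS rates.

test_that("distances are planar metres from the earliest record", {
  d <- distancesToFirst(data.frame(x = c(0, 3000), y = c(0, 4000),
                                   year = c(2008, 2009)))
  expect_equal(as.vector(d), c(0, 5000))  # 3-4-5 triangle
  expect_equal(attr(d, "p0"), 1)

  # translation invariance
  set.seed(13)
  recs <- data.frame(x = runif(40, 0, 1e6), y = runif(40, 0, 1e6),
                     year = sample(2008:2020, 40, replace = TRUE))
  shifted <- transform(recs, x = x + 123456, y = y - 654321)
  expect_equal(as.vector(distancesToFirst(recs)),
               as.vector(distancesToFirst(shifted)), tolerance = 1e-9)
})

test_that("the yearly cumulative maximum carries silent years forward", {
  s <- cummaxByYear(c(0, 10000, 7000, 12000) * 1, 2008:2011)
  expect_equal(s$cummax, c(0, 10000, 10000, 12000))

  s2 <- cummaxByYear(c(0, 20000), c(2008, 2010))
  expect_equal(s2$year, 2008:2010)
  expect_equal(s2$cummax, c(0, 0, 20000))

  set.seed(4)
  s3 <- cummaxByYear(runif(30, 0, 1e5),
                     sample(2008:2020, 30, replace = TRUE),
                     span = c(2008, 2022))
  expect_true(all(diff(s3$cummax) >= 0))
  expect_equal(nrow(s3), 15)
})

test_that("OLS rates are slope/1000 with R2, never negative", {
  f <- fitRate(2008:2012, seq(0, 20000, 5000))
  expect_equal(f$rate_km_per_year, 5)
  expect_equal(f$r2, 1)
  expect_equal(f$n_years, 5)

  # zero-variance response: rate 0, undefined fit quality
  f0 <- fitRate(2020:2024, rep(35000, 5))
  expect_equal(f0$rate_km_per_year, 0)
  expect_true(is.na(f0$r2))

  expect_error(fitRate(2010, 0), "at least 2 years")

  # any non-decreasing response yields a non-negative slope
  set.seed(77)
  for (i in 1:20) {
    y <- cumsum(abs(rnorm(8, 0, 1e4)))
    expect_gte(fitRate(2008:2015, y)$rate_km_per_year, 0)
  }
})

test_that("phase fits share breakpoint years and recover exact kinks", {
  yr <- 2008:2024
  # piecewise-linear: 5 km/yr to 2011, then 50 km/yr
  cm <- ifelse(yr <= 2011, (yr - 2008) * 5000,
               3 * 5000 + (yr - 2011) * 50000)
  fits <- fitPhases(data.frame(year = yr, cummax = cm), breakpoints = 2011,
                    phaseNames = c("lag", "expansion"))
  expect_equal(fits$from, c(2008, 2011))
  expect_equal(fits$until, c(2011, 2024))  # 2011 belongs to both phases
  expect_equal(fits$rate_km_per_year, c(5, 50), tolerance = 1e-9)
  expect_equal(fits$r2, c(1, 1), tolerance = 1e-12)

  # no breakpoints: identical to a single overall fit
  expect_equal(fitPhases(data.frame(year = yr, cummax = cm)),
               fitRate(yr, cm))

  expect_error(fitPhases(data.frame(year = yr, cummax = cm),
                         breakpoints = c(2008)), "strictly inside")
  # a gapped (observed-years-only) series can leave a phase with one point
  expect_error(fitPhases(data.frame(year = c(2008, 2009, 2011),
                                    cummax = c(0, 1000, 2000)),
                         breakpoints = 2010,
                         phaseNames = c("a", "tiny")),
               "'tiny'.*fewer than 2 years")
})

test_that("per-population rates fit each population's own yearly series", {
  sim <- generateInvasion(twoBasinScenario(6))
  pl <- runSyntheticPipeline(sim, threshold = 1.0)
  rates <- pl$rates
  expect_equal(sort(unique(rates$population)),
               populationTable(pl$partition)$population)
  expect_true(all(rates$rate_km_per_year >= 0))
  expect_true(all(rates$phase == "overall"))

  # phase-wise fits appear alongside the overall fit when configured
  nm <- populationTable(pl$partition)$name[1]
  bp <- list(setNames(list(c(2011, 2014)), nm))[[1]]
  rates2 <- populationRates(pl$partition, sim$records, breakpoints = bp)
  sub <- rates2[rates2$name == nm, ]
  expect_setequal(sub$phase,
                  c("overall", "lag phase", "expansion phase", "final phase"))
})
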