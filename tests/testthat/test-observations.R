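# Snapping to raster cells and per-cell deduplication.

grid10 <- costRaster(matrix(0.5, 10, 12), xmin = 0, ymax = 100000,
                     cellsize = 10000)

test_that("points snap to the cell containing them, half-open convention", {
  # exact centre of cell (4, 7)
  ctr <- cellCenters(grid10, data.frame(row = 4, col = 7))
  s <- snapRecords(data.frame(id = "a", x = ctr$x, y = ctr$y, year = 2010),
                   grid10)
  expect_equal(c(s$row, s$col), c(4, 7))

  # point on the vertical edge between (1,1) and (1,2) belongs to (1,2)
  s2 <- snapRecords(data.frame(id = "b", x = 10000, y = 95000, year = 2010),
                    grid10)
  expect_equal(c(s2$row, s2$col), c(1, 2))
  # point on the horizontal edge between (1,1) and (2,1) belongs to (2,1)
  s3 <- snapRecords(data.frame(id = "c", x = 5000, y = 90000, year = 2010),
                    grid10)
  expect_equal(c(s3$row, s3$col), c(2, 1))
})

test_that("out-of-bounds records are rejected by id", {
  recs <- data.frame(id = c("ok", "bad"), x = c(5000, 2e6), y = c(5000, 0),
                     year = 2010)
  expect_error(snapRecords(recs, grid10), "bad")
})

test_that("snapping round-trips through cell centres", {
  set.seed(11)
  n <- 100
  recs <- data.frame(id = seq_len(n),
                     x = runif(n, 0, 12 * 10000 - 1),
                     y = runif(n, 100000 - 10 * 10000 + 1, 100000),
                     year = 2010)
  s <- snapRecords(recs, grid10)
  expect_true(all(s$row >= 1 & s$row <= 10 & s$col >= 1 & s$col <= 12))
  ctr <- cellCenters(grid10, s)
  s2 <- snapRecords(data.frame(id = recs$id, x = ctr$x, y = ctr$y,
                               year = 2010), grid10)
  expect_identical(s2[, c("row", "col")], s[, c("row", "col")])
})

test_that("dedupe keeps one record per cell with the earliest year", {
  ctr <- cellCenters(grid10, data.frame(row = c(3, 3, 5), col = c(4, 4, 6)))
  recs <- data.frame(id = c("r1", "r2", "r3"),
                     x = ctr$x, y = ctr$y, year = c(2012, 2010, 2015))
  s <- snapRecords(recs, grid10)
  cells <- dedupeRecords(recs, s)
  expect_equal(nrow(cells), 2)
  shared <- cells[cells$row == 3 & cells$col == 4, ]
  expect_equal(shared$year, 2010)
  expect_equal(shared$n_members, 2)
  expect_identical(shared$member_ids[[1]], c("r1", "r2"))  # input order
})

test_that("dedupe partitions the raw records and is stable under re-snapping", {
  set.seed(3)
  n <- 60
  recs <- data.frame(id = paste0("r", seq_len(n)),
                     x = runif(n, 0, 119999), y = runif(n, 1, 100000),
                     year = sample(2008:2015, n, replace = TRUE))
  s <- snapRecords(recs, grid10)
  cells <- dedupeRecords(recs, s)
  expect_equal(sum(cells$n_members), n)
  expect_false(anyDuplicated(cells[, c("row", "col")]) > 0)
  expect_true(all(vapply(seq_len(nrow(cells)), function(i) {
    yrs <- recs$year[match(cells$member_ids[[i]], recs$id)]
    cells$year[i] == min(yrs)
  }, logical(1))))
  # records on distinct cells dedupe to themselves
  solo <- cells[cells$n_members == 1, ]
  expect_true(all(recs$year[match(unlist(solo$member_ids), recs$id)] == solo$year))
})

test_that("records on impassable cells are kept but flagged", {
  m <- matrix(0.5, 10, 12); m[2, 2] <- Inf
  r <- costRaster(m, xmin = 0, ymax = 100000, cellsize = 10000)
  ctr <- cellCenters(r, data.frame(row = 2, col = 2))
  s <- snapRecords(data.frame(id = "sea", x = ctr$x, y = ctr$y, year = 2010), r)
  expect_true(s$impassable)
})

test_that("the isolation pre-filter drops only far-away records", {
  recs <- data.frame(id = c("a", "b", "far"),
                     x = c(0, 10000, 900000), y = c(0, 0, 0), year = 2010)
  expect_message(out <- filterIsolated(recs, maxKm = 100), "far")
  expect_identical(out$id, c("a", "b"))
  expect_identical(filterIsolated(recs, maxKm = 1000)$id, recs$id)
})

test_that("observation CSV reading validates schema and year range", {
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1:2, x = c(0, 1), y = c(0, 1),
                       year = c(2008, 2024)), tmp, row.names = FALSE)
  expect_equal(nrow(readObservations(tmp)), 2)
  write.csv(data.frame(id = 1, x = 0, y = 0, year = 1066), tmp,
            row.names = FALSE)
  expect_error(readObservations(tmp), "plausible range")
  write.csv(data.frame(id = 1, x = 0, yy = 0, year = 2010), tmp,
            row.names = FALSE)
  expect_error(readObservations(tmp), "missing column")
})

test_that("cell records survive a CSV round trip", {
  set.seed(5)
  recs <- data.frame(id = paste0("r", 1:20),
                     x = runif(20, 0, 119999), y = runif(20, 1, 100000),
                     year = sample(2008:2012, 20, replace = TRUE))
  cells <- dedupeRecords(recs, snapRecords(recs, grid10))
  tmp <- tempfile(fileext = ".csv")
  writeCellRecords(cells, tmp)
  back <- readCellRecords(tmp)
  expect_equal(back$row, cells$row)
  expect_equal(back$year, cells$year)
  expect_identical(back$member_ids, unname(cells$member_ids))
})
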