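test_that("fixture digits are deterministic with the stated pixel counts", {
  d1 <- make_fixture_digits()
  d2 <- make_fixture_digits()
  expect_identical(d1, d2)
  expect_equal(d1[["1"]]$n_active, 76)
  expect_equal(sum(!d1[["1"]]$grid), 708)
  for (p in d1) {
    expect_equal(dim(p$grid), c(28, 28))
    expect_gt(p$n_active, 0)
    # strictly inside the retina: empty one-pixel border
    expect_false(any(p$grid[c(1, 28), ]) || any(p$grid[, c(1, 28)]))
  }
})

test_that("noise epochs have the configured density and are independent", {
  pat <- make_fixture_digits()[["1"]]
  sched <- make_schedule(list(), numeric(0), 51 / 784)
  set.seed(9)
  acts <- replicate(3000, length(sample_epoch(sched, 784)$active))
  # binomial mean within a CLT band
  se <- sqrt(51 * (1 - 51 / 784)) / sqrt(3000)
  expect_lt(abs(mean(acts) - 51), 4 * se)
  # per-pixel activity uncorrelated across consecutive epochs
  set.seed(10)
  on <- replicate(2000, seq_len(784) %in% sample_epoch(sched, 784)$active)
  r <- cor(as.vector(on[1, -2000]), as.vector(on[1, -1]))
  expect_lt(abs(r), 0.08)
  # degenerate schedules
  empty <- make_schedule(list(), numeric(0), 0)
  expect_length(sample_epoch(empty, 784)$active, 0)
  only_pat <- make_schedule(list(pat), 1, 0.1)
  draw <- sample_epoch(only_pat, 784)
  expect_identical(draw$kind, "pattern")
  expect_identical(draw$active, pattern_active(pat))
})

test_that("fixed-count noise mode activates exactly the rounded count", {
  sched <- make_schedule(list(), numeric(0), 51 / 784, mode = "fixed")
  set.seed(2)
  for (i in 1:5) {
    a <- sample_epoch(sched, 784)$active
    expect_length(a, 51)
    expect_false(any(duplicated(a)))
  }
})

test_that("patterns round-trip through PGM and CSV", {
  p <- make_fixture_digits()[["1"]]
  f_pgm <- tempfile(fileext = ".pgm")
  write_pattern(p, f_pgm, "pgm")
  expect_identical(load_pattern(f_pgm)$grid, p$grid)
  f_csv <- tempfile(fileext = ".csv")
  write_pattern(p, f_csv, "csv")
  expect_identical(load_pattern(f_csv)$grid, p$grid)
})

test_that("binary PGM (P5) and IDX images are read correctly", {
  p <- make_fixture_digits()[["2"]]
  vals <- ifelse(t(p$grid), 255L, 0L) # PGM stores rows top to bottom
  f5 <- tempfile(fileext = ".pgm")
  con <- file(f5, "wb")
  writeChar("P5\n28 28\n255\n", con, eos = NULL)
  writeBin(as.raw(as.vector(vals)), con)
  close(con)
  expect_identical(load_pattern(f5)$grid, p$grid)
  # two-image IDX file; read the second
  fi <- tempfile(fileext = ".idx")
  con <- file(fi, "wb")
  writeBin(c(2051L, 2L, 28L, 28L), con, size = 4, endian = "big")
  writeBin(as.raw(rep(0L, 784)), con)
  writeBin(as.raw(as.vector(vals)), con)
  close(con)
  expect_identical(load_pattern(fi, format = "idx", index = 2)$grid, p$grid)
  expect_warning(load_pattern(fi, format = "idx", index = 1), "no active")
  expect_error(load_pattern(fi, format = "idx", index = 3), "range")
})

test_that("malformed bitmaps are rejected", {
  f <- tempfile(fileext = ".csv")
  write.table(matrix(0, 27, 28), f, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(load_pattern(f), "27x28")
  f0 <- tempfile(fileext = ".csv")
  write.table(matrix(0, 28, 28), f0, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_warning(load_pattern(f0), "no active pixels")
})
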