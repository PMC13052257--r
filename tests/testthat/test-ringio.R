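test_that("Tucson 999 terminator decodes values as hundredths of mm", {
  f <- write_rwl_lines("TST01 1990   100   200   999")
  out <- read_rwl(f)
  expect_length(out, 1L)
  expect_equal(out[[1]]$series_id, "TST01")
  expect_equal(out[[1]]$first_year, 1990L)
  expect_equal(out[[1]]$widths, c(1.00, 2.00))
})

test_that("Tucson -9999 terminator decodes values as thousandths of mm", {
  f <- write_rwl_lines("TST02 2000   1500   800   -9999")
  out <- read_rwl(f)
  expect_equal(out[[1]]$widths, c(1.5, 0.8))
  expect_equal(ring_years(out[[1]]), c(2000L, 2001L))
})

test_that("write/read round trip is the identity in both dialects", {
  series <- list(
    ring_series("ALPHA01", c(1.23, 0.57, 2.10, 0.94, 1.11), 1987),
    ring_series("BETA02", round(runif(27, 0.1, 4), 2), 1951))
  for (dialect in c("0.01", "0.001")) {
    f <- tempfile(fileext = ".rwl")
    write_rwl(series, f, dialect = dialect)
    back <- read_rwl(f)
    expect_length(back, 2L)
    for (i in 1:2) {
      expect_equal(back[[i]]$series_id, series[[i]]$series_id)
      expect_equal(back[[i]]$first_year, series[[i]]$first_year)
      expect_equal(back[[i]]$widths, series[[i]]$widths)
    }
    # bit-stable: writing the same input twice gives identical bytes
    f2 <- tempfile(fileext = ".rwl")
    write_rwl(series, f2, dialect = dialect)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("zero-width (absent) rings survive the round trip as 0.0", {
  # hand-decoded fixture: 0 in the value field is a dated but absent ring
  f <- write_rwl_lines(c("ABS01  1995    50     0    75   120   999"))
  out <- read_rwl(f)
  expect_equal(out[[1]]$widths, c(0.50, 0.00, 0.75, 1.20))
  expect_equal(which(out[[1]]$widths == 0), 2L)
  f2 <- tempfile(); write_rwl(out, f2)
  expect_equal(read_rwl(f2)[[1]]$widths, out[[1]]$widths)
})

test_that("a mid-series 999 value is data, not a terminator", {
  f <- write_rwl_lines("BIG01  2000   999   100   999")
  out <- read_rwl(f)
  expect_equal(out[[1]]$widths, c(9.99, 1.00))
})

test_that("decade lines spanning boundaries keep years contiguous", {
  rs <- ring_series("SPAN01", seq(0.5, 2.9, by = 0.1), 1987)  # 25 rings
  f <- tempfile(); write_rwl(list(rs), f)
  lines <- readLines(f)
  expect_gte(length(lines), 3L)  # 1987-1989, 1990-1999, 2000-...
  back <- read_rwl(f)[[1]]
  expect_equal(ring_years(back), 1987:2011)
  expect_equal(back$widths, rs$widths)
})

test_that("malformed input fails loudly with the offending line", {
  f <- write_rwl_lines(c("OK01   1990   100   200   999",
                         "BAD02  19xx   100   999"))
  expect_error(read_rwl(f), "line 2")
  # overlapping duplicate id (re-appearing after another series)
  f2 <- write_rwl_lines(c("DUP01  1990   100   999",
                          "OTH01  1990   100   999",
                          "DUP01  1950   100   999"))
  expect_error(read_rwl(f2), "duplicate")
  # non-contiguous decades within one series
  f3 <- write_rwl_lines(c("GAP01  1990   100   110   120   130   140",
                          "GAP01  2000   150   999"))
  expect_error(read_rwl(f3), "non-contiguous")
})

test_that("write_rwl rejects bad input and writes empty file for empty list", {
  f <- tempfile()
  write_rwl(list(), f)
  expect_identical(readLines(f), character(0))
  rs <- ring_series("NEG01", c(1, 2), 1990)
  rs$widths[2] <- -1  # bypass the constructor check
  expect_error(write_rwl(list(rs), f), "negative")
  wide <- ring_series("WIDE01", c(1234.5, 1), 1990)
  expect_error(write_rwl(list(wide), f, dialect = "0.001"), "overflow")
})

test_that("ring_series enforces its invariants", {
  expect_error(ring_series("X", numeric(0), 1990), "nonempty")
  expect_error(ring_series("X", c(1, -0.5), 1990), ">= 0")
  expect_error(ring_series("X", c(1, NA), 1990), "finite")
  rs <- ring_series("X", c(1, 2, 3), 2000, pith_offset = 4L)
  expect_equal(cambial_ages(rs), 5:7)
  expect_equal(max(ring_years(rs)), 2000 + 3 - 1)
})

test_that("read_monthly_table builds the year x month matrix with gaps", {
  f <- tempfile(fileext = ".csv")
  d <- data.frame(year = 1990, month = 1:12, value = 1:12)
  write.csv(d, f, row.names = FALSE)
  env <- read_monthly_table(f, "tmean")
  expect_s3_class(env, "monthly_env")
  expect_equal(env$years, 1990L)
  expect_equal(as.numeric(env$values[1, ]), 1:12)
  expect_equal(env$units, "degC")

  # missing June: one missing cell, no error
  write.csv(d[d$month != 6, ], f, row.names = FALSE)
  env2 <- read_monthly_table(f, "ppt")
  expect_equal(sum(is.na(env2$values)), 1L)
  expect_true(is.na(env2$values[1, 6]))

  # duplicates and bad months rejected
  write.csv(rbind(d, d[5, ]), f, row.names = FALSE)
  expect_error(read_monthly_table(f, "tmean"), "duplicate")
  write.csv(data.frame(year = 1990, month = 13, value = 1), f,
            row.names = FALSE)
  expect_error(read_monthly_table(f, "tmean"), "month")
  write.csv(data.frame(year = 1990, month = 1, value = "abc"), f,
            row.names = FALSE)
  expect_error(read_monthly_table(f, "tmean"), "non-numeric")
})

test_that("monthly tables round-trip through write_monthly_table", {
  set.seed(1)
  m <- matrix(rnorm(36, 100, 10), 3, 12)
  m[2, 7] <- NA
  env <- monthly_env("water_depth", 1990:1992, m)
  f <- tempfile(fileext = ".csv")
  write_monthly_table(env, f)
  back <- read_monthly_table(f, "water_depth")
  expect_equal(back$years, env$years)
  expect_equal(back$values, env$values)
})

test_that("isotope and covariate tables validate their keys", {
  f <- tempfile(fileext = ".csv")
  d <- data.frame(tree_id = "T1", year = c(2000, 2010),
                  cambial_age = c(50, 60), d13c = c(-26.1, -25.8))
  write.csv(d, f, row.names = FALSE)
  expect_silent(read_isotope_table(f))
  d2 <- d; d2$d13c[1] <- -10
  write.csv(d2, f, row.names = FALSE)
  expect_warning(read_isotope_table(f), "plausible")
  d3 <- rbind(d, d[1, ])
  write.csv(d3, f, row.names = FALSE)
  expect_error(read_isotope_table(f), "tree x year")

  write.csv(data.frame(tree_id = c("A", "B"), dist_to_road = c(100, 200)),
            f, row.names = FALSE)
  expect_equal(nrow(read_covariate_table(f)), 2L)
})
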