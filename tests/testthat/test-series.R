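test_that("read_timeseries parses CSV with outcome and control columns", {
  df <- tibble::tibble(
    date = format(months_from("2003-01", 24), "%Y-%m-%d"),
    J12_18 = rpois(24, 300),
    ach_noj = rpois(24, 5000)
  )
  path <- write_temp_csv(df)
  s <- read_timeseries(path, "date", "J12_18", "ach_noj")
  expect_s3_class(s, "monthly_series")
  expect_equal(nrow(s), 24)
  expect_equal(attr(s, "controls"), "ach_noj")
  expect_equal(s$outcome, as.numeric(df$J12_18))
  expect_equal(s$ach_noj, as.numeric(df$ach_noj))

  s2 <- read_timeseries(path, "date", "J12_18")
  expect_length(attr(s2, "controls"), 0)
})

test_that("schema, parse and contiguity failures are specific errors", {
  df <- tibble::tibble(date = format(months_from("2005-01", 6), "%Y-%m-%d"),
                       cases = 1:6)
  path <- write_temp_csv(df)
  expect_error(read_timeseries(path, "date", "counts"),
               class = "itspower_error_schema")
  expect_error(read_timeseries(path, "month", "cases"),
               class = "itspower_error_schema")

  bad <- df
  bad$date[3] <- "not-a-date"
  expect_error(read_timeseries(write_temp_csv(bad), "date", "cases"),
               "row 3", class = "itspower_error_parse")

  gap <- df[-3, ] # March 2005 missing between Feb and Apr
  expect_error(read_timeseries(write_temp_csv(gap), "date", "cases"),
               class = "itspower_error_contiguity")

  dup <- df
  dup$date[2] <- dup$date[1]
  expect_error(read_timeseries(write_temp_csv(dup), "date", "cases"),
               class = "itspower_error_contiguity")

  na_counts <- df
  na_counts$cases[4] <- NA
  expect_error(read_timeseries(write_temp_csv(na_counts), "date", "cases"),
               class = "itspower_error_value")
})

test_that("day-first dates parse only with an explicit format", {
  df <- tibble::tibble(date = c("15/01/2004", "10/02/2004", "01/03/2004"),
                       cases = c(3L, 4L, 5L))
  path <- write_temp_csv(df)
  expect_error(read_timeseries(path, "date", "cases"),
               class = "itspower_error_parse")
  s <- read_timeseries(path, "date", "cases", date_format = "%d/%m/%Y")
  expect_equal(s$date, as.Date(c("2004-01-01", "2004-02-01", "2004-03-01")))
})

test_that("YYYY-MM dates and within-month days normalize to month starts", {
  s <- make_series(1:3, start = "2011-01")
  s2 <- monthly_series(c("2011-01", "2011-02", "2011-03"), 1:3)
  s3 <- monthly_series(c("2011-01-07", "2011-02-28", "2011-03-15"), 1:3)
  expect_equal(s$date, s2$date)
  expect_equal(s$date, s3$date)
})

test_that("write/read round trip preserves the series exactly", {
  set.seed(1)
  s <- make_series(rpois(36, 120), controls = list(ach_noj = rpois(36, 900)),
                   outcome_name = "J12_18")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(s, path)
  s2 <- read_timeseries(path, "date", "J12_18", "ach_noj")
  expect_equal(s2$date, s$date)
  expect_equal(s2$outcome, s$outcome)
  expect_equal(s2$ach_noj, s$ach_noj)
  expect_equal(attr(s2, "controls"), attr(s, "controls"))
})

test_that("split_periods divides at the introduction month", {
  set.seed(2)
  s <- make_series(rpois(144, 200), start = "2003-01") # 2003-01..2014-12
  w <- analysis_window("2011-01", "2012-12")
  parts <- split_periods(s, w)
  expect_equal(nrow(parts$pre), 96)
  expect_equal(nrow(parts$post), 24)
  expect_equal(parts$post$date[1], as.Date("2011-01-01"))
  # concatenation restores the original slice bit-exactly
  expect_equal(c(parts$pre$outcome, parts$post$outcome), s$outcome[1:120])

  expect_error(split_periods(s, analysis_window("2003-01", "2003-06")),
               class = "itspower_error_range")
  one <- split_periods(s, analysis_window("2011-01", "2011-01"))
  expect_equal(nrow(one$post), 1)
})

test_that("truncate_baseline drops whole years and composes", {
  set.seed(3)
  s <- make_series(rpois(84, 150), start = "2003-01") # 2003-2009
  t3 <- truncate_baseline(s, 3)
  expect_equal(t3$date[1], as.Date("2006-01-01"))
  expect_equal(nrow(t3), 48)
  expect_identical(truncate_baseline(s, 0), s)
  expect_error(truncate_baseline(make_series(rpois(24, 10)), 2),
               class = "itspower_error_range")
  # composition: dropping a then b equals dropping a + b
  expect_equal(truncate_baseline(truncate_baseline(s, 1), 2)$outcome,
               truncate_baseline(s, 3)$outcome)
})
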