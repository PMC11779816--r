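test_that("reading a long CSV fills timestamp gaps with missing bins", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,animal_id,ali",
    "2024-01-01T00:00:00,m1,5",
    "2024-01-01T00:01:00,m1,0",
    "2024-01-01T00:03:00,m1,8"
  ), f)
  act <- read_activity_csv(f)
  expect_equal(nrow(act), 4)
  expect_equal(act$ali, c(5, 0, NA, 8))
})

test_that("validation rejects out-of-range ALI, bad timestamps and duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,animal_id,ali", "2024-01-01T00:00:00,m1,120"), f)
  expect_error(read_activity_csv(f), "out of \\[0,100\\]")

  writeLines(c("timestamp,animal_id,ali", "not-a-time,m1,5"), f)
  expect_error(read_activity_csv(f), "timestamp")

  writeLines(c("timestamp,animal_id,ali",
               "2024-01-01T00:00:00,m1,5",
               "2024-01-01T00:00:00,m1,6"), f)
  expect_error(read_activity_csv(f), "duplicate")
})

test_that("write/read round trip preserves values, missing mask and metadata", {
  act <- make_activity(c(1.25, NA, 3.5, 0), sex = "F", genotype = "WT")
  f <- withr::local_tempfile(fileext = ".csv")
  write_activity_csv(act, f)
  back <- read_activity_csv(f)
  expect_equal(back$ali, act$ali)
  expect_equal(back$sex, act$sex)
  expect_equal(back$genotype, act$genotype)
  expect_equal(back$time, act$time)
})

test_that("wide-dialect exports are accepted on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "timestamp,m1,m2",
    "2024-01-01T00:00:00,1,4",
    "2024-01-01T00:01:00,2,5"
  ), f)
  act <- read_activity_csv(f)
  expect_setequal(unique(act$animal_id), c("m1", "m2"))
  expect_equal(act$ali[act$animal_id == "m2"], c(4, 5))
})

test_that("cycle expansion yields 2 episodes per day summing to 24 h", {
  for (d in c(1, 2, 7)) {
    s <- schedule_cycle(T0, days = d)
    expect_equal(nrow(s), 2 * d)
    expect_equal(
      sum(as.numeric(difftime(s$end, s$start, units = "hours"))), 24 * d
    )
    expect_equal(s$state, rep(c("light", "dark"), d))
  }
})

test_that("schedule validation flags overlaps and unknown states", {
  bad <- tibble::tibble(
    start = T0 + c(0, 10 * 3600), end = T0 + c(12, 22) * 3600,
    state = c("light", "dark")
  )
  expect_error(validate_schedule(bad), "overlap")
  expect_error(
    validate_schedule(tibble::tibble(start = T0, end = T0 + 3600,
                                     state = "dusk")),
    "unknown lighting state"
  )
})

test_that("constant-condition schedules are a single episode over the span", {
  s <- schedule_constant(T0, days = 10, state = "dark")
  expect_equal(nrow(s), 1)
  expect_equal(as.numeric(difftime(s$end, s$start, units = "days")), 10)
})

test_that("schedule files round trip through CSV and JSON", {
  s <- schedule_cycle(T0, days = 2)
  fc <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(s, start = format(start, "%Y-%m-%dT%H:%M:%S"),
                                 end = format(end, "%Y-%m-%dT%H:%M:%S")), fc)
  expect_equal(read_schedule(fc)$state, s$state)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    dplyr::mutate(s, start = format(start, "%Y-%m-%dT%H:%M:%S"),
                  end = format(end, "%Y-%m-%dT%H:%M:%S")),
    fj, auto_unbox = TRUE
  )
  expect_equal(read_schedule(fj)$start, s$start)
})

test_that("metrics tables round trip with empty fields for undefined values", {
  m <- tibble::tibble(
    animal_id = rep(c("a", "b"), each = 3),
    phase = rep(c("LD", "DD", "LL"), 2),
    is_value = c(0.9, NA, 0.3, 0.8, 0.7, NA)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(m, f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 6)
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(back$is_value, m$is_value)
  # empty input -> header only
  write_metrics_csv(m[0, ], f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 0)
})
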