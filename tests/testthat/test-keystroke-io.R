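test_that("study weeks partition the study window into 7-day blocks", {
  cal <- test_calendar()
  dates <- study_dates(cal)
  expect_length(dates, 35L)
  wk <- study_week_of(dates, cal)
  expect_equal(unname(table(wk)), rep(7L, 5L), ignore_attr = TRUE)
  # half-open boundaries
  expect_identical(study_week_of(cal$start_date, cal), 1L)
  expect_identical(study_week_of(cal$start_date + 7, cal), 2L)
  expect_identical(study_week_of(cal$start_date + 34, cal), 5L)
  expect_identical(study_week_of(cal$start_date + 35, cal), NA_integer_)
  expect_identical(study_week_of(cal$start_date - 1, cal), NA_integer_)
})

test_that("calendar validation and config round-trip", {
  expect_error(study_calendar("2023-05-01", n_weeks = 2, n_adjustment_weeks = 2),
               "n_adjustment_weeks")
  cal <- test_calendar()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calendar_config(cal, f)
  cal2 <- read_calendar_config(f)
  expect_equal(cal2, cal)
})

test_that("well-formed CSV parses in press order and malformed rows are counted", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,press_time,release_time",
    "P01,2023-05-02T10:00:00.500,2023-05-02T10:00:00.620",
    "P01,2023-05-02T09:59:59.999,2023-05-02T10:00:00.100",
    "P01,2023-05-02T22:30:00.000,2023-05-02T22:30:00.050",
    "P01,2023-05-02T11:00:00.000,2023-05-02T10:59:59.000",  # release < press
    "P01,not-a-time,2023-05-02T12:00:00.000"
  ), f)
  log <- read_event_log(f)
  expect_s3_class(log, "event_log")
  expect_identical(log$participant_id, "P01")
  expect_identical(nrow(log$events), 3L)
  expect_identical(log$n_skipped, 2L)
  expect_true(!is.unsorted(log$events$press_time))
})

test_that("empty or missing logs raise informative errors", {
  expect_error(read_event_log(file.path(tempdir(), "nope.csv")), "not found")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,press_time,release_time",
               "P01,bad,worse"), f)
  expect_error(read_event_log(f), "no parseable")
})

test_that("events outside the study window are dropped and counted", {
  cal <- test_calendar()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,press_time,release_time",
    "P01,2023-04-30T23:59:59.999,2023-05-01T00:00:00.100",  # before start
    "P01,2023-05-10T12:00:00.000,2023-05-10T12:00:00.080",
    "P01,2023-06-05T00:00:00.000,2023-06-05T00:00:00.050"   # after end
  ), f)
  log <- read_event_log(f, calendar = cal)
  expect_identical(nrow(log$events), 1L)
  expect_identical(log$n_out_of_range, 2L)
})

test_that("write/read round-trips are identity at millisecond precision", {
  cal <- test_calendar()
  gen <- generate_participant(small_cohort_config()$profiles$no, cal,
                              seed = 5L, participant_id = "P01")
  log <- gen$log
  ms <- function(t) round(as.numeric(t) * 1000)
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_event_log(log, f, format = fmt)
    back <- read_event_log(f, format = fmt)
    expect_identical(back$participant_id, log$participant_id)
    expect_identical(ms(back$events$press_time), ms(log$events$press_time))
    expect_identical(ms(back$events$release_time), ms(log$events$release_time))
  }
})

test_that("reading a shuffled file yields the same event log as the sorted file", {
  cal <- test_calendar()
  gen <- generate_participant(small_cohort_config()$profiles$no, cal,
                              seed = 6L, participant_id = "P01")
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_log(gen$log, f)
  lines <- readLines(f)
  set.seed(1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(lines[1], sample(lines[-1])), f2)
  a <- read_event_log(f); b <- read_event_log(f2)
  expect_equal(as.numeric(b$events$press_time), as.numeric(a$events$press_time))
  expect_equal(as.numeric(b$events$release_time),
               as.numeric(a$events$release_time))
})

test_that("mixed participant ids in one log are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,press_time,release_time",
               "P01,2023-05-02T10:00:00.000,2023-05-02T10:00:00.100",
               "P02,2023-05-02T11:00:00.000,2023-05-02T11:00:00.100"), f)
  expect_error(read_event_log(f), "mixes participant ids")
})

test_that("ULS-8 reader validates items, duplicates, and cardinality", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("participant_id", paste0("q", 1:8)), collapse = ",")
  writeLines(c(hdr, "P01,1,1,1,1,1,1,4,4"), f)
  r <- read_uls8_file(f)
  expect_identical(unname(unlist(r[1, paste0("q", 1:8)])),
                   c(1L, 1L, 1L, 1L, 1L, 1L, 4L, 4L))

  writeLines(c(hdr, "P01,1,1,5,1,1,1,4,4"), f)
  expect_error(read_uls8_file(f), "q3")

  writeLines(c(hdr, "P01,1,1,1,1,1,1,4,4", "P01,2,2,2,2,2,2,3,3"), f)
  expect_error(read_uls8_file(f), "duplicate")

  rows <- sprintf("P%02d,%s", 1:59,
                  apply(matrix(sample(1:4, 59 * 8, replace = TRUE), 59), 1,
                        paste, collapse = ","))
  writeLines(c(hdr, rows), f)
  expect_identical(nrow(read_uls8_file(f)), 59L)
})
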