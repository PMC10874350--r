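test_that("bins tile the day and match the stated boundaries", {
  tb <- time_bins()
  expect_identical(tb$start_hour, c(0, 6, 12, 17, 21))
  expect_identical(tb$end_hour[5], 24)
  expect_identical(as.character(bin_of(5 + 59 / 60 + 59.999 / 3600)), "sleep")
  expect_identical(as.character(bin_of(6)), "morning")
  expect_identical(as.character(bin_of(17)), "evening")
  # enumerate all 1440 whole minutes: 360/360/300/240/180 per bin
  mins <- (0:1439) / 60
  expect_identical(unname(c(table(bin_of(mins)))),
                   c(360L, 360L, 300L, 240L, 180L))
  expect_error(bin_of(24), "\\[0, 24\\)")
})

test_that("daily_bin_counts bins events by press time with zero-filled dates", {
  cal <- test_calendar()
  d <- cal$start_date + 8  # a post-adjustment date
  mk <- function(hms) as.POSIXct(paste(format(d), hms), tz = "UTC")
  press <- mk(c("01:00:00", "07:00:00", "22:00:00"))
  log <- lonelykeys:::new_event_log(
    "P01", data.frame(press_time = press, release_time = press + 0.1))
  days <- daily_bin_counts(log, cal)
  expect_identical(nrow(days), 28L)  # one row per post-adjustment date
  row <- days[days$date == d, ]
  expect_identical(unname(unlist(row[c("sleep", "morning", "afternoon",
                                       "evening", "night")])),
                   c(1L, 1L, 0L, 0L, 1L))
  expect_identical(row$total, 3L)
  expect_identical(sum(days$total), 3L)  # conservation
  # all other dates present with zero counts
  expect_true(all(days$total[days$date != d] == 0L))
  expect_identical(days$day_type,
                   ifelse(format(days$date, "%u") %in% c("6", "7"),
                          "weekend", "weekday"))
})

test_that("completeness filter implements the 3-of-4 complete-weeks rule", {
  cal <- test_calendar()
  zero_on <- function(idx) {
    make_days(cal, counts = function(i) {
      if (i %in% idx) integer(5) else rep(1L, 5L)
    })
  }
  # full data
  dec <- completeness_filter(zero_on(integer(0)), cal)
  expect_true(dec$included)
  expect_identical(dec$complete_weeks, 2:5)
  # one zero day in each of weeks 2 and 3 -> only 2 complete weeks
  dec <- completeness_filter(zero_on(c(1, 8)), cal)
  expect_false(dec$included)
  expect_identical(dec$complete_weeks, 4:5)
  expect_match(dec$reason, "2, 3")
  # zero day in week 2 only -> included via weeks 3,4,5
  dec <- completeness_filter(zero_on(3), cal)
  expect_true(dec$included)
  expect_identical(dec$complete_weeks, 3:5)
})

test_that("profile averaging follows the per-day-ratio convention", {
  cal <- test_calendar()
  # two active days: (1,1,1,1,1) and (0,0,0,0,5); rest zero
  days <- make_days(cal, counts = function(i) {
    if (i == 1) rep(1L, 5) else if (i == 2) c(0L, 0L, 0L, 0L, 5L) else integer(5)
  })
  p <- participant_profile(days[1:2, ])
  expect_equal(unname(p$mean_ratios), c(0.1, 0.1, 0.1, 0.1, 0.6))
  expect_equal(unname(p$mean_counts), c(0.5, 0.5, 0.5, 0.5, 3))
  # pooled alternative diverges when daily totals differ:
  # days (1,1,1,1,1) and (0,0,0,0,10) -> pooled (1,1,1,1,11)/15
  days10 <- days
  days10[2, c("night", "total")] <- c(10L, 10L)
  p2 <- participant_profile(days10[1:2, ], ratio_method = "pooled")
  expect_equal(unname(p2$mean_ratios), c(1, 1, 1, 1, 11) / 15)
  p2b <- participant_profile(days10[1:2, ])
  expect_equal(unname(p2b$mean_ratios), c(0.1, 0.1, 0.1, 0.1, 0.6))
  # single-day identity
  one <- make_days(cal, counts = function(i)
    if (i == 1) c(2L, 0L, 0L, 0L, 0L) else integer(5))
  p3 <- participant_profile(one[1, , drop = FALSE])
  expect_equal(unname(p3$mean_counts), c(2, 0, 0, 0, 0))
  expect_equal(unname(p3$mean_ratios), c(1, 0, 0, 0, 0))
  # zero-total days count toward the count mean, not the ratio mean
  p4 <- participant_profile(days[1:3, ])
  expect_equal(unname(p4$mean_counts), c(1, 1, 1, 1, 6) / 3)
  expect_equal(unname(p4$mean_ratios), c(0.1, 0.1, 0.1, 0.1, 0.6))
  expect_identical(p4$n_days_used, 3L)
})

test_that("ratio profiles sum to one and are day-order invariant", {
  cal <- test_calendar()
  set.seed(11)
  days <- make_days(cal, counts = function(i)
    as.integer(rpois(5, c(3, 10, 15, 20, 12))))
  p <- participant_profile(days)
  for (v in list(p$mean_ratios, p$weekday_mean_ratios, p$weekend_mean_ratios)) {
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0 & v <= 1))
  }
  perm <- days[sample(nrow(days)), ]
  expect_equal(participant_profile(perm)[-1], p[-1])
})

test_that("a variant with no qualifying days is flagged undefined", {
  cal <- test_calendar()
  days <- make_days(cal, counts = function(i) rep(1L, 5))
  days[days$day_type == "weekend", c("sleep", "morning", "afternoon",
                                     "evening", "night", "total")] <- 0L
  p <- participant_profile(days)
  expect_identical(p$n_weekend_days_used, 0L)
  expect_true(all(is.na(p$weekend_mean_ratios)))
  expect_false(anyNA(p$weekday_mean_ratios))
})

test_that("vectorized cohort profiles match the per-participant reference path", {
  cfg <- small_cohort_config(seed = 31L)
  coh <- generate_cohort(cfg, events = FALSE)
  cp <- lonelykeys:::cohort_profiles(coh$daily_counts, cfg$calendar)
  for (pid in sample(cp$profiles$participant_id, 4)) {
    days <- coh$daily_counts[coh$daily_counts$participant_id == pid, ]
    days <- days[!is.na(study_week_of(days$date, cfg$calendar)) &
                   study_week_of(days$date, cfg$calendar) > 1, ]
    dec <- completeness_filter(days, cfg$calendar)
    expect_true(dec$included)
    p <- participant_profile(days, dec$complete_weeks, cfg$calendar)
    row <- cp$profiles[cp$profiles$participant_id == pid, ]
    bins <- c("sleep", "morning", "afternoon", "evening", "night")
    expect_equal(unname(unlist(row[paste0("count_", bins)])),
                 unname(p$mean_counts))
    expect_equal(unname(unlist(row[paste0("ratio_", bins)])),
                 unname(p$mean_ratios))
    expect_equal(unname(unlist(row[paste0("wd_", bins)])),
                 unname(p$weekday_mean_ratios))
    expect_equal(unname(unlist(row[paste0("we_", bins)])),
                 unname(p$weekend_mean_ratios))
    expect_identical(row$n_days_used, p$n_days_used)
  }
})
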