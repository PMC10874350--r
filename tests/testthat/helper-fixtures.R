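# Shared fixtures built in code: tiny calendars, constructed day tables,
# and scaled-down cohort configs used across test files.

test_calendar <- function() study_calendar("2023-05-01")  # a Monday

# Build a one-participant daily-counts table over the post-adjustment
# window; `counts` is a function(date_index) -> length-5 integer vector,
# defaulting to one keystroke per bin each day.
make_days <- function(calendar = test_calendar(),
                      counts = function(i) rep(1L, 5L),
                      pid = "P001") {
  dates <- study_dates(calendar, post_adjustment = TRUE)
  m <- t(vapply(seq_along(dates), counts, integer(5)))
  colnames(m) <- c("sleep", "morning", "afternoon", "evening", "night")
  out <- data.frame(participant_id = pid, date = dates,
                    day_type = ifelse(format(dates, "%u") %in% c("6", "7"),
                                      "weekend", "weekday"),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  out$total <- as.integer(rowSums(m))
  out
}

# Low-rate cohort config for fast event-level tests
small_cohort_config <- function(seed = 101L,
                                group_sizes = c(no = 3L, moderate = 3L,
                                                severe = 3L, very_severe = 3L)) {
  profs <- lapply(default_profiles(), function(p) {
    group_intensity_profile(p$label, p$weekday_rates / 30,
                            p$weekend_rates / 30,
                            day_dropout_prob = 0, overdispersion = 0.3)
  })
  sim_cohort_config(group_sizes = group_sizes, profiles = profs, seed = seed)
}
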