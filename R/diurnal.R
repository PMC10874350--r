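# Diurnal feature extraction: five clock-time bins, per-day bin counts,
# the weekly-completeness filter, and per-participant averaged count and
# ratio profiles (overall and weekday/weekend).

.BIN_LABELS <- c("sleep", "morning", "afternoon", "evening", "night")
.BIN_STARTS <- c(0, 6, 12, 17, 21)   # hours, half-open [start, end)
.BIN_ENDS   <- c(6, 12, 17, 21, 24)

#' The five diurnal time bins
#'
#' The 24-hour day is tiled by five half-open clock-time bins:
#' sleep 00:00-06:00, morning 06:00-12:00, afternoon 12:00-17:00,
#' evening 17:00-21:00, night 21:00-24:00.
#'
#' @return data.frame with columns `label`, `start_hour`, `end_hour`.
#' @export
time_bins <- function() {
  data.frame(label = .BIN_LABELS, start_hour = .BIN_STARTS,
             end_hour = .BIN_ENDS, stringsAsFactors = FALSE)
}

#' Assign clock times to diurnal bins
#'
#' @param clock_time numeric hours in `[0, 24)`, or `POSIXct` (the clock
#'   time of day is used; the date is ignored).
#' @return Factor with levels `sleep`, `morning`, `afternoon`, `evening`,
#'   `night`.
#' @examples
#' bin_of(c(5.999, 6, 17, 23.5))
#' @export
bin_of <- function(clock_time) {
  if (inherits(clock_time, "POSIXct")) {
    secs <- as.numeric(clock_time) %% 86400
    hours <- secs / 3600
  } else {
    hours <- as.numeric(clock_time)
  }
  if (any(!is.finite(hours) | hours < 0 | hours >= 24))
    stop("clock_time must lie in [0, 24)")
  idx <- findInterval(hours, .BIN_STARTS)
  factor(.BIN_LABELS[idx], levels = .BIN_LABELS)
}

.day_type_of <- function(date) {
  # ISO weekday: 6 = Saturday, 7 = Sunday
  ifelse(format(date, "%u") %in% c("6", "7"), "weekend", "weekday")
}

#' Per-day five-bin keystroke counts
#'
#' Counts each event once, in the bin of its press timestamp, on the
#' calendar date of its press timestamp. One record is produced for every
#' post-adjustment study date (zero-count days included), so downstream
#' completeness filtering sees logging gaps as zero-total days.
#'
#' @param log an `event_log` (see [read_event_log()]).
#' @param calendar a [study_calendar()].
#' @return data.frame with one row per post-adjustment study date: columns
#'   `participant_id`, `date`, `day_type` (`weekday`/`weekend`), the five
#'   bin counts `sleep`..`night`, and `total`.
#' @export
daily_bin_counts <- function(log, calendar) {
  stopifnot(inherits(log, "event_log"), inherits(calendar, "study_calendar"))
  dates <- study_dates(calendar, post_adjustment = TRUE)
  out <- data.frame(participant_id = log$participant_id, date = dates,
                    day_type = .day_type_of(dates), stringsAsFactors = FALSE)
  m <- matrix(0L, nrow = length(dates), ncol = 5L,
              dimnames = list(NULL, .BIN_LABELS))
  press <- log$events$press_time
  if (length(press) > 0L) {
    ev_date <- as.Date(press, tz = .STUDY_TZ)
    keep <- ev_date %in% dates
    if (any(keep)) {
      di <- match(ev_date[keep], dates)
      bi <- as.integer(bin_of(press[keep]))
      tab <- table(factor(di, levels = seq_along(dates)),
                   factor(bi, levels = 1:5))
      m <- matrix(as.integer(tab), nrow = length(dates),
                  dimnames = list(NULL, .BIN_LABELS))
    }
  }
  out <- cbind(out, as.data.frame(m))
  out$total <- as.integer(rowSums(m))
  out
}

#' Weekly-completeness inclusion filter
#'
#' A post-adjustment study week is complete when all 7 of its days have a
#' nonzero keystroke total. A participant is included when at least
#' `min_complete_weeks` of the post-adjustment weeks are complete (the
#' 3-of-4 rule under the default 5-week calendar).
#'
#' @param days per-day counts from [daily_bin_counts()] (one participant).
#' @param calendar a [study_calendar()].
#' @param min_complete_weeks minimum number of complete weeks (default 3).
#' @return List with `participant_id`, `included` (logical),
#'   `complete_weeks` (integer vector), and a human-readable `reason`.
#' @export
completeness_filter <- function(days, calendar, min_complete_weeks = 3L) {
  stopifnot(inherits(calendar, "study_calendar"))
  weeks <- analysis_weeks(calendar)
  wk <- study_week_of(days$date, calendar)
  complete <- vapply(weeks, function(w) {
    idx <- which(wk == w)
    length(idx) == 7L && all(days$total[idx] > 0L)
  }, logical(1))
  complete_weeks <- weeks[complete]
  included <- length(complete_weeks) >= min_complete_weeks
  reason <- if (all(complete)) {
    "all analysis weeks complete"
  } else {
    sprintf("incomplete week%s: %s",
            if (sum(!complete) == 1L) "" else "s",
            paste(weeks[!complete], collapse = ", "))
  }
  list(participant_id = days$participant_id[1],
       included = included,
       complete_weeks = complete_weeks,
       reason = reason)
}

#' Per-participant diurnal typing profile
#'
#' Averages per-day bin counts and per-day count ratios over the days of
#' the participant's complete weeks. A day's ratio vector is its bin counts
#' divided by its total; zero-total days contribute to the count means but
#' are skipped in the ratio means (0/0 is undefined). Weekday and weekend
#' ratio profiles average over the respective day-type subsets; a variant
#' with no qualifying day is returned as `NA` with its `n_*_used` count 0.
#'
#' @param days per-day counts from [daily_bin_counts()] (one participant).
#' @param complete_weeks integer vector of complete week indices from
#'   [completeness_filter()]; only days inside these weeks enter the
#'   profile. `NULL` uses all provided days.
#' @param calendar a [study_calendar()] (required when `complete_weeks`
#'   is given).
#' @param ratio_method `"per_day"` (default) averages per-day ratio
#'   vectors; `"pooled"` divides the summed counts by the summed total.
#' @return List of class `participant_profile` with fields `participant_id`,
#'   `mean_counts`, `mean_ratios`, `weekday_mean_ratios`,
#'   `weekend_mean_ratios` (named length-5 numerics), and the day tallies
#'   `n_days_used`, `n_weekdays_used`, `n_weekend_days_used` (days with
#'   nonzero totals for the ratio variants).
#' @export
participant_profile <- function(days, complete_weeks = NULL, calendar = NULL,
                                ratio_method = c("per_day", "pooled")) {
  ratio_method <- match.arg(ratio_method)
  if (!is.null(complete_weeks)) {
    if (is.null(calendar))
      stop("calendar is required when complete_weeks is given")
    days <- days[study_week_of(days$date, calendar) %in% complete_weeks, ,
                 drop = FALSE]
  }
  if (nrow(days) == 0L) stop("no days to profile")
  m <- as.matrix(days[.BIN_LABELS])
  total <- days$total
  mean_counts <- colMeans(m)

  ratio_mean <- function(rows) {
    rows <- rows[total[rows] > 0L]
    if (length(rows) == 0L)
      return(list(r = stats::setNames(rep(NA_real_, 5L), .BIN_LABELS), n = 0L))
    sub <- m[rows, , drop = FALSE]
    r <- if (ratio_method == "per_day") {
      colMeans(sub / total[rows])
    } else {
      colSums(sub) / sum(total[rows])
    }
    list(r = r, n = length(rows))
  }

  all_r <- ratio_mean(seq_len(nrow(days)))
  wd_r <- ratio_mean(which(days$day_type == "weekday"))
  we_r <- ratio_mean(which(days$day_type == "weekend"))

  structure(
    list(participant_id = days$participant_id[1],
         mean_counts = mean_counts,
         mean_ratios = all_r$r,
         weekday_mean_ratios = wd_r$r,
         weekend_mean_ratios = we_r$r,
         n_days_used = nrow(days),
         n_weekdays_used = wd_r$n,
         n_weekend_days_used = we_r$n),
    class = "participant_profile"
  )
}

# Vectorized cohort-level inclusion + profiles over a stacked daily-counts
# table (all participants). Semantics identical to completeness_filter()
# + participant_profile(); a property test asserts the equivalence. Used
# on the hot path of replicated simulation studies.
cohort_profiles <- function(daily_counts, calendar, min_complete_weeks = 3L,
                            ratio_method = c("per_day", "pooled")) {
  ratio_method <- match.arg(ratio_method)
  dt <- data.table::as.data.table(daily_counts)
  dt <- dt[!is.na(study_week_of(date, calendar)) &
             study_week_of(date, calendar) > calendar$n_adjustment_weeks]
  dt[, week := study_week_of(date, calendar)]

  wk_complete <- dt[, .(complete = .N == 7L && all(total > 0L)),
                    by = .(participant_id, week)]
  incl <- wk_complete[, .(
    n_complete = sum(complete),
    complete_weeks = list(week[complete]),
    incomplete_weeks = list(week[!complete])
  ), by = participant_id]
  incl[, included := n_complete >= min_complete_weeks]
  incl[, reason := vapply(incomplete_weeks, function(w) {
    if (length(w) == 0L) "all analysis weeks complete"
    else sprintf("incomplete week%s: %s", if (length(w) == 1L) "" else "s",
                 paste(w, collapse = ", "))
  }, "")]

  # included participants, days inside their complete weeks only
  keep <- merge(dt, wk_complete, by = c("participant_id", "week"))
  keep <- keep[complete == TRUE &
                 participant_id %in% incl[included == TRUE, participant_id]]
  keep[, complete := NULL]

  profs <- NULL
  if (nrow(keep) > 0L) {
    bins <- .BIN_LABELS
    count_part <- keep[, c(.(n_days_used = .N,
                             total_keystrokes = sum(total)),
                           lapply(.SD, mean)),
                       by = participant_id, .SDcols = bins]
    data.table::setnames(count_part, bins, paste0("count_", bins))

    rpart <- function(sub, prefix) {
      sub <- sub[total > 0L]
      if (ratio_method == "per_day") {
        out <- sub[, c(.(n = .N), lapply(.SD, function(x) mean(x / total))),
                   by = participant_id, .SDcols = bins]
      } else {
        out <- sub[, c(.(n = .N), lapply(.SD, function(x) sum(x) / sum(total))),
                   by = participant_id, .SDcols = bins]
      }
      data.table::setnames(out, c("n", bins),
                           c(paste0("n_", prefix), paste0(prefix, "_", bins)))
      out
    }
    r_all <- rpart(keep, "ratio")
    r_wd <- rpart(keep[day_type == "weekday"], "wd")
    r_we <- rpart(keep[day_type == "weekend"], "we")

    profs <- Reduce(function(a, b) merge(a, b, by = "participant_id", all.x = TRUE),
                    list(count_part, r_all, r_wd, r_we))
    for (nm in c("n_ratio", "n_wd", "n_we"))
      profs[[nm]][is.na(profs[[nm]])] <- 0L
    profs <- as.data.frame(profs)
  }

  list(inclusion = as.data.frame(
         incl[, .(participant_id, included, n_complete, reason)]),
       complete_weeks = stats::setNames(incl$complete_weeks, incl$participant_id),
       profiles = profs)
}
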