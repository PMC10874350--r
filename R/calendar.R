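#' Study calendar
#'
#' A study calendar anchors the keystroke analysis to a fixed observation
#' window: `n_weeks` consecutive 7-day study weeks starting at `start_date`,
#' of which the first `n_adjustment_weeks` are discarded as an adjustment
#' period (participants acclimatising to the logging keyboard). Study week
#' `w` (1-based) spans the half-open date range
#' `[start_date + 7*(w-1), start_date + 7*w)`.
#'
#' All timestamps in this package are naive local clock time in a single
#' study timezone; no DST or timezone arithmetic is performed.
#'
#' @param start_date first day of the study (`Date` or ISO-8601 string).
#' @param n_weeks total number of study weeks (default 5).
#' @param n_adjustment_weeks leading weeks excluded from analysis (default 1).
#' @return An object of class `study_calendar`.
#' @examples
#' cal <- study_calendar("2023-05-01")
#' study_week_of(as.Date("2023-05-08"), cal)  # 2
#' @export
study_calendar <- function(start_date, n_weeks = 5L, n_adjustment_weeks = 1L) {
  start_date <- as.Date(start_date)
  if (length(start_date) != 1L || is.na(start_date))
    stop("start_date must be a single valid date")
  n_weeks <- as.integer(n_weeks)
  n_adjustment_weeks <- as.integer(n_adjustment_weeks)
  if (n_weeks < 1L) stop("n_weeks must be >= 1")
  if (n_adjustment_weeks < 0L || n_adjustment_weeks >= n_weeks)
    stop("n_adjustment_weeks must be in [0, n_weeks)")
  structure(
    list(start_date = start_date, n_weeks = n_weeks,
         n_adjustment_weeks = n_adjustment_weeks),
    class = "study_calendar"
  )
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("Study calendar: %d weeks from %s (%d adjustment week%s excluded)\n",
              x$n_weeks, format(x$start_date), x$n_adjustment_weeks,
              if (x$n_adjustment_weeks == 1L) "" else "s"))
  invisible(x)
}

#' Map dates to study week indices
#'
#' @param date vector of `Date` (or coercible).
#' @param calendar a [study_calendar()].
#' @return Integer vector of 1-based week indices; `NA` marks dates outside
#'   the study window (before `start_date` or on/after
#'   `start_date + 7 * n_weeks`).
#' @export
study_week_of <- function(date, calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  date <- as.Date(date)
  offset <- as.integer(date - calendar$start_date)
  week <- offset %/% 7L + 1L
  week[offset < 0L | week > calendar$n_weeks] <- NA_integer_
  week
}

#' Enumerate study dates
#'
#' @param calendar a [study_calendar()].
#' @param post_adjustment if `TRUE`, only dates in weeks after the
#'   adjustment period.
#' @return Vector of `Date`, one per study day.
#' @export
study_dates <- function(calendar, post_adjustment = FALSE) {
  stopifnot(inherits(calendar, "study_calendar"))
  from <- if (post_adjustment) 7L * calendar$n_adjustment_weeks else 0L
  calendar$start_date + seq.int(from, 7L * calendar$n_weeks - 1L)
}

#' Study weeks retained for analysis
#'
#' @param calendar a [study_calendar()].
#' @return Integer vector of week indices after the adjustment period
#'   (e.g. `2:5` for the default calendar).
#' @export
analysis_weeks <- function(calendar) {
  stopifnot(inherits(calendar, "study_calendar"))
  seq.int(calendar$n_adjustment_weeks + 1L, calendar$n_weeks)
}

#' Read / write a calendar config file
#'
#' The config is a small YAML key-value file with keys `start_date`,
#' `n_weeks`, `n_adjustment_weeks`.
#'
#' @param path file path.
#' @return `read_calendar_config` returns a [study_calendar()];
#'   `write_calendar_config` returns `path` invisibly.
#' @export
read_calendar_config <- function(path) {
  if (!file.exists(path)) stop("calendar config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (k in c("start_date", "n_weeks", "n_adjustment_weeks"))
    if (is.null(cfg[[k]])) stop("calendar config missing key: ", k)
  study_calendar(cfg$start_date, cfg$n_weeks, cfg$n_adjustment_weeks)
}

#' @rdname read_calendar_config
#' @param calendar a [study_calendar()].
#' @export
write_calendar_config <- function(calendar, path) {
  stopifnot(inherits(calendar, "study_calendar"))
  yaml::write_yaml(
    list(start_date = format(calendar$start_date),
         n_weeks = calendar$n_weeks,
         n_adjustment_weeks = calendar$n_adjustment_weeks),
    path
  )
  invisible(path)
}
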