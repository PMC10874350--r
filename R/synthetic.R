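# Synthetic keystroke cohort generator. Events are drawn from a
# piecewise-constant (per-bin) inhomogeneous Poisson process: for every
# study date and diurnal bin the keystroke count is Poisson with a
# group-specific day-type rate scaled by a per-participant lognormal
# activity multiplier; whole days drop out independently to emulate
# logging gaps. Press times are placed uniformly within their bin at
# millisecond resolution. Every draw is recorded as ground truth, so the
# feature-extraction stages can be checked against the generator exactly.

#' Group intensity profile
#'
#' The generative parameters of one loneliness group: expected keystrokes
#' per day in each diurnal bin, separately for weekdays and weekends, plus
#' a day-level dropout probability and a per-participant overdispersion
#' (the sd, on the log scale, of a lognormal activity multiplier with mean
#' 1 that scales all of a participant's rates).
#'
#' @param label group label.
#' @param weekday_rates,weekend_rates nonnegative numeric vectors of 5
#'   expected keystrokes/day (bin order sleep..night).
#' @param day_dropout_prob probability in `[0, 1)` that a given day's
#'   events are lost entirely.
#' @param overdispersion nonnegative lognormal sd of the participant
#'   activity multiplier.
#' @return List of class `group_intensity_profile`.
#' @export
group_intensity_profile <- function(label, weekday_rates, weekend_rates,
                                    day_dropout_prob = 0,
                                    overdispersion = 0) {
  stopifnot(length(weekday_rates) == 5L, length(weekend_rates) == 5L,
            all(weekday_rates >= 0), all(weekend_rates >= 0),
            day_dropout_prob >= 0, day_dropout_prob < 1,
            overdispersion >= 0)
  if (sum(weekday_rates) == 0 && sum(weekend_rates) == 0)
    warning("profile '", label, "' has zero intensity everywhere")
  structure(
    list(label = label,
         weekday_rates = stats::setNames(as.numeric(weekday_rates), .BIN_LABELS),
         weekend_rates = stats::setNames(as.numeric(weekend_rates), .BIN_LABELS),
         day_dropout_prob = day_dropout_prob,
         overdispersion = overdispersion),
    class = "group_intensity_profile"
  )
}

#' Default group intensity profiles
#'
#' The shipped study-condition profiles. The no/moderate/severe groups are
#' evening-peaked with a weekday/weekend divergence (weekend mornings
#' quieter, weekend nights busier); the very-severe group is
#' night+sleep-peaked with identical weekday and weekend shapes. All
#' profiles total ~4,500 keystrokes/day; the lognormal multiplier sd of
#' 0.55 reproduces a between-participant coefficient of variation of
#' about 0.6; day dropout of 0.023/day makes roughly 10% of participants
#' fail the 3-complete-weeks rule.
#'
#' @return Named list of [group_intensity_profile()]s, one per loneliness
#'   group.
#' @export
default_profiles <- function() {
  evening_wd <- c(150, 700, 1100, 1600, 950)
  evening_we <- c(250, 400, 1000, 1300, 1550)
  night_owl <- c(1200, 300, 800, 900, 1300)
  mk <- function(lbl, wd, we)
    group_intensity_profile(lbl, wd, we, day_dropout_prob = 0.023,
                            overdispersion = 0.55)
  list(no = mk("no", evening_wd, evening_we),
       moderate = mk("moderate", evening_wd, evening_we),
       severe = mk("severe", evening_wd, evening_we),
       very_severe = mk("very_severe", night_owl, night_owl))
}

#' Null intensity profiles
#'
#' All four groups share one evening-peaked profile with no day dropout,
#' so every group difference is pure noise and group sizes stay exactly at
#' their nominal values. Used for type-I-error calibration of the
#' group-level tests.
#'
#' @return Named list of identical [group_intensity_profile()]s.
#' @export
null_profiles <- function() {
  evening_wd <- c(150, 700, 1100, 1600, 950)
  evening_we <- c(250, 400, 1000, 1300, 1550)
  mk <- function(lbl)
    group_intensity_profile(lbl, evening_wd, evening_we,
                            day_dropout_prob = 0, overdispersion = 0.55)
  stats::setNames(lapply(.ULS8_LEVELS, mk), .ULS8_LEVELS)
}

#' Simulation cohort configuration
#'
#' @param group_sizes named integer vector of participants per loneliness
#'   group; defaults to the study's analyzed sizes 18/26/10/5.
#' @param calendar a [study_calendar()].
#' @param profiles named list of [group_intensity_profile()]s covering all
#'   groups in `group_sizes`.
#' @param seed master seed; per-participant seeds are derived from it (see
#'   Details).
#' @details Per-participant reproducibility uses a splitting rule: stream
#'   `j` for participant index `i` gets seed
#'   `((seed mod 2147483647) * 48271 + (2 i + j) * 16807) mod 2147483647`,
#'   a Lehmer-style hash of the master seed and participant index. Two
#'   streams per participant (questionnaire, events) keep the event draw
#'   count from influencing the questionnaire.
#' @return List of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(group_sizes = c(no = 18L, moderate = 26L,
                                              severe = 10L, very_severe = 5L),
                              calendar = study_calendar("2023-05-01"),
                              profiles = default_profiles(),
                              seed = 1L) {
  stopifnot(inherits(calendar, "study_calendar"),
            all(group_sizes > 0),
            all(names(group_sizes) %in% .ULS8_LEVELS),
            all(names(group_sizes) %in% names(profiles)))
  structure(
    list(group_sizes = group_sizes, calendar = calendar,
         profiles = profiles, seed = as.integer(seed)),
    class = "sim_cohort_config"
  )
}

# Deterministic participant-seed derivation (documented in
# sim_cohort_config). Exact in double arithmetic: 48271 * 2^31 < 2^53.
.mix_seed <- function(master, k) {
  s <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(k) * 16807
  as.integer(s %% 2147483647)
}

#' Generate one participant's ULS-8 response
#'
#' Rejection-samples uniform item vectors (each item uniform on 1..4)
#' until the scored total falls in the target group's band. Draws from the
#' current RNG stream.
#'
#' @param group a loneliness group label.
#' @return Integer vector of 8 items.
#' @export
generate_uls8 <- function(group) {
  bands <- loneliness_bands()
  band <- bands[bands$label == group, ]
  if (nrow(band) != 1L) stop("unknown group: ", group)
  repeat {
    items <- sample.int(4L, 8L, replace = TRUE)
    s <- score_uls8(items)
    if (s >= band$lo && s <= band$hi) return(items)
  }
}

#' Generate one participant's keystroke log
#'
#' For each study date (all weeks, including the adjustment week) and each
#' diurnal bin, draws a Poisson count at the profile's day-type rate times
#' the participant's activity multiplier, then zeroes whole dropped-out
#' days. In event mode each keystroke's press time is placed uniformly
#' within its bin on the millisecond grid, with release = press + a short
#' positive dwell.
#'
#' @param profile a [group_intensity_profile()].
#' @param calendar a [study_calendar()].
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @param participant_id id string for the emitted records.
#' @param events if `FALSE`, skip event placement and return counts only
#'   (same counts as event mode for the same seed).
#' @return List with `log` (an `event_log`, or `NULL` in counts-only mode
#'   or when no events survive), `counts` (per-day bin-count data.frame
#'   over all study dates), and `truth` (list: `multiplier`,
#'   `dropped_dates`, `draws` — the pre-dropout Poisson draw matrix).
#' @export
generate_participant <- function(profile, calendar, seed, participant_id,
                                 events = TRUE) {
  stopifnot(inherits(profile, "group_intensity_profile"),
            inherits(calendar, "study_calendar"))
  set.seed(seed)
  dates <- study_dates(calendar)
  n <- length(dates)
  day_type <- .day_type_of(dates)
  rates <- rbind(profile$weekday_rates, profile$weekend_rates)
  lam <- rates[ifelse(day_type == "weekend", 2L, 1L), , drop = FALSE]

  s <- profile$overdispersion
  multiplier <- if (s > 0) exp(stats::rnorm(1, -s^2 / 2, s)) else 1
  dropped <- stats::runif(n) < profile$day_dropout_prob
  draws <- matrix(stats::rpois(n * 5L, as.vector(lam * multiplier)),
                  nrow = n, dimnames = list(NULL, .BIN_LABELS))
  observed <- draws
  observed[dropped, ] <- 0L

  counts <- data.frame(participant_id = participant_id, date = dates,
                       day_type = day_type, stringsAsFactors = FALSE)
  counts <- cbind(counts, as.data.frame(observed))
  counts$total <- as.integer(rowSums(observed))

  log <- NULL
  if (events && sum(observed) > 0L) {
    day_idx <- rep(rep(seq_len(n), times = 5L), times = as.vector(observed))
    bin_idx <- rep(rep(1:5, each = n), times = as.vector(observed))
    n_ev <- length(day_idx)
    u <- stats::runif(n_ev)
    start_ms <- .BIN_STARTS[bin_idx] * 3600 * 1000
    width_ms <- (.BIN_ENDS[bin_idx] - .BIN_STARTS[bin_idx]) * 3600 * 1000
    press_ms <- pmin(floor(start_ms + u * width_ms), start_ms + width_ms - 1)
    day_ms <- as.numeric(dates[day_idx] - as.Date("1970-01-01")) * 86400 * 1000
    dwell_ms <- pmax(1, round(stats::runif(n_ev, 50, 300)))
    press <- as.POSIXct((day_ms + press_ms) / 1000,
                        origin = "1970-01-01", tz = .STUDY_TZ)
    release <- as.POSIXct((day_ms + press_ms + dwell_ms) / 1000,
                          origin = "1970-01-01", tz = .STUDY_TZ)
    ord <- order(press)
    log <- new_event_log(participant_id,
                         data.frame(press_time = press[ord],
                                    release_time = release[ord]))
  }

  list(log = log, counts = counts,
       truth = list(multiplier = multiplier,
                    dropped_dates = dates[dropped],
                    draws = draws))
}

#' Generate a synthetic cohort
#'
#' Draws every participant's ULS-8 response and keystroke log under the
#' configured group profiles. Deterministic given `config$seed`; two
#' cohorts with different seeds share group sizes but nothing else.
#'
#' @param config a [sim_cohort_config()].
#' @param events if `FALSE`, generate bin counts only (fast path for
#'   replicated simulation studies; counts match event mode draw-for-draw).
#' @return List of class `sim_cohort`: `config`, `events` (named list of
#'   `event_log`s, or `NULL`s in counts-only mode), `daily_counts`
#'   (stacked per-day counts over all study dates), `uls8` (data.frame
#'   `participant_id`, `q1`..`q8`), and `ground_truth` (per-participant
#'   group, multiplier, dropped days, draw matrices).
#' @export
generate_cohort <- function(config, events = TRUE) {
  stopifnot(inherits(config, "sim_cohort_config"))
  groups <- rep(names(config$group_sizes), times = config$group_sizes)
  n <- length(groups)
  ids <- sprintf("P%03d", seq_len(n))

  logs <- vector("list", n); names(logs) <- ids
  counts_list <- vector("list", n)
  uls8_rows <- vector("list", n)
  truth <- vector("list", n); names(truth) <- ids

  for (i in seq_len(n)) {
    g <- groups[i]
    set.seed(.mix_seed(config$seed, 2L * i))
    items <- generate_uls8(g)
    uls8_rows[[i]] <- c(list(participant_id = ids[i]),
                        stats::setNames(as.list(items), paste0("q", 1:8)))
    gen <- generate_participant(config$profiles[[g]], config$calendar,
                                seed = .mix_seed(config$seed, 2L * i + 1L),
                                participant_id = ids[i], events = events)
    logs[[i]] <- gen$log
    counts_list[[i]] <- gen$counts
    truth[[ids[i]]] <- c(list(group = g), gen$truth)
  }

  structure(
    list(config = config,
         events = if (events) logs else NULL,
         daily_counts = as.data.frame(data.table::rbindlist(counts_list)),
         uls8 = as.data.frame(data.table::rbindlist(uls8_rows)),
         ground_truth = truth),
    class = "sim_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' Lays out a cohort directory in the pipeline's input formats:
#' `events/<participant>.csv` (or `.jsonl`), `uls8.csv`, `calendar.yaml`,
#' and `ground_truth.json` (group assignments, multipliers, dropped days,
#' and the full pre-dropout draw matrices).
#'
#' @param cohort a `sim_cohort` generated with `events = TRUE`.
#' @param dir output directory (created if needed).
#' @param format event-log format, `"csv"` or `"jsonl"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "jsonl")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  format <- match.arg(format)
  if (is.null(cohort$events))
    stop("cohort was generated counts-only; regenerate with events = TRUE")
  dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$events)) {
    log <- cohort$events[[pid]]
    if (is.null(log)) next
    write_event_log(log, file.path(dir, "events", paste0(pid, ".", format)),
                    format = format)
  }
  data.table::fwrite(cohort$uls8, file.path(dir, "uls8.csv"))
  write_calendar_config(cohort$config$calendar, file.path(dir, "calendar.yaml"))
  gt <- lapply(cohort$ground_truth, function(t) {
    list(group = t$group, multiplier = t$multiplier,
         dropped_dates = format(t$dropped_dates),
         draws = t$draws)  # serialized row-wise: one array of 5 per date
  })
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         group_sizes = as.list(cohort$config$group_sizes),
         participants = gt),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
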