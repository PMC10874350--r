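# Event-log and questionnaire I/O. Owns the timestamp conventions: naive
# local clock time, millisecond resolution, serialized as ISO-8601 with
# milliseconds. Internally times are POSIXct pinned to UTC so that clock
# arithmetic is DST-free.

.STUDY_TZ <- "UTC"

# Format POSIXct as ISO-8601 with exact milliseconds. Integer-millisecond
# arithmetic avoids the truncation artefacts of %OS3 on values such as
# x.023 that are not exactly representable in binary.
format_iso_ms <- function(t) {
  ms <- round(as.numeric(t) * 1000)
  secs <- ms %/% 1000
  frac <- ms %% 1000
  base <- format(as.POSIXct(secs, origin = "1970-01-01", tz = .STUDY_TZ),
                 "%Y-%m-%dT%H:%M:%S")
  sprintf("%s.%03d", base, frac)
}

# Parse ISO-8601 local timestamps ("T" or space separator, optional
# fractional seconds) onto the millisecond grid. Unparseable entries -> NA.
parse_iso_ms <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  t <- as.POSIXct(x, tz = .STUDY_TZ, format = "%Y-%m-%d %H:%M:%OS")
  ms <- round(as.numeric(t) * 1000)
  as.POSIXct(ms / 1000, origin = "1970-01-01", tz = .STUDY_TZ)
}

new_event_log <- function(participant_id, events, source_path = NA_character_,
                          n_skipped = 0L, n_out_of_range = 0L) {
  structure(
    list(participant_id = participant_id,
         events = events,
         source_path = source_path,
         n_skipped = as.integer(n_skipped),
         n_out_of_range = as.integer(n_out_of_range)),
    class = "event_log"
  )
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("Keystroke event log: participant %s, %d events",
              x$participant_id, nrow(x$events)))
  if (x$n_skipped > 0L) cat(sprintf(" (%d malformed rows skipped)", x$n_skipped))
  if (x$n_out_of_range > 0L)
    cat(sprintf(" (%d events outside the study window dropped)", x$n_out_of_range))
  cat("\n")
  invisible(x)
}

#' Read a keystroke event log
#'
#' Reads one participant's keystroke events from CSV or JSON-lines. Each
#' record carries `participant_id`, `press_time` and `release_time` as
#' ISO-8601 local timestamps with millisecond resolution. Malformed rows
#' (unparseable timestamps, or release before press) are skipped and
#' counted in the returned log's `n_skipped`; when a `calendar` is given,
#' events whose press time falls outside the study window are dropped and
#' counted in `n_out_of_range`. Events are returned sorted by press time,
#' preserving file order among equal timestamps.
#'
#' @param path file path.
#' @param format `"csv"` or `"jsonl"`; guessed from the extension by default.
#' @param calendar optional [study_calendar()] used to drop out-of-window
#'   events.
#' @return An object of class `event_log`: fields `participant_id`,
#'   `events` (data.frame with `press_time`, `release_time`), `source_path`,
#'   `n_skipped`, `n_out_of_range`.
#' @export
read_event_log <- function(path, format = c("auto", "csv", "jsonl"),
                           calendar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("event log file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"

  if (format == "csv") {
    raw <- data.table::fread(path, colClasses = "character",
                             na.strings = NULL, showProgress = FALSE)
    need <- c("participant_id", "press_time", "release_time")
    if (!all(need %in% names(raw)))
      stop("event log ", path, " lacks required columns: ",
           paste(setdiff(need, names(raw)), collapse = ", "))
    raw <- as.data.frame(raw)[need]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    bad <- vapply(recs, function(r) {
      is.null(r) || !all(c("participant_id", "press_time", "release_time") %in% names(r))
    }, logical(1))
    recs <- recs[!bad]
    raw <- data.frame(
      participant_id = vapply(recs, function(r) as.character(r$participant_id), ""),
      press_time = vapply(recs, function(r) as.character(r$press_time), ""),
      release_time = vapply(recs, function(r) as.character(r$release_time), ""),
      stringsAsFactors = FALSE
    )
    raw$.n_pre_skipped <- sum(bad)
  }

  n_skipped <- if (!is.null(raw$.n_pre_skipped)) raw$.n_pre_skipped[1] else 0L
  raw$.n_pre_skipped <- NULL

  press <- parse_iso_ms(raw$press_time)
  release <- parse_iso_ms(raw$release_time)
  ok <- !is.na(press) & !is.na(release) & release >= press &
    !is.na(raw$participant_id) & nzchar(raw$participant_id)
  n_skipped <- n_skipped + sum(!ok)
  press <- press[ok]; release <- release[ok]
  pid <- unique(raw$participant_id[ok])

  if (length(press) == 0L)
    stop("no parseable keystroke events in ", path)
  if (length(pid) > 1L)
    stop("event log ", path, " mixes participant ids: ",
         paste(pid, collapse = ", "))

  n_oor <- 0L
  if (!is.null(calendar)) {
    inside <- !is.na(study_week_of(as.Date(press, tz = .STUDY_TZ), calendar))
    n_oor <- sum(!inside)
    press <- press[inside]; release <- release[inside]
    if (length(press) == 0L)
      stop("all events in ", path, " fall outside the study window")
  }

  ord <- order(press)  # stable: preserves file order among ties
  new_event_log(pid,
                data.frame(press_time = press[ord], release_time = release[ord]),
                source_path = path, n_skipped = n_skipped,
                n_out_of_range = n_oor)
}

#' Write a keystroke event log
#'
#' Serializes an `event_log` as CSV or JSON-lines with bit-exact ISO-8601
#' millisecond timestamps, so that [read_event_log()] round-trips it
#' field-for-field.
#'
#' @param log an `event_log`.
#' @param path output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, format = c("csv", "jsonl")) {
  stopifnot(inherits(log, "event_log"))
  format <- match.arg(format)
  press <- format_iso_ms(log$events$press_time)
  release <- format_iso_ms(log$events$release_time)
  if (format == "csv") {
    data.table::fwrite(
      data.table::data.table(participant_id = log$participant_id,
                             press_time = press, release_time = release),
      path)
  } else {
    writeLines(sprintf(
      '{"participant_id":%s,"press_time":"%s","release_time":"%s"}',
      jsonlite::toJSON(log$participant_id, auto_unbox = TRUE), press, release
    ), path)
  }
  invisible(path)
}

#' Read a ULS-8 questionnaire file
#'
#' Reads a CSV with columns `participant_id`, `q1` ... `q8`; each item must
#' be an integer in 1..4. Scoring happens downstream ([score_uls8()]); this
#' reader only validates.
#'
#' @param path file path.
#' @return data.frame with one row per participant (columns
#'   `participant_id`, `q1`..`q8`).
#' @export
read_uls8_file <- function(path) {
  if (!file.exists(path)) stop("ULS-8 file not found: ", path)
  items <- paste0("q", 1:8)
  raw <- as.data.frame(data.table::fread(path, showProgress = FALSE))
  need <- c("participant_id", items)
  if (!all(need %in% names(raw)))
    stop("ULS-8 file lacks required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  raw <- raw[need]
  raw$participant_id <- as.character(raw$participant_id)
  dup <- raw$participant_id[duplicated(raw$participant_id)]
  if (length(dup) > 0L)
    stop("duplicate participant ids in ULS-8 file: ",
         paste(unique(dup), collapse = ", "))
  for (it in items) {
    v <- raw[[it]]
    bad <- which(!is.finite(v) | v != as.integer(v) | v < 1 | v > 4)
    if (length(bad) > 0L)
      stop(sprintf("ULS-8 item %s out of range 1..4 at row %d (participant %s)",
                   it, bad[1], raw$participant_id[bad[1]]))
    raw[[it]] <- as.integer(v)
  }
  raw
}
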