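# ULS-8 scoring: 8 items answered 1..4, items 7 and 8 reverse-coded
# (5 - answer), total 8..32, four loneliness bands.

.ULS8_LEVELS <- c("no", "moderate", "severe", "very_severe")

#' Loneliness score bands
#'
#' The four ULS-8 loneliness groups and their inclusive total-score bands:
#' no 8-13, moderate 14-20, severe 21-25, very severe 26-32. The bands
#' partition the attainable score range 8..32.
#'
#' @return data.frame with columns `label`, `lo`, `hi`.
#' @export
loneliness_bands <- function() {
  data.frame(label = .ULS8_LEVELS,
             lo = c(8L, 14L, 21L, 26L),
             hi = c(13L, 20L, 25L, 32L),
             stringsAsFactors = FALSE)
}

.check_uls8_items <- function(items) {
  if (length(items) != 8L)
    stop("a ULS-8 response has exactly 8 items, got ", length(items))
  if (any(!is.finite(items) | items != as.integer(items) | items < 1 | items > 4))
    stop("ULS-8 items must be integers in 1..4")
  as.integer(items)
}

#' Score a ULS-8 response
#'
#' Items 1-6 are scored as answered; items 7 and 8 are reverse-coded as
#' `5 - answer`. The total therefore lies in 8..32.
#'
#' @param items integer vector of length 8, each element in 1..4
#'   (items in questionnaire order).
#' @return Integer total score.
#' @examples
#' score_uls8(c(4, 4, 4, 4, 4, 4, 1, 1))  # 32
#' score_uls8(c(1, 1, 1, 1, 1, 1, 4, 4))  # 8
#' @export
score_uls8 <- function(items) {
  items <- .check_uls8_items(items)
  sum(items[1:6]) + sum(5L - items[7:8])
}

#' Assign loneliness groups from ULS-8 totals
#'
#' @param total integer vector of ULS-8 total scores, each in 8..32.
#' @return Factor with levels `no`, `moderate`, `severe`, `very_severe`.
#' @examples
#' assign_group(c(13, 14, 26))
#' @export
assign_group <- function(total) {
  if (any(!is.finite(total) | total < 8 | total > 32))
    stop("ULS-8 total score must be in 8..32")
  bands <- loneliness_bands()
  idx <- findInterval(total, bands$lo)
  factor(bands$label[idx], levels = .ULS8_LEVELS)
}

#' Score a table of ULS-8 responses
#'
#' Vectorized scoring of the table returned by [read_uls8_file()].
#'
#' @param responses data.frame with columns `participant_id`, `q1`..`q8`.
#' @return data.frame with columns `participant_id`, `total`, `group`.
#' @export
score_uls8_table <- function(responses) {
  items <- paste0("q", 1:8)
  stopifnot(all(c("participant_id", items) %in% names(responses)))
  m <- as.matrix(responses[items])
  if (any(!is.finite(m) | m != round(m) | m < 1 | m > 4))
    stop("ULS-8 items must be integers in 1..4")
  total <- as.integer(rowSums(m[, 1:6, drop = FALSE]) +
                        rowSums(5 - m[, 7:8, drop = FALSE]))
  data.frame(participant_id = as.character(responses$participant_id),
             total = total,
             group = assign_group(total),
             stringsAsFactors = FALSE)
}
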