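# Weekday/weekend profile similarity. A participant whose typing-ratio
# profile barely changes between weekdays and weekends (cosine near 1)
# keeps the same diurnal routine all week.

#' Cosine similarity of two vectors
#'
#' `(u . v) / (||u|| ||v||)`. For nonnegative ratio profiles the value lies
#' in `[0, 1]` and equals 1 exactly when the vectors are positive scalar
#' multiples of each other.
#'
#' @param u,v finite numeric vectors of equal length, each with at least
#'   one nonzero entry.
#' @return Numeric scalar.
#' @examples
#' cosine_similarity(c(1, 2, 0, 0, 0), c(2, 1, 0, 0, 0))  # 0.8
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("u and v must be finite")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Weekday-weekend similarity of a participant's typing-ratio profiles
#'
#' Cosine similarity between the weekday and weekend mean typing-count
#' ratio profiles. When either variant is undefined (no qualifying day of
#' that type), the participant is flagged rather than scored, so the
#' group-level test can exclude them with a logged reason.
#'
#' @param profile a [participant_profile()].
#' @return List with `participant_id`, `cosine` (`NA` when undefined) and
#'   `reason` (`NA` when defined).
#' @export
weekday_weekend_similarity <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  wd <- profile$weekday_mean_ratios
  we <- profile$weekend_mean_ratios
  missing <- c(if (profile$n_weekdays_used == 0L || any(is.na(wd))) "weekday",
               if (profile$n_weekend_days_used == 0L || any(is.na(we))) "weekend")
  if (length(missing) > 0L) {
    return(list(participant_id = profile$participant_id, cosine = NA_real_,
                reason = paste("undefined", paste(missing, collapse = " and "),
                               "ratio profile")))
  }
  list(participant_id = profile$participant_id,
       cosine = cosine_similarity(wd, we),
       reason = NA_character_)
}
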