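# Quadratic shape statistics: an ordinary least-squares degree-2 fit to a
# participant's five-bin mean typing-count profile. The sign of the
# quadratic coefficient a2 separates evening-peaked (concave, a2 < 0) from
# late-night / U-shaped (convex, a2 > 0) diurnal patterns.

#' Design points for the quadratic fit
#'
#' The default abscissa is the bin index 1..5 (the polyfit-on-vector
#' idiom); `"midpoint_hours"` instead uses each bin's clock-time midpoint
#' (3, 9, 14.5, 19, 22.5 h), which accounts for the unequal bin widths.
#'
#' @param abscissa `"index"` or `"midpoint_hours"`.
#' @return Numeric vector of length 5.
#' @export
quadratic_design_points <- function(abscissa = c("index", "midpoint_hours")) {
  abscissa <- match.arg(abscissa)
  if (abscissa == "index") 1:5 else (.BIN_STARTS + .BIN_ENDS) / 2
}

#' Fit a second-order polynomial to a five-bin profile
#'
#' Ordinary least squares fit of `y = a2 x^2 + a1 x + a0` to the five bin
#' values, plus the Pearson correlation `r` between observed and fitted
#' values. For a constant profile the fit degenerates to
#' `a2 = a1 = 0, a0 = const` and `r` is undefined (`NA`, not 0).
#'
#' @param profile numeric vector of 5 finite values (bin order
#'   sleep..night), typically `mean_counts` from [participant_profile()].
#' @param abscissa design points, see [quadratic_design_points()].
#' @return List of class `quadratic_fit`: `a2`, `a1`, `a0`, `fitted`
#'   (length 5), `r`, `r_defined`.
#' @examples
#' fit_quadratic(c(1, 4, 9, 16, 25))  # a2 = 1, a1 = 0, a0 = 0, r = 1
#' @export
fit_quadratic <- function(profile, abscissa = c("index", "midpoint_hours")) {
  if (length(profile) != 5L || any(!is.finite(profile)))
    stop("profile must be 5 finite values")
  x <- quadratic_design_points(abscissa)
  fit <- stats::lm(profile ~ x + I(x^2))
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::fitted(fit))
  r_defined <- stats::sd(profile) > 0 && stats::sd(fitted) > 0
  r <- if (r_defined) stats::cor(profile, fitted) else NA_real_
  structure(
    list(a2 = unname(cf[3]), a1 = unname(cf[2]), a0 = unname(cf[1]),
         fitted = fitted, r = r, r_defined = r_defined),
    class = "quadratic_fit"
  )
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("Quadratic fit: a2 = %.4g, a1 = %.4g, a0 = %.4g, r = %s\n",
              x$a2, x$a1, x$a0,
              if (x$r_defined) sprintf("%.3f", x$r) else "undefined"))
  invisible(x)
}

# Batched OLS: one stats::lm.fit call with a matrix response fits every
# participant at once. Returns coef (n x 3: a0, a1, a2) and fitted (n x 5).
# A unit test pins this path to the scalar fit_quadratic().
.fit_quadratic_matrix <- function(count_matrix, abscissa = "index") {
  x <- quadratic_design_points(abscissa)
  X <- cbind(1, x, x^2)
  fit <- stats::lm.fit(X, t(count_matrix))
  coef <- t(fit$coefficients)
  colnames(coef) <- c("a0", "a1", "a2")
  fitted <- t(X %*% fit$coefficients)
  # row-wise Pearson correlation observed vs fitted; NA when degenerate
  oc <- count_matrix - rowMeans(count_matrix)
  fc <- fitted - rowMeans(fitted)
  denom <- sqrt(rowSums(oc^2) * rowSums(fc^2))
  r <- ifelse(denom > 0, rowSums(oc * fc) / denom, NA_real_)
  list(coef = coef, fitted = fitted, r = unname(r))
}

#' Quadratic coefficients for a set of participants
#'
#' Fits [fit_quadratic()] to each participant's mean-count profile and
#' collects the coefficients, ready for the group-level ANOVA.
#'
#' @param profiles either a list of [participant_profile()] objects or a
#'   data.frame with columns `participant_id` and `count_sleep` ..
#'   `count_night` (the cohort profile table).
#' @param abscissa see [quadratic_design_points()].
#' @return data.frame with columns `participant_id`, `a2`, `a1`, `a0`, `r`.
#' @export
quadratic_coefficients <- function(profiles,
                                   abscissa = c("index", "midpoint_hours")) {
  abscissa <- match.arg(abscissa)
  if (is.data.frame(profiles)) {
    ids <- profiles$participant_id
    m <- as.matrix(profiles[paste0("count_", .BIN_LABELS)])
  } else {
    ids <- vapply(profiles, function(p) p$participant_id, "")
    m <- do.call(rbind, lapply(profiles, function(p) p$mean_counts))
  }
  if (any(!is.finite(m)))
    stop("non-finite mean-count profile for participant ",
         ids[which(!stats::complete.cases(m))[1]])
  f <- .fit_quadratic_matrix(m, abscissa)
  data.frame(participant_id = ids,
             a2 = unname(f$coef[, "a2"]), a1 = unname(f$coef[, "a1"]),
             a0 = unname(f$coef[, "a0"]), r = f$r,
             stringsAsFactors = FALSE)
}

#' Group-level fitted curves
#'
#' Averages per-participant fitted quadratic curves within each loneliness
#' group and reports the correlation between the group-mean observed
#' profile and the group-mean fitted curve.
#'
#' @param count_matrix numeric matrix, one row per participant, 5 columns
#'   of mean bin counts.
#' @param group factor of group labels aligned to the rows.
#' @param abscissa see [quadratic_design_points()].
#' @return data.frame with one row per group and bin: `group`, `bin`,
#'   `mean_observed`, `mean_fitted`, plus per-group `r` (repeated).
#' @export
group_fitted_curves <- function(count_matrix, group,
                                abscissa = c("index", "midpoint_hours")) {
  abscissa <- match.arg(abscissa)
  fits <- .fit_quadratic_matrix(count_matrix, abscissa)$fitted
  out <- lapply(levels(droplevels(group)), function(g) {
    idx <- which(group == g)
    obs <- colMeans(count_matrix[idx, , drop = FALSE])
    fit <- colMeans(fits[idx, , drop = FALSE])
    data.frame(group = g, bin = .BIN_LABELS, mean_observed = obs,
               mean_fitted = fit,
               r = if (stats::sd(obs) > 0 && stats::sd(fit) > 0)
                 stats::cor(obs, fit) else NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}
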