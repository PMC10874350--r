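# Group-level statistical battery: one-way ANOVA across the loneliness
# groups, Tukey-Kramer post-hoc comparisons (the groups are unbalanced),
# and Welch's two-sample t-test. All tests delegate to stats:: fitters;
# the wrappers add input validation, degenerate-case handling, and a
# uniform result shape.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (length(g) < 2L || any(!is.finite(g)))
      stop("group '", nm, "' needs >= 2 finite observations")
  }
  groups
}

.stack_groups <- function(groups) {
  data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: `F = MS_between / MS_within`
#' with `k - 1` and `N - k` degrees of freedom. When every group has zero
#' internal variance the result is degenerate: `F = 0, p = 1` if the means
#' also agree, otherwise `F = Inf, p = 0`, flagged via `degenerate`.
#'
#' @param groups named list of `k >= 2` numeric vectors, each with at
#'   least 2 finite observations.
#' @return List of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `group_means`, `group_ns`, `degenerate`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # F = 13.5
#' @export
one_way_anova <- function(groups) {
  groups <- .check_groups(groups)
  d <- .stack_groups(groups)
  k <- length(groups); n <- nrow(d)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (n - k)
  res <- list(df_between = k - 1L, df_within = n - k,
              group_means = vapply(groups, mean, 0),
              group_ns = lengths(groups), degenerate = FALSE)
  if (msw == 0) {
    same <- length(unique(res$group_means)) == 1L
    res$F <- if (same) 0 else Inf
    res$p <- if (same) 1 else 0
    res$degenerate <- TRUE
  } else {
    fit <- stats::oneway.test(y ~ g, data = d, var.equal = TRUE)
    res$F <- unname(fit$statistic)
    res$p <- unname(fit$p.value)
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tukey-Kramer multiple comparisons
#'
#' All-pairs post-hoc comparison after a one-way ANOVA, using the
#' Tukey-Kramer studentized-range procedure (valid for unequal group
#' sizes): for groups i, j,
#' `q_ij = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`,
#' with adjusted p from the studentized-range distribution on `k` groups
#' and `N - k` degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return List of class `tukey_result`: `pairs` (data.frame with
#'   `group1`, `group2`, `diff`, `q`, `p_adj`), `df_within`, `ms_within`.
#' @export
tukey_hsd <- function(groups) {
  groups <- .check_groups(groups)
  d <- .stack_groups(groups)
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit)$g
  msw <- sum(stats::resid(fit)^2) / fit$df.residual
  if (msw == 0) stop("Tukey comparison undefined: zero within-group variance")
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  means <- vapply(groups, mean, 0); ns <- lengths(groups)
  g1 <- vapply(nm, `[`, "", 1L); g2 <- vapply(nm, `[`, "", 2L)
  diff <- tk[, "diff"]
  q <- abs(diff) / sqrt(msw / 2 * (1 / ns[g1] + 1 / ns[g2]))
  structure(
    list(pairs = data.frame(group1 = g1, group2 = g2,
                            diff = unname(diff), q = unname(q),
                            p_adj = unname(tk[, "p adj"]),
                            stringsAsFactors = FALSE, row.names = NULL),
         df_within = fit$df.residual, ms_within = msw),
    class = "tukey_result"
  )
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey-Kramer multiple comparisons:\n")
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Two-sided location test without the equal-variance assumption:
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples with at least 2 finite values each; at least
#'   one sample must have nonzero variance.
#' @return List of class `welch_result`: `t`, `df` (possibly non-integer),
#'   `p`, `mean_a`, `mean_b`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 4, 6))  # t = -1.549
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b))))
    stop("each sample needs >= 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("Welch's t undefined: both samples have zero variance")
  fit <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(t = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value), mean_a = mean(a), mean_b = mean(b)),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.2f, df = %.1f, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}
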