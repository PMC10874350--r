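# Independent textbook-formula oracles for the statistical battery; kept
# free of the package's own code paths.

oracle_anova <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  k <- length(groups); n <- length(y)
  means <- vapply(groups, mean, 0)
  ssb <- sum(lengths(groups) * (means - mean(y))^2)
  ssw <- sum((y - means[gi])^2)
  dfb <- k - 1L; dfw <- n - k
  Fst <- (ssb / dfb) / (ssw / dfw)
  list(F = Fst, df_between = dfb, df_within = dfw,
       p = stats::pf(Fst, dfb, dfw, lower.tail = FALSE),
       ms_within = ssw / dfw)
}

oracle_tukey <- function(groups) {
  a <- oracle_anova(groups)
  k <- length(groups)
  ns <- lengths(groups); means <- vapply(groups, mean, 0)
  pairs <- t(combn(names(groups), 2L))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    se <- sqrt(a$ms_within / 2 * (1 / ns[g1] + 1 / ns[g2]))
    q <- abs(means[g1] - means[g2]) / se
    data.frame(group1 = g1, group2 = g2, q = unname(q),
               p_adj = stats::ptukey(q, k, a$df_within, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
}

oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Degree-2 OLS by explicit normal equations
oracle_quadratic <- function(y, x = 1:5) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(a0 = beta[1], a1 = beta[2], a2 = beta[3], fitted = drop(X %*% beta))
}
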