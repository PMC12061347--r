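# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: OLS by normal equations, ANOVA by explicit
# sums of squares on change scores.

# One-way ANOVA on change scores via explicit sums of squares. For a
# two-level within factor this equals the split-plot group x time
# interaction test.
oracle_change_anova <- function(change, group) {
  group <- as.character(group)
  grand <- mean(change)
  arms <- split(change, group)
  ss_b <- sum(vapply(arms, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(arms, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(arms) - 1L
  df2 <- length(change) - length(arms)
  f <- (ss_b / df1) / (ss_w / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE),
       eta = ss_b / (ss_b + ss_w))
}

# OLS by normal equations, with t-based 95% CI for each coefficient.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tq <- qt(0.975, df)
  list(beta = drop(beta), se = se,
       ci_low = drop(beta) - tq * se, ci_high = drop(beta) + tq * se,
       p = 2 * pt(abs(drop(beta) / se), df, lower.tail = FALSE))
}

# Deterministic threshold agent: happy iff index <= cut; never learns.
fixed_policy_agent <- function(cut) {
  list(respond = function(i) if (i <= cut) "happy" else "sad",
       update = function(signal) invisible(NULL),
       criterion = function() cut)
}

# Small synthetic outcome table with exact per-arm pre/post means.
two_point_cohort <- function(arm_means, spread = 2) {
  rows <- lapply(names(arm_means), function(a) {
    m <- arm_means[[a]]
    data.frame(participant_id = paste0(a, c("_1", "_2")),
               condition = a, age = c(20L, 25L), gender = c("woman", "man"),
               ims_pre = m[["pre"]] + c(-spread, spread),
               ims_post = m[["post"]] + c(-spread, spread),
               bp_pre = 7, bp_post = 7,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
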