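#' Tukey-fence outlier filter
#'
#' Keeps values within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation between order statistics
#' (`stats::quantile(type = 7)`). Values exactly on a fence are kept.
#'
#' @param values Numeric vector of at least 4 values.
#' @param k Fence multiplier (default 1.5).
#' @return List with `keep` (logical mask), `fences` (length-2 numeric),
#'   and `n_removed`.
#' @examples
#' tukey_filter(c(1:9, 100))$keep
#' @export
tukey_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    stop("insufficient data: Tukey fences need at least 4 values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(keep = keep, fences = fences, n_removed = sum(!keep))
}

long_outcomes <- function(outcomes, outcome = c("ims", "bp")) {
  outcome <- match.arg(outcome)
  pre <- outcomes[[paste0(outcome, "_pre")]]
  post <- outcomes[[paste0(outcome, "_post")]]
  if (is.null(pre) || is.null(post)) {
    stop("outcomes must contain ", outcome, "_pre and ", outcome, "_post",
         call. = FALSE)
  }
  n <- nrow(outcomes)
  data.frame(
    pid = factor(rep(outcomes$participant_id, 2L)),
    group = factor(rep(outcomes$condition, 2L)),
    time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
    value = c(pre, post)
  )
}

#' Group-by-time interaction from a mixed-design ANOVA
#'
#' Fits the standard split-plot (one between-subject factor: arm; one
#' two-level within-subject factor: pre/post) ANOVA via `stats::aov` with
#' an `Error(participant)` stratum, and returns the group x time
#' interaction: `F`, its degrees of freedom, `p`, and partial eta squared
#' (`SS_interaction / (SS_interaction + SS_error_within)`). With two time
#' points this interaction F is identical to a one-way ANOVA F on
#' post - pre change scores.
#'
#' @param outcomes Cohort data frame (see [simulate_cohort()]).
#' @param outcome `"ims"` (mood totals) or `"bp"` (balance points).
#' @return List with `F`, `df_between`, `df_within`, `p`,
#'   `partial_eta_sq`, `outcome`.
#' @export
mixed_anova_time_group <- function(outcomes, outcome = c("ims", "bp")) {
  outcome <- match.arg(outcome)
  arm_n <- table(outcomes$condition)
  if (length(arm_n) < 2L) {
    stop("degenerate design: need at least 2 arms", call. = FALSE)
  }
  if (any(arm_n < 2L)) {
    stop("degenerate design: arm(s) with fewer than 2 participants: ",
         paste(names(arm_n)[arm_n < 2L], collapse = ", "), call. = FALSE)
  }
  d <- long_outcomes(outcomes, outcome)
  fit <- stats::aov(value ~ group * time + Error(pid), data = d)
  within <- summary(fit)[["Error: Within"]][[1L]]
  rn <- trimws(rownames(within))
  i_int <- match("group:time", rn)
  i_res <- match("Residuals", rn)
  ss_int <- within[i_int, "Sum Sq"]
  ss_res <- within[i_res, "Sum Sq"]
  f <- within[i_int, "F value"]
  df1 <- within[i_int, "Df"]
  df2 <- within[i_res, "Df"]
  list(F = unname(f),
       df_between = unname(df1),
       df_within = unname(df2),
       p = unname(stats::pf(f, df1, df2, lower.tail = FALSE)),
       partial_eta_sq = unname(ss_int / (ss_int + ss_res)),
       outcome = outcome)
}

#' Baseline-adjusted pairwise treatment contrast
#'
#' Ordinary least squares of the post-training score on an arm indicator,
#' optionally adjusting for the baseline (pre) score, age, and gender
#' (treatment-coded with the largest category as reference; undisclosed
#' gender is retained as its own category). The arm coefficient `B` is the
#' adjusted difference `arm_pair[2]` minus `arm_pair[1]`, with a 95% CI
#' from the t distribution on residual degrees of freedom.
#'
#' @param outcomes Cohort data frame.
#' @param response `"ims"` or `"bp"` — the post-training score modelled.
#' @param arm_pair Length-2 character vector of condition labels; the
#'   second is the indicator level.
#' @param covariates Character subset of `c("baseline", "age", "gender")`;
#'   empty for the unadjusted model.
#' @return List with `term` (arm indicator name), `B`, `ci_low`, `ci_high`,
#'   `p`, `adjusted`, `covariates`, `n`, and the full coefficient table
#'   (`coef_table`).
#' @export
adjusted_regression <- function(outcomes, response = c("ims", "bp"),
                                arm_pair, covariates = c("baseline", "age", "gender")) {
  response <- match.arg(response)
  if (length(arm_pair) != 2L || anyDuplicated(arm_pair)) {
    stop("arm_pair must be two distinct condition labels", call. = FALSE)
  }
  covariates <- if (length(covariates)) {
    match.arg(covariates, c("baseline", "age", "gender"), several.ok = TRUE)
  } else character(0)
  d <- outcomes[outcomes$condition %in% arm_pair, , drop = FALSE]
  if (!all(arm_pair %in% d$condition)) {
    stop("both arms of arm_pair must be present in the cohort", call. = FALSE)
  }
  d$arm <- factor(d$condition, levels = arm_pair)
  d$post <- d[[paste0(response, "_post")]]
  terms <- "arm"
  if ("baseline" %in% covariates) {
    d$baseline <- d[[paste0(response, "_pre")]]
    terms <- c(terms, "baseline")
  }
  if ("age" %in% covariates) terms <- c(terms, "age")
  if ("gender" %in% covariates && length(unique(d$gender)) > 1L) {
    tab <- sort(table(d$gender), decreasing = TRUE)
    d$gender <- factor(d$gender, levels = names(tab))
    terms <- c(terms, "gender")
  }
  fml <- stats::as.formula(paste("post ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: collinear term(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  arm_term <- paste0("arm", arm_pair[2L])
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)$coefficients
  list(term = arm_term,
       B = unname(stats::coef(fit)[arm_term]),
       ci_low = unname(ci[arm_term, 1L]),
       ci_high = unname(ci[arm_term, 2L]),
       p = unname(sm[arm_term, "Pr(>|t|)"]),
       adjusted = length(covariates) > 0L,
       covariates = setdiff(terms, "arm"),
       n = nrow(d),
       coef_table = data.frame(term = rownames(sm),
                               B = unname(sm[, "Estimate"]),
                               ci_low = unname(ci[, 1L]),
                               ci_high = unname(ci[, 2L]),
                               p = unname(sm[, "Pr(>|t|)"]),
                               stringsAsFactors = FALSE))
}

#' A-priori sample size for a two-sample t test
#'
#' Smallest per-group n such that a two-sided two-sample t test at level
#' `alpha` reaches the requested power against a standardized mean
#' difference `d`, with equal group sizes, computed by iterating n upward
#' under the exact noncentral-t distribution (noncentrality
#' `d * sqrt(n / 2)` on `2n - 2` df). The exact computation matters: the
#' normal approximation understates n by one at small effect sizes.
#'
#' @param effect_size_d Standardized effect size (Cohen's d), > 0.
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param n_max Safety cap on the iteration.
#' @return List with `n_per_group`, `n_total`, and `achieved_power`.
#' @examples
#' power_n_per_group(0.2, 0.80, 0.05)$n_per_group  # 394
#' @export
power_n_per_group <- function(effect_size_d, power = 0.80, alpha = 0.05,
                              n_max = 1e6L) {
  if (!is.finite(effect_size_d) || effect_size_d <= 0) {
    stop("divergence: effect_size_d must be > 0 for a finite sample size",
         call. = FALSE)
  }
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  for (n in 2:n_max) {
    pw <- t_test_power(n, effect_size_d, alpha)
    if (pw >= power) {
      return(list(n_per_group = as.integer(n), n_total = 2L * as.integer(n),
                  achieved_power = pw))
    }
  }
  stop("divergence: no n <= n_max reaches the requested power", call. = FALSE)
}

# Exact power of the two-sided two-sample t test at per-group size n.
t_test_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Per-arm descriptive statistics
#'
#' @param outcomes Cohort data frame.
#' @param outcome `"ims"` or `"bp"`.
#' @return Data frame with one row per arm: `condition`, `n`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`, `improvement` (mean post - pre).
#' @export
descriptives <- function(outcomes, outcome = c("ims", "bp")) {
  outcome <- match.arg(outcome)
  if (nrow(outcomes) == 0L) stop("empty cohort", call. = FALSE)
  pre <- outcomes[[paste0(outcome, "_pre")]]
  post <- outcomes[[paste0(outcome, "_post")]]
  arms <- split(seq_len(nrow(outcomes)), outcomes$condition)
  out <- do.call(rbind, lapply(names(arms), function(a) {
    i <- arms[[a]]
    data.frame(condition = a, n = length(i),
               pre_mean = mean(pre[i]), pre_sd = stats::sd(pre[i]),
               post_mean = mean(post[i]), post_sd = stats::sd(post[i]),
               improvement = mean(post[i] - pre[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full trial analysis pipeline
#'
#' Pipeline order is fixed: (1) Tukey-fence outlier filtering of
#' post-training values of the configured outcome(s) within arm, applied
#' exactly once, with a per-arm audit of removals; (2) per-arm
#' descriptives; (3) group x time mixed ANOVAs for balance points and mood;
#' (4) all pairwise arm contrasts, adjusted and unadjusted, for both
#' outcomes (mood contrasts adjust for baseline mood, age and gender;
#' balance-point contrasts for the baseline balance point).
#'
#' @param outcomes Cohort data frame.
#' @param outlier_on Character vector of outcomes the 1.5 IQR rule is
#'   applied to (post-training values, within arm); any of `"ims"`,
#'   `"bp"`, or `character(0)` to disable filtering.
#' @return A list of class `gcbm_report`: `filter_audit`, `n_analyzed`,
#'   `descriptives`, `anova`, `contrasts`.
#' @export
run_full_analysis <- function(outcomes, outlier_on = c("ims", "bp")) {
  if (nrow(outcomes) == 0L) stop("empty cohort", call. = FALSE)
  arms <- sort(unique(outcomes$condition))

  # outlier filter, within arm, on post-training values; union over outcomes
  drop <- rep(FALSE, nrow(outcomes))
  audit <- list()
  for (oc in outlier_on) {
    post <- outcomes[[paste0(oc, "_post")]]
    removed <- stats::setNames(integer(length(arms)), arms)
    for (a in arms) {
      i <- which(outcomes$condition == a)
      if (length(i) >= 4L) {
        tf <- tukey_filter(post[i])
        drop[i[!tf$keep]] <- TRUE
        removed[a] <- tf$n_removed
      }
    }
    audit[[oc]] <- as.list(removed)
  }
  kept <- outcomes[!drop, , drop = FALSE]

  anova <- list(); contrasts <- list()
  pairs <- utils::combn(arms, 2L, simplify = FALSE)
  for (oc in c("bp", "ims")) {
    anova[[oc]] <- mixed_anova_time_group(kept, oc)
    covs <- if (oc == "ims") c("baseline", "age", "gender") else "baseline"
    for (p in pairs) {
      key <- paste(oc, p[1L], "vs", p[2L], sep = ".")
      contrasts[[paste0(key, ".adjusted")]] <-
        adjusted_regression(kept, oc, p, covariates = covs)
      contrasts[[paste0(key, ".unadjusted")]] <-
        adjusted_regression(kept, oc, p, covariates = character(0))
    }
  }

  structure(list(
    filter_audit = list(rule = "1.5 x IQR Tukey fences on post-training values, within arm",
                        outcomes = outlier_on,
                        removed = audit,
                        n_removed_total = sum(drop)),
    n_analyzed = nrow(kept),
    descriptives = list(ims = descriptives(kept, "ims"),
                        bp = descriptives(kept, "bp")),
    anova = anova,
    contrasts = contrasts
  ), class = "gcbm_report")
}
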