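test_that("Tukey fences keep the bulk and drop gross outliers", {
  # constant data: IQR = 0, everything kept
  tf <- tukey_filter(rep(5, 6))
  expect_true(all(tf$keep))
  expect_equal(tf$n_removed, 0L)

  # 1..9 plus 100: Q1 = 3.25, Q3 = 7.75 by linear interpolation,
  # fences (-3.5, 14.5), so only the 100 falls outside
  tf <- tukey_filter(c(1:9, 100))
  expect_equal(tf$fences, c(-3.5, 14.5))
  expect_equal(tf$keep, c(rep(TRUE, 9), FALSE))

  # symmetric data give fences symmetric about the median
  x <- c(2, 4, 6, 8, 10)
  tf <- tukey_filter(x)
  expect_equal(mean(tf$fences), median(x))

  # values exactly on a fence are kept
  expect_true(tukey_filter(c(-3.5, 1:9))$keep[1])

  expect_error(tukey_filter(c(1, 2, 3)), "at least 4")
})

test_that("group x time interaction matches the change-score oracle", {
  # hand-built 6-participant, 3-arm dataset
  d <- data.frame(
    participant_id = paste0("P", 1:6),
    condition = rep(c("cbm_training", "gcbm_training", "cbm_control"), each = 2),
    age = 25L, gender = "woman",
    ims_pre = c(90, 100, 95, 105, 92, 98),
    ims_post = c(97, 104, 106, 112, 93, 100),
    bp_pre = 7, bp_post = 7.5, stringsAsFactors = FALSE
  )
  res <- mixed_anova_time_group(d, "ims")
  oracle <- oracle_change_anova(d$ims_post - d$ims_pre, d$condition)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$df_between, oracle$df1)
  expect_equal(res$df_within, oracle$df2)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$partial_eta_sq, oracle$eta, tolerance = 1e-10)
  expect_gte(res$partial_eta_sq, 0)
  expect_lte(res$partial_eta_sq, 1)
})

test_that("identical change scores in every arm give a zero interaction", {
  d <- data.frame(
    participant_id = paste0("P", 1:6),
    condition = rep(c("cbm_training", "gcbm_training", "cbm_control"), each = 2),
    age = 25L, gender = "man",
    ims_pre = c(90, 100, 95, 105, 92, 98),
    bp_pre = 7, bp_post = 7, stringsAsFactors = FALSE
  )
  # every arm has change scores {2, 6}: equal arm means, nonzero residual
  d$ims_post <- d$ims_pre + rep(c(2, 6), 3)
  res <- mixed_anova_time_group(d, "ims")
  expect_equal(res$F, 0, tolerance = 1e-10)
  expect_equal(res$partial_eta_sq, 0, tolerance = 1e-10)
})

test_that("degenerate designs are refused", {
  d <- data.frame(participant_id = c("a", "b", "c"),
                  condition = c("cbm_training", "cbm_training", "cbm_control"),
                  ims_pre = c(1, 2, 3), ims_post = c(2, 3, 4),
                  age = 20L, gender = "woman", bp_pre = 7, bp_post = 7)
  expect_error(mixed_anova_time_group(d, "ims"), "fewer than 2")
  expect_error(mixed_anova_time_group(d[1:2, ], "ims"), "at least 2 arms")
})

test_that("adjusted regression agrees with the normal-equations oracle", {
  # 8-row hand dataset, two arms, baseline + age covariates
  d <- data.frame(
    participant_id = paste0("P", 1:8),
    condition = rep(c("cbm_control", "gcbm_training"), each = 4),
    age = c(19L, 24L, 28L, 22L, 30L, 18L, 25L, 21L),
    gender = "woman",
    ims_pre = c(80, 95, 102, 88, 91, 84, 99, 107),
    ims_post = c(84, 97, 110, 90, 99, 95, 104, 118),
    bp_pre = 7, bp_post = 7, stringsAsFactors = FALSE
  )
  res <- adjusted_regression(d, "ims", c("cbm_control", "gcbm_training"),
                             covariates = c("baseline", "age"))
  X <- cbind(1, d$condition == "gcbm_training", d$ims_pre, d$age)
  o <- oracle_ols(X, d$ims_post)
  expect_equal(res$B, o$beta[2], tolerance = 1e-10)
  expect_equal(res$ci_low, o$ci_low[2], tolerance = 1e-10)
  expect_equal(res$ci_high, o$ci_high[2], tolerance = 1e-10)
  expect_equal(res$p, o$p[2], tolerance = 1e-10)
  expect_true(res$ci_low <= res$B && res$B <= res$ci_high)

  # unadjusted model reduces to the difference in arm means
  res_u <- adjusted_regression(d, "ims", c("cbm_control", "gcbm_training"),
                               covariates = character(0))
  expect_false(res_u$adjusted)
  expect_equal(res_u$B, mean(d$ims_post[5:8]) - mean(d$ims_post[1:4]),
               tolerance = 1e-10)
})

test_that("arms with identical outcomes give a zero treatment effect", {
  d <- data.frame(
    participant_id = paste0("P", 1:8),
    condition = rep(c("cbm_control", "gcbm_training"), each = 4),
    age = rep(c(20L, 26L, 22L, 24L), 2), gender = "woman",
    ims_pre = rep(c(90, 95, 100, 105), 2),
    ims_post = rep(c(94, 99, 104, 109), 2),
    bp_pre = 7, bp_post = 7, stringsAsFactors = FALSE
  )
  # zero-noise construction fits perfectly; the lm warning is expected
  res <- suppressWarnings(
    adjusted_regression(d, "ims", c("cbm_control", "gcbm_training"),
                        covariates = c("baseline", "age")))
  expect_equal(res$B, 0, tolerance = 1e-10)
})

test_that("baseline orthogonal to arm: adjusted B equals residualized mean difference", {
  set.seed(7)
  n <- 20
  arm <- rep(c("cbm_control", "gcbm_training"), each = n / 2)
  base <- rep(c(85, 90, 100, 110, 95), 4)  # identical distribution per arm
  post <- 0.6 * base + ifelse(arm == "gcbm_training", 5, 0) + rnorm(n, 0, 2)
  d <- data.frame(participant_id = paste0("P", 1:n), condition = arm,
                  age = 25L, gender = "man", ims_pre = base, ims_post = post,
                  bp_pre = 7, bp_post = 7, stringsAsFactors = FALSE)
  res <- adjusted_regression(d, "ims", c("cbm_control", "gcbm_training"),
                             covariates = "baseline")
  r_post <- residuals(lm(post ~ base))
  fw <- mean(r_post[arm == "gcbm_training"]) - mean(r_post[arm == "cbm_control"])
  expect_equal(res$B, fw, tolerance = 1e-10)
})

test_that("collinear covariates raise a rank-deficiency error naming terms", {
  d <- data.frame(
    participant_id = paste0("P", 1:8),
    condition = rep(c("cbm_control", "gcbm_training"), each = 4),
    gender = "woman",
    ims_pre = c(80, 95, 102, 88, 91, 84, 99, 107),
    ims_post = c(84, 97, 110, 90, 99, 95, 104, 118),
    bp_pre = 7, bp_post = 7, stringsAsFactors = FALSE
  )
  d$age <- d$ims_pre  # age aliases the baseline exactly
  expect_error(adjusted_regression(d, "ims", c("cbm_control", "gcbm_training"),
                                   covariates = c("baseline", "age")),
               "rank-deficient.*age")
  expect_error(adjusted_regression(d, "ims", c("cbm_control", "cbm_control")),
               "distinct")
  expect_error(adjusted_regression(d, "ims", c("cbm_control", "cbm_training")),
               "both arms")
})

test_that("power solver reproduces exact noncentral-t sample sizes", {
  res <- power_n_per_group(0.2, 0.80, 0.05)
  expect_equal(res$n_per_group, 394L)
  expect_equal(res$n_total, 788L)
  expect_gte(res$achieved_power, 0.80)
  expect_equal(power_n_per_group(0.5, 0.80, 0.05)$n_per_group, 64L)
  # monotone: larger effects never need more participants
  ds <- c(0.1, 0.2, 0.3, 0.5, 0.8)
  ns <- vapply(ds, function(d) power_n_per_group(d)$n_per_group, integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(power_n_per_group(0), "divergence")
  expect_error(power_n_per_group(0.2, alpha = 1.2), "alpha")
  expect_error(power_n_per_group(0.2, power = 0), "power")
})

test_that("descriptives report per-arm means, SDs and improvements", {
  d <- data.frame(participant_id = c("a", "b"), condition = "cbm_training",
                  age = 20L, gender = "woman",
                  ims_pre = c(100, 100), ims_post = c(104, 104),
                  bp_pre = c(7, 8), bp_post = c(8, 9), stringsAsFactors = FALSE)
  out <- descriptives(d, "ims")
  expect_equal(out$improvement, 4)
  expect_equal(out$pre_mean, 100)
  expect_equal(out$pre_sd, 0)
  expect_equal(descriptives(d, "bp")$improvement, 1)
  expect_error(descriptives(d[0, ], "ims"), "empty")
})

test_that("the full pipeline filters once, audits removals, and reports all contrasts", {
  coh <- simulate_cohort(c(cbm_training = 20, gcbm_training = 20, cbm_control = 15),
                         root_seed = 31)$outcomes
  rep0 <- run_full_analysis(coh, outlier_on = character(0))
  expect_equal(rep0$n_analyzed, nrow(coh))
  expect_equal(rep0$filter_audit$n_removed_total, 0L)
  # 3 arm pairs x adjusted/unadjusted x 2 outcomes
  expect_length(rep0$contrasts, 12L)
  expect_setequal(rep0$descriptives$ims$condition,
                  c("cbm_training", "gcbm_training", "cbm_control"))

  # deterministic cohort with no natural outliers, then one injected
  set.seed(1)
  tight <- data.frame(
    participant_id = sprintf("P%02d", 1:18),
    condition = rep(c("cbm_training", "gcbm_training", "cbm_control"), each = 6),
    age = rep(c(22L, 28L, 19L, 25L, 30L, 21L), 3),
    gender = rep(c("woman", "man"), 9),
    ims_pre = rep(c(95, 97, 99, 101, 103, 105), 3),
    ims_post = rep(c(95, 97, 99, 101, 103, 105), 3) +
      rep(c(3.2, 4.8, 4.1, 5.0, 3.6, 4.4), 3),
    bp_pre = rep(c(6.8, 7.0, 7.2, 7.4, 7.6, 7.8), 3),
    bp_post = rep(c(6.8, 7.0, 7.2, 7.4, 7.6, 7.8), 3) +
      rep(c(0.12, 0.31, 0.05, 0.44, 0.23, 0.36), 3),
    stringsAsFactors = FALSE
  )
  clean <- run_full_analysis(tight, outlier_on = "ims")
  expect_equal(clean$filter_audit$n_removed_total, 0L)
  tight$ims_post[1] <- 154
  dirty <- run_full_analysis(tight, outlier_on = "ims")
  expect_equal(dirty$filter_audit$n_removed_total, 1L)
  expect_equal(dirty$filter_audit$removed$ims$cbm_training, 1L)
  expect_equal(dirty$n_analyzed, clean$n_analyzed - 1L)
})
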