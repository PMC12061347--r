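#' Mood-outcome model parameters
#'
#' Pre-training mood totals are drawn per arm from a truncated normal; the
#' post-training total adds the arm's configured mean improvement, a
#' coupling to the participant's own balance-point shift (centred on the
#' arm's expected shift, so the configured improvement stays the arm mean
#' regardless of the coupling), and residual noise:
#'
#' `post = pre + delta[arm] + beta * (bp_shift - E[bp_shift | arm]) + N(0, noise_sd)`
#'
#' truncated to `score_range`. Defaults emulate a 22-item mood scale summed
#' over 7-point items (total range 22-154) with arm means and dispersions
#' typical of large online mood-training cohorts.
#'
#' @param pre_mean,pre_sd Named numeric vectors (by condition) or scalars:
#'   pre-training mood mean and SD.
#' @param arm_effects Named numeric vector: mean mood improvement per
#'   condition.
#' @param bias_coupling_beta Mood points gained per unit of balance-point
#'   shift beyond the arm's expected shift.
#' @param expected_bp_shift Named numeric vector: the expected raw
#'   balance-point shift per condition, used to centre the coupling term.
#' @param noise_sd Residual change-score SD (>= 0; 0 gives the
#'   deterministic limit).
#' @param score_range Length-2 numeric, truncation bounds of the summed
#'   mood scale.
#' @return An object of class `gcbm_mood_params`.
#' @export
mood_model_params <- function(
    pre_mean = c(cbm_training = 96.39, gcbm_training = 98.12,
                 cbm_control = 95.50, gcbm_control = 95.50),
    pre_sd = c(cbm_training = 25.32, gcbm_training = 27.27,
               cbm_control = 26.54, gcbm_control = 26.54),
    arm_effects = c(cbm_training = 5.35, gcbm_training = 7.01,
                    cbm_control = 3.63, gcbm_control = 3.63),
    bias_coupling_beta = 1.0,
    expected_bp_shift = c(cbm_training = 0.87, gcbm_training = 1.35,
                          cbm_control = 0, gcbm_control = 0),
    noise_sd = 13,
    score_range = c(22, 154)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(score_range) != 2L || score_range[1] >= score_range[2]) {
    stop("score_range must be (low, high) with low < high", call. = FALSE)
  }
  structure(list(pre_mean = pre_mean, pre_sd = pre_sd,
                 arm_effects = arm_effects,
                 bias_coupling_beta = bias_coupling_beta,
                 expected_bp_shift = expected_bp_shift,
                 noise_sd = noise_sd, score_range = score_range),
            class = "gcbm_mood_params")
}

arm_value <- function(x, condition) {
  if (is.null(names(x))) return(rep_len(x, length(condition)))
  if (!all(condition %in% names(x))) {
    stop("configuration error: no value configured for condition(s) ",
         paste(setdiff(condition, names(x)), collapse = ", "), call. = FALSE)
  }
  unname(x[condition])
}

#' Simulate post-training mood totals
#'
#' Vectorised over participants. See [mood_model_params()] for the model.
#'
#' @param ims_pre Numeric vector of pre-training mood totals.
#' @param bp_shift Numeric vector of raw balance-point shifts (post - pre).
#' @param condition Character vector of condition labels.
#' @param params A [mood_model_params()].
#' @return Numeric vector of post-training mood totals within
#'   `params$score_range`.
#' @examples
#' p <- mood_model_params(noise_sd = 0, bias_coupling_beta = 0)
#' simulate_mood(95.50, 0, "cbm_control", p)  # 99.13
#' @export
simulate_mood <- function(ims_pre, bp_shift, condition, params = mood_model_params()) {
  stopifnot(inherits(params, "gcbm_mood_params"))
  n <- length(ims_pre)
  delta <- arm_value(params$arm_effects, condition)
  centre <- arm_value(params$expected_bp_shift, condition)
  post <- ims_pre + delta +
    params$bias_coupling_beta * (bp_shift - centre) +
    stats::rnorm(n, 0, params$noise_sd)
  pmin(pmax(post, params$score_range[1]), params$score_range[2])
}

#' Default agent populations per trial arm
#'
#' Each arm's simulated participants share a response-noise scale and
#' learning rate; initial criteria vary across participants as
#' `N(criterion_mean, criterion_sd)`. Criteria centre on the ambiguous
#' middle of the continuum, where balance points concentrate. Learning
#' rates are calibrated so that mean raw balance-point shifts under the
#' default task design are about +0.9 in the text-feedback training arm
#' and +1.4 in the gamified training arm, with control arms matched to
#' their family's learning rate (their unshifted target yields no net
#' drift).
#'
#' @return Named list (by condition) of lists with fields
#'   `criterion_mean`, `criterion_sd`, `slope_s`, `learning_rate_eta`.
#' @export
default_agent_populations <- function() {
  base <- list(criterion_mean = 7.5, criterion_sd = 1.2, slope_s = 0.75)
  list(
    cbm_training = c(base, learning_rate_eta = 0.10),
    gcbm_training = c(base, learning_rate_eta = 0.19),
    cbm_control = c(base, learning_rate_eta = 0.10),
    gcbm_control = c(base, learning_rate_eta = 0.19)
  )
}

#' Simulate a full randomized cohort
#'
#' Each simulated participant is assigned an arm, drawn from that arm's
#' agent population, run through a complete four-block task session
#' ([run_session()]), and given pre/post mood totals from the mood model.
#' Ages are uniform on 18-30 and gender follows a configurable mix. The
#' whole cohort is reproducible from `root_seed`.
#'
#' @param n_per_arm Named integer vector: participants per condition.
#'   Defaults to the post-exclusion arm sizes of a large single-session
#'   online trial (400 text-feedback training, 397 gamified training, 119
#'   control).
#' @param agent_populations Named list per condition; see
#'   [default_agent_populations()].
#' @param mood_params A [mood_model_params()].
#' @param config Base [session_config()]; its `condition` and `rng_seed`
#'   are overridden per participant.
#' @param root_seed Integer seed governing all randomness.
#' @param gender_mix Named probability vector for the gender covariate.
#' @param keep_logs If `TRUE`, also return the concatenated trial logs of
#'   every session (152 rows per participant under the default design).
#' @return List with `outcomes` (data frame, one row per participant:
#'   `participant_id`, `condition`, `age`, `gender`, `ims_pre`, `ims_post`,
#'   `bp_pre`, `bp_post`) and `logs` (data frame or `NULL`).
#' @examples
#' coh <- simulate_cohort(c(gcbm_training = 3, cbm_control = 2), root_seed = 11)
#' coh$outcomes
#' @export
simulate_cohort <- function(n_per_arm = c(cbm_training = 400L,
                                          gcbm_training = 397L,
                                          cbm_control = 119L),
                            agent_populations = default_agent_populations(),
                            mood_params = mood_model_params(),
                            config = session_config(),
                            root_seed = 1L,
                            gender_mix = c(woman = 0.551, man = 0.428,
                                           undisclosed = 0.021),
                            keep_logs = FALSE) {
  if (is.null(names(n_per_arm)) || !all(names(n_per_arm) %in% CONDITIONS)) {
    stop("configuration error: n_per_arm must be named by condition labels (",
         paste(CONDITIONS, collapse = ", "), ")", call. = FALSE)
  }
  missing_pop <- setdiff(names(n_per_arm)[n_per_arm > 0], names(agent_populations))
  if (length(missing_pop)) {
    stop("configuration error: no agent population for condition(s) ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  }
  condition <- rep(names(n_per_arm), times = n_per_arm)
  n <- length(condition)
  empty <- data.frame(participant_id = character(), condition = character(),
                      age = integer(), gender = character(),
                      ims_pre = numeric(), ims_post = numeric(),
                      bp_pre = numeric(), bp_post = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(outcomes = empty, logs = NULL))

  seeds <- derive_seeds(root_seed, 2L)
  set.seed(seeds[1L])
  session_seeds <- sample.int(.Machine$integer.max - 1L, n)
  age <- sample(18:30, n, replace = TRUE)
  gender <- sample(names(gender_mix), n, replace = TRUE, prob = gender_mix)
  pre_mu <- arm_value(mood_params$pre_mean, condition)
  pre_sd <- arm_value(mood_params$pre_sd, condition)
  ims_pre <- pmin(pmax(stats::rnorm(n, pre_mu, pre_sd), mood_params$score_range[1]),
                  mood_params$score_range[2])
  pop <- agent_populations[condition]
  c0 <- stats::rnorm(n,
                     vapply(pop, `[[`, numeric(1), "criterion_mean"),
                     vapply(pop, `[[`, numeric(1), "criterion_sd"))

  bp_pre <- bp_post <- numeric(n)
  logs <- if (keep_logs) vector("list", n) else NULL
  for (k in seq_len(n)) {
    cfg_k <- config
    cfg_k$condition <- condition[k]
    cfg_k$rng_seed <- session_seeds[k]
    cfg_k <- validate_session_config(cfg_k)
    ag <- make_agent(agent_params(criterion_c0 = c0[k],
                                  slope_s = pop[[k]]$slope_s,
                                  learning_rate_eta = pop[[k]]$learning_rate_eta),
                     n_levels = cfg_k$n_levels)
    sess <- run_session(ag, cfg_k)
    bp_pre[k] <- sess$bp_pre$raw
    bp_post[k] <- sess$bp_post$raw
    if (keep_logs) {
      lg <- sess$trials
      lg <- cbind(participant_id = sprintf("P%04d", k),
                  condition = condition[k], lg, stringsAsFactors = FALSE)
      logs[[k]] <- lg
    }
  }

  set.seed(seeds[2L])
  ims_post <- simulate_mood(ims_pre, bp_post - bp_pre, condition, mood_params)

  outcomes <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    condition = condition, age = age, gender = gender,
    ims_pre = ims_pre, ims_post = ims_post,
    bp_pre = bp_pre, bp_post = bp_post,
    stringsAsFactors = FALSE
  )
  list(outcomes = outcomes,
       logs = if (keep_logs) do.call(rbind, logs) else NULL)
}
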