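#' Build the baseline (or test) block schedule
#'
#' Every stimulus on the continuum is presented
#' `reps_per_stimulus_baseline` times in uniformly random order.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (callers such as [run_session()] pass a derived child seed so
#'   schedules do not depend on agent behaviour).
#' @return Integer vector of stimulus indices, length
#'   `config$baseline_trials`.
#' @examples
#' sched <- build_baseline_schedule(session_config(), seed = 42)
#' table(sched)
#' @export
build_baseline_schedule <- function(config, seed = NULL) {
  validate_session_config(config)
  pool <- rep(seq_len(config$n_levels), times = config$reps_per_stimulus_baseline)
  if (!is.null(seed)) set.seed(seed)
  sample(pool, length(pool), replace = FALSE)
}

#' Build one training-block schedule
#'
#' Presents each stimulus the number of times given by the configuration's
#' `training_frequency_map` (default: endpoints once, mildly ambiguous
#' stimuli twice, the ambiguous middle three times — 31 trials), shuffled.
#'
#' @inheritParams build_baseline_schedule
#' @return Integer vector of stimulus indices, length
#'   `sum(config$training_frequency_map)`.
#' @export
build_training_schedule <- function(config, seed = NULL) {
  validate_session_config(config)
  fm <- config$training_frequency_map
  idx <- as.integer(names(fm))
  pool <- rep(idx, times = as.integer(fm))
  if (!is.null(seed)) set.seed(seed)
  if (length(pool) <= 1L) return(pool)
  sample(pool, length(pool), replace = FALSE)
}

#' Estimate a balance point from block responses
#'
#' The balance point is the continuum position at which a responder is
#' equally likely to call a face happy or sad, estimated as the proportion
#' of "happy" responses in the block multiplied by the number of stimulus
#' levels. E.g. 30 "happy" responses in a 45-trial block on a 15-level
#' continuum give (30/45) x 15 = 10. For feedback targeting, balance points
#' are rounded half-up to the nearest whole number.
#'
#' Only response counts matter: the estimate is invariant to which stimuli
#' elicited the responses and to response order.
#'
#' @param responses Character vector of `"happy"` / `"sad"` responses.
#' @param n_levels Number of morph steps on the continuum.
#' @param source_block `"baseline"` or `"test"`.
#' @return An object of class `gcbm_balance_point` with fields `raw`,
#'   `rounded`, `source_block`, `n_happy`, `n_trials`.
#' @examples
#' bp <- estimate_balance_point(rep(c("happy", "sad"), c(30, 15)), 15, "baseline")
#' bp$raw      # 10
#' bp$rounded  # 10
#' @export
estimate_balance_point <- function(responses, n_levels = 15L,
                                   source_block = c("baseline", "test")) {
  source_block <- match.arg(source_block)
  if (length(responses) == 0L) {
    stop("insufficient data: cannot estimate a balance point from zero trials",
         call. = FALSE)
  }
  bad <- setdiff(unique(responses), c("happy", "sad"))
  if (length(bad)) {
    stop("invalid response value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_happy <- sum(responses == "happy")
  n_trials <- length(responses)
  raw <- n_happy / n_trials * n_levels
  structure(
    list(raw = raw,
         rounded = round_half_up(raw),
         source_block = source_block,
         n_happy = n_happy,
         n_trials = n_trials),
    class = "gcbm_balance_point"
  )
}

#' @export
print.gcbm_balance_point <- function(x, ...) {
  cat(sprintf("<balance point> raw %.3f (rounded %d) from %d/%d happy in %s block\n",
              x$raw, x$rounded, x$n_happy, x$n_trials, x$source_block))
  invisible(x)
}

# Round half away from the floor ("round half up"): 10.5 -> 11.
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Compute the feedback target balance point
#'
#' Training conditions shift the rounded baseline balance point upward by
#' `shift` (toward calling more faces happy), clamped to the continuum;
#' control conditions leave it unchanged, so control feedback rewards
#' responding exactly as at baseline.
#'
#' @param baseline A `gcbm_balance_point` (or its rounded integer value).
#' @param condition A condition label (see [session_config()]).
#' @param shift Non-negative integer increment for training conditions.
#' @param n_levels Continuum length, used to clamp the target.
#' @return Integer target balance point in `[0, n_levels]`.
#' @examples
#' compute_target_balance_point(10, "gcbm_training", 2, 15)  # 12
#' compute_target_balance_point(10, "cbm_control", 2, 15)    # 10
#' compute_target_balance_point(14, "cbm_training", 2, 15)   # 15 (clamped)
#' @export
compute_target_balance_point <- function(baseline, condition, shift = 2L,
                                         n_levels = 15L) {
  rounded <- if (inherits(baseline, "gcbm_balance_point")) baseline$rounded
             else as.integer(baseline)
  if (is.na(rounded) || rounded < 0L || rounded > n_levels) {
    stop("baseline rounded balance point must lie in [0, n_levels]", call. = FALSE)
  }
  if (shift < 0L) {
    stop("configuration error: shift must be >= 0", call. = FALSE)
  }
  if (!condition %in% CONDITIONS) {
    stop("configuration error: unknown condition '", condition, "'", call. = FALSE)
  }
  if (condition %in% TRAINING_CONDITIONS) {
    min(rounded + as.integer(shift), as.integer(n_levels))
  } else {
    rounded
  }
}

#' Feedback-correct label of a stimulus under a target balance point
#'
#' With index 1 the happy end of the continuum, a stimulus is labelled
#' `"happy"` iff its index is at or below the target (boundary inclusive,
#' so a responder who answers perfectly to the labels has an expected
#' balance point equal to the target).
#'
#' @param stimulus_index Integer vector of indices in `1..n_levels`.
#' @param target_balance_point Integer target.
#' @param n_levels Continuum length.
#' @return Character vector, `"happy"` or `"sad"` per stimulus.
#' @export
correct_label <- function(stimulus_index, target_balance_point, n_levels = 15L) {
  if (any(stimulus_index < 1L | stimulus_index > n_levels)) {
    stop("stimulus_index out of range 1..", n_levels, call. = FALSE)
  }
  ifelse(stimulus_index <= target_balance_point, "happy", "sad")
}

#' Text feedback for a training trial (CBM conditions)
#'
#' @param response `"happy"` or `"sad"`.
#' @param stimulus_index Stimulus shown.
#' @param target Target balance point defining correctness.
#' @param n_levels Continuum length.
#' @return List with `correct` (logical) and `feedback_text`; the text
#'   names the target-implied emotion of the face, e.g.
#'   `"Correct! That face was happy"`.
#' @export
cbm_feedback <- function(response, stimulus_index, target, n_levels = 15L) {
  label <- correct_label(stimulus_index, target, n_levels)
  correct <- response == label
  list(correct = correct,
       feedback_text = sprintf("%s! That face was %s",
                               ifelse(correct, "Correct", "Incorrect"), label))
}

#' Points awarded for a training trial (gamified conditions)
#'
#' Incorrect answers earn nothing. Correct answers earn
#' `max_points - decay_per_step * |stimulus - baseline balance point|`,
#' floored at `min_points_correct`, so the most ambiguous stimuli (nearest
#' the participant's own balance point) are worth the most.
#'
#' @inheritParams cbm_feedback
#' @param baseline_rounded The participant's rounded baseline balance point.
#' @param params [scoring_params()].
#' @return Non-negative integer vector of points.
#' @examples
#' gcbm_points("happy", 10, target = 12, baseline_rounded = 10)  # 10
#' gcbm_points("happy", 6, target = 12, baseline_rounded = 10)   # 6
#' gcbm_points("sad", 6, target = 12, baseline_rounded = 10)     # 0
#' @export
gcbm_points <- function(response, stimulus_index, target, baseline_rounded,
                        params = scoring_params(), n_levels = 15L) {
  validate_scoring_params(params)
  label <- correct_label(stimulus_index, target, n_levels)
  correct <- response == label
  pts <- pmax(params$max_points -
                params$decay_per_step * abs(stimulus_index - baseline_rounded),
              params$min_points_correct)
  as.integer(ifelse(correct, pts, 0L))
}

#' Run one complete task session for an agent
#'
#' Executes the four-block design — baseline, two training blocks, test —
#' against a simulated participant. The baseline block estimates the
#' pre-training balance point, from which the feedback target is computed
#' (shifted in training conditions, unchanged in control). Training trials
#' deliver text feedback (CBM family) or points (gamified family) and feed
#' corrective signals to the agent's learning rule; the test block
#' estimates the post-training balance point. The target is fixed from
#' baseline for both training blocks.
#'
#' Block schedules and agent response noise draw from independent child
#' streams of `config$rng_seed`, so schedules are reproducible regardless
#' of agent behaviour.
#'
#' @param agent An agent created by [make_agent()], exposing `respond` and
#'   `update` (see that help page for the contract).
#' @param config A [session_config()].
#' @return List with `trials` (data frame of trial records), `bp_pre`,
#'   `bp_post` (balance points), `target`, `total_points`, and
#'   `final_criterion`.
#' @examples
#' ag <- make_agent(agent_params(criterion_c0 = 8, slope_s = 0.75,
#'                               learning_rate_eta = 0.3))
#' sess <- run_session(ag, session_config("gcbm_training", rng_seed = 7))
#' nrow(sess$trials)      # 152
#' sess$bp_pre$raw
#' @export
run_session <- function(agent, config = session_config()) {
  validate_session_config(config)
  if (!is.list(agent) || !is.function(agent$respond) || !is.function(agent$update)) {
    stop("protocol error: agent must provide respond() and update() functions",
         call. = FALSE)
  }
  n_blocks <- 2L + config$training_blocks
  seeds <- derive_seeds(config$rng_seed, n_blocks + 1L)

  # Build every schedule first (schedule stream), then switch to the agent
  # stream once: schedules are reproducible from the root seed no matter how
  # the agent behaves.
  sched_baseline <- build_baseline_schedule(config, seed = seeds[1L])
  sched_training <- lapply(seq_len(config$training_blocks),
                           function(b) build_training_schedule(config, seed = seeds[1L + b]))
  sched_test <- build_baseline_schedule(config, seed = seeds[n_blocks])
  set.seed(seeds[n_blocks + 1L])  # agent stream for the whole session

  gamified <- config$condition %in% GCBM_CONDITIONS

  blocks <- list()
  # --- baseline ---
  sched <- sched_baseline
  resp <- vapply(sched, function(i) agent$respond(i), character(1))
  bp_pre <- estimate_balance_point(resp, config$n_levels, "baseline")
  blocks$baseline <- data.frame(
    block = "baseline", trial_index = seq_along(sched),
    stimulus_index = sched, response = resp,
    correct = NA, feedback_text = NA_character_, points_awarded = NA_integer_,
    stringsAsFactors = FALSE
  )

  target <- compute_target_balance_point(bp_pre, config$condition,
                                         config$shift, config$n_levels)

  # --- training blocks (sequential: learning updates between trials) ---
  total_points <- 0L
  for (tb in seq_len(config$training_blocks)) {
    sched <- sched_training[[tb]]
    nt <- length(sched)
    resp <- character(nt); corr <- logical(nt)
    ftxt <- rep(NA_character_, nt); pts <- rep(NA_integer_, nt)
    for (k in seq_len(nt)) {
      i <- sched[k]
      r <- agent$respond(i)
      label <- correct_label(i, target, config$n_levels)
      ok <- r == label
      if (gamified) {
        pts[k] <- gcbm_points(r, i, target, bp_pre$rounded,
                              config$scoring, config$n_levels)
        total_points <- total_points + pts[k]
      } else {
        ftxt[k] <- sprintf("%s! That face was %s",
                           if (ok) "Correct" else "Incorrect", label)
      }
      signal <- if (ok) "none" else if (label == "happy") "push_happy" else "push_sad"
      agent$update(signal)
      resp[k] <- r; corr[k] <- ok
    }
    blocks[[paste0("training", tb)]] <- data.frame(
      block = paste0("training", tb), trial_index = seq_len(nt),
      stimulus_index = sched, response = resp, correct = corr,
      feedback_text = ftxt, points_awarded = pts, stringsAsFactors = FALSE
    )
  }

  # --- test ---
  sched <- sched_test
  resp <- vapply(sched, function(i) agent$respond(i), character(1))
  bp_post <- estimate_balance_point(resp, config$n_levels, "test")
  blocks$test <- data.frame(
    block = "test", trial_index = seq_along(sched),
    stimulus_index = sched, response = resp,
    correct = NA, feedback_text = NA_character_, points_awarded = NA_integer_,
    stringsAsFactors = FALSE
  )

  trials <- do.call(rbind, blocks)
  rownames(trials) <- NULL
  list(trials = trials, bp_pre = bp_pre, bp_post = bp_post, target = target,
       total_points = total_points, final_criterion = agent$criterion())
}
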