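# Condition labels. The task family (text feedback vs. points) and whether the
# training target is shifted are both encoded in the condition.
CONDITIONS <- c("cbm_training", "cbm_control", "gcbm_training", "gcbm_control")

TRAINING_CONDITIONS <- c("cbm_training", "gcbm_training")
GCBM_CONDITIONS <- c("gcbm_training", "gcbm_control")
BLOCKS <- c("baseline", "training1", "training2", "test")

#' Default per-stimulus presentation counts for one training block
#'
#' The unambiguous continuum endpoints are shown once, mildly ambiguous
#' stimuli twice, and the most ambiguous (middle) stimuli three times, so
#' that training concentrates on the region where balance points fall.
#' Sums to 31 for the default 15-level continuum.
#'
#' @param n_levels Number of morph steps on the continuum.
#' @return Named integer vector mapping stimulus index to presentations.
#' @export
default_training_frequencies <- function(n_levels = 15L) {
  if (n_levels != 15L) {
    stop("default training frequencies are defined for the 15-level continuum; ",
         "supply `training_frequency_map` explicitly for n_levels = ", n_levels,
         call. = FALSE)
  }
  freq <- c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3, 2, 2, 2, 1, 1)
  stats::setNames(as.integer(freq), as.character(1:15))
}

#' Session configuration for one CBM/GCBM task run
#'
#' Bundles every design constant of a single task session: the morph
#' continuum, block sizes, per-stimulus training frequencies, the training
#' target shift, stimulus timing, and the session's random seed. Index 1 is
#' the unambiguously happy end of the continuum and index `n_levels` the
#' unambiguously sad end.
#'
#' @param condition One of `"cbm_training"`, `"cbm_control"`,
#'   `"gcbm_training"`, `"gcbm_control"`. Training conditions shift the
#'   feedback target upward by `shift`; control conditions key feedback to
#'   the unmodified baseline balance point.
#' @param n_levels Number of morph steps (default 15).
#' @param reps_per_stimulus_baseline Presentations of each stimulus in the
#'   baseline and test blocks (default 3).
#' @param baseline_trials Trials in the baseline (and test) block; must equal
#'   `n_levels * reps_per_stimulus_baseline`.
#' @param training_blocks Number of training blocks (default 2).
#' @param training_frequency_map Named integer vector, stimulus index to
#'   presentations per training block. Defaults to
#'   [default_training_frequencies()] (31 trials/block).
#' @param shift Balance-point increment applied to the training target in
#'   training conditions (default 2); ignored in control conditions.
#' @param fixation_ms,stimulus_ms Trial timing metadata in milliseconds
#'   (defaults 600 and 200; the legacy text-feedback task used 150 ms
#'   stimuli). Carried as metadata: the simulator does not model time.
#' @param scoring [scoring_params()] used under the gamified conditions.
#' @param rng_seed Integer root seed for the session. Schedules and agent
#'   responses draw from independent child streams derived from it.
#' @return An object of class `gcbm_config` (a validated list).
#' @examples
#' cfg <- session_config("gcbm_training", rng_seed = 1)
#' cfg$baseline_trials
#' sum(cfg$training_frequency_map)
#' @export
session_config <- function(condition = "gcbm_training",
                           n_levels = 15L,
                           reps_per_stimulus_baseline = 3L,
                           baseline_trials = n_levels * reps_per_stimulus_baseline,
                           training_blocks = 2L,
                           training_frequency_map = default_training_frequencies(n_levels),
                           shift = 2L,
                           fixation_ms = 600L,
                           stimulus_ms = 200L,
                           scoring = scoring_params(),
                           rng_seed = 1L) {
  cfg <- structure(
    list(
      condition = condition,
      n_levels = as.integer(n_levels),
      reps_per_stimulus_baseline = as.integer(reps_per_stimulus_baseline),
      baseline_trials = as.integer(baseline_trials),
      training_blocks = as.integer(training_blocks),
      training_frequency_map = training_frequency_map,
      shift = as.integer(shift),
      fixation_ms = as.integer(fixation_ms),
      stimulus_ms = as.integer(stimulus_ms),
      scoring = scoring,
      rng_seed = as.integer(rng_seed)
    ),
    class = "gcbm_config"
  )
  validate_session_config(cfg)
}

#' @rdname session_config
#' @param x Object to validate.
#' @export
validate_session_config <- function(x) {
  stopifnot(inherits(x, "gcbm_config"))
  if (!x$condition %in% CONDITIONS) {
    stop("configuration error: unknown condition '", x$condition, "'; must be one of ",
         paste(CONDITIONS, collapse = ", "), call. = FALSE)
  }
  if (is.na(x$n_levels) || x$n_levels < 3L) {
    stop("configuration error: n_levels must be >= 3", call. = FALSE)
  }
  if (x$baseline_trials != x$n_levels * x$reps_per_stimulus_baseline) {
    stop("configuration error: baseline_trials (", x$baseline_trials,
         ") must equal n_levels * reps_per_stimulus_baseline (",
         x$n_levels * x$reps_per_stimulus_baseline, ")", call. = FALSE)
  }
  fm <- x$training_frequency_map
  if (is.null(names(fm)) || anyNA(suppressWarnings(as.integer(names(fm))))) {
    stop("configuration error: training_frequency_map must be named by stimulus index",
         call. = FALSE)
  }
  idx <- as.integer(names(fm))
  if (!setequal(idx, seq_len(x$n_levels))) {
    missing <- setdiff(seq_len(x$n_levels), idx)
    extra <- setdiff(idx, seq_len(x$n_levels))
    stop("configuration error: training_frequency_map must cover every stimulus index ",
         "1..", x$n_levels,
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ",")),
         if (length(extra)) paste0("; out of range: ", paste(extra, collapse = ",")),
         call. = FALSE)
  }
  if (any(fm < 0) || anyNA(fm)) {
    stop("configuration error: training frequencies must be non-negative", call. = FALSE)
  }
  if (x$shift < 0L) {
    stop("configuration error: shift must be >= 0", call. = FALSE)
  }
  if (x$training_blocks < 0L) {
    stop("configuration error: training_blocks must be >= 0", call. = FALSE)
  }
  if (x$fixation_ms <= 0L || x$stimulus_ms <= 0L) {
    stop("configuration error: all durations must be > 0", call. = FALSE)
  }
  validate_scoring_params(x$scoring)
  x
}

#' @export
print.gcbm_config <- function(x, ...) {
  cat("<gcbm_config>\n")
  cat("  condition:        ", x$condition, "\n")
  cat("  continuum:        ", x$n_levels, "levels (1 = happy end)\n")
  cat("  baseline/test:    ", x$baseline_trials, "trials (each stimulus x",
      x$reps_per_stimulus_baseline, ")\n")
  cat("  training:         ", x$training_blocks, "block(s) x",
      sum(x$training_frequency_map), "trials\n")
  cat("  target shift:     ", if (x$condition %in% TRAINING_CONDITIONS) x$shift else 0, "\n")
  cat("  timing:           ", x$fixation_ms, "ms fixation /", x$stimulus_ms, "ms stimulus\n")
  cat("  rng_seed:         ", x$rng_seed, "\n")
  invisible(x)
}

#' Point-scoring parameters for the gamified task
#'
#' Correct responses earn `max_points` minus `decay_per_step` for each
#' continuum step between the stimulus and the participant's baseline
#' balance point, floored at `min_points_correct`; incorrect responses
#' always earn zero. This rewards correct classification of the most
#' ambiguous stimuli (those nearest the balance point) most highly.
#'
#' @param max_points Points for a correct answer at the baseline balance
#'   point itself (default 10).
#' @param decay_per_step Points lost per continuum step away from the
#'   baseline balance point (default 1).
#' @param min_points_correct Floor for a correct answer (default 1); must be
#'   positive so every correct answer is rewarded.
#' @return An object of class `gcbm_scoring`.
#' @export
scoring_params <- function(max_points = 10L, decay_per_step = 1L,
                           min_points_correct = 1L) {
  p <- structure(
    list(max_points = as.integer(max_points),
         decay_per_step = as.integer(decay_per_step),
         min_points_correct = as.integer(min_points_correct)),
    class = "gcbm_scoring"
  )
  validate_scoring_params(p)
}

validate_scoring_params <- function(p) {
  stopifnot(inherits(p, "gcbm_scoring"))
  if (is.na(p$max_points) || p$max_points < 1L) {
    stop("configuration error: max_points must be a positive integer", call. = FALSE)
  }
  if (is.na(p$decay_per_step) || p$decay_per_step < 0L) {
    stop("configuration error: decay_per_step must be >= 0", call. = FALSE)
  }
  if (is.na(p$min_points_correct) || p$min_points_correct < 1L ||
      p$min_points_correct > p$max_points) {
    stop("configuration error: min_points_correct must be in [1, max_points]",
         call. = FALSE)
  }
  p
}

# Derive n reproducible child seeds from a root seed without disturbing the
# caller's RNG stream ordering guarantees: used so block schedules are
# reproducible independent of how many random draws the agent makes.
derive_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
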