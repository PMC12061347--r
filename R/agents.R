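#' Parameters of a simulated participant
#'
#' The agent carries a latent decision criterion `c` on the morph
#' continuum: stimuli below the criterion tend to be called happy. The
#' response rule is a logistic psychometric function,
#' `P(happy | i) = logistic((c + 0.5 - i) / s)`, whose half-point offset
#' makes an integer criterion map exactly to an integer balance point in
#' the noiseless limit. Corrective feedback nudges the criterion by a fixed
#' learning-rate step.
#'
#' @param criterion_c0 Initial criterion, in continuum units.
#' @param slope_s Positive response-noise scale; `s -> 0` gives a
#'   deterministic threshold responder.
#' @param learning_rate_eta Non-negative criterion step applied on each
#'   corrective event (an error, i.e. negative feedback or a zero-point
#'   trial). Correct answers carry no corrective content.
#' @return An object of class `gcbm_agent_params`.
#' @export
agent_params <- function(criterion_c0 = 7.5, slope_s = 0.75,
                         learning_rate_eta = 0.1) {
  if (slope_s <= 0) stop("slope_s must be > 0", call. = FALSE)
  if (learning_rate_eta < 0) stop("learning_rate_eta must be >= 0", call. = FALSE)
  structure(list(criterion_c0 = criterion_c0, slope_s = slope_s,
                 learning_rate_eta = learning_rate_eta),
            class = "gcbm_agent_params")
}

#' Probability that an agent responds "happy"
#'
#' @param stimulus_index Integer vector in `1..n_levels`.
#' @param criterion_c Current criterion.
#' @param slope_s Positive noise scale.
#' @return Numeric vector of probabilities.
#' @export
prob_happy <- function(stimulus_index, criterion_c, slope_s) {
  stats::plogis((criterion_c + 0.5 - stimulus_index) / slope_s)
}

#' Draw a single response from the psychometric response rule
#'
#' @inheritParams prob_happy
#' @param n_levels Continuum length (index range check).
#' @return `"happy"` or `"sad"`.
#' @export
agent_respond <- function(stimulus_index, criterion_c, slope_s, n_levels = 15L) {
  if (any(stimulus_index < 1L | stimulus_index > n_levels)) {
    stop("stimulus_index out of range 1..", n_levels, call. = FALSE)
  }
  p <- prob_happy(stimulus_index, criterion_c, slope_s)
  ifelse(stats::runif(length(p)) < p, "happy", "sad")
}

#' Apply a corrective signal to the criterion
#'
#' `push_happy` (the face was happy per the feedback but the agent said
#' sad) raises the criterion by the learning rate; `push_sad` lowers it;
#' `none` leaves it unchanged. The criterion is clamped to `[0, n_levels]`.
#'
#' @param criterion_c Current criterion.
#' @param signal One of `"push_happy"`, `"push_sad"`, `"none"`.
#' @param eta Learning-rate step.
#' @param n_levels Continuum length (clamp bound).
#' @return Updated criterion.
#' @export
update_criterion <- function(criterion_c, signal = c("none", "push_happy", "push_sad"),
                             eta, n_levels = 15L) {
  signal <- match.arg(signal)
  c_new <- switch(signal,
                  push_happy = criterion_c + eta,
                  push_sad = criterion_c - eta,
                  none = criterion_c)
  min(max(c_new, 0), n_levels)
}

#' Closed-form expected raw balance point of an agent
#'
#' Under uniform per-stimulus presentation, the expected raw balance point
#' equals the sum of happy-response probabilities over the continuum,
#' `sum_i P(happy | i)`. In the `s -> 0` limit with an integer criterion
#' `k` this is exactly `k`.
#'
#' @inheritParams prob_happy
#' @param n_levels Continuum length.
#' @return Real expected balance point in `[0, n_levels]`.
#' @export
expected_balance_point <- function(criterion_c, slope_s, n_levels = 15L) {
  if (slope_s <= 0) stop("slope_s must be > 0", call. = FALSE)
  sum(prob_happy(seq_len(n_levels), criterion_c, slope_s))
}

#' Create a stateful agent for [run_session()]
#'
#' Wraps [agent_params()] into the closure interface the session runner
#' consumes: `respond(stimulus_index)` draws a response from the current
#' criterion, `update(signal)` applies the learning rule, `criterion()`
#' reads the current criterion, and `history()` returns the criterion
#' trajectory for diagnostics.
#'
#' @param params An [agent_params()].
#' @param n_levels Continuum length (criterion clamp bound).
#' @return A list of functions (`respond`, `update`, `criterion`,
#'   `history`, `reset`) sharing mutable state.
#' @export
make_agent <- function(params = agent_params(), n_levels = 15L) {
  stopifnot(inherits(params, "gcbm_agent_params"))
  c_now <- min(max(params$criterion_c0, 0), n_levels)
  traj <- c_now
  list(
    respond = function(stimulus_index) {
      agent_respond(stimulus_index, c_now, params$slope_s, n_levels)
    },
    update = function(signal) {
      c_now <<- update_criterion(c_now, signal, params$learning_rate_eta, n_levels)
      traj <<- c(traj, c_now)
      invisible(c_now)
    },
    criterion = function() c_now,
    history = function() traj,
    reset = function() {
      c_now <<- min(max(params$criterion_c0, 0), n_levels)
      traj <<- c_now
      invisible(c_now)
    }
  )
}
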