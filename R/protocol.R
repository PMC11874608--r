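# Training-session logic: coordination feedback, knowledge of results,
# bandwidth fading, and progression/stop rules.

#' Per-sample coordination feedback signal
#'
#' Coordination feedback changes the colour of the dots whenever the
#' produced relative phase is within an error bandwidth of the target; this
#' computes that indicator for every sample of a scored trial.
#'
#' @param series A [relative_phase_series()] result.
#' @param bandwidth Feedback bandwidth, degrees.
#' @return Logical vector, one element per sample: feedback on?
#' @export
feedback_signal <- function(series, bandwidth) {
  stopifnot(inherits(series, "phase_series"))
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive")
  }
  folded_distance(series$relative_phase, series$target_phase) <= bandwidth
}

#' Is coordination feedback shown on this trial?
#'
#' Feedback is given on all training trials except every fifth, which is run
#' without it to prevent dependence on the feedback.
#'
#' @param trial_index Trial number within the session, `>= 1`. Vectorised.
#' @return Logical: feedback present?
#' @export
feedback_schedule <- function(trial_index) {
  if (any(trial_index < 1) || any(trial_index != round(trial_index))) {
    stop("trial_index must be a positive integer")
  }
  trial_index %% 5 != 0
}

#' Knowledge-of-results comment for a trial score
#'
#' Maps the percentage score to the standard post-trial comment. Interval
#' edges are half-open `[lower, upper)` with the top bucket closed at 100.
#'
#' @param ptt_percent Performance score as a percentage, in `[0, 100]`.
#' @return The comment string.
#' @examples
#' kr_comment(60)
#' @export
kr_comment <- function(ptt_percent) {
  if (!is.finite(ptt_percent) || ptt_percent < 0 || ptt_percent > 100) {
    stop("ptt_percent must be in [0, 100]")
  }
  if (ptt_percent < 25) {
    "This is still a little low—keep trying!"
  } else if (ptt_percent < 50) {
    "Definitely improving—keep it up!"
  } else if (ptt_percent < 75) {
    "Doing great—keep it up!"
  } else {
    "This is really great—great job!"
  }
}

#' Initial progression state for a training run
#'
#' @param bandwidth Starting feedback bandwidth, degrees (default 30).
#' @return An object of class `progression_state` tracking the bandwidth,
#'   session count, per-session score history, and stop status.
#' @export
progression_state <- function(bandwidth = 30) {
  if (!bandwidth %in% c(30, 25, 20, 15, 10)) {
    stop("bandwidth must be one of 30, 25, 20, 15, 10")
  }
  structure(list(bandwidth = bandwidth, session_count = 0L,
                 history = list(), bandwidth_history = numeric(),
                 stopped = FALSE, stop_reason = "none"),
            class = "progression_state")
}

#' Apply one training session to the progression state
#'
#' Implements the predefined training criteria. A session's 30 PTT20 scores
#' are appended to the history; if more than 0.5 was achieved in at least
#' 20 of the 30 trials the feedback bandwidth is reduced by 5 degrees for
#' the next session (floor 10). Training stops when the last two sessions
#' were both run at the 10-degree bandwidth with PTT20 above 0.6 in at least
#' 20 trials each, or after 10 sessions.
#'
#' @param state A [progression_state()].
#' @param session_scores Numeric vector of exactly 30 PTT20 values.
#' @param max_sessions Session cap (default 10).
#' @return The updated `progression_state`.
#' @export
progression_update <- function(state, session_scores, max_sessions = 10) {
  stopifnot(inherits(state, "progression_state"))
  if (state$stopped) stop("training already stopped")
  if (length(session_scores) != 30) {
    stop("a training session has exactly 30 trial scores")
  }
  if (any(!is.finite(session_scores)) || any(session_scores < 0) ||
      any(session_scores > 1)) {
    stop("scores must be proportions in [0, 1]")
  }
  ran_at <- state$bandwidth
  state$session_count <- state$session_count + 1L
  state$history[[state$session_count]] <- session_scores
  state$bandwidth_history <- c(state$bandwidth_history, ran_at)
  if (sum(session_scores > 0.5) >= 20) {
    state$bandwidth <- max(state$bandwidth - 5, 10)
  }
  ns <- state$session_count
  if (ns >= 2) {
    last_two_at_10 <- all(state$bandwidth_history[(ns - 1):ns] == 10)
    crit <- vapply(state$history[(ns - 1):ns],
                   function(s) sum(s > 0.6) >= 20, logical(1))
    if (last_two_at_10 && all(crit)) {
      state$stopped <- TRUE
      state$stop_reason <- "criterion_met"
    }
  }
  if (!state$stopped && ns >= max_sessions) {
    state$stopped <- TRUE
    state$stop_reason <- "max_sessions"
  }
  state
}

#' @export
print.progression_state <- function(x, ...) {
  cat(sprintf(
    "<progression_state> session %d, bandwidth %g deg, %s\n",
    x$session_count, x$bandwidth,
    if (x$stopped) paste("stopped:", x$stop_reason) else "running"))
  invisible(x)
}

#' Run the training protocol on a virtual participant
#'
#' Drives a simulated participant through training sessions until the stop
#' rules fire: each session simulates 30 trials at the trained phase with
#' the skill state supplied by `skill_fn`, scores them (PTT20), logs the
#' feedback schedule and knowledge-of-results comments, and updates the
#' progression state.
#'
#' @param skill_fn Function `(session_index) -> skill_state` giving the
#'   participant's skill at each session (the learning trajectory).
#' @param osc An [oscillator_params()] object for the trials.
#' @param bandwidth Starting feedback bandwidth, degrees.
#' @param max_sessions Session cap (default 10).
#' @param seed Optional integer seed for the whole run.
#' @return A list with the final `state` and a per-session list `sessions`,
#'   each holding `bandwidth`, `scores`, `feedback` (per-trial flags) and
#'   `kr` (comments for feedback trials).
#' @export
run_protocol <- function(skill_fn, osc = oscillator_params(),
                         bandwidth = 30, max_sessions = 10, seed = NULL) {
  stopifnot(is.function(skill_fn))
  run <- function() {
    state <- progression_state(bandwidth)
    sessions <- list()
    while (!state$stopped) {
      si <- state$session_count + 1L
      sk <- skill_fn(si)
      stopifnot(inherits(sk, "skill_state"))
      scores <- vapply(seq_len(30), function(j) {
        tr <- simulate_movement_trial(osc, sk, session_index = si,
                                      trial_index = j)
        score_trial(tr)$ptt
      }, numeric(1))
      fb <- feedback_schedule(seq_len(30))
      kr <- ifelse(fb, vapply(scores * 100, kr_comment, character(1)),
                   NA_character_)
      sessions[[si]] <- list(bandwidth = state$bandwidth, scores = scores,
                             feedback = fb, kr = kr)
      state <- progression_update(state, scores, max_sessions)
    }
    list(state = state, sessions = sessions)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
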