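# Transformed 1-up/2-down adaptive staircases for the 2AFC judgement task,
# reversal-based threshold estimation, and position-perturbed displays.

#' Staircase configuration
#'
#' A transformed 1-up/2-down staircase converges on the 70.71%-correct
#' point. The down step is a fixed fraction of the up step (default 54.88%,
#' i.e. 5.488 degrees for a 10-degree up step); the run starts with an
#' initial descent from 30 degrees and stops after 8 reversals.
#'
#' @param initial_difference Starting difference from 90 degrees, degrees.
#' @param step_up Step size up (after an error), degrees.
#' @param down_ratio Down step as a fraction of `step_up`, in `(0, 1)`.
#' @param n_reversal_stop Number of reversals at which the staircase stops.
#' @param side Which side of 90 degrees this staircase probes.
#' @return An object of class `staircase_config` (with the derived
#'   `step_down` included).
#' @export
staircase_config <- function(initial_difference = 30, step_up = 10,
                             down_ratio = 0.5488, n_reversal_stop = 8,
                             side = c("above_90", "below_90")) {
  side <- match.arg(side)
  if (!is.finite(step_up) || step_up <= 0) stop("step_up must be positive")
  if (!is.finite(down_ratio) || down_ratio <= 0 || down_ratio >= 1) {
    stop("down_ratio must be in (0, 1)")
  }
  if (n_reversal_stop < 2) stop("n_reversal_stop must be at least 2")
  if (!is.finite(initial_difference) || initial_difference <= 0) {
    stop("initial_difference must be positive")
  }
  structure(list(initial_difference = initial_difference,
                 step_up = step_up, down_ratio = down_ratio,
                 step_down = step_up * down_ratio,
                 n_reversal_stop = as.integer(n_reversal_stop),
                 side = side),
            class = "staircase_config")
}

#' Initialise a staircase
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state`: the staircase begins in
#'   `initial_descent` mode at the configured starting difference, with no
#'   reversals recorded.
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(config = config,
                 current_difference = config$initial_difference,
                 mode = "initial_descent",
                 consecutive_correct = 0L,
                 reversals = numeric(),
                 last_direction = "none",
                 finished = FALSE,
                 trial_count = 0L),
            class = "staircase_state")
}

#' Advance a staircase by one response
#'
#' During the initial descent every correct response steps the difference
#' down by the down step; the first error steps up by the up step, records
#' the first reversal, and switches to 1-up/2-down mode. Thereafter two
#' consecutive correct responses step down (a reversal if the last step was
#' up) and any error steps up (a reversal if the last step was down).
#' Reversal values are the difference at which the reversing response
#' occurred. The difference is floored at 1 degree; the staircase finishes
#' when the configured reversal count is reached.
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  if (state$finished) stop("staircase already finished")
  cfg <- state$config
  level <- state$current_difference
  state$trial_count <- state$trial_count + 1L
  if (state$mode == "initial_descent") {
    if (correct) {
      state$current_difference <- max(level - cfg$step_down, 1)
      state$last_direction <- "down"
    } else {
      state$reversals <- c(state$reversals, level)
      state$current_difference <- level + cfg$step_up
      state$last_direction <- "up"
      state$mode <- "updown"
    }
  } else {
    if (correct) {
      state$consecutive_correct <- state$consecutive_correct + 1L
      if (state$consecutive_correct >= 2L) {
        if (state$last_direction == "up") {
          state$reversals <- c(state$reversals, level)
        }
        state$current_difference <- max(level - cfg$step_down, 1)
        state$last_direction <- "down"
        state$consecutive_correct <- 0L
      }
    } else {
      state$consecutive_correct <- 0L
      if (state$last_direction == "down") {
        state$reversals <- c(state$reversals, level)
      }
      state$current_difference <- level + cfg$step_up
      state$last_direction <- "up"
    }
  }
  if (length(state$reversals) >= cfg$n_reversal_stop) state$finished <- TRUE
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> %s: %.2f deg, %d reversals, %s\n",
    x$config$side, x$current_difference, length(x$reversals),
    if (x$finished) "finished" else x$mode))
  invisible(x)
}

#' Run one interleaved 2AFC judgement session
#'
#' Runs two independent staircases (one probing differences above 90
#' degrees, one below), interleaved by a seeded uniform-random pick among
#' the unfinished staircases, against a simulated observer. Each trial draws
#' a response at the chosen staircase's current difference; the session ends
#' when both staircases have finished.
#'
#' @param observer An [observer_model()].
#' @param configs List of two [staircase_config()]s, one per side.
#' @param seed Optional integer seed; fixes both the interleaving and the
#'   observer's responses.
#' @return A list of class `judgement_session`: `trials` (data frame with
#'   `trial`, `side`, `difference`, `correct`) and `staircases` (final
#'   states, named by side).
#' @export
run_2afc_session <- function(observer,
                             configs = list(staircase_config(side = "above_90"),
                                            staircase_config(side = "below_90")),
                             seed = NULL) {
  stopifnot(inherits(observer, "observer_model"), length(configs) == 2)
  sides <- vapply(configs, `[[`, "", "side")
  if (length(unique(sides)) != 2) {
    stop("configs must cover both sides of 90 degrees")
  }
  run <- function() {
    states <- lapply(configs, staircase_init)
    names(states) <- sides
    rows <- list()
    k <- 0L
    repeat {
      open <- which(!vapply(states, `[[`, logical(1), "finished"))
      if (length(open) == 0) break
      i <- if (length(open) == 1) open else open[sample.int(2, 1)]
      level <- states[[i]]$current_difference
      correct <- stats::runif(1) < observer_prob(observer, level)
      states[[i]] <- staircase_update(states[[i]], correct)
      k <- k + 1L
      rows[[k]] <- data.frame(trial = k, side = sides[i],
                              difference = level, correct = correct)
    }
    structure(list(trials = do.call(rbind, rows), staircases = states),
              class = "judgement_session")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Estimate the 90-degree discrimination threshold from a session
#'
#' For each staircase, the reversal differences are averaged excluding the
#' first reversal; the session threshold is the mean of the two per-side
#' values.
#'
#' @param session A `judgement_session` from [run_2afc_session()], or a list
#'   of two `staircase_state`s.
#' @return Threshold in degrees (difference from 90).
#' @export
estimate_threshold <- function(session) {
  states <- if (inherits(session, "judgement_session")) {
    session$staircases
  } else {
    session
  }
  if (length(states) != 2) stop("need exactly two staircases")
  per_side <- vapply(states, function(s) {
    stopifnot(inherits(s, "staircase_state"))
    if (!s$finished) stop("both staircases must be finished")
    r <- s$reversals
    if (length(r) < 2) stop("need at least 2 reversals per staircase")
    mean(r[-1])
  }, numeric(1))
  mean(per_side)
}

#' Generate a position-perturbed judgement display
#'
#' Builds a two-dot display at a fixed relative phase in which the top dot's
#' amplitude is redrawn uniformly on `[min_frac * nominal, max_amplitude]`
#' at each of its own half-cycle boundaries (zero crossings, so position and
#' instantaneous phase stay continuous), and the bottom dot's amplitude is
#' set to half the top dot's current amplitude at each of its own
#' boundaries. This destroys relative-position information (where the dots
#' are within their cycles varies randomly) while preserving the mean
#' relative phase between them.
#'
#' @param osc An [oscillator_params()]; `osc$amplitude` is the nominal
#'   (unperturbed) amplitude.
#' @param relative_phase Phase difference between top and bottom dot,
#'   degrees.
#' @param max_amplitude Largest allowed top-dot amplitude, screen units
#'   (the screen-edge constraint). Default 1.5 times nominal.
#' @param seed Optional integer seed for the amplitude draws.
#' @param min_frac Lower bound of the amplitude draw as a fraction of
#'   nominal (the midline-crossing constraint). Setting `min_frac = 1` with
#'   `max_amplitude = osc$amplitude` disables the perturbation.
#' @return A list with `spec` (class `perturbed_display_spec`: per-half-cycle
#'   amplitude sequences for both dots plus display parameters) and `trial`
#'   (a [trial_time_series()]; top dot as the left channel).
#' @export
generate_perturbed_display <- function(osc, relative_phase,
                                       max_amplitude = 1.5 * osc$amplitude,
                                       seed = NULL, min_frac = 0.25) {
  stopifnot(inherits(osc, "oscillator_params"))
  if (!is.finite(max_amplitude) || max_amplitude <= 0) {
    stop("max_amplitude must be positive")
  }
  if (min_frac <= 0 || min_frac * osc$amplitude > max_amplitude) {
    stop("min_frac must be positive and min_frac * nominal <= max_amplitude")
  }
  if (osc$duration * osc$frequency < 1) {
    stop("duration must cover at least two half-cycles")
  }
  run <- function() {
    fs <- osc$sample_rate
    n <- round(osc$duration * fs)
    tt <- (seq_len(n) - 1) / fs
    rho <- relative_phase * pi / 180
    theta_top <- 2 * pi * osc$frequency * tt
    theta_bot <- theta_top - rho
    half <- 1 / (2 * osc$frequency) # half-cycle period, s
    # index of the half-cycle each sample belongs to, per dot
    k_top <- floor(theta_top / pi) + 1
    k_bot <- floor(pmax(theta_bot, 0) / pi) + 1 # bottom may start mid-cycle
    lo <- min_frac * osc$amplitude
    amps_top <- stats::runif(max(k_top), min = lo, max = max_amplitude)
    # bottom amplitude = half the top amplitude in force when the bottom
    # half-cycle starts
    bot_starts <- (seq_len(max(k_bot)) - 1) * half + rho / (2 * pi * osc$frequency)
    top_at <- amps_top[pmin(pmax(floor(bot_starts / half), 0) + 1,
                            length(amps_top))]
    amps_bot <- 0.5 * top_at
    top <- amps_top[k_top] * sin(theta_top)
    bot <- amps_bot[k_bot] * sin(theta_bot)
    spec <- structure(list(half_cycle_amplitudes_top = amps_top,
                           half_cycle_amplitudes_bottom = amps_bot,
                           relative_phase = relative_phase,
                           frequency = osc$frequency,
                           duration = osc$duration),
                      class = "perturbed_display_spec")
    trial <- trial_time_series(time = tt, left_position = top,
                               right_position = bot,
                               target_phase = abs(wrap_180(relative_phase)),
                               sample_rate = fs)
    list(spec = spec, trial = trial)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
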