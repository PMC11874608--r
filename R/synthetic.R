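# Synthetic movement and observer generators.
#
# The movement generator is a stochastic differential equation on the
# relative phase between the two effectors: an HKB-style intrinsic potential
# with attractors at 0 and 180 degrees plus a learned attraction toward the
# trial's target phase, integrated by Euler-Maruyama at the display sample
# rate. The observer is a standard 2AFC Weibull observer with a small lapse
# rate, parameterised directly by its 70.71%-correct difference so that the
# transformed 1-up/2-down convergence point is an analytic test hook.

#' Oscillator parameters for simulated bimanual trials
#'
#' Bundles the display/movement constants used by the trial generator:
#' movement frequency, on-screen amplitude, sample rate and trial duration.
#' Defaults follow the usual task set-up: 1 Hz movements with a 300-pixel
#' amplitude, recorded at 60 Hz for 20 s.
#'
#' @param frequency Movement frequency, cycles/s. Must be positive.
#' @param amplitude Movement amplitude, screen units (pixels). Must be positive.
#' @param sample_rate Sampling rate, samples/s. Must be at least
#'   `4 * frequency`.
#' @param duration Trial duration, seconds. Must be positive.
#' @return An object of class `oscillator_params`.
#' @examples
#' oscillator_params()
#' oscillator_params(duration = 4) # a judgement display
#' @export
oscillator_params <- function(frequency = 1, amplitude = 300,
                              sample_rate = 60, duration = 20) {
  vals <- c(frequency = frequency, amplitude = amplitude,
            sample_rate = sample_rate, duration = duration)
  if (!all(is.finite(vals))) {
    stop("oscillator parameters must be finite numbers")
  }
  if (frequency <= 0) stop("frequency must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (sample_rate < 4 * frequency) {
    stop("sample_rate must be at least 4 times the movement frequency")
  }
  structure(list(frequency = frequency, amplitude = amplitude,
                 sample_rate = sample_rate, duration = duration),
            class = "oscillator_params")
}

#' Skill state of a simulated participant
#'
#' Describes how stably a virtual participant produces a target relative
#' phase. The intrinsic parameters set the depth of the 0 degree
#' (`intrinsic_a`) and 180 degree (`intrinsic_b`) attractors of the
#' coordination dynamic; `coupling_strength` is the learned attraction
#' toward `target_phase` that grows with training; `noise_sd` scales the
#' stochastic perturbation of relative phase.
#'
#' With the default intrinsic parameters and zero coupling the generator
#' reproduces the stylised pre-training facts of this task: 0 degrees is most
#' stable, 180 degrees is stable but less so, and 90 degrees is unstable.
#'
#' @param target_phase Target relative phase, degrees.
#' @param coupling_strength Learned attraction toward `target_phase`,
#'   dimensionless, `>= 0`. Zero means untrained.
#' @param intrinsic_a Depth of the 0-degree attractor, dimensionless, `> 0`.
#' @param intrinsic_b Depth of the 180-degree attractor, dimensionless,
#'   `>= 0`. 180 degrees is an attractor when `intrinsic_b > intrinsic_a / 4`.
#' @param noise_sd Phase diffusion, degrees per sqrt(second), `>= 0`.
#' @return An object of class `skill_state`.
#' @export
skill_state <- function(target_phase = 90, coupling_strength = 0,
                        intrinsic_a = 1, intrinsic_b = 0.75,
                        noise_sd = 35) {
  vals <- c(target_phase, coupling_strength, intrinsic_a, intrinsic_b,
            noise_sd)
  if (!all(is.finite(vals))) stop("skill parameters must be finite numbers")
  if (intrinsic_a <= 0) stop("intrinsic_a must be positive")
  if (intrinsic_b < 0) stop("intrinsic_b must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (coupling_strength < 0) stop("coupling_strength must be non-negative")
  structure(list(target_phase = target_phase,
                 coupling_strength = coupling_strength,
                 intrinsic_a = intrinsic_a, intrinsic_b = intrinsic_b,
                 noise_sd = noise_sd),
            class = "skill_state")
}

#' Construct a trial time series
#'
#' Container for one two-channel position trace plus task metadata. Usually
#' produced by [simulate_movement_trial()] or [read_trials()] rather than
#' called directly.
#'
#' @param time Time grid, seconds; strictly increasing with a constant step.
#' @param left_position,right_position Position traces, screen units.
#' @param target_phase Target relative phase, degrees.
#' @param session_index,trial_index Positive integer indices.
#' @param sample_rate Samples/s; must match the time grid.
#' @return An object of class `trial_time_series`.
#' @export
trial_time_series <- function(time, left_position, right_position,
                              target_phase, session_index = 1L,
                              trial_index = 1L, sample_rate = NULL) {
  n <- length(time)
  if (length(left_position) != n || length(right_position) != n) {
    stop("time, left_position and right_position must have equal length")
  }
  if (n < 2) stop("a trial needs at least two samples")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)) {
    stop("time must be strictly increasing with a constant step")
  }
  if (!all(is.finite(left_position)) || !all(is.finite(right_position))) {
    stop("positions must be finite")
  }
  if (session_index < 1 || trial_index < 1) {
    stop("session_index and trial_index must be >= 1")
  }
  if (is.null(sample_rate)) sample_rate <- 1 / dt[1]
  structure(list(time = time, left_position = left_position,
                 right_position = right_position,
                 target_phase = target_phase,
                 session_index = as.integer(session_index),
                 trial_index = as.integer(trial_index),
                 sample_rate = sample_rate),
            class = "trial_time_series")
}

#' @export
print.trial_time_series <- function(x, ...) {
  cat(sprintf(
    "<trial_time_series> %d samples @ %g Hz, target %g deg (session %d, trial %d)\n",
    length(x$time), x$sample_rate, x$target_phase, x$session_index,
    x$trial_index))
  invisible(x)
}

#' Simulate one bimanual movement trial
#'
#' Generates a two-channel position trace whose relative phase follows a
#' stochastic coordination dynamic. The left channel is `A * sin(w t)`; the
#' right channel is `A * sin(w t + phi(t))` where the relative phase
#' `phi` (degrees) evolves by Euler-Maruyama steps of
#'
#' `dphi = [ -a sin(phi) - 2 b sin(2 phi) + c sin(target - phi) ] * (180/pi) dt
#'          + sqrt(dt) noise_sd epsilon`
#'
#' with `a = intrinsic_a`, `b = intrinsic_b`, `c = coupling_strength` and
#' `epsilon` standard normal. The trial starts on target, `phi(0) =
#' target_phase`.
#'
#' @param osc An [oscillator_params()] object.
#' @param skill A [skill_state()] object.
#' @param seed Optional integer; fixes the noise stream without touching the
#'   caller's RNG state.
#' @param session_index,trial_index Metadata attached to the trial.
#' @return A [trial_time_series()].
#' @examples
#' tr <- simulate_movement_trial(oscillator_params(), skill_state(), seed = 1)
#' score_trial(tr)$ptt
#' @export
simulate_movement_trial <- function(osc, skill, seed = NULL,
                                    session_index = 1L, trial_index = 1L) {
  stopifnot(inherits(osc, "oscillator_params"), inherits(skill, "skill_state"))
  run <- function() {
    fs <- osc$sample_rate
    n <- round(osc$duration * fs)
    dt <- 1 / fs
    tt <- (seq_len(n) - 1) * dt
    deg <- pi / 180
    phi <- numeric(n)
    phi[1] <- skill$target_phase
    eps <- stats::rnorm(n - 1)
    for (i in seq_len(n - 1)) {
      p <- phi[i] * deg
      drift <- (-skill$intrinsic_a * sin(p) -
                  2 * skill$intrinsic_b * sin(2 * p) +
                  skill$coupling_strength *
                    sin(skill$target_phase * deg - p)) / deg
      phi[i + 1] <- phi[i] + dt * drift + sqrt(dt) * skill$noise_sd * eps[i]
    }
    omega <- 2 * pi * osc$frequency
    trial_time_series(time = tt,
                      left_position = osc$amplitude * sin(omega * tt),
                      right_position = osc$amplitude * sin(omega * tt +
                                                             phi * deg),
                      target_phase = skill$target_phase,
                      session_index = session_index,
                      trial_index = trial_index,
                      sample_rate = fs)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default multi-session study design
#'
#' Builds the session/phase/trial-count table of the standard design:
#' a Baseline assessment (5 trials at each of 0, 30, ..., 180 degrees),
#' `n_training` training sessions of 30 trials at the trained phase, then
#' Post-training and Retention assessments identical to Baseline.
#'
#' @param n_training Number of training sessions.
#' @param assessment_trials Trials per phase in assessment sessions.
#' @param training_trials Trials per training session.
#' @param phases Assessment phases, degrees.
#' @param trained_phase The trained phase, degrees.
#' @return A data frame with columns `session_index`, `session`, `type`,
#'   `phase`, `n_trials`, with the trained phase stored as an attribute.
#' @export
default_study_design <- function(n_training = 8, assessment_trials = 5,
                                 training_trials = 30,
                                 phases = seq(0, 180, by = 30),
                                 trained_phase = 90) {
  stopifnot(n_training >= 1, assessment_trials >= 1, training_trials >= 1)
  sessions <- c("Baseline", paste("Training", seq_len(n_training)),
                "Post-training", "Retention")
  rows <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    if (grepl("^Training", s)) {
      rows[[i]] <- data.frame(session_index = i, session = s,
                              type = "training", phase = trained_phase,
                              n_trials = training_trials)
    } else {
      rows[[i]] <- data.frame(session_index = i, session = s,
                              type = "assessment", phase = phases,
                              n_trials = assessment_trials)
    }
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  attr(design, "trained_phase") <- trained_phase
  design
}

#' Build a session-wise skill schedule
#'
#' Convenience constructor for the ground-truth learning trajectory of a
#' virtual participant: coupling toward the trained phase grows across
#' sessions as a saturating exponential,
#' `c(s) = coupling_max * (1 - exp(-rate * (s - 1)))`, while the intrinsic
#' dynamic stays fixed.
#'
#' @param n_sessions Number of sessions covered.
#' @param coupling_max Asymptotic coupling strength.
#' @param rate Per-session growth rate; larger is a faster learner.
#' @param ... Further arguments passed to [skill_state()] (e.g. `noise_sd`).
#' @return A list of [skill_state()] objects, one per session.
#' @export
make_skill_schedule <- function(n_sessions, coupling_max = 8, rate = 0.5,
                                ...) {
  stopifnot(n_sessions >= 1, coupling_max >= 0, rate >= 0)
  lapply(seq_len(n_sessions), function(s) {
    skill_state(coupling_strength = coupling_max * (1 - exp(-rate * (s - 1))),
                ...)
  })
}

#' Simulate a full multi-session study
#'
#' Runs the trial generator over a study design for one or more groups of
#' virtual participants, attaching the generating skill schedule as ground
#' truth for parameter-recovery tests. Within assessment sessions the learned
#' coupling is applied only at the trained phase; untrained phases are
#' produced by the intrinsic dynamic alone (the generator does not model
#' transfer).
#'
#' @param design A design table from [default_study_design()].
#' @param skill_schedule Named list: one entry per group, each a list of
#'   [skill_state()] objects with one element per session in `design`.
#' @param n_per_group Named integer vector of participants per group, in the
#'   same order as `skill_schedule`.
#' @param osc An [oscillator_params()] object used for every trial.
#' @param seed Optional integer seed fixing the whole dataset.
#' @return An object of class `study_dataset`: a list with `participants`
#'   (each holding `id`, `group`, `skill_schedule`, and per-session lists of
#'   trials) and the `design`.
#' @examples
#' des <- default_study_design(n_training = 1, assessment_trials = 1,
#'                             training_trials = 2)
#' sched <- list(YA = make_skill_schedule(4, coupling_max = 6, rate = 1))
#' ds <- simulate_study(des, sched, n_per_group = c(YA = 1), seed = 1)
#' @export
simulate_study <- function(design, skill_schedule,
                           n_per_group = c(YA = 9, OA = 5),
                           osc = oscillator_params(), seed = NULL) {
  if (is.null(design) || nrow(design) == 0) stop("design must be non-empty")
  if (!is.list(skill_schedule) || is.null(names(skill_schedule))) {
    stop("skill_schedule must be a named list of per-group schedules")
  }
  n_sessions <- max(design$session_index)
  for (g in names(skill_schedule)) {
    if (length(skill_schedule[[g]]) < n_sessions) {
      stop(sprintf("schedule for group '%s' covers %d of %d sessions",
                   g, length(skill_schedule[[g]]), n_sessions))
    }
  }
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(skill_schedule))) {
    stop("n_per_group must be named after skill_schedule groups")
  }
  trained <- attr(design, "trained_phase")
  if (is.null(trained)) trained <- 90
  run <- function() {
    participants <- list()
    for (g in names(n_per_group)) {
      for (p in seq_len(n_per_group[[g]])) {
        id <- sprintf("%s%02d", g, p)
        sessions <- list()
        for (si in seq_len(n_sessions)) {
          base <- skill_schedule[[g]][[si]]
          rows <- design[design$session_index == si, , drop = FALSE]
          trials <- list()
          k <- 0L
          for (r in seq_len(nrow(rows))) {
            ph <- rows$phase[r]
            sk <- skill_state(
              target_phase = ph,
              coupling_strength = if (ph == trained)
                base$coupling_strength else 0,
              intrinsic_a = base$intrinsic_a,
              intrinsic_b = base$intrinsic_b,
              noise_sd = base$noise_sd)
            for (j in seq_len(rows$n_trials[r])) {
              k <- k + 1L
              trials[[k]] <- simulate_movement_trial(
                osc, sk, session_index = si, trial_index = k)
            }
          }
          sessions[[rows$session[1]]] <- trials
        }
        participants[[id]] <- list(id = id, group = g,
                                   skill_schedule = skill_schedule[[g]],
                                   sessions = sessions)
      }
    }
    structure(list(participants = participants, design = design,
                   trained_phase = trained),
              class = "study_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.study_dataset <- function(x, ...) {
  groups <- table(vapply(x$participants, `[[`, "", "group"))
  cat(sprintf("<study_dataset> %d participants (%s), %d sessions\n",
              length(x$participants),
              paste(sprintf("%s n=%d", names(groups), groups),
                    collapse = ", "),
              max(x$design$session_index)))
  invisible(x)
}

#' Simulated 2AFC observer
#'
#' A Weibull-family observer for the 90-degree judgement task. The
#' probability of a correct 2AFC response to a comparison display differing
#' from 90 degrees by `delta` is
#' `P(delta) = 0.5 + (0.5 - lapse_rate) * F(delta)` where `F` is a cumulative
#' Weibull rescaled so that `P(threshold_70) = sqrt(0.5) ~ 0.7071` when the
#' lapse rate is zero -- the convergence point of a transformed 1-up/2-down
#' staircase.
#'
#' @param threshold_70 Difference from 90 degrees, in degrees, at which the
#'   observer is 70.71% correct (lapse-free). Must be positive.
#' @param slope Weibull shape parameter, `> 0`. The default 3.5 is the
#'   conventional shape for 2AFC psychometric functions (the QUEST default).
#' @param lapse_rate Probability in `[0, 0.1]` of attention lapses.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(threshold_70, slope = 3.5, lapse_rate = 0.02) {
  if (!is.finite(threshold_70) || threshold_70 <= 0) {
    stop("threshold_70 must be positive")
  }
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (!is.finite(lapse_rate) || lapse_rate < 0 || lapse_rate > 0.1) {
    stop("lapse_rate must be in [0, 0.1]")
  }
  structure(list(threshold_70 = threshold_70, slope = slope,
                 lapse_rate = lapse_rate),
            class = "observer_model")
}

#' Probability of a correct response
#'
#' @param obs An [observer_model()].
#' @param comparison_delta Absolute difference of the comparison phase from
#'   90 degrees, degrees, `>= 0`. Vectorised.
#' @return Probability of a correct 2AFC response.
#' @export
observer_prob <- function(obs, comparison_delta) {
  stopifnot(inherits(obs, "observer_model"))
  if (any(!is.finite(comparison_delta)) || any(comparison_delta < 0)) {
    stop("comparison_delta must be non-negative and finite")
  }
  k <- obs$slope
  # scale chosen so F(threshold_70) = sqrt(2) - 1, hence P = 0.7071 lapse-free
  scale <- obs$threshold_70 / (-log(2 - sqrt(2)))^(1 / k)
  f <- 1 - exp(-(comparison_delta / scale)^k)
  0.5 + (0.5 - obs$lapse_rate) * f
}

#' Draw one 2AFC response from a simulated observer
#'
#' @inheritParams observer_prob
#' @param seed Optional integer seed for the single Bernoulli draw.
#' @return Logical: was the response correct?
#' @export
observer_respond <- function(obs, comparison_delta, seed = NULL) {
  p <- observer_prob(obs, comparison_delta)
  draw <- function() stats::runif(length(p)) < p
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Relative position information variable
#'
#' The normalized relative-position variable `cos(theta) = x / sqrt(v^2 + x^2)`
#' for a unit-amplitude, unit-angular-frequency oscillator: 1 at peak
#' amplitude, 0 at the midline crossing. This is the perceptual variable
#' hypothesised to support perception of 90 degrees after learning.
#'
#' @param x Normalized position.
#' @param v Normalized velocity.
#' @return Values in `[-1, 1]`. Vectorised.
#' @examples
#' relative_position_variable(0.6, 0.8) # 0.6
#' @export
relative_position_variable <- function(x, v) {
  if (length(x) != length(v)) stop("x and v must have equal length")
  if (any(x == 0 & v == 0)) {
    stop("phase undefined where position and velocity are both zero")
  }
  x / sqrt(v^2 + x^2)
}
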