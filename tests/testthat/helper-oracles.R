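# Shared fixtures and independent oracles, built in code at test time.

# a clean two-channel sinusoid trial with constant phase offset (degrees)
make_sine_trial <- function(offset_deg, duration = 20, fs = 60, A = 300,
                            f = 1, target = NULL) {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  if (is.null(target)) target <- abs(offset_deg)
  trial_time_series(time = tt,
                    left_position = A * sin(2 * pi * f * tt),
                    right_position = A * sin(2 * pi * f * tt -
                                               offset_deg * pi / 180),
                    target_phase = target, sample_rate = fs)
}

# naive per-sample counting oracle for proportion of time on target
ptt_count_oracle <- function(folded_phase, target, bandwidth) {
  hits <- 0L
  for (s in folded_phase) {
    d <- min(abs(s - target), s + target, 360 - s - target)
    if (d <= bandwidth) hits <- hits + 1L
  }
  hits / length(folded_phase)
}

# brute-force replay of a 1-up/2-down staircase: tracks the level
# trajectory and detects reversals as direction changes of the steps
staircase_replay_oracle <- function(responses, cfg) {
  level <- cfg$initial_difference
  levels <- numeric()
  last_dir <- 0L
  descent <- TRUE
  cc <- 0L
  revs <- numeric()
  for (r in responses) {
    if (length(revs) >= cfg$n_reversal_stop) break
    levels <- c(levels, level)
    step <- 0
    if (descent) {
      if (r) {
        step <- -cfg$step_down
      } else {
        step <- cfg$step_up
        descent <- FALSE
      }
    } else if (r) {
      cc <- cc + 1L
      if (cc == 2L) {
        step <- -cfg$step_down
        cc <- 0L
      }
    } else {
      cc <- 0L
      step <- cfg$step_up
    }
    if (step != 0) {
      d <- if (step > 0) 1L else -1L
      if ((last_dir != 0L && d != last_dir) || (last_dir == 0L && d > 0L)) {
        revs <- c(revs, level)
      }
      last_dir <- d
      level <- max(level + step, 1)
    }
  }
  list(levels = levels, reversals = revs)
}

# drift-balance stationary point of a 1-up/2-down rule: the proportion
# correct p* at which expected movement is zero, (1 - p*^2) / p*^2 = ratio
updown_stationary_p <- function(down_up_ratio) sqrt(1 / (1 + down_up_ratio))

# difference level at which a lapse-free observer responds correctly with
# probability p (inverse of the psychometric function)
observer_quantile <- function(obs, p) {
  stopifnot(obs$lapse_rate == 0)
  scale <- obs$threshold_70 / (-log(2 - sqrt(2)))^(1 / obs$slope)
  scale * (-log(1 - (2 * p - 1)))^(1 / obs$slope)
}
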