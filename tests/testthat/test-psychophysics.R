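test_that("staircase initialisation matches the task defaults", {
  cfg <- staircase_config()
  expect_equal(cfg$initial_difference, 30)
  expect_equal(cfg$step_up, 10)
  expect_equal(cfg$step_down, 5.488) # 54.88% of the up step
  st <- staircase_init(cfg)
  expect_equal(st$current_difference, 30)
  expect_identical(st$mode, "initial_descent")
  expect_length(st$reversals, 0)
  expect_false(st$finished)
  expect_error(staircase_config(down_ratio = 1.2), "down_ratio")
  expect_error(staircase_config(n_reversal_stop = 1), "n_reversal_stop")
})

test_that("staircase stepping follows the transformed 1-up/2-down rules", {
  cfg <- staircase_config()
  st <- staircase_init(cfg)
  # initial descent: correct steps down by the down step
  st <- staircase_update(st, TRUE)
  expect_equal(st$current_difference, 30 - 5.488)
  expect_identical(st$mode, "initial_descent")
  # first error: up step, first reversal, switch to up/down mode
  lvl <- st$current_difference
  st <- staircase_update(st, FALSE)
  expect_equal(st$current_difference, lvl + 10)
  expect_identical(st$mode, "updown")
  expect_equal(st$reversals, lvl)
  # up/down mode: one correct does nothing, the second steps down
  lvl <- st$current_difference
  st <- staircase_update(st, TRUE)
  expect_equal(st$current_difference, lvl)
  st <- staircase_update(st, TRUE)
  expect_equal(st$current_difference, lvl - 5.488)
  # that down-step after an up-step is a reversal
  expect_length(st$reversals, 2)
  expect_equal(st$reversals[2], lvl)
})

test_that("the difference never drops below the 1-degree floor", {
  cfg <- staircase_config(initial_difference = 2)
  st <- staircase_init(cfg)
  for (i in 1:6) st <- staircase_update(st, TRUE)
  expect_gte(st$current_difference, 1)
})

test_that("reversal bookkeeping matches a brute-force replay oracle", {
  set.seed(77)
  cfg <- staircase_config()
  for (rep in 1:30) {
    responses <- runif(200) < 0.72
    st <- staircase_init(cfg)
    levels <- numeric()
    for (r in responses) {
      if (st$finished) break
      levels <- c(levels, st$current_difference)
      st <- staircase_update(st, r)
    }
    oracle <- staircase_replay_oracle(responses, cfg)
    expect_equal(levels, oracle$levels)
    expect_equal(st$reversals, oracle$reversals)
  }
})

test_that("interleaved sessions are deterministic and stop on reversals", {
  obs <- observer_model(15, lapse_rate = 0)
  a <- run_2afc_session(obs, seed = 101)
  b <- run_2afc_session(obs, seed = 101)
  expect_identical(a$trials, b$trials)
  for (st in a$staircases) {
    expect_true(st$finished)
    expect_length(st$reversals, 8)
  }
  # both sides appear in the log
  expect_setequal(unique(a$trials$side), c("above_90", "below_90"))
  expect_error(staircase_update(a$staircases[[1]], TRUE), "finished")
})

test_that("threshold estimation averages reversals excluding the first", {
  mk_state <- function(revs) {
    st <- staircase_init(staircase_config())
    st$reversals <- revs
    st$finished <- TRUE
    st
  }
  revs <- c(30, 20, 25, 15, 20, 10, 15, 5)
  both <- list(mk_state(revs), mk_state(revs))
  expect_equal(estimate_threshold(both), mean(revs[-1]))
  expect_equal(estimate_threshold(both), 15.71, tolerance = 0.005)
  # mean of the two per-side means
  ab <- list(mk_state(rep(10, 8)), mk_state(rep(20, 8)))
  expect_equal(estimate_threshold(ab), 15)
  # unfinished or reversal-poor staircases are rejected
  expect_error(estimate_threshold(list(staircase_init(staircase_config()),
                                       mk_state(revs))), "finished")
  expect_error(estimate_threshold(list(mk_state(5), mk_state(revs))),
               "2 reversals")
})

test_that("sessions converge on the drift-balance point of the rule", {
  # a 1-up/2-down staircase with down/up ratio r is stationary where
  # (1 - p^2) / p^2 = r; for r = 0.5488 that is the 80.35%-correct level
  obs <- observer_model(15, lapse_rate = 0)
  p_star <- updown_stationary_p(0.5488)
  level_star <- observer_quantile(obs, p_star)
  est <- vapply(1:100, function(i) {
    estimate_threshold(run_2afc_session(obs, seed = 7000 + i))
  }, numeric(1))
  expect_lt(abs(mean(est) - level_star), 2)
})

test_that("position perturbation scrambles amplitude but not relative phase", {
  osc <- oscillator_params(duration = 4)
  for (i in 1:12) {
    d <- generate_perturbed_display(osc, 90, seed = 400 + i)
    spec <- d$spec
    # bottom amplitudes are half of concurrent top amplitudes
    expect_true(all(spec$half_cycle_amplitudes_bottom %in%
                      (0.5 * spec$half_cycle_amplitudes_top)))
    # the amplitude sequence really varies
    expect_gt(var(spec$half_cycle_amplitudes_top), 0)
    # constraints: midline crossing and screen bound
    expect_true(all(spec$half_cycle_amplitudes_top > 0))
    expect_true(all(spec$half_cycle_amplitudes_top <= 1.5 * osc$amplitude))
    # the scoring pipeline still reads ~90 degrees
    lt <- continuous_phase(preprocess_trajectory(d$trial$left_position, 60))
    rt <- continuous_phase(preprocess_trajectory(d$trial$right_position, 60))
    s <- relative_phase_series(lt, rt, 90)
    expect_lt(abs(mean(s$relative_phase) - 90), 3)
  }
})

test_that("disabling the amplitude draw reproduces the unperturbed display", {
  osc <- oscillator_params(duration = 4)
  d <- generate_perturbed_display(osc, 90, max_amplitude = osc$amplitude,
                                  min_frac = 1, seed = 1)
  tt <- d$trial$time
  expect_equal(d$trial$left_position, osc$amplitude * sin(2 * pi * tt),
               tolerance = 1e-9)
  expect_equal(d$trial$right_position,
               0.5 * osc$amplitude * sin(2 * pi * tt - pi / 2),
               tolerance = 1e-9)
  expect_error(generate_perturbed_display(osc, 90, max_amplitude = -1),
               "max_amplitude")
})
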