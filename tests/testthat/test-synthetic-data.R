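test_that("parameter constructors reject invalid inputs", {
  expect_error(oscillator_params(frequency = 0), "frequency")
  expect_error(oscillator_params(frequency = NA_real_), "finite")
  expect_error(oscillator_params(sample_rate = 3, frequency = 1), "4 times")
  expect_error(skill_state(intrinsic_a = 0), "intrinsic_a")
  expect_error(skill_state(noise_sd = -1), "noise_sd")
  expect_error(skill_state(coupling_strength = -0.1), "coupling_strength")
  expect_error(observer_model(-5), "threshold_70")
  expect_error(observer_model(15, lapse_rate = 0.5), "lapse_rate")
})

test_that("noiseless dynamics settle on their fixed points", {
  osc <- oscillator_params()
  # strong learned coupling holds the trial on target: perfect score
  tr <- simulate_movement_trial(
    osc, skill_state(target_phase = 90, coupling_strength = 25,
                     noise_sd = 0), seed = 1)
  expect_equal(score_trial(tr)$ptt, 1.0)
  # with a deep-enough 180-degree attractor, anti-phase is self-sustaining
  tr180 <- simulate_movement_trial(
    osc, skill_state(target_phase = 180, coupling_strength = 0,
                     intrinsic_b = 0.75, noise_sd = 0), seed = 1)
  expect_equal(score_trial(tr180)$ptt, 1.0)
})

test_that("a fixed seed reproduces the trial bit for bit", {
  osc <- oscillator_params(duration = 5)
  sk <- skill_state()
  a <- simulate_movement_trial(osc, sk, seed = 42)
  b <- simulate_movement_trial(osc, sk, seed = 42)
  expect_identical(a, b)
  c <- simulate_movement_trial(osc, sk, seed = 43)
  expect_false(identical(a$right_position, c$right_position))
})

test_that("simulated studies follow the design table", {
  des <- default_study_design(n_training = 1)
  sched <- list(YA = make_skill_schedule(4, coupling_max = 6, rate = 1))
  ds <- simulate_study(des, sched, n_per_group = c(YA = 1),
                       osc = oscillator_params(duration = 2), seed = 7)
  p <- ds$participants[[1]]
  expect_identical(names(p$sessions),
                   c("Baseline", "Training 1", "Post-training", "Retention"))
  # Baseline: 5 trials at each of 7 phases
  base_phases <- vapply(p$sessions$Baseline, `[[`, numeric(1), "target_phase")
  expect_identical(as.vector(table(base_phases)), rep(5L, 7))
  expect_setequal(unique(base_phases), seq(0, 180, by = 30))
  # training: 30 trials, all at 90
  train_phases <- vapply(p$sessions$`Training 1`, `[[`, numeric(1),
                         "target_phase")
  expect_length(train_phases, 30)
  expect_true(all(train_phases == 90))
  # ground truth retained
  expect_s3_class(p$skill_schedule[[1]], "skill_state")
  # determinism across runs
  ds2 <- simulate_study(des, sched, n_per_group = c(YA = 1),
                        osc = oscillator_params(duration = 2), seed = 7)
  expect_identical(ds$participants[[1]]$sessions$Baseline[[1]],
                   ds2$participants[[1]]$sessions$Baseline[[1]])
})

test_that("degenerate study inputs are rejected", {
  sched <- list(YA = make_skill_schedule(4))
  expect_error(simulate_study(NULL, sched), "non-empty")
  des <- default_study_design(n_training = 1)
  expect_error(simulate_study(des, list(YA = make_skill_schedule(2)),
                              n_per_group = c(YA = 1)),
               "covers 2 of 4")
  expect_error(simulate_study(des, unname(sched), n_per_group = c(YA = 1)),
               "named")
})

test_that("observer probabilities hit the analytic anchors", {
  obs <- observer_model(threshold_70 = 15, lapse_rate = 0)
  expect_equal(observer_prob(obs, 0), 0.5)
  expect_equal(observer_prob(obs, 15), sqrt(0.5), tolerance = 1e-12)
  expect_equal(observer_prob(obs, 1e6), 1, tolerance = 1e-9)
  # monotone non-decreasing in the difference
  grid <- observer_prob(obs, seq(0, 90, by = 0.5))
  expect_true(all(diff(grid) >= 0))
  # lapses keep chance performance at zero difference
  obs_l <- observer_model(15, lapse_rate = 0.05)
  expect_equal(observer_prob(obs_l, 0), 0.5)
  expect_lt(observer_prob(obs_l, 1e6), 1)
  # seeded responses are reproducible
  expect_identical(observer_respond(obs, 10, seed = 5),
                   observer_respond(obs, 10, seed = 5))
})

test_that("relative position variable matches hand values and the cosine", {
  expect_equal(relative_position_variable(1, 0), 1.0)
  expect_equal(relative_position_variable(0, 1), 0.0)
  expect_equal(relative_position_variable(0.6, 0.8), 0.6)
  expect_error(relative_position_variable(0, 0), "undefined")
  # equals cos(theta) for a unit-amplitude unit-frequency oscillator
  theta <- seq(0, 4 * pi, length.out = 500)
  x <- cos(theta)
  v <- -sin(theta)
  keep <- !(x == 0 & v == 0)
  expect_equal(relative_position_variable(x[keep], v[keep]), cos(theta)[keep],
               tolerance = 1e-9)
})

test_that("intrinsic dynamic reproduces the stability ordering 0 > 180 > 90", {
  osc <- oscillator_params()
  mean_ptt <- function(phase, n = 30) {
    mean(vapply(seq_len(n), function(i) {
      tr <- simulate_movement_trial(
        osc, skill_state(target_phase = phase, coupling_strength = 0),
        seed = 5000 + phase * 101 + i)
      score_trial(tr)$ptt
    }, numeric(1)))
  }
  m0 <- mean_ptt(0)
  m180 <- mean_ptt(180)
  m90 <- mean_ptt(90)
  expect_gt(m0, m180)
  expect_gt(m180, m90)
})

test_that("performance at 90 degrees is monotone in coupling strength", {
  osc <- oscillator_params()
  mean_ptt <- function(coupling, n = 20) {
    mean(vapply(seq_len(n), function(i) {
      tr <- simulate_movement_trial(
        osc, skill_state(target_phase = 90, coupling_strength = coupling),
        seed = 9000 + round(coupling * 37) + i)
      score_trial(tr)$ptt
    }, numeric(1)))
  }
  m <- vapply(c(0, 2, 5, 10), mean_ptt, numeric(1))
  expect_true(all(diff(m) > -0.01)) # non-decreasing up to sampling noise
  expect_gt(m[4], m[1] + 0.3) # and substantially learnable
})
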