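test_that("simulated channel trials obey the integrator ground truth exactly at zero noise", {
  spec0 <- cohort_spec(k_true = 1, a_true = 0, move_profile = "triangular",
                       amp_sd = 0, hold_sd = 0, sensor_sd = 0, seed = 1)
  sim <- simulate_channel_trial(spec0, move_amplitude = 3)
  ws <- window_preset("human_force")
  smp <- hold_change(sim$trial, "force_x", ws)
  # triangle area: peak * duration / 2
  expect_equal(smp$m, 3 * spec0$move_duration / 2, tolerance = 1e-9)
  expect_equal(smp$dh, smp$m, tolerance = 1e-9)

  # k = 0: hold force is the offset regardless of the move profile
  specA <- cohort_spec(k_true = 0, a_true = 0.7, hold_sd = 0, sensor_sd = 0, seed = 1)
  simA <- simulate_channel_trial(specA, move_amplitude = 5)
  expect_equal(hold_change(simA$trial, "force_x", ws)$dh, 0.7, tolerance = 1e-9)

  # biphasic burst integrates to zero, so the hold force equals the offset
  specB <- cohort_spec(move_profile = "biphasic", a_true = 0.2, hold_sd = 0,
                       sensor_sd = 0, seed = 1)
  simB <- simulate_channel_trial(specB, move_amplitude = 4)
  sB <- hold_change(simB$trial, "force_x", ws)
  expect_lt(abs(sB$m), 1e-9)
  expect_equal(sB$dh, 0.2, tolerance = 1e-9)
})

test_that("identical cohort specs yield bit-identical cohorts", {
  sp <- cohort_spec(n_trials = 25, seed = 77)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_spec(n_trials = 25, seed = 78))
  expect_false(identical(c1$samples$dh, c3$samples$dh))
})

test_that("gain-recovery error grows monotonically with hold-noise level", {
  rmse_at <- function(noise_mult) {
    errs <- vapply(1:30, function(s) {
      sp <- cohort_spec(n_trials = 60, hold_sd = 0.3 * noise_mult, seed = s)
      fit <- suppressWarnings(fit_integration(simulate_cohort(sp)$samples))
      fit$k - 1
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  rmses <- vapply(c(0, 0.5, 1, 2), rmse_at, numeric(1))
  expect_true(all(diff(rmses) > 0))
})

test_that("the trial-to-trial learner follows its closed-form recursions", {
  sched <- build_schedule("healthy_curl")

  # no error sensitivity: state stays at zero, hold forces at the offset
  spB0 <- cohort_spec(error_sensitivity_B = 0, a_true = 0.1, amp_sd = 0,
                      hold_sd = 0, sensor_sd = 0, seed = 3)
  simB0 <- simulate_adaptation_experiment(spB0, sched)
  expect_true(all(simB0$states$state == 0))
  expect_equal(simB0$channel_samples$dh,
               rep(0.1, nrow(simB0$channel_samples)), tolerance = 1e-9)

  # full retention and sensitivity: state tracks the field after one trial
  spAB <- cohort_spec(retention_A = 1, error_sensitivity_B = 1, amp_sd = 0,
                      hold_sd = 0, sensor_sd = 0, seed = 3)
  simAB <- simulate_adaptation_experiment(spAB, sched)
  nonchan <- which(!sched$channel)
  # state on each trial equals the previous non-channel trial's field magnitude
  prev_b <- vapply(seq_len(nrow(sched)), function(i) {
    j <- nonchan[nonchan < i]
    if (length(j) == 0) 0 else sched$b[max(j)]
  }, numeric(1))
  expect_equal(simAB$states$state, prev_b, tolerance = 1e-12)

  # channel-trial samples lie exactly on dh = k m at zero noise
  fit <- suppressWarnings(fit_integration(simAB$channel_samples))
  expect_equal(fit$k, 1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("adaptation experiments at default noise still recover the gain", {
  sp <- cohort_spec(seed = 11)
  sim <- simulate_adaptation_experiment(sp, build_schedule("healthy_curl"))
  fit <- fit_integration(sim$channel_samples)
  expect_lt(abs(fit$k - 1), 0.2)
  expect_gt(fit$r_squared, 0.3)

  # gain adaptation switched on drives the gain downward during ramp
  spg <- cohort_spec(gain_learning_rate = 0.02, seed = 11)
  simg <- simulate_adaptation_experiment(spg, build_schedule("healthy_curl"))
  expect_lt(min(simg$states$gain), 1)
  expect_true(all(diff(simg$states$gain) <= 1e-12))
})

test_that("directionally tuned EMG cohorts reproduce the pooled integrator relation", {
  sp0 <- cohort_spec(k_true = 0.8, amp_mean = 0.6, amp_sd = 0, hold_sd = 0,
                     sensor_sd = 0, seed = 5)
  emg <- simulate_emg_cohort(sp0, n_muscles = 4, trials_per_direction = 2)
  fit <- suppressWarnings(fit_integration(emg$samples))
  expect_equal(fit$k, 0.8, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # movement orthogonal to the preferred direction: no burst, no hold change
  orth <- emg$samples[abs(emg$truth$m_true) < 1e-9, ]
  expect_true(all(abs(orth$dh) < 1e-9))

  # muscles without hold modulation degrade their own fits, not the others'
  spn <- cohort_spec(k_true = 1, amp_mean = 0.6, amp_sd = 0.1, hold_sd = 0.05,
                     sensor_sd = 0.01, seed = 6)
  emg2 <- simulate_emg_cohort(spn, n_muscles = 5, trials_per_direction = 4,
                              non_integrating = 5)
  emg2$samples$muscle <- emg2$truth$muscle
  per <- cross_predictor_regressions(emg2$samples, "own")$per_muscle
  expect_lt(per$r_squared[per$muscle == "m5"], 0.3)
  expect_true(all(per$r_squared[per$muscle != "m5"] > 0.7))
})

test_that("probe sessions embed the field geometry they were generated from", {
  # null on the probe line: along-probe force crosses zero at that distance
  mod <- postural_field_model(1.5, 0, -2, 0, -2)
  ses <- simulate_probe_session(mod, directions = 0, sensor_sd = 0)
  s0 <- ses[order(ses$displacement), ]
  cross <- s0$displacement[which(diff(sign(s0$force_along)) != 0)[1]]
  expect_equal(cross, 1.5, tolerance = 0.01)

  # full 12-ray session: generate-then-fit recovers the model
  mod2 <- postural_field_model(-0.4, 0.6, -1.8, 0.4, -3)
  ses2 <- simulate_probe_session(mod2, sensor_sd = 0)
  fit2 <- fit_spring_model(ses2, seed = 2)
  expect_lt(max(abs(fit2$null - mod2$null)), 1e-5)

  # post-adaptation scenario: null shifted ~1 cm along the 0 deg probe,
  # recovered by the bootstrap intercept estimator on multi-subject traces
  shift <- postural_field_model(1, 0, -2, 0, -2)
  traces <- do.call(rbind, lapply(1:8, function(s) {
    ss <- simulate_probe_session(shift, directions = 0, sensor_sd = 0.05,
                                 subject = s, seed = 100 + s,
                                 spec_for = function(dir) probe_preset("4cm", dir))
    data.frame(subject = s, displacement = ss$displacement, force = ss$force_along)
  }))
  np <- estimate_null_point(traces, reps = 200, seed = 4)
  expect_equal(np$intercept, 1, tolerance = 0.1)
  expect_true(np$ci[1] <= 1.05 && np$ci[2] >= 0.95)
})
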