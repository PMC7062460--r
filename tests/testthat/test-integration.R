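test_that("move integral matches analytic areas and vanishes for balanced bursts", {
  dt <- 0.002
  t <- seq(0, 2, by = dt)

  # integrand identically zero
  expect_equal(move_integral(rep(0.4, length(t)), t, 0.4, 0.2, 1.5), 0)

  # triangular burst of peak P on [t0, T]: area P (T - t0) / 2
  t0 <- 0.5; T1 <- 1.1; P <- 2.4
  s <- (t - t0) / (T1 - t0)
  u <- 0.1 + ifelse(s > 0 & s < 1, P * (1 - abs(2 * s - 1)), 0)
  got <- move_integral(u, t, 0.1, t0, T1)
  expect_equal(got, P * (T1 - t0) / 2, tolerance = P * dt)

  # antisymmetric biphasic burst: lobes cancel (the zero-integral mechanism)
  ub <- 0.1 + ifelse(s > 0 & s < 1, sin(2 * pi * s), 0)
  expect_lt(abs(move_integral(ub, t, 0.1, t0, T1)), 1e-9)

  expect_error(move_integral(u, t, 0.1, -0.5, 1), "outside trace")
  expect_error(move_integral(u, t, 0.1, 1.5, 0.5), "t0 must precede")
})

test_that("hold_change measures hold levels, flags slow trials, recovers known steps", {
  ws <- window_preset("human_force")

  flat <- ts_trial(seq(-1, 2, by = 0.005),
                   list(force_x = rep(0.7, 601)), onset = 0, offset = 0.5)
  s0 <- hold_change(flat, "force_x", ws)
  expect_equal(s0$dh, 0)
  expect_equal(s0$m, 0)

  # constructed hold step of known size
  tr <- step_trial(hold1 = 0.3, dh = 0.45, burst_peak = 2)
  s1 <- hold_change(tr, "force_x", ws)
  expect_equal(s1$hold1, 0.3, tolerance = 1e-12)
  expect_equal(s1$dh, 0.45, tolerance = 1e-12)
  expect_equal(s1$m, 2 * 0.5 / 2, tolerance = 1e-9)  # sin^2 burst area = P dur / 2
  expect_false(s1$excluded)

  # 0.9 s movement exceeds the 850 ms monkey-reach cutoff
  slow <- step_trial(onset = 0, offset = 0.9, t_range = c(-1, 2.5))
  s2 <- hold_change(slow, "force_x", window_preset("monkey_reach_out"))
  expect_true(s2$excluded)
  expect_equal(s2$duration, 0.9)
})

test_that("integration fit is exact on lines, affine-equivariant, and its CI is calibrated", {
  samples <- line_samples(n = 30, k = 0.5, a = 0.1)
  fit <- suppressWarnings(fit_integration(samples))
  expect_equal(fit$k, 0.5, tolerance = 1e-12)
  expect_equal(fit$a, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # scaling dh by c scales k and a by c; scaling m by c scales k by 1/c
  set.seed(7)
  noisy <- data.frame(m = runif(50), dh = runif(50))
  f0 <- fit_integration(noisy)
  f_dh <- fit_integration(transform(noisy, dh = 3 * dh))
  expect_equal(f_dh$k, 3 * f0$k)
  expect_equal(f_dh$a, 3 * f0$a)
  f_m <- fit_integration(transform(noisy, m = 4 * m))
  expect_equal(f_m$k, f0$k / 4)
  expect_equal(f_m$a, f0$a)

  # Monte-Carlo calibration: true slope inside the 95% CI in >= 93% of seeds
  hits <- vapply(1:500, function(s) {
    set.seed(s)
    m <- rnorm(200)
    d <- data.frame(m = m, dh = 1.0 * m + rnorm(200, 0, 0.4))
    ci <- fit_integration(d)$ci_k
    ci[1] <= 1 && 1 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)

  expect_error(fit_integration(data.frame(m = rep(1, 5), dh = 1:5)),
               "degenerate predictor")
  expect_error(fit_integration(data.frame(m = 1:2, dh = 1:2)), "at least 3")

  # excluded rows are dropped from the fit
  sx <- rbind(samples, data.frame(m = 0, dh = 99, hold1 = 0, hold2 = 99))
  sx$excluded <- c(rep(FALSE, 30), TRUE)
  expect_equal(suppressWarnings(fit_integration(sx))$k, 0.5, tolerance = 1e-12)
})

test_that("move/hold decomposition inverts its own forward model", {
  t <- seq(0, 2, by = 0.005)

  # u constant at hold1: pure hold
  d0 <- decompose_move_hold(rep(0.4, length(t)), t, 0.4, 1.5)
  expect_equal(max(abs(d0$move)), 0)
  expect_equal(d0$hold, rep(0.4, length(t)))

  # k = 0: everything above hold1 is move
  u <- 0.4 + bell_speed(t, 0.5, 1, 1)
  dk0 <- decompose_move_hold(u, t, 0.4, 0)
  expect_equal(dk0$move, u - 0.4)
  expect_equal(dk0$hold, rep(0.4, length(t)))

  # forward-construct u from a known m* (k = 1), then invert
  mstar <- bell_speed(t, 0.3, 0.9, 2)
  integ <- cumsum(c(0, diff(t) / 2 * (mstar[-1] + mstar[-length(t)])))
  u2 <- mstar + 0.25 + 1 * integ
  d2 <- decompose_move_hold(u2, t, 0.25, 1)
  expect_lt(max(abs(d2$move - mstar)), 1e-6)

  # end-of-trace consistency: once m has decayed, h(T) - hold1 = k * integral(m)
  expect_equal(d2$hold[length(t)] - 0.25, 1 * integ[length(t)], tolerance = 1e-6)
})

test_that("extremum predictor follows the max-or-min rule", {
  t <- seq(0, 1, by = 0.001)
  pos <- ifelse(t > 0.2 & t < 0.6, 3 * sin(pi * (t - 0.2) / 0.4), 0)
  expect_equal(extremum_predictor(0.1 + pos, t, 0.1, 0, 1), 3, tolerance = 1e-6)
  expect_equal(extremum_predictor(0.1 - pos, t, 0.1, 0, 1), -3, tolerance = 1e-6)

  # net-positive biphasic: report the positive lobe peak
  biph <- ifelse(t > 0.2 & t < 0.6, 2 * sin(2 * pi * (t - 0.2) / 0.4), 0) +
    ifelse(t > 0.2 & t < 0.6, 0.5, 0)
  expect_equal(extremum_predictor(biph, t, 0, 0, 1), max(biph), tolerance = 1e-6)
})

test_that("hold1 restriction retains the normal-CDF fraction and reports variance drop", {
  # all-equal hold1: nothing to restrict
  same <- data.frame(hold1 = rep(2, 20), m = rnorm(20), dh = rnorm(20))
  r0 <- restricted_hold1_filter(same)
  expect_equal(nrow(r0$samples), 20)
  expect_equal(r0$variance_reduction, 0)

  # standard-normal hold1: retained fraction ~ 2 Phi(1) - 1 = 0.6827
  set.seed(42)
  big <- data.frame(hold1 = rnorm(10000), m = rnorm(10000), dh = rnorm(10000))
  r1 <- restricted_hold1_filter(big)
  expect_equal(r1$retained_fraction, 2 * pnorm(1) - 1, tolerance = 0.01)
  expect_gt(r1$variance_reduction, 0.5)

  # correlated structure: filtering hold1 barely moves the m-dh correlation
  set.seed(43)
  m <- rnorm(5000); h1 <- rnorm(5000, 0, 0.5)
  d <- data.frame(hold1 = h1, m = m, dh = m + rnorm(5000, 0, 1) - 0.2 * h1)
  r2 <- restricted_hold1_filter(d)
  expect_lt(abs(r2$r2_after - r2$r2_before), 0.07)

  expect_error(restricted_hold1_filter(same[1:5, ]), ">= 10 samples")
})

test_that("cross-predictor regressions separate the hypothesis from its rivals", {
  # own-mode on exact lines: R2 = 1 for every muscle
  ex <- do.call(rbind, lapply(c("a", "b", "c"), function(mu) {
    d <- line_samples(n = 20, k = 1, a = 0, seed = match(mu, letters))
    d$muscle <- mu; d$trial <- 1:20; d
  }))
  own <- cross_predictor_regressions(ex, "own")
  expect_equal(own$mean_r2, 1, tolerance = 1e-12)

  # other-mode with independent move noise across muscles: mean R2 near zero
  set.seed(9)
  ind <- do.call(rbind, lapply(c("a", "b", "c"), function(mu) {
    m <- rnorm(500)
    data.frame(muscle = mu, trial = 1:500, m = m, dh = m + rnorm(500, 0, 0.3),
               hold1 = 0, hold2 = 0)
  }))
  oth <- cross_predictor_regressions(ind, "other")
  expect_lt(oth$mean_r2, 0.02)

  expect_error(cross_predictor_regressions(ex, "position"), "position_h2")
})

test_that("confidence ellipse matches the chi-squared construction", {
  # points with exactly known sample covariance diag(4, 1)
  a <- sqrt(6); b <- sqrt(1.5)
  pts <- rbind(c(a, 0), c(-a, 0), c(0, b), c(0, -b))
  e <- confidence_ellipse(pts, 0.95)
  expect_equal(unname(e$center), c(0, 0))
  expect_equal(unname(e$axes), sqrt(c(4, 1) * qchisq(0.95, 2)), tolerance = 1e-12)
  expect_equal(e$angle, 0)

  # isotropic cloud: axes equal within sampling error at sqrt(5.991)
  set.seed(3)
  cl <- cbind(rnorm(20000), rnorm(20000))
  ei <- confidence_ellipse(cl)
  expect_equal(unname(ei$axes), rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)

  expect_error(confidence_ellipse(cbind(1:10, 2 * (1:10))), "singular")
  expect_error(confidence_ellipse(pts[1:2, ]), ">= 3 points")
})
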