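test_that("spring force is the exact linear map", {
  m <- postural_field_model(0, 0, 1, 0, 1)
  expect_equal(spring_force(m, c(0, 0)), c(0, 0))
  expect_equal(spring_force(m, c(1, 0)), c(1, 0))

  m2 <- postural_field_model(0, 0, 2, 1, 3)
  expect_equal(spring_force(m2, c(1, -1)), c(1, -2))  # hand matrix product

  # linearity and translation: F(p) - F(null) = K (p - null)
  m3 <- postural_field_model(0.5, -0.2, -1.2, 0.4, -2)
  p1 <- c(1, 1); p2 <- c(-0.5, 2)
  expect_equal(spring_force(m3, p1 + p2 - m3$null),
               spring_force(m3, p1) + spring_force(m3, p2))
})

test_that("spring fit recovers generating parameters and respects the ellipse mask", {
  truth <- postural_field_model(0.8, 0.3, -1.5, 0.3, -2.5)
  ses <- simulate_probe_session(truth, sensor_sd = 0)
  fit <- fit_spring_model(ses, seed = 1)
  expect_lt(max(abs(fit$null - truth$null)), 1e-6)
  expect_lt(max(abs(fit$K - truth$K)) / max(abs(truth$K)), 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)

  # translation equivariance: shifting all positions shifts the null only
  shifted <- ses
  shifted$x <- ses$x + 0.7; shifted$y <- ses$y - 0.4
  fit2 <- fit_spring_model(shifted, mask_x = Inf, mask_y = Inf, seed = 1)
  expect_equal(unname(fit2$null), unname(truth$null + c(0.7, -0.4)),
               tolerance = 1e-5)
  expect_equal(fit2$K, truth$K, tolerance = 1e-5)

  # mask: a wild point at x = 2.3 cm is outside and ignored; at 2.2 it is not
  base <- fit_spring_model(ses, seed = 1)
  out_pt <- data.frame(x = 2.3, y = 0, fx = 500, fy = -500)
  with_out <- fit_spring_model(rbind(ses[, c("x", "y", "fx", "fy")], out_pt),
                               seed = 1)
  expect_equal(with_out$null, base$null, tolerance = 1e-9)
  in_pt <- data.frame(x = 2.2, y = 0, fx = 500, fy = -500)
  with_in <- fit_spring_model(rbind(ses[, c("x", "y", "fx", "fy")], in_pt),
                              seed = 1)
  expect_gt(max(abs(with_in$null - base$null)), 0.01)

  expect_error(fit_spring_model(data.frame(x = c(0.5, 1, 1.5), y = 0,
                                           fx = 1:3, fy = 1:3)),
               "distinct directions")
})

test_that("field orientation and stiffness summaries follow the eigenstructure", {
  expect_equal(field_orientation(postural_field_model(0, 0, 2, 0, 1)), 0)
  expect_equal(field_orientation(postural_field_model(0, 0, 1, 0, 2)), 90)
  expect_equal(field_orientation(postural_field_model(0, 0, 1.1, 1, 1.1)), 45)
  expect_error(field_orientation(postural_field_model(0, 0, 1, 0, 1)),
               "orientation undefined")

  expect_equal(field_stiffness(postural_field_model(0, 0, 2, 0, 1)), sqrt(5))
  expect_equal(field_stiffness(postural_field_model(0, 0, 0, 0, 0)), 0)
  expect_equal(field_stiffness(postural_field_model(0, 0, 2, 1, 3)), sqrt(15))
})

test_that("probe trajectories hit the printed durations and are C1 at phase joins", {
  tr25 <- generate_probe_trajectory(probe_preset("2.5cm"))
  expect_equal(round(attr(tr25, "total_duration"), 2), 7.67)
  expect_equal(round(attr(tr25, "plateau_duration"), 2), 5.87)
  expect_equal(round(attr(generate_probe_trajectory(probe_preset("4cm")),
                          "total_duration"), 2), 11.67)
  tr5 <- generate_probe_trajectory(probe_preset("5cm"))
  expect_equal(round(attr(tr5, "total_duration"), 2), 15.03)
  expect_equal(round(attr(tr5, "plateau_duration"), 2), 11.73)

  for (tr in list(tr25, tr5)) {
    expect_lt(abs(max(tr$displacement) - attr(tr, "total_displacement")), 1e-9)
    expect_true(all(diff(tr$displacement) >= -1e-12))  # monotone
    # numerical derivative of position tracks the velocity trace everywhere:
    # no jumps at phase joins beyond central-difference truncation error
    dt <- tr$time[2] - tr$time[1]
    num_v <- (tr$displacement[-(1:2)] - tr$displacement[1:(nrow(tr) - 2)]) / (2 * dt)
    expect_lt(max(abs(num_v - tr$speed[-c(1, nrow(tr))])), 0.01)
    expect_equal(tr$speed[nrow(tr)], 0)
  }

  # degenerate plateau: two mirrored ramps
  deg <- generate_probe_trajectory(probe_spec(0, 0.15, 0.75, 0.375, 0, buffer = 0))
  expect_equal(attr(deg, "total_displacement"), 0.3)
  expect_equal(attr(deg, "total_duration"), 1.5)

  # infeasible ramp: large displacement incompatible with terminal speed
  expect_error(generate_probe_trajectory(probe_spec(0, 0.05, 1, 1, 1)),
               "infeasible")
})

test_that("null-point estimation finds linear and exponential crossings deterministically", {
  # noiseless linear field: intercept at the algebraic zero crossing
  grid <- seq(0, 4, by = 0.05)
  lin <- do.call(rbind, lapply(1:5, function(s) {
    data.frame(subject = s, displacement = grid, force = -1.5 * (grid - 1.2))
  }))
  est <- estimate_null_point(lin, reps = 50, seed = 1)
  expect_lt(abs(est$intercept - 1.2), 0.01)

  # exponential cohort: accurate recovery and seed determinism
  set.seed(21)
  traces <- probe_force_cohort(n_subjects = 19, white_sd = 0.05,
                               amp_sd = 0.3, offset_sd = 0.05)
  e1 <- estimate_null_point(traces, reps = 200, seed = 5)
  e2 <- estimate_null_point(traces, reps = 200, seed = 5)
  expect_identical(e1$intercept, e2$intercept)
  expect_lt(abs(e1$intercept - 1.2), 0.1)
  expect_lt(e1$ci[1], e1$ci[2])

  # all-positive forces: no crossing to find
  pos <- transform(lin, force = force + 10)
  expect_error(estimate_null_point(pos, reps = 50, seed = 1), "no zero crossing")
})

test_that("polar interpolation reproduces knots, wraps angles, and tracks a linear field", {
  truth <- postural_field_model(0.6, -0.4, -2, 0.5, -1.2)
  ses <- simulate_probe_session(truth, sensor_sd = 0)
  fld <- interpolate_field_polar(ses, step = 0.1)

  # querying on a measured ray at a radius knot reproduces the measurement
  r0 <- fld$radii[11]
  q <- query_field(fld, r0 * cos(45 * pi / 180), r0 * sin(45 * pi / 180))
  truef <- spring_force(truth, c(r0 * cos(45 * pi / 180), r0 * sin(45 * pi / 180)))
  expect_equal(c(q$fx, q$fy), unname(truef), tolerance = 1e-9)

  # wrap-around: 357.5 deg interpolates between the 345 and 0 deg rays
  qw <- query_field(fld, r0 * cos(357.5 * pi / 180), r0 * sin(357.5 * pi / 180))
  f345 <- spring_force(truth, r0 * c(cos(345 * pi / 180), sin(345 * pi / 180)))
  f0 <- spring_force(truth, c(r0, 0))
  w <- (357.5 - 345) / 15
  expect_equal(qw$fx, (1 - w) * f345[1] + w * f0[1], tolerance = 1e-9)
  expect_equal(qw$fy, (1 - w) * f345[2] + w * f0[2], tolerance = 1e-9)

  # along each measured ray at half range the field is reproduced closely
  r_mid <- max(fld$radii) / 2
  for (a in fld$angles) {
    u <- c(cos(a * pi / 180), sin(a * pi / 180))
    qm <- query_field(fld, r_mid * u[1], r_mid * u[2])
    fm <- spring_force(truth, r_mid * u)
    expect_lt(sqrt((qm$fx - fm[1])^2 + (qm$fy - fm[2])^2),
              0.05 * sqrt(sum(fm^2)))
  }

  expect_error(interpolate_field_polar(ses[ses$direction_deg != 90, ]),
               "missing rays at 90")
})
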