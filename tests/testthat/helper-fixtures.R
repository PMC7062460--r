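# trial builders used across test files

# bell-shaped speed profile (peak cm/s) over [t_on, t_off], zero elsewhere
bell_speed <- function(time, t_on, t_off, peak) {
  s <- (time - t_on) / (t_off - t_on)
  v <- ifelse(s > 0 & s < 1, peak * 16 * s^2 * (1 - s)^2, 0)
  v
}

# channel trial with a piecewise-constant hold step and a move burst:
# u = hold1 before onset, hold1 + burst during movement, hold1 + dh after
step_trial <- function(hold1 = 0.3, dh = 0.5, burst_peak = 2,
                       onset = 0, offset = 0.5, dt = 0.005,
                       t_range = c(-1, 2), meta = list()) {
  t <- seq(t_range[1], t_range[2], by = dt)
  s <- (t - onset) / (offset - onset)
  burst <- ifelse(s > 0 & s < 1, burst_peak * sin(pi * s)^2, 0)
  u <- hold1 + burst + ifelse(t > offset + 1e-9, dh, 0)
  ts_trial(t, list(force_x = u), onset = onset, offset = offset, meta = meta)
}

# exact-line integration samples
line_samples <- function(n = 20, k = 0.5, a = 0.1, seed = 1) {
  set.seed(seed)
  m <- stats::runif(n, -2, 2)
  data.frame(m = m, dh = k * m + a, hold1 = 0, hold2 = k * m + a)
}

# probe-force cohort for null-point tests: each subject's along-probe force
# is amp_s * (exp(B d) - exp(B d0)) + offset_s + white noise; the population
# mean curve crosses zero at d0
probe_force_cohort <- function(n_subjects = 19, d0 = 1.2, B = -0.9,
                               amp_mean = 3, amp_sd = 0.6, offset_sd = 0.15,
                               white_sd = 0.15, d_max = 4, step = 0.05) {
  grid <- seq(0, d_max, by = step)
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    amp <- stats::rnorm(1, amp_mean, amp_sd)
    off <- stats::rnorm(1, 0, offset_sd)
    data.frame(subject = s, displacement = grid,
               force = amp * (exp(B * grid) - exp(B * d0)) + off +
                 stats::rnorm(length(grid), 0, white_sd))
  }))
}
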