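#' Specification of a synthetic cohort
#'
#' Ground-truth parameters for forward simulation of the serial
#' move-to-hold integrator architecture: a move controller emits a lateral
#' force burst on each reach, and the hold controller's output steps by the
#' gain-scaled time-integral of that burst. Defaults describe a human
#' channel-trial experiment: 200 Hz sampling, 10 cm reaches of about 0.5 s,
#' lateral move-force bursts with trial-to-trial amplitude variability, and
#' noise levels chosen so the within-trial integration statistic explains
#' roughly half the hold-force variance, as observed in null-field cohorts.
#'
#' @param n_trials trials per subject (default 150).
#' @param n_subjects number of subjects (default 1).
#' @param k_true integration gain (1/s, default 1).
#' @param a_true integration offset (N, default 0).
#' @param move_profile burst shape: `"bell"` (minimum-jerk-like speed
#'   profile), `"triangular"`, or `"biphasic"` (equal opposite lobes,
#'   integral zero).
#' @param amp_mean,amp_sd peak burst amplitude mean and SD across trials (N).
#' @param move_duration burst duration (s, default 0.5).
#' @param hold_sd SD of additive noise on the hold-force step (N).
#' @param sensor_sd SD of white force-sensor noise added to every sample (N).
#' @param retention_A,error_sensitivity_B single-state trial-to-trial
#'   learner parameters (unitless; `0 <= A <= 1`).
#' @param gain_learning_rate eta (1/cm): when positive, the integration
#'   gain adapts downward in proportion to endpoint error.
#' @param sample_rate Hz (default 200).
#' @param seed integer seed; identical specs give bit-identical cohorts.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_trials = 150, n_subjects = 1, k_true = 1,
                        a_true = 0, move_profile = c("bell", "triangular",
                                                     "biphasic"),
                        amp_mean = 4, amp_sd = 1.2, move_duration = 0.5,
                        hold_sd = 0.3, sensor_sd = 0.05,
                        retention_A = 0.98, error_sensitivity_B = 0.1,
                        gain_learning_rate = 0, sample_rate = 200,
                        seed = 1L) {
  move_profile <- match.arg(move_profile)
  stopifnot(retention_A >= 0, retention_A <= 1,
            hold_sd >= 0, sensor_sd >= 0, amp_sd >= 0, move_duration > 0)
  structure(list(n_trials = n_trials, n_subjects = n_subjects,
                 k_true = k_true, a_true = a_true,
                 move_profile = move_profile, amp_mean = amp_mean,
                 amp_sd = amp_sd, move_duration = move_duration,
                 hold_sd = hold_sd, sensor_sd = sensor_sd,
                 retention_A = retention_A,
                 error_sensitivity_B = error_sensitivity_B,
                 gain_learning_rate = gain_learning_rate,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# unit-peak burst shapes on [0, 1]
.burst_shape <- function(profile, s) {
  switch(profile,
    bell = sin(pi * s)^2,
    triangular = 1 - abs(2 * s - 1),
    biphasic = sin(2 * pi * s))
}

#' Simulate one channel trial of the integrator architecture
#'
#' Generates a lateral move-force burst (the move command scaled by the
#' current learner state plus amplitude noise), embeds exact onset/offset
#' events, and sets the hold-period force to the gain-scaled trapezoidal
#' integral of the move force plus the offset `a_true` and hold noise; the
#' hold force rises over 0.3 s after movement offset and is sustained flat
#' through the hold window. Sensor noise is added last. The trial carries a
#' bell-shaped speed channel so event detection can also be exercised.
#'
#' @param spec a [cohort_spec].
#' @param move_amplitude peak lateral move force (N); when `NULL`, drawn
#'   from `N(amp_mean, amp_sd)`. The caller controls the RNG stream.
#' @param hold1 pre-movement hold force (N, default 0).
#' @param meta metadata list attached to the trial.
#' @return List with `trial` (a [ts_trial]) and `truth` (list:
#'   `move_integral`, `hold_change`, `k`, `a`, `amplitude`).
#' @export
simulate_channel_trial <- function(spec, move_amplitude = NULL, hold1 = 0,
                                   meta = list()) {
  dt <- 1 / spec$sample_rate
  dur <- spec$move_duration
  t <- seq(-1, dur + 2, by = dt)
  onset <- 0; offset <- dur
  if (is.null(move_amplitude)) {
    move_amplitude <- stats::rnorm(1, spec$amp_mean, spec$amp_sd)
  }
  inmove <- t >= onset & t <= offset
  m <- numeric(length(t))
  m[inmove] <- move_amplitude * .burst_shape(spec$move_profile,
                                             (t[inmove] - onset) / dur)
  # ground-truth integral with the same quadrature the analysis uses
  M <- pracma::trapz(t[inmove], m[inmove])
  dh <- spec$k_true * M + spec$a_true + stats::rnorm(1, 0, spec$hold_sd)
  rise <- pmin(pmax((t - offset) / 0.3, 0), 1)   # settles after offset
  u <- hold1 + m + dh * (3 * rise^2 - 2 * rise^3)
  u <- u + stats::rnorm(length(t), 0, spec$sensor_sd)
  # 10 cm reach bell speed profile for event detection (cm/s)
  speed <- numeric(length(t))
  speed[inmove] <- (10 / dur) * (30 * ((t[inmove]) / dur)^2 *
                                   (1 - (t[inmove]) / dur)^2)
  trial <- ts_trial(t, list(force_x = u, speed = speed),
                    onset = onset, offset = offset, meta = meta)
  list(trial = trial,
       truth = list(move_integral = M, hold_change = dh,
                    k = spec$k_true, a = spec$a_true,
                    amplitude = move_amplitude))
}

#' Simulate a null-field channel-trial cohort
#'
#' Draws `n_trials` channel trials per subject with independent burst
#' amplitudes and returns the integration samples measured by
#' [hold_change()] with the `human_force` windows, alongside the ground
#' truth.
#'
#' @param spec a [cohort_spec].
#' @return List with `samples` (`data.frame`) and `truth` (`data.frame`).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  ws <- window_preset("human_force")
  rows <- vector("list", spec$n_subjects * spec$n_trials)
  truths <- vector("list", length(rows))
  i <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (tr in seq_len(spec$n_trials)) {
      i <- i + 1L
      sim <- simulate_channel_trial(spec, meta = list(subject = s, trial = tr))
      rows[[i]] <- hold_change(sim$trial, "force_x", ws)
      truths[[i]] <- data.frame(subject = s, trial = tr,
                                m_true = sim$truth$move_integral,
                                dh_true = sim$truth$hold_change,
                                k_true = spec$k_true)
    }
  }
  list(samples = do.call(rbind, rows), truth = do.call(rbind, truths))
}

#' Simulate a force-field adaptation experiment
#'
#' Runs a single-state trial-to-trial learner over a perturbation schedule:
#' on every non-channel trial the adapted state updates as
#' `x <- A x + B (b_trial - x)`; on channel trials the commanded lateral
#' force (state times the reach velocity profile) is recorded through
#' [simulate_channel_trial()]. When the spec's `gain_learning_rate` is
#' positive, the integration gain additionally adapts downward in
#' proportion to a generated endpoint error, itself proportional to the
#' mismatch between the produced hold force and the force needed to stay on
#' target. The learner is testing scaffolding: it stands in for the human
#' adaptation the schedules induce, it is not a claim about learning.
#'
#' @param spec a [cohort_spec].
#' @param schedule an `adaptation_schedule` from [build_schedule()].
#' @param v_peak peak reach speed (m/s, default 0.375) converting the
#'   learner state (N*s/m) into a peak lateral force.
#' @return List with `channel_samples` (integration samples on channel
#'   trials with scheduled `b`), `states` (per-trial latent state), `truth`.
#' @export
simulate_adaptation_experiment <- function(spec, schedule, v_peak = 0.375) {
  stopifnot(inherits(schedule, "adaptation_schedule"), "b" %in% names(schedule))
  set.seed(spec$seed)
  ws <- window_preset("human_force")
  A <- spec$retention_A; B <- spec$error_sensitivity_B
  eta <- spec$gain_learning_rate
  x <- 0; k <- spec$k_true
  states <- numeric(nrow(schedule)); gains <- numeric(nrow(schedule))
  rows <- list(); truths <- list()
  for (i in seq_len(nrow(schedule))) {
    states[i] <- x; gains[i] <- k
    if (schedule$channel[i]) {
      sp <- spec; sp$k_true <- k
      sim <- simulate_channel_trial(
        sp, move_amplitude = x * v_peak + stats::rnorm(1, 0, spec$amp_sd),
        meta = list(trial = schedule$trial[i], phase = schedule$phase[i]))
      smp <- hold_change(sim$trial, "force_x", ws)
      smp$b <- schedule$b[i]
      rows[[length(rows) + 1L]] <- smp
      truths[[length(truths) + 1L]] <-
        data.frame(trial = schedule$trial[i], state = x, k = k,
                   m_true = sim$truth$move_integral,
                   dh_true = sim$truth$hold_change)
    } else {
      x <- A * x + B * (schedule$b[i] - x)
      if (eta > 0) {
        # endpoint error proportional to uncompensated hold-force mismatch
        err <- 0.5 * (k * x * v_peak * spec$move_duration / 2) / max(1, abs(k))
        k <- max(0, k - eta * err)
      }
    }
  }
  list(channel_samples = do.call(rbind, rows),
       states = data.frame(trial = schedule$trial, state = states, gain = gains),
       truth = do.call(rbind, truths))
}

#' Simulate a directionally tuned EMG cohort
#'
#' Generates per-muscle, per-direction reach trials in which each muscle's
#' move burst is scaled by cosine tuning around its preferred direction
#' (negative values are suppression below the hold-1 level), and the hold-2
#' plateau equals hold-1 plus the gain-scaled burst integral plus noise.
#' Muscles listed in `non_integrating` receive near-zero hold modulation,
#' emulating recorded muscles that burst during movement but barely change
#' their holding activity.
#'
#' @param spec a [cohort_spec]; `amp_mean` is the peak burst in normalized
#'   units at the preferred direction, `hold_sd`/`sensor_sd` likewise.
#' @param n_directions number of equally spaced targets (default 8).
#' @param n_muscles number of muscles (default 5, preferred directions
#'   equally spaced).
#' @param trials_per_direction repeats per direction (default 3).
#' @param hold1_level baseline hold-1 activity (default 0.2).
#' @param non_integrating indices of muscles with near-zero hold
#'   modulation.
#' @return List with `trials` (list of [ts_trial] with `emg` channel and
#'   meta muscle/direction), `samples` (via the `monkey_reach_out`
#'   windows), `truth`.
#' @export
simulate_emg_cohort <- function(spec, n_directions = 8, n_muscles = 5,
                                trials_per_direction = 3, hold1_level = 0.2,
                                non_integrating = integer(0)) {
  set.seed(spec$seed)
  dirs <- seq(0, 360, length.out = n_directions + 1)[-(n_directions + 1)]
  pds <- seq(0, 360, length.out = n_muscles + 1)[-(n_muscles + 1)]
  dt <- 1 / spec$sample_rate
  dur <- spec$move_duration
  t <- seq(-1, dur + 1.2, by = dt)
  inmove <- t >= 0 & t <= dur
  shape <- numeric(length(t))
  shape[inmove] <- .burst_shape("bell", t[inmove] / dur)
  ws <- window_preset("monkey_reach_out")
  # reach-out windows need h1 back to -0.7 s and h2 to +0.45 s: t range ok
  trials <- list(); rows <- list(); truths <- list()
  for (mu in seq_len(n_muscles)) {
    integrates <- !(mu %in% non_integrating)
    for (di in seq_along(dirs)) {
      tune <- cos((dirs[di] - pds[mu]) * pi / 180)
      for (rep in seq_len(trials_per_direction)) {
        amp <- spec$amp_mean * tune + stats::rnorm(1, 0, spec$amp_sd)
        m <- amp * shape
        M <- pracma::trapz(t[inmove], m[inmove])
        dh_core <- if (integrates) spec$k_true * M + spec$a_true else 0.02 * M
        dh <- dh_core + stats::rnorm(1, 0, spec$hold_sd)
        rise <- pmin(pmax((t - dur) / 0.25, 0), 1)
        u <- hold1_level + m + dh * (3 * rise^2 - 2 * rise^3) +
          stats::rnorm(length(t), 0, spec$sensor_sd)
        trial <- ts_trial(t, list(emg = u), onset = 0, offset = dur,
                          meta = list(muscle = paste0("m", mu),
                                      direction = dirs[di],
                                      trial = rep,
                                      integrates = integrates))
        trials[[length(trials) + 1L]] <- trial
        smp <- hold_change(trial, "emg", ws)
        rows[[length(rows) + 1L]] <- smp
        truths[[length(truths) + 1L]] <-
          data.frame(muscle = paste0("m", mu), direction = dirs[di],
                     trial = rep, m_true = M, dh_true = dh,
                     k_true = if (integrates) spec$k_true else 0.02)
      }
    }
  }
  list(trials = trials, samples = do.call(rbind, rows),
       truth = do.call(rbind, truths))
}

#' Simulate a postural probe session
#'
#' For each probe direction, generates the imposed trajectory, evaluates
#' the ground-truth spring field along the displaced positions, projects
#' the force on the probe direction, and adds sensor noise. Positions are
#' relative to the pre-probe hand position (the probe origin).
#'
#' @param model a [postural_field_model] (the ground truth).
#' @param directions probe directions in degrees (default the 12-direction
#'   experimental set).
#' @param spec_for function mapping a direction to a [probe_spec] (default:
#'   the 2.5 cm preset for every direction).
#' @param sensor_sd force-sensor noise SD (N, default 0).
#' @param subject subject label stored with the traces.
#' @param seed integer seed.
#' @return `data.frame` with columns `subject`, `direction_deg`,
#'   `displacement`, `x`, `y`, `fx`, `fy`, `force_along`.
#' @export
simulate_probe_session <- function(model,
                                   directions = c(0, 15, 30, 45, 90, 135, 180,
                                                  225, 270, 315, 330, 345),
                                   spec_for = function(dir) probe_preset("2.5cm", dir),
                                   sensor_sd = 0, subject = 1L, seed = 1L) {
  set.seed(seed)
  out <- lapply(directions, function(dir) {
    traj <- generate_probe_trajectory(spec_for(dir))
    # keep the displacement-unique part (ramp + plateau + final ramp)
    keep <- !duplicated(traj$displacement)
    disp <- traj$displacement[keep]
    u <- c(cos(dir * pi / 180), sin(dir * pi / 180))
    pos <- cbind(disp * u[1], disp * u[2])
    f <- spring_force(model, pos)
    f <- f + matrix(stats::rnorm(length(f), 0, sensor_sd), ncol = 2)
    # subject-on-handle force projected on the probe direction: for a
    # restoring field (negative-definite K) this decreases with displacement
    # and crosses zero where the probe passes the null point
    data.frame(subject = subject, direction_deg = dir, displacement = disp,
               x = pos[, 1], y = pos[, 2], fx = f[, 1], fy = f[, 2],
               force_along = f[, 1] * u[1] + f[, 2] * u[2])
  })
  do.call(rbind, out)
}
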