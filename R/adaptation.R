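#' Velocity-dependent (curl) force field
#'
#' `fx = -b vy`, `fy = b vx`: the robot force is perpendicular and
#' proportional to hand velocity. Positive `b` gives a clockwise field,
#' negative `b` counterclockwise. The matrix is antisymmetric, so the field
#' does no net work around any closed velocity profile.
#'
#' @param b field magnitude (N*s/m).
#' @param velocity length-2 vector or 2-column matrix (m/s).
#' @return Force (N), same shape as `velocity`.
#' @export
curl_field_force <- function(b, velocity) {
  if (is.matrix(velocity)) {
    cbind(fx = -b * velocity[, 2], fy = b * velocity[, 1])
  } else {
    c(fx = -b * velocity[2], fy = b * velocity[1])
  }
}

#' Position-dependent quadratic perturbation (zero-integral design)
#'
#' Lateral force as a quadratic function of along-reach position over a
#' 20 cm reach: the first component vanishes at 0 and 10 cm with vertex
#' value `ff1` at 5 cm; the second vanishes at 10 and 20 cm with vertex
#' value `ff2` at 15 cm. With `ff1 = -ff2` the spatial integral over the
#' whole reach is exactly zero, dissociating continuation of move forces
#' from their integral.
#'
#' @param y along-reach position (cm, in \[0, 20\]); vectorized.
#' @param ff1,ff2 vertex forces of the two components (N).
#' @return Lateral force (N).
#' @export
quadratic_field_force <- function(y, ff1, ff2) {
  if (any(y < 0 | y > 20)) stop("quadratic_field_force: position outside [0, 20] cm")
  ifelse(y <= 10,
         ff1 * y * (10 - y) / 25,
         ff2 * (y - 10) * (20 - y) / 25)
}

#' Build a perturbation schedule
#'
#' Emits the full outward-trial list for the named experiment template,
#' with evenly incremented field magnitudes during ramp phases, phase
#' labels, and a channel-trial mask (on channel trials the robot replaces
#' the field with a force channel, so the applied field magnitude is zero
#' while the *scheduled* magnitude is retained for analysis).
#'
#' Templates (outward-trial counts):
#' * `"healthy_curl"`: 20 null, 100 ramp 0 to `b_max` (default 15 N*s/m),
#'   50 plateau, 100 deramp, 20 washout; channel every 5th.
#' * `"stroke_curl"`: 20 null, 80 ramp 0 to 18 N*s/m, 40 plateau,
#'   80 deramp, 20 washout; channel every 5th.
#' * `"zero_integral"`: 25 null, 100 ramp of `ff2` from 0 to 3.5 N, then
#'   200 trials ramping `ff1` from 0 to -3.5 N with `ff2` held at 3.5 N;
#'   channel every 5th. Set `control = TRUE` to hold `ff1` at 0 in the
#'   second phase (the repetition/fatigue control).
#' * `"probe_gradual"`: 50 null (probe every 5th), ramp 0 to -10.5 N*s/m
#'   over 175 outward trials; channel/probe every 5th.
#'
#' @param template experiment template name.
#' @param b_max plateau curl magnitude (N*s/m); sign sets CW/CCW.
#' @param channel_every channel-trial spacing in outward trials (default 5).
#' @param control for `"zero_integral"`: run the control variant.
#' @return `data.frame` of class `adaptation_schedule` with columns
#'   `trial`, `phase`, `channel` and `b` (curl templates) or `ff1`, `ff2`
#'   (zero-integral template).
#' @export
build_schedule <- function(template = c("healthy_curl", "stroke_curl",
                                        "zero_integral", "probe_gradual"),
                           b_max = NULL, channel_every = 5, control = FALSE) {
  template <- match.arg(template)
  stopifnot(channel_every >= 2)
  ramp_to <- function(n, to) to * seq_len(n) / n
  if (template %in% c("healthy_curl", "stroke_curl", "probe_gradual")) {
    cfg <- switch(template,
      healthy_curl = list(null = 20, ramp = 100, plateau = 50, deramp = 100,
                          washout = 20, b = if (is.null(b_max)) 15 else b_max),
      stroke_curl = list(null = 20, ramp = 80, plateau = 40, deramp = 80,
                         washout = 20, b = if (is.null(b_max)) 18 else b_max),
      probe_gradual = list(null = 50, ramp = 175, plateau = 0, deramp = 0,
                           washout = 0, b = if (is.null(b_max)) -10.5 else b_max))
    b <- c(rep(0, cfg$null), ramp_to(cfg$ramp, cfg$b),
           rep(cfg$b, cfg$plateau),
           if (cfg$deramp > 0) cfg$b * (1 - seq_len(cfg$deramp) / cfg$deramp),
           rep(0, cfg$washout))
    phase <- rep(c("null", "ramp", "plateau", "deramp", "washout"),
                 c(cfg$null, cfg$ramp, cfg$plateau, cfg$deramp, cfg$washout))
    sched <- data.frame(trial = seq_along(b), phase = phase, b = b)
  } else {
    n1 <- 25; n2 <- 100; n3 <- 200
    ff2 <- c(rep(0, n1), ramp_to(n2, 3.5), rep(3.5, n3))
    ff1 <- c(rep(0, n1 + n2),
             if (control) rep(0, n3) else ramp_to(n3, -3.5))
    phase <- rep(c("null", "ramp_ff2", "ramp_ff1"), c(n1, n2, n3))
    sched <- data.frame(trial = seq_along(ff1), phase = phase,
                        ff1 = ff1, ff2 = ff2)
  }
  sched$channel <- sched$trial %% channel_every == 0
  if ("b" %in% names(sched)) {
    sched$b_applied <- ifelse(sched$channel, 0, sched$b)  # channel replaces field
  }
  class(sched) <- c("adaptation_schedule", "data.frame")
  sched
}

#' Endpoint error of a reach trajectory
#'
#' The largest positive lateral deviation of the hand from its terminal
#' position over the part of the reach past a progress threshold (80% of
#' the along-axis displacement); if no positive deviation occurs there, the
#' most negative deviation is returned instead. The trajectory is aligned
#' by subtracting the terminal position, so the measure is invariant to
#' rigid translation. "Positive" is a sign convention (the direction of the
#' endpoint correction, opposite the mid-movement field-induced error); flip
#' it with `positive_direction = -1`.
#'
#' @param lateral lateral hand positions (cm).
#' @param along along-axis hand progress (cm, from reach start).
#' @param total_displacement full reach extent (cm).
#' @param threshold_fraction progress threshold (default 0.8).
#' @param positive_direction +1 or -1; multiplies `lateral` before applying
#'   the rule.
#' @return List of class `endpoint_error` with `error` (cm, in the
#'   convention of `positive_direction`), `time_index` (sample index of the
#'   extremum) and `threshold_fraction`.
#' @export
endpoint_error <- function(lateral, along, total_displacement,
                           threshold_fraction = 0.8, positive_direction = 1) {
  stopifnot(length(lateral) == length(along))
  lat <- positive_direction * (lateral - lateral[length(lateral)])
  past <- which(along > threshold_fraction * total_displacement)
  if (length(past) < 3L) stop("endpoint_error: fewer than 3 samples past the progress threshold")
  seg <- lat[past]
  if (any(seg > 0)) {
    i <- past[which.max(seg)]
  } else {
    i <- past[which.min(seg)]
  }
  structure(list(error = lat[i], time_index = i,
                 threshold_fraction = threshold_fraction),
            class = "endpoint_error")
}

#' Integration gain from channel-trial samples
#'
#' Two estimators of the gain relating hold force to the reach force
#' integral: the ratio of the median hold-force change to the median
#' move-force integral (used over channel trials at the perturbation
#' plateau), and the OLS regression slope (required in the null period,
#' where both medians are near zero and the ratio is undefined).
#'
#' @param samples `data.frame` with columns `m` (N*s) and `dh` (N).
#' @param method `"ratio"` or `"regression"`.
#' @param min_median_m guard for the ratio method: minimum `|median(m)|`
#'   (N*s, default 0.05) below which the ratio is refused.
#' @return Gain in 1/s.
#' @export
integration_gain <- function(samples, method = c("ratio", "regression"),
                             min_median_m = 0.05) {
  method <- match.arg(method)
  if (method == "ratio") {
    med_m <- stats::median(samples$m)
    if (abs(med_m) < min_median_m) {
      stop("integration_gain: median move integral near zero; use method = \"regression\"")
    }
    stats::median(samples$dh) / med_m
  } else {
    fit_integration(samples)$k
  }
}

#' Relationship between adapted integration gain and endpoint error
#'
#' OLS of each subject's end-of-adaptation integration gain on their
#' (mean or median) endpoint error. On adapting cohorts larger endpoint
#' errors reduce the gain, so the slope is expected negative.
#'
#' @param gains per-subject integration gains (1/s).
#' @param errors per-subject endpoint errors (cm).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
gain_vs_error <- function(gains, errors) {
  stopifnot(length(gains) == length(errors))
  ok <- is.finite(gains) & is.finite(errors)
  if (sum(ok) < 3L) stop("gain_vs_error: need >= 3 subjects")
  if (stats::var(errors[ok]) == 0) stop("gain_vs_error: degenerate error variance")
  fit <- stats::lm(gains[ok] ~ errors[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = sum(ok))
}
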