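#' Time-integral of move-period output above the initial hold level
#'
#' Computes `M = integral over [t0, T] of (u(t) - hold1) dt` by trapezoidal
#' quadrature, with linear interpolation of `u` at the integration bounds
#' when they fall between samples. This is the move-period predictor of the
#' integration statistic: the change in hold-period output is modelled as
#' `k * M + a`.
#'
#' @param u numeric trace (normalized EMG or baseline-corrected force).
#' @param time sample times (s).
#' @param hold1 pre-movement hold level subtracted from `u`.
#' @param t0,T integration bounds (s), `t0 < T`, both inside the trace.
#' @return Scalar integral in signal-units * s.
#' @export
move_integral <- function(u, time, hold1, t0, T) {
  stopifnot(length(u) == length(time))
  if (!(t0 < T)) stop("move_integral: t0 must precede T")
  if (t0 < time[1] - 1e-12 || T > time[length(time)] + 1e-12) {
    stop("move_integral: integration bounds outside trace")
  }
  inside <- time > t0 & time < T
  tt <- c(t0, time[inside], T)
  uu <- c(stats::approx(time, u, xout = t0)$y, u[inside],
          stats::approx(time, u, xout = T)$y)
  pracma::trapz(tt, uu - hold1)
}

#' Per-trial integration sample: hold change and move integral
#'
#' Measures the quantities entering the integration regression for one
#' trial: the pre-movement hold level `hold1`, the post-movement hold level
#' `hold2`, their difference `dh`, and the move-period integral `m` taken
#' from `integration_lead` seconds before onset up to movement offset.
#' Trials whose movement duration exceeds the window spec's cutoff are
#' flagged `excluded` (they are returned, never silently dropped).
#'
#' @param trial a [ts_trial] with onset and offset set (or detectable from a
#'   `speed` channel using the spec's thresholds).
#' @param channel channel to analyse.
#' @param spec a [window_spec] (see [window_preset()]).
#' @return One-row `data.frame` with columns `hold1`, `hold2`, `dh`, `m`,
#'   `duration`, `excluded`, plus any scalar metadata fields of the trial.
#' @export
hold_change <- function(trial, channel, spec) {
  if (is.na(trial$onset) || is.na(trial$offset)) {
    sp <- trial$channels[["speed"]]
    if (is.null(sp)) stop("hold_change: trial lacks onset/offset and a speed channel")
    ev <- detect_onset_offset(sp, trial$time, spec$onset_threshold,
                              spec$offset_threshold)
    trial$onset <- ev[["onset"]]; trial$offset <- ev[["offset"]]
  }
  duration <- trial$offset - trial$onset
  excluded <- !is.na(spec$max_duration) && duration > spec$max_duration
  u <- trial_channel(trial, channel)
  hold1 <- trial_window_mean(trial, channel, spec$h1_start, spec$h1_duration,
                             anchor = "onset")
  hold2 <- trial_window_mean(trial, channel, spec$h2_start, spec$h2_duration,
                             anchor = "offset")
  m <- move_integral(u, trial$time, hold1,
                     trial$onset - spec$integration_lead, trial$offset)
  out <- data.frame(hold1 = hold1, hold2 = hold2, dh = hold2 - hold1,
                    m = m, duration = duration, excluded = excluded)
  for (nm in names(trial$meta)) {
    v <- trial$meta[[nm]]
    if (length(v) == 1L && is.atomic(v)) out[[nm]] <- v
  }
  out
}

#' Fit the integration gain and offset
#'
#' Ordinary least squares of the change in hold-period output on the
#' move-period integral: `dh = k * m + a`. The slope `k` (units 1/s) is the
#' integration gain; `a` absorbs systematic error from approximating the
#' move command by the hold1-subtracted signal. R-squared is the squared
#' Pearson correlation of fitted and observed values, equivalent to the
#' coefficient of determination for this simple regression.
#'
#' @param samples `data.frame` with columns `m` and `dh` (rows flagged
#'   `excluded`, if present, are removed first).
#' @param level confidence level for the slope interval (default 0.95).
#' @return An object of class `integration_fit`: list with `k`, `a`,
#'   `r_squared`, `n`, `ci_k`, `residual_sd` and the underlying `lm` fit.
#' @export
fit_integration <- function(samples, level = 0.95) {
  if (!is.null(samples$excluded)) samples <- samples[!samples$excluded, ]
  samples <- samples[is.finite(samples$m) & is.finite(samples$dh), ]
  n <- nrow(samples)
  if (n < 3L) stop("fit_integration: need at least 3 samples")
  if (stats::var(samples$m) <= 0) stop("degenerate predictor: m has zero variance")
  fit <- stats::lm(dh ~ m, data = samples)
  co <- stats::coef(fit)
  ci <- stats::confint(fit, "m", level = level)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((samples$dh - mean(samples$dh))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(k = unname(co["m"]), a = unname(co["(Intercept)"]),
         r_squared = r2, n = n, ci_k = unname(ci[1, ]),
         residual_sd = sqrt(ss_res / stats::df.residual(fit)), fit = fit),
    class = "integration_fit")
}

#' @export
print.integration_fit <- function(x, ...) {
  cat(sprintf("<integration_fit> k = %.4g 1/s [%.4g, %.4g], a = %.4g, R2 = %.3f, n = %d\n",
              x$k, x$ci_k[1], x$ci_k[2], x$a, x$r_squared, x$n))
  invisible(x)
}

#' Decompose a trace into move and hold commands
#'
#' Solves `u(t) = m(t) + hold1 + k * integral(m)` forward in time for the
#' move command `m(t)`, given a gain `k`; the hold command is
#' `h(t) = u(t) - m(t)`. Each sample's `m` appears in its own trapezoid
#' term, so the implicit step is solved in closed form, making the recursion
#' bit-reproducible: `m_i (1 + k dt / 2) = u_i - hold1 - k (I_{i-1} + dt/2 m_{i-1})`.
#'
#' @param u numeric trace.
#' @param time sample times (uniform step).
#' @param hold1 pre-movement hold level.
#' @param k assumed integration gain (1/s, `>= 0`).
#' @return List of class `decomposition` with `move`, `hold`, `time`,
#'   `gain_assumed`; `move + hold` reproduces `u` to machine precision.
#' @export
decompose_move_hold <- function(u, time, hold1, k) {
  stopifnot(k >= 0, length(u) == length(time))
  n <- length(u)
  dt <- (time[n] - time[1]) / (n - 1L)
  m <- numeric(n)
  m[1] <- u[1] - hold1
  integ <- 0
  denom <- 1 + k * dt / 2
  for (i in 2:n) {
    m[i] <- (u[i] - hold1 - k * (integ + dt / 2 * m[i - 1L])) / denom
    integ <- integ + dt / 2 * (m[i - 1L] + m[i])
  }
  structure(list(move = m, hold = u - m, time = time, gain_assumed = k),
            class = "decomposition")
}

#' Extremum-based rival predictor of hold activity
#'
#' The alternative to the integral: the maximum of `u - hold1` over the
#' movement when the muscle increased activity on average, otherwise the
#' minimum. Used to compare variance explained by the movement extremum
#' against the movement integral.
#'
#' @param u numeric trace.
#' @param time sample times.
#' @param hold1 pre-movement hold level.
#' @param t0,T movement window bounds (s).
#' @return Scalar extremum (signal-units).
#' @export
extremum_predictor <- function(u, time, hold1, t0, T) {
  keep <- time >= t0 & time <= T
  d <- u[keep] - hold1
  if (mean(d) >= 0) max(d) else min(d)
}

#' Restrict trials to near-mean initial hold activity
#'
#' Keeps trials whose `hold1` lies within `n_sd` standard deviations of the
#' (per-group) mean, the control showing that move-hold correlations are not
#' driven by shared fluctuations in initial activity. Reports the fractional
#' reduction in hold1 variance and the move-integral/hold-change correlation
#' before and after, both as Pearson r and as variance explained.
#'
#' @param samples `data.frame` with columns `hold1`, `m`, `dh` and optional
#'   grouping columns.
#' @param n_sd retention band half-width in SD units (default 1).
#' @param group optional column name(s) defining muscle/subject groups
#'   within which the band is applied.
#' @return List with `samples` (retained rows), `retained_fraction`,
#'   `variance_reduction`, `r_before`, `r_after`, `r2_before`, `r2_after`.
#' @export
restricted_hold1_filter <- function(samples, n_sd = 1, group = NULL) {
  if (nrow(samples) < 10L) stop("restricted_hold1_filter: need >= 10 samples")
  if (is.null(group)) {
    keys <- rep.int(1L, nrow(samples))
  } else {
    keys <- interaction(samples[group], drop = TRUE)
  }
  keep <- unlist(lapply(split(seq_len(nrow(samples)), keys), function(idx) {
    h <- samples$hold1[idx]
    idx[abs(h - mean(h)) <= n_sd * stats::sd(h)]
  }), use.names = FALSE)
  if (length(keep) == 0L) stop("restricted_hold1_filter: empty subset")
  sub <- samples[sort(keep), ]
  v_before <- stats::var(samples$hold1)
  v_after <- stats::var(sub$hold1)
  r_before <- stats::cor(samples$m, samples$dh)
  r_after <- stats::cor(sub$m, sub$dh)
  list(samples = sub,
       retained_fraction = nrow(sub) / nrow(samples),
       variance_reduction = if (v_before > 0) 1 - v_after / v_before else 0,
       r_before = r_before, r_after = r_after,
       r2_before = r_before^2, r2_after = r_after^2)
}

#' Per-muscle control regressions against rival predictors
#'
#' Runs one OLS per muscle under the selected mode and summarizes R-squared
#' across muscles (mean +/- SEM):
#'
#' * `"own"`: hold change on the muscle's own move integral (the hypothesis).
#' * `"hold1"`: hold2 on hold1 (initial-activity alternative).
#' * `"other"`: hold change on each *other* muscle's move integral, averaged
#'   over pairs (co-contraction alternative). Requires a `trial` column to
#'   pair simultaneous recordings.
#' * `"position"`: hold2 activity on hold-period position within condition
#'   (biomechanical alternative); requires a `position_h2` column.
#' * `"displacement"`: move integral on trial displacement; requires
#'   `position_h1` and `position_h2`.
#'
#' @param samples `data.frame` with columns `muscle`, `m`, `dh`, `hold1`,
#'   `hold2` and the mode-specific columns noted above.
#' @param mode regression mode.
#' @return List with `per_muscle` (`data.frame` muscle, r_squared, n),
#'   `mean_r2`, `sem_r2`.
#' @export
cross_predictor_regressions <- function(samples,
                                        mode = c("own", "other", "hold1",
                                                 "position", "displacement")) {
  mode <- match.arg(mode)
  need <- switch(mode,
    own = c("m", "dh"), hold1 = c("hold1", "hold2"),
    other = c("m", "dh", "trial"),
    position = c("hold2", "position_h2"),
    displacement = c("m", "position_h1", "position_h2"))
  missing_cols <- setdiff(c("muscle", need), names(samples))
  if (length(missing_cols) > 0L) {
    stop(sprintf("cross_predictor_regressions: missing columns %s for mode '%s'",
                 paste(missing_cols, collapse = ", "), mode))
  }
  muscles <- unique(samples$muscle)
  r2_one <- function(y, x) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }
  rows <- lapply(muscles, function(mu) {
    d <- samples[samples$muscle == mu, ]
    r2 <- switch(mode,
      own = r2_one(d$dh, d$m),
      hold1 = r2_one(d$hold2, d$hold1),
      position = r2_one(d$hold2, d$position_h2),
      displacement = r2_one(d$m, d$position_h2 - d$position_h1),
      other = {
        others <- setdiff(muscles, mu)
        vals <- vapply(others, function(ot) {
          o <- samples[samples$muscle == ot, ]
          shared <- intersect(d$trial, o$trial)
          if (length(shared) < 3L) return(NA_real_)
          r2_one(d$dh[match(shared, d$trial)], o$m[match(shared, o$trial)])
        }, numeric(1))
        mean(vals, na.rm = TRUE)
      })
    if (is.na(r2)) warning(sprintf("muscle '%s' skipped: fewer than 3 usable trials", mu))
    data.frame(muscle = mu, r_squared = r2, n = nrow(d))
  })
  per <- do.call(rbind, rows)
  ok <- is.finite(per$r_squared)
  list(per_muscle = per,
       mean_r2 = mean(per$r_squared[ok]),
       sem_r2 = stats::sd(per$r_squared[ok]) / sqrt(sum(ok)))
}

#' Confidence ellipse of a bivariate sample
#'
#' Ellipse from the sample mean and covariance: half-axis lengths are the
#' square roots of the covariance eigenvalues scaled by the chi-squared
#' (2 df) quantile at the requested level; the angle is the orientation of
#' the major axis in degrees.
#'
#' @param points two-column matrix or data.frame of observations.
#' @param level confidence level (default 0.95).
#' @return List of class `ellipse_params`: `center`, `axes` (half-lengths,
#'   major first), `angle` (deg in (-90, 90]), `level`.
#' @export
confidence_ellipse <- function(points, level = 0.95) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3L) stop("confidence_ellipse: need >= 3 points")
  S <- stats::cov(pts)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(ev$values)) {
    stop("confidence_ellipse: singular covariance")
  }
  q <- stats::qchisq(level, df = 2)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  structure(list(center = colMeans(pts), axes = sqrt(ev$values * q),
                 angle = ang, level = level),
            class = "ellipse_params")
}
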