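#' Two-dimensional linear spring model of the postural field
#'
#' The field of restoring forces generated while holding the limb still is
#' modelled as a linear spring with a single equilibrium (null) point:
#' `F = K (p - p_null)`, with `K` a symmetric 2x2 stiffness matrix
#' (`kxy = kyx`). Positions are in cm relative to the terminal hand
#' position; forces in N.
#'
#' @param x_null,y_null null-point coordinates (cm).
#' @param kxx,kxy,kyy stiffness entries (N/cm).
#' @param r_squared fit quality when estimated from data (fraction), else `NA`.
#' @return Object of class `postural_field_model`.
#' @export
postural_field_model <- function(x_null, y_null, kxx, kxy, kyy,
                                 r_squared = NA_real_) {
  structure(
    list(null = c(x = x_null, y = y_null),
         K = matrix(c(kxx, kxy, kxy, kyy), 2, 2,
                    dimnames = list(c("x", "y"), c("x", "y"))),
         r_squared = r_squared),
    class = "postural_field_model")
}

#' @export
print.postural_field_model <- function(x, ...) {
  cat(sprintf("<postural_field_model> null = (%.3f, %.3f) cm\n",
              x$null[1], x$null[2]))
  cat(sprintf("  K (N/cm): [%.3f %.3f; %.3f %.3f]  |K|_F = %.3f",
              x$K[1, 1], x$K[1, 2], x$K[2, 1], x$K[2, 2], field_stiffness(x)))
  if (!is.na(x$r_squared)) cat(sprintf("  R2 = %.3f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Force exerted by the spring field at a position
#'
#' @param model a [postural_field_model].
#' @param position length-2 vector or 2-column matrix of positions (cm).
#' @return Force vector(s) in N, same shape as `position`.
#' @export
spring_force <- function(model, position) {
  if (is.matrix(position)) {
    sweep(position, 2, model$null) %*% t(model$K)
  } else {
    as.vector(model$K %*% (position - model$null))
  }
}

#' Fit the spring model to probe forces
#'
#' Estimates the five parameters (null point and symmetric stiffness) by
#' minimizing the summed squared force error pooled over the x and y
#' components, using only samples inside the elliptical mask around the
#' terminal hand position (half-axes 2.25 cm along x and 1.5 cm along y).
#' For a fixed null point the stiffness entries enter linearly, so they are
#' profiled out by linear least squares and the search is a seeded
#' multi-start 2-D optimization over the null point alone (default 8
#' restarts, best of restarts returned) -- a deterministic replacement for a
#' stochastic global search at the same objective.
#'
#' @param forces `data.frame` with columns `x`, `y` (cm, relative to the
#'   terminal hand position) and `fx`, `fy` (N).
#' @param mask_x,mask_y ellipse half-axes of the mask (cm); `Inf` disables.
#' @param restarts number of optimizer restarts (default 8).
#' @param seed integer seed for the restart draws.
#' @return A [postural_field_model] with `r_squared` filled in.
#' @export
fit_spring_model <- function(forces, mask_x = 2.25, mask_y = 1.5,
                             restarts = 8, seed = 1L) {
  stopifnot(all(c("x", "y", "fx", "fy") %in% names(forces)))
  keep <- (forces$x / mask_x)^2 + (forces$y / mask_y)^2 <= 1
  d <- forces[keep, ]
  if (nrow(d) < 3L) stop("fit_spring_model: fewer than 3 samples inside mask")
  dirs <- unique(round(atan2(d$y, d$x) %% pi, 6))
  if (length(dirs) < 3L) {
    stop("fit_spring_model: need probe samples along >= 3 distinct directions")
  }
  obj <- function(null) .spring_profile(d, null)$sse
  span_x <- min(mask_x, max(abs(d$x), 1)); span_y <- min(mask_y, max(abs(d$y), 1))
  starts <- rbind(c(0, 0),
                  if (restarts > 1L) {
                    set.seed(seed)
                    cbind(stats::runif(restarts - 1L, -span_x, span_x),
                          stats::runif(restarts - 1L, -span_y, span_y))
                  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("fit_spring_model: optimizer failed on all restarts")
  }
  prof <- .spring_profile(d, best$par)
  f <- c(d$fx, d$fy)
  ss_tot <- sum((f - mean(f))^2)
  postural_field_model(best$par[1], best$par[2],
                       prof$theta[1], prof$theta[2], prof$theta[3],
                       r_squared = 1 - prof$sse / ss_tot)
}

# profile the linear stiffness parameters out for a fixed null point:
# fx = kxx dx + kxy dy ; fy = kxy dx + kyy dy. For fixed null this is a
# 3-parameter linear least-squares problem solved by its normal equations
# in closed form (the objective is evaluated many times per fit).
.spring_profile <- function(d, null) {
  dx <- d$x - null[1]; dy <- d$y - null[2]
  sxx <- sum(dx * dx); sxy <- sum(dx * dy); syy <- sum(dy * dy)
  XtX <- matrix(c(sxx, sxy, 0,
                  sxy, sxx + syy, sxy,
                  0, sxy, syy), 3, 3)
  Xtf <- c(sum(dx * d$fx), sum(dy * d$fx) + sum(dx * d$fy), sum(dy * d$fy))
  theta <- tryCatch(solve(XtX, Xtf), error = function(e) rep(NA_real_, 3))
  if (anyNA(theta)) return(list(theta = rep(NA_real_, 3), sse = Inf))
  rx <- d$fx - theta[1] * dx - theta[2] * dy
  ry <- d$fy - theta[2] * dx - theta[3] * dy
  list(theta = theta, sse = sum(rx * rx) + sum(ry * ry))
}

#' Orientation of the stiffness field
#'
#' Angle (degrees, mapped to (-90, 90]) of the eigenvector of `K`
#' associated with its largest eigenvalue.
#'
#' @param model a [postural_field_model].
#' @return Angle in degrees; errors when the eigenvalues are (numerically)
#'   equal, in which case the orientation is undefined.
#' @export
field_orientation <- function(model) {
  ev <- eigen(model$K, symmetric = TRUE)
  if (abs(ev$values[1] - ev$values[2]) <= 1e-9 * max(abs(ev$values), 1e-12)) {
    stop("field_orientation: equal eigenvalues, orientation undefined")
  }
  v <- ev$vectors[, which.max(ev$values)]
  ang <- atan2(v[2], v[1]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Overall stiffness of the field
#'
#' Frobenius norm of the symmetric stiffness matrix:
#' `sqrt(kxx^2 + 2 kxy^2 + kyy^2)`.
#'
#' @param model a [postural_field_model].
#' @return Stiffness in N/cm.
#' @export
field_stiffness <- function(model) {
  sqrt(model$K[1, 1]^2 + 2 * model$K[1, 2]^2 + model$K[2, 2]^2)
}

#' Postural probe specification
#'
#' A probe displaces the held hand along a straight line in three phases:
#' a smooth ramp from rest to the plateau speed, a constant-speed plateau,
#' and a mirrored ramp back to rest, followed by a stationary buffer.
#'
#' @param direction probe direction (deg, with respect to the x-axis).
#' @param ramp_displacement,ramp_duration ramp distance (cm) and duration (s).
#' @param plateau_speed constant-phase speed (cm/s).
#' @param plateau_displacement constant-phase distance (cm).
#' @param buffer stationary buffer after the final ramp (s).
#' @param sample_rate sampling rate (Hz).
#' @return Object of class `probe_spec`.
#' @export
probe_spec <- function(direction = 0, ramp_displacement, ramp_duration,
                       plateau_speed, plateau_displacement, buffer = 0.3,
                       sample_rate = 200) {
  stopifnot(plateau_speed > 0, ramp_displacement > 0, ramp_duration > 0,
            plateau_displacement >= 0, buffer >= 0)
  structure(list(direction = direction,
                 ramp_displacement = ramp_displacement,
                 ramp_duration = ramp_duration,
                 plateau_speed = plateau_speed,
                 plateau_displacement = plateau_displacement,
                 buffer = buffer, sample_rate = sample_rate),
            class = "probe_spec")
}

#' Printed probe presets
#'
#' The three probe lengths used experimentally: 2.5 cm (0.15 cm / 0.75 s
#' ramps, 2.2 cm plateau), 4 cm (0.15 cm / 0.75 s ramps, 3.7 cm plateau) and
#' 5 cm (0.3 cm / 1.5 s ramps, 4.4 cm plateau); all with plateau speed
#' 0.375 cm/s and a 0.3 s terminal buffer. Total durations are 7.67, 11.67
#' and 15.03 s.
#'
#' @param total one of `"2.5cm"`, `"4cm"`, `"5cm"`.
#' @param direction probe direction (deg).
#' @return A [probe_spec].
#' @export
probe_preset <- function(total = c("2.5cm", "4cm", "5cm"), direction = 0) {
  total <- match.arg(total)
  switch(total,
    "2.5cm" = probe_spec(direction, 0.15, 0.75, 0.375, 2.2),
    "4cm"  = probe_spec(direction, 0.15, 0.75, 0.375, 3.7),
    "5cm"  = probe_spec(direction, 0.30, 1.50, 0.375, 4.4))
}

#' Generate the imposed probe trajectory
#'
#' Phase 1 is a quintic ramp starting at rest with zero acceleration and
#' ending at the plateau speed with zero acceleration after covering the
#' ramp displacement; phase 2 moves at constant speed over the plateau
#' displacement; phase 3 is the time-mirrored ramp to rest; a stationary
#' buffer follows. Position and velocity are continuous at every phase
#' join.
#'
#' @param spec a [probe_spec].
#' @return `data.frame` with columns `time` (s), `displacement` (cm along
#'   the probe direction) and `speed` (cm/s), plus attributes
#'   `total_duration`, `plateau_duration`, `total_displacement`.
#' @export
generate_probe_trajectory <- function(spec) {
  D <- spec$ramp_displacement; Tr <- spec$ramp_duration
  V <- spec$plateau_speed
  # quintic coefficients a3..a5 from x(T)=D, x'(T)=V, x''(T)=0 (a0=a1=a2=0)
  A <- rbind(c(Tr^3, Tr^4, Tr^5),
             c(3 * Tr^2, 4 * Tr^3, 5 * Tr^4),
             c(6 * Tr, 12 * Tr^2, 20 * Tr^3))
  a <- solve(A, c(D, V, 0))
  ramp_pos <- function(t) a[1] * t^3 + a[2] * t^4 + a[3] * t^5
  ramp_vel <- function(t) 3 * a[1] * t^2 + 4 * a[2] * t^3 + 5 * a[3] * t^4
  chk <- seq(0, Tr, length.out = 200)
  if (any(ramp_vel(chk) < -1e-9)) {
    stop("generate_probe_trajectory: infeasible ramp boundary conditions (velocity reversal)")
  }
  Tp <- spec$plateau_displacement / V
  total <- 2 * Tr + Tp + spec$buffer
  dt <- 1 / spec$sample_rate
  t <- seq(0, total, by = dt)
  x <- numeric(length(t)); v <- numeric(length(t))
  p1 <- t <= Tr
  x[p1] <- ramp_pos(t[p1]); v[p1] <- ramp_vel(t[p1])
  p2 <- t > Tr & t <= Tr + Tp
  x[p2] <- D + V * (t[p2] - Tr); v[p2] <- V
  p3 <- t > Tr + Tp & t <= 2 * Tr + Tp
  tb <- 2 * Tr + Tp - t[p3]            # mirrored ramp
  x[p3] <- 2 * D + V * Tp - ramp_pos(tb)
  v[p3] <- ramp_vel(tb)
  p4 <- t > 2 * Tr + Tp
  x[p4] <- 2 * D + V * Tp; v[p4] <- 0
  out <- data.frame(time = t, displacement = x, speed = v)
  attr(out, "total_duration") <- total
  attr(out, "plateau_duration") <- Tp
  attr(out, "total_displacement") <- 2 * D + V * Tp
  out
}

# three-parameter exponential f(d) = A exp(B d) + C fitted by profiling:
# for fixed B the problem is linear in (A, C); optimize over B in 1-D.
# The exponential is centred on mean(d) for numerical range; the x-intercept
# is invariant to that reparameterization. Falls back to a linear fit when
# the optimal |B| is below `b_tol` per cm.
.fit_force_exponential <- function(d, f, b_range = c(-4, 4), b_tol = 1e-3) {
  dbar <- mean(d); dc <- d - dbar
  prof <- function(B) {
    e <- exp(B * dc)
    se <- sum(e); see <- sum(e * e); n <- length(d)
    det <- see * n - se * se
    if (!is.finite(det) || abs(det) < 1e-250) return(list(sse = 1e280))
    sf <- sum(f); sef <- sum(e * f)
    A <- (n * sef - se * sf) / det
    C <- (see * sf - se * sef) / det
    r <- f - (A * e + C)
    sse <- sum(r * r)
    if (!is.finite(sse)) sse <- 1e280
    list(sse = sse, A = A, C = C)
  }
  op <- stats::optimize(function(B) prof(B)$sse, b_range, tol = 1e-8)
  B <- op$minimum
  if (abs(B) < b_tol) {
    lf <- stats::lm.fit(cbind(1, d), f)
    s <- lf$coefficients[2]; c0 <- lf$coefficients[1]
    if (s == 0) return(list(intercept = NA_real_, A = NA, B = 0, C = c0))
    return(list(intercept = -c0 / s, A = s, B = 0, C = c0, linear = TRUE))
  }
  pb <- prof(B)
  ratio <- -pb$C / pb$A
  intercept <- if (is.finite(ratio) && ratio > 0) log(ratio) / B + dbar
               else NA_real_
  list(intercept = intercept, A = pb$A, B = B, C = pb$C, linear = FALSE)
}

#' Estimate the null point from probe forces along one direction
#'
#' Resamples each subject's along-probe force onto a common 0.05 cm
#' displacement grid, then bootstraps: in each replicate subjects are
#' resampled with replacement, the mean force-vs-displacement profile is
#' computed, a three-parameter exponential `A exp(B d) + C` is fitted, and
#' its x-intercept `ln(-C/A)/B` recorded (a linear fit is used when the
#' optimal `|B|` degenerates below 1e-3 per cm). Returns the replicate-mean
#' intercept with a percentile confidence interval.
#'
#' @param traces `data.frame` with columns `subject`, `displacement` (cm)
#'   and `force` (N, along the probe, positive toward the pre-probe hold
#'   position).
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param grid_step displacement resampling step (cm, default 0.05).
#' @param level confidence level (default 0.95).
#' @return List with `intercept` (cm), `ci` (length 2), `replicates`,
#'   `n_subjects`, `failed_fraction`.
#' @export
estimate_null_point <- function(traces, reps = 2000, seed = 1L,
                                grid_step = 0.05, level = 0.95) {
  stopifnot(all(c("subject", "displacement", "force") %in% names(traces)))
  subjects <- unique(traces$subject)
  lo <- max(tapply(traces$displacement, traces$subject, min))
  hi <- min(tapply(traces$displacement, traces$subject, max))
  grid <- seq(ceiling(lo / grid_step) * grid_step, hi, by = grid_step)
  if (length(grid) < 5L) stop("estimate_null_point: displacement grids do not overlap")
  mat <- vapply(subjects, function(s) {
    d <- traces[traces$subject == s, ]
    stats::approx(d$displacement, d$force, xout = grid, ties = mean)$y
  }, numeric(length(grid)))
  mean_all <- rowMeans(mat)
  if (min(mean_all) > 0 || max(mean_all) < 0) {
    stop("no zero crossing: mean force does not change sign over the probe")
  }
  set.seed(seed)
  ns <- length(subjects)
  intercepts <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    fbar <- rowMeans(mat[, idx, drop = FALSE])
    intercepts[r] <- .fit_force_exponential(grid, fbar)$intercept
  }
  failed <- mean(!is.finite(intercepts))
  if (failed > 0.5) {
    stop("no zero crossing: exponential fit failed the sign condition in >50% of replicates")
  }
  ok <- intercepts[is.finite(intercepts)]
  alpha <- (1 - level) / 2
  list(intercept = mean(ok),
       ci = unname(stats::quantile(ok, c(alpha, 1 - alpha))),
       replicates = ok, n_subjects = ns, failed_fraction = failed)
}

#' Interpolate probe forces into a two-dimensional field
#'
#' Resamples each probe ray's forces on a regular radial grid (about 0.1 cm)
#' and bilinearly interpolates force components on the (radius x angle)
#' polar grid, with angular wrap-around, to estimate the postural field
#' between the measured probe directions.
#'
#' @param traces `data.frame` with columns `direction_deg`, `displacement`
#'   (cm) and `fx`, `fy` (N).
#' @param angles the measured probe directions; defaults to the 12-direction
#'   experimental set. Missing rays raise an error naming the absent angles.
#' @param step radial resampling step (cm, default 0.1).
#' @return Object of class `polar_field` with the polar grids; evaluate it
#'   at Cartesian points with [query_field()] or grid it with
#'   [field_grid()].
#' @export
interpolate_field_polar <- function(traces,
                                    angles = c(0, 15, 30, 45, 90, 135, 180,
                                               225, 270, 315, 330, 345),
                                    step = 0.1) {
  have <- unique(traces$direction_deg)
  absent <- setdiff(angles, have)
  if (length(absent) > 0L) {
    stop(sprintf("interpolate_field_polar: missing rays at %s deg",
                 paste(absent, collapse = ", ")))
  }
  angles <- sort(angles %% 360)
  r_max <- min(vapply(angles, function(a) {
    max(traces$displacement[traces$direction_deg == a])
  }, numeric(1)))
  radii <- seq(0, r_max, by = step)
  resample <- function(a, col) {
    d <- traces[traces$direction_deg == a, ]
    stats::approx(d$displacement, d[[col]], xout = radii, ties = mean,
                  rule = 2)$y
  }
  fx <- vapply(angles, resample, numeric(length(radii)), col = "fx")
  fy <- vapply(angles, resample, numeric(length(radii)), col = "fy")
  structure(list(radii = radii, angles = angles, fx = fx, fy = fy),
            class = "polar_field")
}

#' Evaluate an interpolated postural field at Cartesian points
#'
#' @param field a `polar_field` from [interpolate_field_polar()].
#' @param x,y query coordinates (cm, same origin as the probes), vectors of
#'   equal length.
#' @return `data.frame` with `x`, `y`, `fx`, `fy`; queries outside the
#'   radial support return `NA`.
#' @export
query_field <- function(field, x, y) {
  r <- sqrt(x^2 + y^2)
  th <- (atan2(y, x) * 180 / pi) %% 360
  ang <- field$angles; na <- length(ang)
  out_fx <- numeric(length(x)); out_fy <- numeric(length(x))
  for (i in seq_along(x)) {
    if (r[i] > max(field$radii) + 1e-9) { out_fx[i] <- out_fy[i] <- NA; next }
    # bracketing angles with wrap-around
    j_hi <- findInterval(th[i], ang) + 1L
    j_lo <- j_hi - 1L
    if (j_lo == 0L) { j_lo <- na; a_lo <- ang[na] - 360 } else a_lo <- ang[j_lo]
    if (j_hi > na) { j_hi <- 1L; a_hi <- ang[1] + 360 } else a_hi <- ang[j_hi]
    w <- if (a_hi > a_lo) (th[i] - a_lo) / (a_hi - a_lo) else 0
    interp_r <- function(mat, j) {
      stats::approx(field$radii, mat[, j], xout = min(r[i], max(field$radii)),
                    rule = 2)$y
    }
    out_fx[i] <- (1 - w) * interp_r(field$fx, j_lo) + w * interp_r(field$fx, j_hi)
    out_fy[i] <- (1 - w) * interp_r(field$fy, j_lo) + w * interp_r(field$fy, j_hi)
  }
  data.frame(x = x, y = y, fx = out_fx, fy = out_fy)
}

#' Cartesian grid rendering of an interpolated field
#'
#' @param field a `polar_field`.
#' @param step grid step (cm, default 0.25).
#' @return `data.frame` of grid points inside the radial support with the
#'   interpolated `fx`, `fy`.
#' @export
field_grid <- function(field, step = 0.25) {
  r_max <- max(field$radii)
  g <- seq(-r_max, r_max, by = step)
  pts <- expand.grid(x = g, y = g)
  out <- query_field(field, pts$x, pts$y)
  out[stats::complete.cases(out), ]
}
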