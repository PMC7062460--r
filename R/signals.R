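#' Rectify and smooth a signal with a Gaussian kernel
#'
#' Full-wave rectifies a signed trace and convolves it with a discrete
#' Gaussian kernel, the standard preprocessing for intramuscular EMG before
#' trial analysis (kernel SD 20 ms for reach EMG, 200 ms for slow finger
#' tracking). The kernel is truncated at +/- 4 SD and renormalized to unit
#' sum; near the edges the kernel is renormalized over the available samples
#' rather than padding, so constants are preserved exactly and interior
#' signal mass is conserved.
#'
#' @param x numeric vector, uniformly sampled signed signal.
#' @param kernel_sd kernel standard deviation in seconds (> one sample step).
#' @param dt sample step in seconds.
#' @param rectify take `abs(x)` first (default `TRUE`).
#' @return Numeric vector, same length as `x`, nonnegative when
#'   `rectify = TRUE`.
#' @examples
#' x <- c(rep(0, 50), rep(1, 20), rep(0, 50))
#' y <- rectify_and_smooth(x, kernel_sd = 0.02, dt = 0.001)
#' @export
rectify_and_smooth <- function(x, kernel_sd, dt, rectify = TRUE) {
  if (!is.numeric(kernel_sd) || kernel_sd <= 0) {
    stop("rectify_and_smooth: kernel_sd must be > 0")
  }
  if (!is.numeric(dt) || dt <= 0) stop("rectify_and_smooth: dt must be > 0")
  if (kernel_sd < dt) {
    stop("rectify_and_smooth: kernel_sd shorter than one sample step")
  }
  if (rectify) x <- abs(x)
  sd_samp <- kernel_sd / dt
  half <- ceiling(4 * sd_samp)
  kern <- stats::dnorm(seq(-half, half), sd = sd_samp)
  kern <- kern / sum(kern)
  n <- length(x)
  # full convolution, then edge renormalization by the in-range kernel mass
  y <- stats::convolve(x, rev(kern), type = "open")[(half + 1):(half + n)]
  y <- y / .edge_mass(n, kern, half)
  # FFT convolution leaves O(eps) ringing; a rectified signal is nonnegative
  if (rectify) y <- pmax(y, 0)
  y
}

# kernel mass falling inside the signal support for each output sample
.edge_mass <- function(n, kern, half) {
  cs <- cumsum(kern)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, half + 1L - (i - 1L))
    hi <- min(length(kern), half + 1L + (n - i))
    mass[i] <- cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
  }
  mass
}

#' Normalize EMG traces for one muscle
#'
#' Applies the task normalization: the mean activity over a reference hold
#' window (e.g. the central home location or the 12 degree finger hold) is
#' set to zero, and the maximum activity across the whole task is set to
#' one. The affine transform `(x - offset) / scale` is returned so it can be
#' inverted.
#'
#' @param trials list of [ts_trial] objects for one muscle.
#' @param channel EMG channel name present in every trial.
#' @param ref_start,ref_duration reference window (seconds relative to each
#'   trial's onset) whose mean activity defines the zero level.
#' @return List with `trials` (normalized copies), `offset` and `scale`.
#' @export
normalize_emg <- function(trials, channel, ref_start, ref_duration) {
  stopifnot(length(trials) >= 1L)
  ref_means <- vapply(trials, function(tr) {
    if (is.na(tr$onset)) stop("normalize_emg: trial has no onset event")
    window_mean(trial_channel(tr, channel), tr$time,
                tr$onset + ref_start, ref_duration,
                label = format_trial_id(tr))
  }, numeric(1))
  offset <- mean(ref_means)
  task_max <- max(vapply(trials, function(tr) {
    max(trial_channel(tr, channel) - offset)
  }, numeric(1)))
  if (task_max <= 0) {
    stop("normalize_emg: no positive activity after offsetting; scale undefined")
  }
  out <- lapply(trials, function(tr) {
    tr$channels[[channel]] <- (trial_channel(tr, channel) - offset) / task_max
    tr
  })
  list(trials = out, offset = offset, scale = task_max)
}

#' Detect movement onset and offset from a speed trace
#'
#' Onset is the first sample at which speed reaches the onset threshold
#' (1 cm/s convention). Offset is the first time after peak speed at which
#' speed falls below the offset threshold (3.5 cm/s convention) and stays
#' below it for a dwell period, which rejects transient re-crossings from
#' micro-pauses.
#'
#' @param speed numeric vector of speed magnitude (cm/s).
#' @param time numeric vector of sample times (s).
#' @param onset_threshold,offset_threshold thresholds in cm/s (> 0).
#' @param dwell minimum sub-threshold dwell in seconds (default 0.05).
#' @return Named numeric vector `c(onset = ..., offset = ...)` in seconds.
#' @export
detect_onset_offset <- function(speed, time, onset_threshold = 1,
                                offset_threshold = 3.5, dwell = 0.05) {
  stopifnot(onset_threshold > 0, offset_threshold > 0,
            length(speed) == length(time))
  above <- which(speed >= onset_threshold)
  if (length(above) == 0L) stop("no movement detected")
  i_on <- above[1]
  i_peak <- which.max(speed)
  dt <- (time[length(time)] - time[1]) / (length(time) - 1L)
  n_dwell <- max(1L, ceiling(dwell / dt))
  below <- speed < offset_threshold
  i_off <- NA_integer_
  idx <- which(below & seq_along(speed) > i_peak)
  for (i in idx) {
    run_end <- min(length(speed), i + n_dwell - 1L)
    if (all(below[i:run_end])) { i_off <- i; break }
  }
  if (is.na(i_off)) stop("no movement detected: speed never settles below offset threshold")
  if (!(time[i_on] < time[i_off])) stop("no movement detected")
  c(onset = time[i_on], offset = time[i_off])
}

#' Mean of a trace over a half-open time window
#'
#' Arithmetic mean of the samples whose timestamps fall in
#' `[start, start + duration)`.
#'
#' @param x numeric samples.
#' @param time sample times in seconds.
#' @param start window start (absolute seconds).
#' @param duration window duration in seconds.
#' @param label trial label used in error messages.
#' @return Scalar mean.
#' @export
window_mean <- function(x, time, start, duration, label = "<trace>") {
  stopifnot(length(x) == length(time), duration > 0)
  if (start < time[1] - 1e-12 || start + duration > time[length(time)] + 1e-12) {
    stop(sprintf("window [%.3f, %.3f) s outside trace for trial %s",
                 start, start + duration, label))
  }
  keep <- time >= start - 1e-12 & time < start + duration - 1e-12
  if (!any(keep)) {
    stop(sprintf("window [%.3f, %.3f) s contains no samples for trial %s",
                 start, start + duration, label))
  }
  mean(x[keep])
}

#' Window mean anchored to a trial event
#'
#' @param trial a [ts_trial] with the anchoring event set.
#' @param channel channel name.
#' @param start window start relative to the anchor (s; negative = before).
#' @param duration window duration (s).
#' @param anchor `"onset"` or `"offset"`.
#' @return Scalar mean.
#' @export
trial_window_mean <- function(trial, channel, start, duration,
                              anchor = c("onset", "offset")) {
  anchor <- match.arg(anchor)
  ev <- trial[[anchor]]
  if (is.na(ev)) stop(sprintf("trial %s: %s event not set",
                              format_trial_id(trial), anchor))
  window_mean(trial_channel(trial, channel), trial$time, ev + start, duration,
              label = format_trial_id(trial))
}

#' Average channel-trial forces into a baseline trace
#'
#' Aligns each null-period channel trial at movement onset and averages the
#' force traces sample-wise, truncating to the shortest aligned trace. The
#' result is subtracted from subsequent channel-trial forces so that residual
#' forces reflect the perturbation under study rather than apparatus bias.
#'
#' @param trials list of [ts_trial] null-period channel trials with onsets set.
#' @param channel force channel name.
#' @return List with `offsets` (s, aligned time relative to onset) and
#'   `values` (mean force).
#' @export
baseline_force <- function(trials, channel = "force_x") {
  if (length(trials) == 0L) stop("baseline_force: no null-period trials available")
  aligned <- lapply(trials, function(tr) {
    if (is.na(tr$onset)) stop("baseline_force: trial has no onset")
    list(t = tr$time - tr$onset, x = trial_channel(tr, channel))
  })
  lo <- max(vapply(aligned, function(a) a$t[1], numeric(1)))
  hi <- min(vapply(aligned, function(a) a$t[length(a$t)], numeric(1)))
  if (hi <= lo) stop("baseline_force: trials do not overlap after alignment")
  dt <- trial_dt(trials[[1]])
  grid <- seq(lo, hi, by = dt)
  mat <- vapply(aligned, function(a) {
    stats::approx(a$t, a$x, xout = grid)$y
  }, numeric(length(grid)))
  list(offsets = grid, values = rowMeans(mat))
}

#' Subtract a baseline force trace from a channel trial
#'
#' @param trial a [ts_trial] with onset set.
#' @param baseline result of [baseline_force()].
#' @param channel force channel to correct.
#' @return The trial with `channel` replaced by the baseline-corrected trace;
#'   samples outside the baseline's aligned support are left unchanged.
#' @export
subtract_baseline <- function(trial, baseline, channel = "force_x") {
  if (is.na(trial$onset)) stop("subtract_baseline: trial has no onset")
  rel <- trial$time - trial$onset
  corr <- stats::approx(baseline$offsets, baseline$values, xout = rel,
                        yleft = 0, yright = 0)$y
  trial$channels[[channel]] <- trial_channel(trial, channel) - corr
  trial
}
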