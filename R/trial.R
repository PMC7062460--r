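#' Per-trial multichannel time series
#'
#' Container for one trial's uniformly sampled recordings: hand position and
#' velocity (cm, cm/s), handle forces (N), and/or normalized EMG channels,
#' together with detected movement onset/offset events and trial metadata.
#'
#' @param time numeric vector of sample times in seconds; strictly increasing
#'   with a constant step (relative tolerance 1e-9).
#' @param channels named list of numeric vectors, each the same length as
#'   `time`. Conventional names: `position_x`, `position_y` (cm),
#'   `velocity_x`, `velocity_y` (cm/s), `force_x`, `force_y` (N),
#'   `emg_<muscle>` (normalized a.u.).
#' @param onset,offset movement onset/offset in seconds, or `NULL` when not
#'   yet detected. When both are set, `onset < offset` is required.
#' @param meta named list of trial metadata (subject, arm, trial index,
#'   condition, perturbation magnitude, ...).
#'
#' @return An object of class `ts_trial`.
#' @examples
#' t <- seq(0, 1, by = 0.005)
#' tr <- ts_trial(t, list(force_x = sin(2 * pi * t)), onset = 0.2, offset = 0.8)
#' tr
#' @export
ts_trial <- function(time, channels, onset = NULL, offset = NULL, meta = list()) {
  time <- as.numeric(time)
  if (length(time) < 2L) stop("ts_trial: need at least two samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop("ts_trial: time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt))) {
    stop("ts_trial: sampling step is not constant (rel. tol 1e-9)")
  }
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stop("ts_trial: channels must be a named list")
  }
  for (nm in names(channels)) {
    channels[[nm]] <- as.numeric(channels[[nm]])
    if (length(channels[[nm]]) != length(time)) {
      stop(sprintf("ts_trial: channel '%s' length differs from time", nm))
    }
  }
  if (!is.null(onset) && !is.null(offset) && !(onset < offset)) {
    stop("ts_trial: onset must precede offset")
  }
  structure(
    list(time = time, channels = channels,
         onset = if (is.null(onset)) NA_real_ else as.numeric(onset),
         offset = if (is.null(offset)) NA_real_ else as.numeric(offset),
         meta = meta),
    class = "ts_trial")
}

#' @export
print.ts_trial <- function(x, ...) {
  cat(sprintf("<ts_trial> %d samples @ %.4g Hz, channels: %s\n",
              length(x$time), 1 / trial_dt(x),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  t in [%.3f, %.3f] s; onset %s, offset %s\n",
              x$time[1], x$time[length(x$time)],
              ifelse(is.na(x$onset), "unset", sprintf("%.3f s", x$onset)),
              ifelse(is.na(x$offset), "unset", sprintf("%.3f s", x$offset))))
  invisible(x)
}

#' Sampling step of a trial
#' @param trial a [ts_trial] object.
#' @return The sample step in seconds.
#' @export
trial_dt <- function(trial) {
  (trial$time[length(trial$time)] - trial$time[1]) / (length(trial$time) - 1L)
}

#' Extract a channel from a trial
#' @param trial a [ts_trial] object.
#' @param channel channel name.
#' @return Numeric vector of samples.
#' @export
trial_channel <- function(trial, channel) {
  if (!channel %in% names(trial$channels)) {
    stop(sprintf("trial %s: channel '%s' not present",
                 format_trial_id(trial), channel))
  }
  trial$channels[[channel]]
}

format_trial_id <- function(trial) {
  m <- trial$meta
  id <- c(m$subject, m$trial)
  if (length(id) == 0L) "<unlabelled>" else paste(id, collapse = "/")
}

#' Analysis window specification
#'
#' Defines the hold-period windows, integration bounds and exclusion cutoff
#' used by the integration statistic. All windows are half-open
#' `[start, start + duration)`; `h1` is anchored to movement onset and `h2`
#' to movement offset. Negative starts lie before the anchor.
#'
#' @param h1_start,h1_duration pre-movement hold window, seconds relative to
#'   onset.
#' @param h2_start,h2_duration post-movement hold window, seconds relative to
#'   offset.
#' @param integration_lead seconds before onset at which the move-period
#'   integral begins (captures command changes that precede kinematics).
#' @param max_duration movement-duration exclusion cutoff in seconds, or `NA`
#'   for none.
#' @param onset_threshold,offset_threshold speed thresholds (cm/s) for event
#'   detection when events are not already stored on the trial.
#' @return An object of class `window_spec`.
#' @seealso [window_preset()] for the named conventions used throughout.
#' @export
window_spec <- function(h1_start, h1_duration, h2_start, h2_duration,
                        integration_lead = 0, max_duration = NA_real_,
                        onset_threshold = 1, offset_threshold = 3.5) {
  stopifnot(h1_duration > 0, h2_duration > 0, integration_lead >= 0)
  if (!is.na(max_duration) && max_duration <= 0) {
    stop("window_spec: max_duration must be positive or NA")
  }
  structure(
    list(h1_start = h1_start, h1_duration = h1_duration,
         h2_start = h2_start, h2_duration = h2_duration,
         integration_lead = integration_lead, max_duration = max_duration,
         onset_threshold = onset_threshold,
         offset_threshold = offset_threshold),
    class = "window_spec")
}

#' Named window conventions
#'
#' Stored window presets for the three experimental preparations:
#'
#' * `"monkey_reach_out"`: h1 = \[-700, -350\] ms re onset, h2 = \[+300, +450\] ms
#'   re offset, integration lead 140 ms, 850 ms duration cutoff.
#' * `"monkey_reach_back"`: as above but h1 = \[-300, -200\] ms re onset.
#' * `"monkey_finger"`: h1 = 400 ms window starting 1 s before onset,
#'   h2 = 200 ms window starting 700 ms after offset, lead 150 ms.
#' * `"human_force"`: h1 = 100 ms starting 500 ms before onset, h2 = 100 ms
#'   starting 900 ms after offset, no lead; onset/offset speed thresholds
#'   1 and 3.5 cm/s.
#'
#' @param name one of the preset names above.
#' @return A [window_spec] object.
#' @export
window_preset <- function(name = c("monkey_reach_out", "monkey_reach_back",
                                   "monkey_finger", "human_force")) {
  name <- match.arg(name)
  switch(name,
    monkey_reach_out = window_spec(-0.700, 0.350, 0.300, 0.150,
                                   integration_lead = 0.140,
                                   max_duration = 0.850),
    monkey_reach_back = window_spec(-0.300, 0.100, 0.300, 0.150,
                                    integration_lead = 0.140,
                                    max_duration = 0.850),
    monkey_finger = window_spec(-1.000, 0.400, 0.700, 0.200,
                                integration_lead = 0.150),
    human_force = window_spec(-0.500, 0.100, 0.900, 0.100,
                              integration_lead = 0,
                              onset_threshold = 1, offset_threshold = 3.5))
}
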