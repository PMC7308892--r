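#' Ground-truth trajectories for a simulated subject
#'
#' Builds the per-sample ground truth that drives the signal generator:
#' the SpO2 trajectory (piecewise-constant plateaus joined by linear
#' ramps), the heart-rate trajectory (baseline plus activity offsets), the
#' activity schedule of the configured protocol, and motion-artefact event
#' times drawn from a Poisson process with activity-dependent rate.
#'
#' @param config A [sim_config()] object.
#' @return A data frame of class `ground_truth` with columns `time_s`,
#'   `spo2_true` (%), `heart_rate_true` (beats/min), `activity` and
#'   `artefact_mask`; the artefact event table (onset/duration) is
#'   attached as attribute `"artefact_events"` and the sampling rate as
#'   `"sampling_rate_hz"`.
#' @examples
#' tr <- build_truth(sim_config(protocol = "volunteer_hypoxemia", seed = 1))
#' range(tr$spo2_true)
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  total <- sum(config$spo2_plateaus$duration_s)
  if (total < protocol_min_duration(config$protocol))
    stop("protocol '", config$protocol, "' requires a duration of at least ",
         protocol_min_duration(config$protocol), " s; got ", total, " s")
  set.seed(config$seed)

  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs

  ## SpO2: plateau level, then overwrite the first ramp_s of each plateau
  ## after the first with a linear ramp from the previous level.
  lev <- config$spo2_plateaus$level
  dur <- config$spo2_plateaus$duration_s
  bounds <- cumsum(dur)
  spo2 <- lev[pmin(findInterval(t, c(0, bounds)), length(lev))]
  for (i in seq_along(bounds)[-length(bounds)]) {
    ramp <- min(config$ramp_s, dur[i + 1])
    if (ramp <= 0) next
    sel <- t >= bounds[i] & t < bounds[i] + ramp
    spo2[sel] <- lev[i] + (lev[i + 1] - lev[i]) * (t[sel] - bounds[i]) / ramp
  }

  ## Activity per sample from the protocol's segment schedule.
  sched <- protocol_schedule(config)
  abounds <- cumsum(sched$duration_s)
  aidx <- pmin(findInterval(t, c(0, abounds)), nrow(sched))
  activity <- factor(sched$activity[aidx], levels = activity_levels)

  hr <- config$heart_rate_bpm +
    unname(config$heart_rate_activity_offsets[as.character(activity)])

  ## Motion artefacts: per activity segment, a Poisson number of events at
  ## the activity's rate; each event has a uniform onset and a 0.5-2 s
  ## duration.
  ev_on <- numeric(0); ev_dur <- numeric(0)
  seg_start <- c(0, abounds[-length(abounds)])
  for (i in seq_len(nrow(sched))) {
    rate <- config$motion_rate_per_min[[sched$activity[i]]]
    k <- stats::rpois(1, rate / 60 * sched$duration_s[i])
    if (k > 0) {
      ev_on <- c(ev_on, sort(stats::runif(k, seg_start[i], abounds[i])))
      ev_dur <- c(ev_dur, stats::runif(k, 0.5, 2))
    }
  }
  mask <- rep(FALSE, n)
  for (j in seq_along(ev_on)) {
    sel <- t >= ev_on[j] & t < ev_on[j] + ev_dur[j]
    mask[sel] <- TRUE
  }

  out <- data.frame(time_s = t, spo2_true = spo2, heart_rate_true = hr,
                    activity = activity, artefact_mask = mask)
  attr(out, "artefact_events") <- data.frame(onset_s = ev_on,
                                             duration_s = ev_dur)
  attr(out, "sampling_rate_hz") <- fs
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Invert the linear SpO2 calibration
#'
#' The calibration line is `SpO2 = a * ROS + b`; its inverse,
#' `ROS = (SpO2 - b) / a`, is what the signal generator uses to encode a
#' target saturation into the red/infrared amplitude ratio.
#'
#' @param spo2 Saturation values (%).
#' @param a Slope (% per unit ROS); must be nonzero.
#' @param b Intercept (%).
#' @return ROS values (dimensionless), vectorised over `spo2`.
#' @examples
#' spo2_to_ros(90.1, a = -26.8, b = 116.9)  # 1
#' @seealso [apply_calibration()] for the forward map.
#' @export
spo2_to_ros <- function(spo2, a, b) {
  if (!is.finite(a) || a == 0)
    stop("degenerate calibration: slope 'a' must be nonzero")
  (spo2 - b) / a
}
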