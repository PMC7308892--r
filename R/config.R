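#' Simulation configuration for a synthetic PPG subject
#'
#' Builds and validates the parameter set that fully determines one
#' simulated subject: the desaturation protocol, the pulsatile signal
#' model, artefact and noise levels, and the ground-truth calibration line
#' whose inverse is wired into the generator.
#'
#' Two protocols are supported. `"volunteer_hypoxemia"` emulates a
#' stepwise normobaric hypoxemic challenge: SpO2 plateaus (default 97, 88
#' and 82%) joined by linear ramps, while the subject cycles through
#' walking-in-place, sitting, standing and lying.
#' `"patient_daily_activity"` emulates a daily-activity sequence (lying,
#' sitting, standing, a 6-min walk, cycling) with activity-dependent
#' desaturation plateaus.
#'
#' @param protocol Desaturation/activity protocol.
#' @param sampling_rate_hz Optical sampling rate (samples/s). Must be at
#'   least four times the maximum cardiac frequency.
#' @param spo2_plateaus Data frame with columns `level` (%) and
#'   `duration_s`; defaults depend on the protocol. All levels must lie in
#'   \[70, 100\].
#' @param ramp_s Duration of the linear SpO2 ramp joining consecutive
#'   plateaus (s).
#' @param heart_rate_bpm Baseline heart rate (beats/min).
#' @param heart_rate_activity_offsets Named additive offsets (beats/min)
#'   per activity.
#' @param perfusion_ac_over_dc Baseline pulsatile fraction of the infrared
#'   channel: peak-to-trough pulsatile amplitude divided by the DC level.
#' @param true_slope_a,true_intercept_b Ground-truth calibration line
#'   `SpO2 = a * ROS + b`; `a` must be negative (higher ROS corresponds to
#'   lower SpO2).
#' @param motion_rate_per_min Named artefact event rates (events/min) per
#'   activity.
#' @param artefact_amplitude_range Motion-artefact amplitude as a multiple
#'   of the pulsatile amplitude (uniform range).
#' @param ambient_drift_amplitude Amplitude of the slow ambient-light
#'   drift (arbitrary units; the channels' DC levels are ~1000).
#' @param mains_hz Power-line frequency (Hz).
#' @param mains_amplitude Amplitude of the mains component in the ambient
#'   channel (arbitrary units).
#' @param sensor_noise_sd Standard deviation of additive white sensor
#'   noise per optical channel (arbitrary units).
#' @param reference_noise_sd Standard deviation of the continuous
#'   reference oximeter's AR(1) noise (% SpO2).
#' @param reference_ar1_phi Lag-1 autocorrelation of the reference noise
#'   at 1 Hz.
#' @param abga_noise_sd Standard deviation of arterial blood-gas SaO2
#'   noise (% SaO2).
#' @param dc_ir,dc_red DC optical intensity of the infrared and red
#'   channels (arbitrary units).
#' @param subject_id Subject identifier.
#' @param seed Integer seed; every stochastic element of the subject is a
#'   deterministic function of it.
#'
#' @return An object of class `sim_config` (a validated named list). The
#'   total protocol duration is `sum(spo2_plateaus$duration_s)`.
#' @examples
#' cfg <- sim_config(protocol = "volunteer_hypoxemia", seed = 7)
#' cfg$spo2_plateaus
#' @export
sim_config <- function(protocol = c("patient_daily_activity",
                                    "volunteer_hypoxemia"),
                       sampling_rate_hz = 100,
                       spo2_plateaus = NULL,
                       ramp_s = 30,
                       heart_rate_bpm = 72,
                       heart_rate_activity_offsets = c(lying = -7,
                                                       sitting = 0,
                                                       standing = 6,
                                                       walking = 22,
                                                       cycling = 30),
                       perfusion_ac_over_dc = 0.02,
                       true_slope_a = -26.8,
                       true_intercept_b = 116.9,
                       motion_rate_per_min = c(lying = 0.5, sitting = 0.5,
                                               standing = 0.5, walking = 6,
                                               cycling = 2),
                       artefact_amplitude_range = c(5, 20),
                       ambient_drift_amplitude = 5,
                       mains_hz = 50,
                       mains_amplitude = 1,
                       sensor_noise_sd = 0.5,
                       reference_noise_sd = 0.5,
                       reference_ar1_phi = 0.8,
                       abga_noise_sd = 0.5,
                       dc_ir = 1000,
                       dc_red = 800,
                       subject_id = "S01",
                       seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(spo2_plateaus))
    spo2_plateaus <- default_plateaus(protocol)
  spo2_plateaus <- as.data.frame(spo2_plateaus)
  if (!all(c("level", "duration_s") %in% names(spo2_plateaus)))
    stop("'spo2_plateaus' needs columns 'level' and 'duration_s'")

  cfg <- list(protocol = protocol,
              sampling_rate_hz = sampling_rate_hz,
              spo2_plateaus = spo2_plateaus,
              ramp_s = ramp_s,
              heart_rate_bpm = heart_rate_bpm,
              heart_rate_activity_offsets = heart_rate_activity_offsets,
              perfusion_ac_over_dc = perfusion_ac_over_dc,
              true_slope_a = true_slope_a,
              true_intercept_b = true_intercept_b,
              motion_rate_per_min = motion_rate_per_min,
              artefact_amplitude_range = artefact_amplitude_range,
              ambient_drift_amplitude = ambient_drift_amplitude,
              mains_hz = mains_hz,
              mains_amplitude = mains_amplitude,
              sensor_noise_sd = sensor_noise_sd,
              reference_noise_sd = reference_noise_sd,
              reference_ar1_phi = reference_ar1_phi,
              abga_noise_sd = abga_noise_sd,
              dc_ir = dc_ir,
              dc_red = dc_red,
              subject_id = subject_id,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  lv <- cfg$spo2_plateaus$level
  if (any(lv < 70 | lv > 100))
    stop("SpO2 plateau levels must lie within [70, 100]")
  if (any(cfg$spo2_plateaus$duration_s <= 0))
    stop("plateau durations must be positive")
  miss <- setdiff(activity_levels, names(cfg$heart_rate_activity_offsets))
  if (length(miss))
    stop("heart_rate_activity_offsets missing: ", paste(miss, collapse = ", "))
  miss <- setdiff(activity_levels, names(cfg$motion_rate_per_min))
  if (length(miss))
    stop("motion_rate_per_min missing: ", paste(miss, collapse = ", "))
  hr_max <- cfg$heart_rate_bpm + max(cfg$heart_rate_activity_offsets)
  if (cfg$sampling_rate_hz < 4 * hr_max / 60)
    stop("sampling_rate_hz must be at least 4x the maximum heart-rate ",
         "frequency (", signif(4 * hr_max / 60, 3), " Hz)")
  if (!(cfg$true_slope_a < 0))
    stop("true_slope_a must be negative: higher ROS corresponds to lower SpO2")
  if (cfg$perfusion_ac_over_dc <= 0 || cfg$perfusion_ac_over_dc >= 0.5)
    stop("perfusion_ac_over_dc must be in (0, 0.5)")
  if (abs(cfg$reference_ar1_phi) >= 1)
    stop("reference_ar1_phi must satisfy |phi| < 1")
  if (cfg$dc_ir <= 0 || cfg$dc_red <= 0)
    stop("channel DC levels must be positive")
  invisible(cfg)
}

default_plateaus <- function(protocol) {
  switch(protocol,
    volunteer_hypoxemia = data.frame(
      level = c(97, 88, 82),
      duration_s = c(180, 180, 180)),
    patient_daily_activity = data.frame(
      level = c(94, 94, 93, 88, 86),
      duration_s = c(180, 180, 180, 360, 300)))
}

## Activity schedule as a segment table (activity, duration_s). For the
## patient protocol the five activities take fixed fractions of the total
## duration (so custom plateau tables rescale the schedule); volunteers
## cycle through 45-s bouts of walking/sitting/standing/lying within each
## plateau.
protocol_schedule <- function(cfg) {
  total <- sum(cfg$spo2_plateaus$duration_s)
  if (cfg$protocol == "patient_daily_activity") {
    frac <- c(lying = 0.15, sitting = 0.15, standing = 0.15,
              walking = 0.30, cycling = 0.25)
    data.frame(activity = names(frac), duration_s = unname(frac) * total,
               stringsAsFactors = FALSE)
  } else {
    bout <- 45
    segs <- list()
    cycle <- c("walking", "sitting", "standing", "lying")
    for (d in cfg$spo2_plateaus$duration_s) {
      left <- d; k <- 1L
      while (left > 1e-9) {
        take <- min(bout, left)
        segs[[length(segs) + 1L]] <-
          data.frame(activity = cycle[(k - 1L) %% 4L + 1L],
                     duration_s = take, stringsAsFactors = FALSE)
        left <- left - take; k <- k + 1L
      }
    }
    do.call(rbind, segs)
  }
}

protocol_min_duration <- function(protocol) {
  switch(protocol, patient_daily_activity = 300, volunteer_hypoxemia = 180)
}

#' Signal-processing parameters
#'
#' Parameters of the window-level DSP chain. The defaults reproduce the
#' reference configuration: a fourth-order 0.5--5 Hz band-pass for AC
#' extraction, cardiac-gated averaging over 40-s windows, and rejection of
#' windows whose signal-quality index falls below 70%.
#'
#' @param bandpass_low_hz,bandpass_high_hz Band-pass corner frequencies
#'   (Hz); 0.5--5 Hz covers cardiac fundamentals from 30 to 300 beats/min.
#' @param filter_order Overall band-pass order (must be even; the filter
#'   is applied forward-backward, so the net response is zero-phase).
#' @param window_s Analysis window length (s).
#' @param hop_s Hop between consecutive window starts (s).
#' @param min_beats_per_window Minimum number of usable beat segments; a
#'   window below this is rejected as `too_few_beats`.
#' @param refractory_s Minimum separation between detected beats (s).
#' @param sqi_threshold_pct Signal-quality rejection threshold; a window
#'   with SQI strictly below this value is rejected (SQI exactly at the
#'   threshold is retained).
#' @param ambient_lowpass_hz Upper edge of the sub-cardiac band used to
#'   estimate the ambient-light coupling gain (Hz).
#' @return An object of class `processing_params`.
#' @examples
#' processing_params()
#' @export
processing_params <- function(bandpass_low_hz = 0.5,
                              bandpass_high_hz = 5.0,
                              filter_order = 4L,
                              window_s = 40,
                              hop_s = 10,
                              min_beats_per_window = 20L,
                              refractory_s = 0.33,
                              sqi_threshold_pct = 70,
                              ambient_lowpass_hz = 0.4) {
  if (!(bandpass_low_hz > 0 && bandpass_low_hz < bandpass_high_hz))
    stop("need 0 < bandpass_low_hz < bandpass_high_hz")
  if (filter_order < 2 || filter_order %% 2 != 0)
    stop("filter_order must be a positive even integer")
  if (window_s <= 0 || hop_s <= 0)
    stop("window_s and hop_s must be positive")
  if (sqi_threshold_pct < 0 || sqi_threshold_pct > 100)
    stop("sqi_threshold_pct must lie in [0, 100]")
  structure(list(bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 filter_order = as.integer(filter_order),
                 window_s = window_s,
                 hop_s = hop_s,
                 min_beats_per_window = as.integer(min_beats_per_window),
                 refractory_s = refractory_s,
                 sqi_threshold_pct = sqi_threshold_pct,
                 ambient_lowpass_hz = ambient_lowpass_hz),
            class = "processing_params")
}

#' Full pipeline configuration
#'
#' Bundles the simulation, processing and evaluation parameters that
#' determine one end-to-end experiment, together with the cohort size and
#' master seed. Serialises losslessly to JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param simulation A [sim_config()] object used as the cohort template.
#' @param processing A [processing_params()] object.
#' @param n_subjects Number of simulated subjects (>= 2 for leave-one-out
#'   calibration).
#' @param max_range_pct Stable-reference criterion: a window is discarded
#'   when its within-window continuous-reference range (max - min) exceeds
#'   this many percentage points.
#' @param max_gap_s Maximum distance between a blood-gas sample and the
#'   centre of the retained window it is paired with (s).
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   every stage's intermediates (recordings, references, truth, windows,
#'   report) there as CSV/JSON.
#' @param seed Master seed for the experiment.
#' @return An object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(n_subjects = 3, seed = 42)
#' @export
pipeline_config <- function(simulation = sim_config(),
                            processing = processing_params(),
                            n_subjects = 15L,
                            max_range_pct = 2,
                            max_gap_s = 30,
                            output_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(simulation, "sim_config"),
            inherits(processing, "processing_params"))
  if (n_subjects < 2)
    stop("n_subjects must be >= 2 (leave-one-out calibration)")
  structure(list(simulation = simulation,
                 processing = processing,
                 n_subjects = as.integer(n_subjects),
                 max_range_pct = max_range_pct,
                 max_gap_s = max_gap_s,
                 output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulated-subject configuration (", x$protocol, ")\n", sep = "")
  cat("  duration: ", sum(x$spo2_plateaus$duration_s), " s @ ",
      x$sampling_rate_hz, " Hz\n", sep = "")
  cat("  SpO2 plateaus: ",
      paste(sprintf("%g%% x %gs", x$spo2_plateaus$level,
                    x$spo2_plateaus$duration_s), collapse = ", "), "\n",
      sep = "")
  cat("  truth line: SpO2 = ", x$true_slope_a, " * ROS + ",
      x$true_intercept_b, "\n", sep = "")
  cat("  perfusion AC/DC: ", x$perfusion_ac_over_dc,
      ", sensor noise sd: ", x$sensor_noise_sd,
      ", seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.processing_params <- function(x, ...) {
  cat("PPG processing parameters\n")
  cat("  band-pass: ", x$bandpass_low_hz, "-", x$bandpass_high_hz,
      " Hz, order ", x$filter_order, " (zero-phase)\n", sep = "")
  cat("  window: ", x$window_s, " s, hop ", x$hop_s, " s, min beats ",
      x$min_beats_per_window, "\n", sep = "")
  cat("  SQI rejection threshold: ", x$sqi_threshold_pct, "%\n", sep = "")
  invisible(x)
}
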