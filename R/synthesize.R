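## Cardiac pulse waveform: one period on u in [0, 1), built from two
## Gaussians (fast systolic upstroke, slower diastolic hump), normalised
## to zero mean over a period and unit peak-to-trough amplitude. Zero mean
## keeps the window-average (DC) of the modelled channel equal to its
## configured DC level; unit peak-to-trough makes the configured
## perfusion fraction the AC/DC ratio by construction.
pulse_waveform <- local({
  mu1 <- 0.22; s1 <- 0.07; a1 <- 1.0    # systolic peak
  mu2 <- 0.52; s2 <- 0.13; a2 <- 0.40   # diastolic hump
  raw <- function(u) {
    v <- 0
    for (k in -1:1)                      # wrap Gaussian tails across periods
      v <- v + a1 * exp(-((u - k - mu1)^2) / (2 * s1^2)) +
               a2 * exp(-((u - k - mu2)^2) / (2 * s2^2))
    v
  }
  ug <- seq(0, 1, length.out = 4097)[-4097]
  rg <- raw(ug)
  m <- mean(rg)
  amp <- max(rg) - min(rg)
  function(u) (raw(u %% 1) - m) / amp
})

## Deterministic sub-stream seeds derived from a subject seed, kept within
## 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

## Unit-amplitude damped oscillation of length n samples.
damped_osc <- function(n, fs, freq_hz, tau_s, phase = 0) {
  tt <- (seq_len(n) - 1) / fs
  exp(-tt / tau_s) * sin(2 * pi * freq_hz * tt + phase)
}

#' Synthesize a two-wavelength PPG recording from ground truth
#'
#' Realises the optical measurement model on a ground-truth trajectory.
#' For each sample,
#' `ppg_ir = dc_ir * (1 + p * pulse(t) + p * artefact_ir(t)) + ambient(t) + noise` and
#' `ppg_red = dc_red * (1 + p * ros(t) * pulse(t) + p * artefact_red(t)) + ambient(t) + noise`,
#' where `pulse(t)` is a zero-mean, unit-peak-to-trough cardiac waveform at
#' the true heart rate, `p` is the configured perfusion (AC/DC) fraction
#' and `ros(t) = spo2_to_ros(spo2_true(t), a, b)`. Scaling the red
#' channel's relative pulsatile amplitude by `ros(t)` makes the generator
#' the exact inverse of the downstream ratio-of-signals definition: on
#' clean signal the window-level ROS equals `spo2_to_ros(spo2_true, a, b)`.
#'
#' Motion artefacts are damped oscillations (0.5--2 s) with amplitude
#' 5--20 times the pulsatile amplitude, built from a waveform shared
#' across the two channels (common mechanical origin) plus a smaller
#' channel-specific component, with a lognormal red/infrared amplitude
#' ratio. The ambient channel records slow drift plus the mains
#' component; the identical addend contaminates both optical channels.
#'
#' @param truth A [build_truth()] result.
#' @param config The [sim_config()] that produced `truth`.
#' @return An object of class `ppg_recording`: a list with elements
#'   `subject_id`, `sampling_rate_hz`, `time_s`, `ppg_red`, `ppg_ir`,
#'   `ambient` and `activity`.
#' @examples
#' cfg <- sim_config(seed = 3)
#' rec <- synthesize_recording(build_truth(cfg), cfg)
#' length(rec$ppg_ir)
#' @export
synthesize_recording <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  if (!isTRUE(all.equal(attr(truth, "sampling_rate_hz"), fs)))
    stop("truth and config disagree on the sampling rate")
  set.seed(derive_seed(config$seed, 1))

  n <- nrow(truth)
  t <- truth$time_s
  p <- config$perfusion_ac_over_dc

  ## Cardiac phase integrates the instantaneous heart rate, so rate
  ## changes at activity boundaries keep the phase continuous.
  phase <- cumsum(truth$heart_rate_true / 60) / fs
  w <- pulse_waveform(phase)

  ros_t <- spo2_to_ros(truth$spo2_true, config$true_slope_a,
                       config$true_intercept_b)

  ## Motion artefacts, relative to the pulsatile amplitude.
  art_ir <- numeric(n)
  art_red <- numeric(n)
  ev <- attr(truth, "artefact_events")
  if (!is.null(ev) && nrow(ev) > 0) {
    for (j in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[j] * fs) + 1
      len <- max(2L, round(ev$duration_s[j] * fs))
      i1 <- min(n, i0 + len - 1L)
      if (i0 > n) next
      len <- i1 - i0 + 1L
      amp <- stats::runif(1, config$artefact_amplitude_range[1],
                          config$artefact_amplitude_range[2])
      tau <- ev$duration_s[j] / 3
      f_sh <- stats::runif(1, 1, 8)
      w_sh <- damped_osc(len, fs, f_sh, tau, stats::runif(1, 0, 2 * pi))
      w_i <- damped_osc(len, fs, stats::runif(1, 1, 8), tau,
                        stats::runif(1, 0, 2 * pi))
      w_r <- damped_osc(len, fs, stats::runif(1, 1, 8), tau,
                        stats::runif(1, 0, 2 * pi))
      g_red <- exp(stats::rnorm(1, 0, 0.25))  # red/IR artefact amplitude ratio
      idx <- i0:i1
      art_ir[idx] <- art_ir[idx] + amp * (0.8 * w_sh + 0.6 * w_i)
      art_red[idx] <- art_red[idx] + amp * g_red * (0.8 * w_sh + 0.6 * w_r)
    }
  }

  ## Ambient light: slow drift plus mains, recorded in its own channel and
  ## added identically to both optical channels.
  drift <- config$ambient_drift_amplitude *
    (sin(2 * pi * 0.03 * t + stats::runif(1, 0, 2 * pi)) +
     0.5 * sin(2 * pi * 0.071 * t + stats::runif(1, 0, 2 * pi)))
  mains <- config$mains_amplitude *
    sin(2 * pi * config$mains_hz * t + stats::runif(1, 0, 2 * pi))
  ambient <- drift + mains

  ppg_ir <- config$dc_ir * (1 + p * w + p * art_ir) + ambient +
    stats::rnorm(n, 0, config$sensor_noise_sd)
  ppg_red <- config$dc_red * (1 + p * ros_t * w + p * art_red) + ambient +
    stats::rnorm(n, 0, config$sensor_noise_sd)

  structure(list(subject_id = config$subject_id,
                 sampling_rate_hz = fs,
                 time_s = t,
                 ppg_red = ppg_red,
                 ppg_ir = ppg_ir,
                 ambient = ambient,
                 activity = truth$activity),
            class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat("PPG recording '", x$subject_id, "': ",
      length(x$time_s), " samples @ ", x$sampling_rate_hz, " Hz (",
      round(length(x$time_s) / x$sampling_rate_hz), " s)\n", sep = "")
  cat("  activities: ",
      paste(levels(droplevels(factor(x$activity))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simulate reference-device readings for a subject
#'
#' Emulates the two reference modalities of an oximeter validation study:
#' a continuous reference pulse oximeter (1 Hz, integer display rounding,
#' autocorrelated AR(1) measurement noise) and sparse arterial blood-gas
#' SaO2 samples, drawn at rest and during cycling with independent noise.
#'
#' @param truth A [build_truth()] result.
#' @param config The matching [sim_config()].
#' @return An object of class `reference_series`: list with `time_s`,
#'   `spo2_ref` (%), `heart_rate_ref` (beats/min), `abga_times_s` and
#'   `sao2_abga` (%).
#' @examples
#' cfg <- sim_config(seed = 5)
#' ref <- simulate_references(build_truth(cfg), cfg)
#' head(ref$spo2_ref)
#' @export
simulate_references <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2))
  dur <- nrow(truth) / config$sampling_rate_hz
  tr <- seq(0, floor(dur) - 1)

  spo2_t <- stats::approx(truth$time_s, truth$spo2_true, tr, rule = 2)$y
  hr_t <- stats::approx(truth$time_s, truth$heart_rate_true, tr, rule = 2)$y

  ## AR(1) noise with stationary sd = reference_noise_sd.
  phi <- config$reference_ar1_phi
  e <- as.numeric(stats::filter(
    stats::rnorm(length(tr), 0, config$reference_noise_sd * sqrt(1 - phi^2)),
    phi, method = "recursive"))
  spo2_ref <- pmin(100, pmax(0, round(spo2_t + e)))
  hr_ref <- round(hr_t + stats::rnorm(length(tr), 0, 1))

  ## Blood-gas draws: one at rest (middle of the first stationary
  ## segment), one during cycling when the protocol has it, otherwise in
  ## the final segment.
  act <- as.character(truth$activity)
  stationary <- act %in% c("lying", "sitting", "standing")
  runs <- rle(stationary)
  ends <- cumsum(runs$lengths)
  first_stat <- which(runs$values)[1]
  if (is.na(first_stat)) {
    t_rest <- truth$time_s[1]
  } else {
    i_mid <- ends[first_stat] - runs$lengths[first_stat] %/% 2
    t_rest <- truth$time_s[i_mid]
  }
  if (any(act == "cycling")) {
    t_ex <- stats::median(truth$time_s[act == "cycling"])
  } else {
    t_ex <- truth$time_s[nrow(truth)] * 0.9
  }
  abga_t <- sort(c(t_rest, t_ex))
  sao2 <- stats::approx(truth$time_s, truth$spo2_true, abga_t, rule = 2)$y +
    stats::rnorm(length(abga_t), 0, config$abga_noise_sd)
  sao2 <- pmin(100, pmax(0, sao2))

  structure(list(time_s = tr,
                 spo2_ref = spo2_ref,
                 heart_rate_ref = hr_ref,
                 abga_times_s = abga_t,
                 sao2_abga = sao2),
            class = "reference_series")
}

#' @export
print.reference_series <- function(x, ...) {
  cat("Reference series: ", length(x$time_s), " s of 1-Hz SpO2/HR, ",
      length(x$abga_times_s), " blood-gas samples\n", sep = "")
  invisible(x)
}

#' Generate a synthetic study cohort
#'
#' Builds `n_subjects` independent subjects from a template configuration.
#' Per-subject seeds are derived deterministically from the master seed,
#' and physiological parameters are jittered between subjects: perfusion
#' (lognormal), baseline heart rate (normal) and a common shift of all
#' SpO2 plateau levels (normal, clamped to \[70, 100\]).
#'
#' @param n_subjects Number of subjects (>= 2, so leave-one-out
#'   calibration is possible downstream).
#' @param config Template [sim_config()].
#' @param seed Master seed (defaults to the template's seed).
#' @param perfusion_jitter_sdlog Lognormal sd of the per-subject perfusion
#'   multiplier (0 disables).
#' @param hr_jitter_sd Sd of the per-subject baseline heart-rate shift
#'   (beats/min; 0 disables).
#' @param plateau_jitter_sd Sd of the per-subject SpO2 plateau shift
#'   (percentage points; 0 disables).
#' @return An object of class `ppg_cohort`: a list with one element per
#'   subject, each a list with `config`, `truth`, `recording` and
#'   `reference`.
#' @examples
#' coh <- make_cohort(2, sim_config(), seed = 11)
#' names(coh)
#' @export
make_cohort <- function(n_subjects, config = sim_config(),
                        seed = config$seed,
                        perfusion_jitter_sdlog = 0.2,
                        hr_jitter_sd = 6,
                        plateau_jitter_sd = 1.5) {
  stopifnot(inherits(config, "sim_config"))
  if (n_subjects < 2)
    stop("n_subjects must be >= 2 (leave-one-out calibration needs at ",
         "least two subjects)")
  set.seed(as.integer(seed))
  n_subjects <- as.integer(n_subjects)
  sub_seed <- sample.int(2147480000L, n_subjects)
  perf_mult <- exp(stats::rnorm(n_subjects, 0, perfusion_jitter_sdlog))
  hr_shift <- stats::rnorm(n_subjects, 0, hr_jitter_sd)
  plateau_shift <- stats::rnorm(n_subjects, 0, plateau_jitter_sd)

  cohort <- vector("list", n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    plat <- config$spo2_plateaus
    plat$level <- pmin(100, pmax(70, plat$level + plateau_shift[i]))
    cfg_i <- sim_config(
      protocol = config$protocol,
      sampling_rate_hz = config$sampling_rate_hz,
      spo2_plateaus = plat,
      ramp_s = config$ramp_s,
      heart_rate_bpm = config$heart_rate_bpm + hr_shift[i],
      heart_rate_activity_offsets = config$heart_rate_activity_offsets,
      perfusion_ac_over_dc = config$perfusion_ac_over_dc * perf_mult[i],
      true_slope_a = config$true_slope_a,
      true_intercept_b = config$true_intercept_b,
      motion_rate_per_min = config$motion_rate_per_min,
      artefact_amplitude_range = config$artefact_amplitude_range,
      ambient_drift_amplitude = config$ambient_drift_amplitude,
      mains_hz = config$mains_hz,
      mains_amplitude = config$mains_amplitude,
      sensor_noise_sd = config$sensor_noise_sd,
      reference_noise_sd = config$reference_noise_sd,
      reference_ar1_phi = config$reference_ar1_phi,
      abga_noise_sd = config$abga_noise_sd,
      dc_ir = config$dc_ir,
      dc_red = config$dc_red,
      subject_id = ids[i],
      seed = sub_seed[i])
    truth <- build_truth(cfg_i)
    cohort[[i]] <- list(config = cfg_i,
                        truth = truth,
                        recording = synthesize_recording(truth, cfg_i),
                        reference = simulate_references(truth, cfg_i))
  }
  names(cohort) <- ids
  structure(cohort, class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat("Synthetic PPG cohort: ", length(x), " subjects (",
      x[[1]]$config$protocol, ")\n", sep = "")
  invisible(x)
}
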