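## Shared fixtures: all synthetic, built in code at test time.

zero_rates <- c(lying = 0, sitting = 0, standing = 0, walking = 0,
                cycling = 0)

## Noise-free, artefact-free subject with constant heart rate: the
## constructive-correctness baseline.
noiseless_cfg <- function(seed = 1, levels = 90, durations = 400, ...) {
  args <- list(protocol = "patient_daily_activity",
               spo2_plateaus = data.frame(level = levels,
                                          duration_s = durations),
               heart_rate_bpm = 60,
               heart_rate_activity_offsets = zero_rates,
               motion_rate_per_min = zero_rates,
               sensor_noise_sd = 0,
               reference_noise_sd = 0,
               abga_noise_sd = 0,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

## Short patient-protocol config (600 s) for pipeline-level tests.
quick_cfg <- function(seed = 1, ...) {
  sim_config(protocol = "patient_daily_activity",
             spo2_plateaus = data.frame(
               level = c(94, 94, 93, 88, 86),
               duration_s = c(90, 90, 90, 180, 150)),
             seed = seed, ...)
}

## Synthetic window table for evaluation-module tests.
fake_windows <- function(n, rejected = rep(FALSE, n),
                         reason = ifelse(rejected, "low_sqi", "none"),
                         activity = rep("sitting", n),
                         t_start = seq(0, by = 10, length.out = n),
                         ros = rep(1, n)) {
  data.frame(subject_id = rep("S01", n), t_start_s = t_start,
             t_end_s = t_start + 40, ac_red = rep(1, n),
             dc_red = rep(100, n), ac_ir = rep(1, n), dc_ir = rep(100, n),
             ros = ros, sqi = rep(100, n), n_beats = rep(40L, n),
             activity = activity, rejected = rejected,
             rejection_reason = reason, stringsAsFactors = FALSE)
}

## Constant-value reference series covering [0, dur).
fake_reference <- function(dur, spo2 = 90, abga_t = numeric(0),
                           sao2 = numeric(0)) {
  structure(list(time_s = seq(0, dur - 1), spo2_ref = rep(spo2, dur),
                 heart_rate_ref = rep(70, dur), abga_times_s = abga_t,
                 sao2_abga = sao2),
            class = "reference_series")
}
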