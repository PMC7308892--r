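test_that("ground truth respects plateau bounds, ramps and seeding", {
  cfg <- sim_config(protocol = "volunteer_hypoxemia",
                    spo2_plateaus = data.frame(level = c(97, 88, 82),
                                               duration_s = c(180, 180, 180)),
                    seed = 11)
  tr <- build_truth(cfg)
  expect_equal(min(tr$spo2_true), 82)
  expect_equal(max(tr$spo2_true), 97)
  expect_equal(nrow(tr), 540 * cfg$sampling_rate_hz)
  # plateau interiors are exactly constant; ramps monotone
  expect_true(all(tr$spo2_true[tr$time_s >= 60 & tr$time_s < 180] == 97))
  ramp <- tr$spo2_true[tr$time_s >= 180 & tr$time_s < 210]
  expect_true(all(diff(ramp) <= 0))

  tr2 <- build_truth(cfg)
  expect_identical(tr, tr2)

  expect_error(build_truth(sim_config(protocol = "volunteer_hypoxemia",
                                      spo2_plateaus = data.frame(
                                        level = 97, duration_s = 100),
                                      seed = 1)),
               "at least")
  expect_error(sim_config(spo2_plateaus = data.frame(level = 60,
                                                     duration_s = 400)),
               "70")
})

test_that("artefact events follow the activity-dependent Poisson rates", {
  cfg <- sim_config(seed = 21)   # patient protocol: 6-min walk, rate 6/min
  tr <- build_truth(cfg)
  sched <- cumsum(c(180, 180, 180, 360, 300))
  ev <- attr(tr, "artefact_events")
  n_walk <- sum(ev$onset_s >= sched[3] & ev$onset_s < sched[4])
  # Poisson(36) central 99% interval, computed from the distribution
  expect_gte(n_walk, qpois(0.005, 36))
  expect_lte(n_walk, qpois(0.995, 36))

  # artefact-mask density higher while walking than while stationary
  walk <- tr$activity == "walking"
  stat <- tr$activity %in% c("lying", "sitting", "standing")
  expect_gt(mean(tr$artefact_mask[walk]), mean(tr$artefact_mask[stat]))
})

test_that("calibration-line inversion is exact and guards the degenerate slope", {
  expect_equal(spo2_to_ros(116.9, a = -26.8, b = 116.9), 0)
  expect_equal(spo2_to_ros(90.1, a = -26.8, b = 116.9), 1)
  s <- seq(70, 100, by = 2.5)
  expect_equal(apply_calibration(spo2_to_ros(s, -29.6, 119.9),
                                 list(a = -29.6, b = 119.9), clamp = FALSE),
               s)
  expect_error(spo2_to_ros(90, a = 0, b = 110), "nonzero")
})

test_that("noiseless synthesis encodes ROS exactly and pulses at the true rate", {
  cfg <- noiseless_cfg(seed = 2)
  tr <- build_truth(cfg)
  rec <- synthesize_recording(tr, cfg)
  win <- process_recording(rec)
  ros_true <- spo2_to_ros(90, cfg$true_slope_a, cfg$true_intercept_b)
  expect_true(all(!win$rejected))
  expect_lt(max(abs(win$ros - ros_true)), 1e-3)

  # 60 bpm over a 40-s window: 40 +/- 1 beats
  ac <- extract_ac(rec$ppg_ir - rec$ambient, cfg$sampling_rate_hz)
  b <- detect_beats(ac, cfg$sampling_rate_hz)
  n40 <- sum(b <= 40 * cfg$sampling_rate_hz)
  expect_gte(n40, 39); expect_lte(n40, 41)

  # positive optics before artefacts; clean AC/DC matches the perfusion
  expect_true(all(rec$ppg_ir > 0) && all(rec$ppg_red > 0))
  clean_ir <- rec$ppg_ir - rec$ambient
  slice <- seq(10 * cfg$sampling_rate_hz, 11 * cfg$sampling_rate_hz)
  acdc <- diff(range(clean_ir[slice])) / mean(clean_ir[slice])
  expect_lt(abs(acdc / cfg$perfusion_ac_over_dc - 1), 0.05)
})

test_that("ambient channel is exactly the mains component when drift is off", {
  cfg <- noiseless_cfg(seed = 3, ambient_drift_amplitude = 0)
  rec <- synthesize_recording(build_truth(cfg), cfg)
  t <- rec$time_s
  # a pure sinusoid at mains_hz: residual of the best-fit quadrature pair
  # is numerically zero
  X <- cbind(sin(2 * pi * cfg$mains_hz * t), cos(2 * pi * cfg$mains_hz * t))
  res <- stats::lm.fit(X, rec$ambient)$residuals
  expect_lt(max(abs(res)), 1e-9)
})

test_that("reference devices reproduce truth when noise-free and match the configured noise level", {
  cfg <- noiseless_cfg(seed = 4)
  tr <- build_truth(cfg)
  ref <- simulate_references(tr, cfg)
  expect_equal(ref$spo2_ref, rep(90, length(ref$time_s)))
  expect_equal(ref$sao2_abga, rep(90, 2))
  expect_length(ref$abga_times_s, 2)

  # configured sd 1.5 recovered empirically (rounding adds ~1/12 variance)
  sds <- numeric(0)
  for (s in 1:6) {
    cfgn <- noiseless_cfg(seed = 100 + s, reference_noise_sd = 1.5)
    trn <- build_truth(cfgn)
    refn <- simulate_references(trn, cfgn)
    sds <- c(sds, refn$spo2_ref - 90)
  }
  expect_gt(sd(sds), 1.35)
  expect_lt(sd(sds), 1.65)
})

test_that("cohorts are reproducible and jitter physiology across subjects", {
  cfg <- quick_cfg(seed = 5)
  c1 <- make_cohort(2, cfg, seed = 42)
  c2 <- make_cohort(2, cfg, seed = 42)
  expect_identical(c1, c2)
  expect_length(c1, 2)
  expect_error(make_cohort(1, cfg), "at least two")

  c3 <- make_cohort(4, cfg, seed = 9)
  perf <- vapply(c3, function(s) s$config$perfusion_ac_over_dc, numeric(1))
  expect_gt(length(unique(perf)), 1)
  hr <- vapply(c3, function(s) s$config$heart_rate_bpm, numeric(1))
  expect_gt(length(unique(hr)), 1)
})
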