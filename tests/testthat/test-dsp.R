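fs <- 100

test_that("ambient correction removes coupled drift without touching clean input", {
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  clean <- 1000 + sin(2 * pi * 1.3 * t)
  expect_identical(correct_ambient(clean, rep(0, length(t)), fs), clean)
  expect_error(correct_ambient(clean, numeric(10), fs), "equal length")

  # drift-only ambient coupled with unit gain: >= 20 dB sub-cardiac
  # power reduction
  amb <- 3 * sin(2 * pi * 0.05 * t) + 1.5 * sin(2 * pi * 0.11 * t)
  x <- clean + 1.0 * amb
  drift_power <- function(v) {
    bf <- signal::butter(2, 0.4 / (fs / 2), type = "low")
    lp <- signal::filtfilt(bf, v - mean(v))
    mean(lp^2)
  }
  y <- correct_ambient(x, amb, fs)
  expect_lt(drift_power(y) / drift_power(x), 0.01)

  # constant ambient: nothing subtracted, offset absorbed into DC
  expect_identical(correct_ambient(clean, rep(5, length(t)), fs), clean)
})

test_that("band-pass AC extraction rejects DC and drift but passes cardiac frequencies", {
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  p <- processing_params()

  out <- extract_ac(rep(1000, length(t)), fs, p)
  expect_lt(max(abs(out)), 1e-9 * 1000)

  mid <- t >= 30 & t < 90   # interior, away from edges
  out <- extract_ac(sin(2 * pi * 1.5 * t), fs, p)
  amp <- diff(range(out[mid])) / 2
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)

  out <- extract_ac(sin(2 * pi * 0.05 * t), fs, p)
  expect_lt(max(abs(out[mid])), 0.05)

  expect_error(extract_ac(rnorm(100), fs, p), "too short")
})

test_that("beat detection counts clean pulses and resists artefact bursts", {
  p <- processing_params()
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t)   # 60 bpm
  b <- detect_beats(x, fs, p)
  expect_gte(length(b), 39); expect_lte(length(b), 41)
  expect_true(all(diff(b) >= round(p$refractory_s * fs)))

  expect_identical(detect_beats(rep(0, 4000), fs, p), integer(0))
  expect_identical(detect_beats(numeric(0), fs, p), integer(0))

  # one 2-s artefact burst: median inter-beat interval unchanged
  ibi_clean <- median(diff(b))
  xa <- x
  burst <- t >= 20 & t < 22
  xa[burst] <- xa[burst] + 10 * sin(2 * pi * 5 * t[burst])
  ba <- detect_beats(xa, fs, p)
  expect_equal(median(diff(ba)), ibi_clean, tolerance = 0.02)
})

test_that("cardiac-gated averaging is exact on identical beats and averages noise as 1/sqrt(N)", {
  beat <- pulse_len <- 100   # 60 bpm at 100 Hz
  shape <- sin(2 * pi * seq(0, 1 - 1 / beat, by = 1 / beat))
  n_beats <- 41
  x <- rep(shape, n_beats)
  beats <- seq(1, by = beat, length.out = n_beats)

  g <- cardiac_gated_average(x, x + 1000, fs, beats, 1, length(x) + 1)
  expect_equal(g$ac_amplitude, 2, tolerance = 1e-3)
  expect_equal(g$dc_level, 1000, tolerance = 1e-6)
  expect_equal(g$n_beats, n_beats - 1)

  # fewer than 2 beats signals "too few"
  g0 <- cardiac_gated_average(x, x, fs, integer(0), 1, length(x) + 1)
  expect_equal(g0$n_beats, 0)
  expect_null(g0$template)

  # template residual sd ~ sigma / sqrt(N) within a factor 1.5
  sigma <- 0.3
  set.seed(1)
  reps <- replicate(20, {
    xn <- x + rnorm(length(x), 0, sigma)
    gn <- cardiac_gated_average(xn, xn, fs, beats, 1, length(x) + 1)
    sd(gn$template - shape)
  })
  expected <- sigma / sqrt(n_beats - 1)
  expect_gt(mean(reps), expected / 1.5)
  expect_lt(mean(reps), expected * 1.5)
})

test_that("ROS is the ratio of relative pulsatile amplitudes and is scale invariant", {
  expect_equal(compute_ros(1, 100, 1, 100), 1)
  expect_equal(compute_ros(2, 100, 1, 100), 2)
  expect_equal(compute_ros(2 * 10, 100 * 10, 1, 100), 2)
  expect_error(compute_ros(1, -1, 1, 100), "DC")
  expect_error(compute_ros(1, 100, 0, 100), "infrared")
})

test_that("end-to-end ROS is invariant to rescaling one raw channel", {
  cfg <- noiseless_cfg(seed = 6)
  rec <- synthesize_recording(build_truth(cfg), cfg)
  win <- process_recording(rec)
  rec10 <- rec
  rec10$ppg_red <- rec$ppg_red * 10   # ambient share scales along
  win10 <- process_recording(rec10)
  expect_lt(max(abs(win10$ros - win$ros)), 1e-9)
})

test_that("SQI is maximal on clean regular signal, zero without beats, and decreases with noise", {
  tpl <- sin(seq(0, 2 * pi, length.out = 80))
  expect_equal(compute_sqi(tpl, tpl, rep(1, 20)), 100)
  expect_equal(compute_sqi(NULL, NULL, numeric(0)), 0)
  expect_equal(compute_sqi(tpl, tpl * 0, rep(1, 20)), 0)

  # Monte-Carlo noise sweep through the window chain: mean SQI strictly
  # decreasing in noise amplitude
  p <- processing_params()
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  pulse <- 0.5 * sin(2 * pi * t)      # 60 bpm, unit peak-to-trough
  sweep <- c(0, 5, 20)
  mean_sqi <- vapply(seq_along(sweep), function(si) {
    set.seed(300 + si)
    mean(replicate(50, {
      ir <- pulse + rnorm(length(t), 0, sweep[si])
      red <- 0.9 * pulse + rnorm(length(t), 0, sweep[si])
      ac_ir <- extract_ac(ir, fs, p); ac_red <- extract_ac(red, fs, p)
      b <- detect_beats(ac_ir, fs, p)
      g_ir <- cardiac_gated_average(ac_ir, ir, fs, b, 1, length(t) + 1)
      g_red <- cardiac_gated_average(ac_red, red, fs, b, 1, length(t) + 1)
      compute_sqi(g_red$template, g_ir$template, diff(b) / fs)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_sqi) < 0))
})

test_that("window segmentation, rejection flags and threshold edge behave as specified", {
  # 400-s noiseless recording, hop 10: floor((400-40)/10)+1 = 37 windows
  cfg <- noiseless_cfg(seed = 7)
  rec <- synthesize_recording(build_truth(cfg), cfg)
  win <- process_recording(rec)
  expect_equal(nrow(win), 37)
  expect_true(all(!win$rejected))
  expect_true(all(win$rejection_reason == "none"))
  expect_equal(win$t_end_s - win$t_start_s, rep(40, 37))

  # SQI exactly at the threshold is retained: clean windows score 100,
  # and a threshold of 100 must not reject them
  p100 <- processing_params(sqi_threshold_pct = 100)
  win100 <- process_recording(rec, p100)
  full <- win100$sqi == 100
  expect_true(any(full))
  expect_true(all(!win100$rejected[full]))

  # an all-noise recording carries no physiological pulsation
  set.seed(8)
  recn <- rec
  recn$ppg_red <- 800 + rnorm(length(rec$time_s), 0, 20)
  recn$ppg_ir <- 1000 + rnorm(length(rec$time_s), 0, 20)
  recn$ambient <- rep(0, length(rec$time_s))
  winn <- process_recording(recn)
  expect_true(all(winn$rejected))

  # shorter than one window: zero rows
  short <- rec
  keep <- rec$time_s < 30
  for (f in c("time_s", "ppg_red", "ppg_ir", "ambient", "activity"))
    short[[f]] <- rec[[f]][keep]
  expect_equal(nrow(process_recording(short)), 0)
})

test_that("rejection is concentrated where motion artefacts are", {
  cfg <- quick_cfg(seed = 31)
  rec <- synthesize_recording(build_truth(cfg), cfg)
  win <- process_recording(rec)
  walk <- win$activity == "walking"
  expect_gt(mean(win$rejected[walk]), mean(win$rejected[!walk]))
})
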