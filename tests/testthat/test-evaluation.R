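test_that("stable-reference filtering discards windows spanning desaturation ramps", {
  w <- fake_windows(3, t_start = c(0, 40, 80))
  ref <- fake_reference(130, spo2 = 90)
  expect_true(all(!filter_stable_reference(w, ref)$rejected))

  # a window spanning an 85 -> 92 ramp (range 7 > 2) is discarded
  ref2 <- fake_reference(130, spo2 = 90)
  ref2$spo2_ref[41:81] <- round(seq(85, 92, length.out = 41))
  out <- filter_stable_reference(w, ref2)
  expect_identical(out$rejection_reason[2], "unstable_reference")
  expect_true(out$rejected[2])
  expect_false(out$rejected[1])

  # infinite tolerance disables the filter
  expect_true(all(!filter_stable_reference(w, ref2, Inf)$rejected))

  # missing reference coverage is unstable
  ref3 <- fake_reference(60, spo2 = 90)
  out3 <- filter_stable_reference(w, ref3)
  expect_identical(out3$rejection_reason[3], "unstable_reference")

  # already-rejected windows keep their original reason
  wr <- fake_windows(1, rejected = TRUE, reason = "low_sqi")
  expect_identical(filter_stable_reference(wr, ref2)$rejection_reason,
                   "low_sqi")
})

test_that("rejection accounting partitions rejected windows by reason", {
  w <- fake_windows(36, rejected = rep(c(TRUE, FALSE), c(12, 24)),
                    reason = rep(c("low_sqi", "none"), c(12, 24)))
  acc <- rejection_accounting(w)
  expect_equal(acc$n_retained, 24)
  expect_equal(acc$rejection_rate_pct, 100 * 12 / 36)
  expect_equal(as.integer(acc$per_reason["low_sqi"]), 12)
  expect_equal(sum(acc$per_reason), acc$n_total - acc$n_retained)

  expect_equal(rejection_accounting(fake_windows(5))$rejection_rate_pct, 0)
  expect_equal(rejection_accounting(
    fake_windows(5, rejected = rep(TRUE, 5)))$rejection_rate_pct, 100)
  expect_error(rejection_accounting(fake_windows(0)), "no windows")
})

test_that("pairing matches retained windows to continuous and blood-gas references", {
  w <- fake_windows(4, t_start = c(0, 40, 80, 120),
                    rejected = c(FALSE, FALSE, TRUE, FALSE),
                    reason = c("none", "none", "low_sqi", "none"))
  w$spo2_est <- c(91, 92, 93, 94)
  ref <- fake_reference(170, spo2 = 90,
                        abga_t = c(30, 105), sao2 = c(90.4, 91.1))

  pc <- pair_with_reference(w, ref, "continuous")
  expect_equal(nrow(pc), 3)          # bijection with retained windows
  expect_equal(pc$spo2_ref, rep(90, 3))

  # abga at t=30: nearest retained centre is 20 (10 s away) -> paired;
  # abga at t=105: nearest retained centre is 140 (35 s away) -> dropped
  pa <- pair_with_reference(w, ref, "abga", max_gap_s = 30)
  expect_equal(nrow(pa), 1)
  expect_equal(pa$t_window, 20)
  expect_equal(pa$spo2_ref, 90.4)

  expect_error(pair_with_reference(fake_windows(2), ref, "continuous"),
               "spo2_est")
})

test_that("accuracy statistics satisfy their defining identities", {
  p0 <- data.frame(spo2_est = c(90, 85, 95), spo2_ref = c(90, 85, 95))
  s0 <- compute_accuracy_stats(p0)
  expect_equal(s0$bias, 0)
  expect_equal(s0$arms, 0)
  expect_equal(s0$bland_altman$loa_low, 0)
  expect_equal(s0$bland_altman$loa_high, 0)
  expect_equal(s0$pearson_r, 1)

  p1 <- data.frame(spo2_est = c(92, 88), spo2_ref = c(90, 90))
  s1 <- compute_accuracy_stats(p1)
  expect_equal(s1$bias, 0)
  expect_equal(s1$arms, 2)

  # A_RMS identity over random pair sets: arms^2 = bias^2 + (n-1)/n sd^2
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    p <- data.frame(spo2_est = runif(n, 80, 100),
                    spo2_ref = runif(n, 80, 100))
    s <- compute_accuracy_stats(p)
    expect_equal(s$arms^2,
                 s$bias^2 + (n - 1) / n * s$precision_sd^2,
                 tolerance = 1e-10)
    expect_gte(s$arms, abs(s$bias))
  }

  # zero variance: correlation undefined and flagged
  pz <- data.frame(spo2_est = rep(90, 4), spo2_ref = c(88, 89, 90, 91))
  expect_false(compute_accuracy_stats(pz)$r_defined)
})

test_that("accuracy statistics match a brute-force recomputation by definition", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    est <- runif(n, 80, 100)
    ref <- est + rnorm(n, 0, 2)
    s <- compute_accuracy_stats(data.frame(spo2_est = est, spo2_ref = ref))
    d <- est - ref
    bias_o <- sum(d) / n
    sd_o <- sqrt(sum((d - bias_o)^2) / (n - 1))
    arms_o <- sqrt(sum(d^2) / n)
    r_o <- sum((est - mean(est)) * (ref - mean(ref))) /
      sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2))
    expect_equal(s$bias, bias_o, tolerance = 1e-12)
    expect_equal(s$precision_sd, sd_o, tolerance = 1e-12)
    expect_equal(s$arms, arms_o, tolerance = 1e-12)
    expect_equal(s$pearson_r, r_o, tolerance = 1e-12)
    expect_equal(s$bland_altman$loa_low, bias_o - 1.96 * sd_o,
                 tolerance = 1e-12)
    expect_equal(s$bland_altman$loa_high, bias_o + 1.96 * sd_o,
                 tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits cover ~95% of gaussian differences", {
  set.seed(47)
  n <- 4000
  est <- 90 + rnorm(n, 0.5, 1.5)
  s <- compute_accuracy_stats(data.frame(spo2_est = est, spo2_ref = 90))
  d <- est - 90
  cover <- mean(d >= s$bland_altman$loa_low & d <= s$bland_altman$loa_high)
  tol <- 3 * sqrt(0.95 * 0.05 / n)
  expect_gt(cover, 0.95 - tol)
  expect_lt(cover, 0.95 + tol)
})

test_that("stratification partitions pairs and computes per-group rejection", {
  pairs <- data.frame(spo2_est = c(90, 91, 88, 87, 92),
                      spo2_ref = c(90, 90, 89, 88, 91),
                      activity = c("walking", "walking", "sitting",
                                   "lying", "cycling"),
                      stringsAsFactors = FALSE)
  st <- stratify(pairs)
  expect_equal(st$overall$stats$n_pairs,
               st$walking$stats$n_pairs + st$stationary$stats$n_pairs)

  all_walk <- pairs[pairs$activity == "walking", ]
  st2 <- stratify(all_walk)
  expect_null(st2$stationary)
  expect_equal(st2$overall$stats$n_pairs, st2$walking$stats$n_pairs)

  # per-stratum rejection denominators from each group's own windows
  w <- fake_windows(10, activity = rep(c("walking", "sitting"), each = 5),
                    rejected = c(rep(TRUE, 4), FALSE,
                                 rep(FALSE, 4), TRUE),
                    reason = c(rep("low_sqi", 4), "none",
                               rep("none", 4), "low_sqi"))
  st3 <- stratify(pairs, w)
  expect_equal(st3$walking$rejection$rejection_rate_pct, 80)
  expect_equal(st3$stationary$rejection$rejection_rate_pct, 20)
})
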