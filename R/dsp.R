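## Zero-phase Butterworth helpers. `signal::butter(n, W)` follows the
## MATLAB convention: a band-pass prototype of order n yields an overall
## filter of order 2n, so a "fourth-order band-pass" uses n = 2.
butter_bandpass <- function(fs, params) {
  signal::butter(params$filter_order / 2,
                 c(params$bandpass_low_hz, params$bandpass_high_hz) / (fs / 2),
                 type = "pass")
}

lowpass_filtfilt <- function(x, fs, cutoff_hz) {
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  ## demeaned to avoid DC-level edge transients from the implicit padding
  signal::filtfilt(bf, x - mean(x))
}

#' Ambient-light correction
#'
#' Removes ambient-light contamination from an optical channel by
#' subtracting a scaled copy of the recorded ambient signal,
#' `channel - g * ambient`. The coupling gain `g` is estimated by least
#' squares restricted to the sub-cardiac band (both series low-passed
#' below `lowpass_hz`), so cardiac-band content cannot drive
#' over-subtraction. When the ambient signal has no sub-cardiac power
#' (e.g. a pure mains component), the gain falls back to full-band least
#' squares; a constant or empty ambient yields `g = 0` and the channel is
#' returned untouched (a constant offset is absorbed into the DC level).
#'
#' @param channel Optical series (red or infrared), arbitrary units.
#' @param ambient Ambient-light series of the same length.
#' @param fs Sampling rate (samples/s).
#' @param lowpass_hz Upper edge of the sub-cardiac estimation band (Hz).
#' @return The corrected series, same length as `channel`.
#' @examples
#' fs <- 100; t <- seq(0, 20, by = 1 / fs)
#' amb <- sin(2 * pi * 0.05 * t)
#' x <- 1000 + sin(2 * pi * 1.3 * t) + amb
#' y <- correct_ambient(x, amb, fs)
#' @export
correct_ambient <- function(channel, ambient, fs, lowpass_hz = 0.4) {
  if (length(channel) != length(ambient))
    stop("channel and ambient must have equal length")
  v_amb <- stats::var(ambient)
  if (!is.finite(v_amb) || v_amb < 1e-24)
    return(channel)
  la <- lowpass_filtfilt(ambient, fs, lowpass_hz)
  lc <- lowpass_filtfilt(channel, fs, lowpass_hz)
  v_la <- stats::var(la)
  if (v_la > 1e-9 * v_amb) {
    g <- stats::cov(lc, la) / v_la
  } else {
    g <- stats::cov(channel, ambient) / v_amb
  }
  channel - g * ambient
}

#' AC component extraction by zero-phase band-pass filtering
#'
#' Estimates the pulsatile (AC) component of a PPG channel with a
#' fourth-order Butterworth band-pass applied forward-backward
#' (zero-phase), so beat fiducials are not delayed relative to the raw
#' signal.
#'
#' @param x Optical series (ideally after [correct_ambient()]).
#' @param fs Sampling rate (samples/s).
#' @param params A [processing_params()] object.
#' @return Band-passed series of the same length.
#' @examples
#' fs <- 100; t <- seq(0, 30, by = 1 / fs)
#' ac <- extract_ac(1000 + sin(2 * pi * 1.5 * t), fs, processing_params())
#' @export
extract_ac <- function(x, fs, params = processing_params()) {
  if (params$bandpass_high_hz >= fs / 2)
    stop("bandpass_high_hz must be below the Nyquist frequency")
  min_len <- ceiling(3 * fs / params$bandpass_low_hz)
  if (length(x) < min_len)
    stop("signal too short for stable filtering: need at least ", min_len,
         " samples (three periods of the low corner frequency)")
  bf <- butter_bandpass(fs, params)
  ## Demean before filtering: filtfilt's implicit zero-padding otherwise
  ## produces edge transients proportional to the DC level.
  signal::filtfilt(bf, x - mean(x))
}

#' Beat detection on the band-passed infrared channel
#'
#' Detects cardiac beats as local maxima of the AC signal exceeding an
#' adaptive threshold (0.4 times the rolling 90th percentile of the
#' rectified signal, evaluated on 10-s blocks), with a refractory period
#' enforced greedily from the largest peak down. The infrared channel is
#' used because it carries the stronger pulsatile signal-to-noise ratio.
#'
#' @param ac_ir Band-passed infrared series (from [extract_ac()]).
#' @param fs Sampling rate (samples/s).
#' @param params A [processing_params()] object (uses `refractory_s`).
#' @return Strictly increasing integer sample indices of beat fiducials
#'   (systolic peaks); an empty or flat signal yields `integer(0)`.
#' @examples
#' fs <- 100; t <- seq(0, 40, by = 1 / fs)
#' beats <- detect_beats(sin(2 * pi * t), fs, processing_params())
#' length(beats)  # ~40 at 60 bpm
#' @export
detect_beats <- function(ac_ir, fs, params = processing_params()) {
  n <- length(ac_ir)
  if (n < 3 || !any(is.finite(ac_ir)) || stats::sd(ac_ir) < 1e-12)
    return(integer(0))

  ## Block-wise adaptive threshold: p90 of |x| per 10-s block.
  block <- max(1L, round(10 * fs))
  blk_id <- (seq_len(n) - 1L) %/% block + 1L
  p90 <- tapply(abs(ac_ir), blk_id, stats::quantile, probs = 0.9,
                names = FALSE)
  thr <- 0.4 * as.numeric(p90)[blk_id]

  cand <- which(ac_ir[2:(n - 1)] > ac_ir[1:(n - 2)] &
                ac_ir[2:(n - 1)] >= ac_ir[3:n]) + 1L
  cand <- cand[ac_ir[cand] > thr[cand] & ac_ir[cand] > 0]
  if (!length(cand)) return(integer(0))

  ## Greedy refractory enforcement, largest peaks first.
  refr <- round(params$refractory_s * fs)
  cand <- cand[order(ac_ir[cand], decreasing = TRUE)]
  keep <- logical(n)
  taken <- logical(n)
  for (i in cand) {
    lo <- max(1L, i - refr); hi <- min(n, i + refr)
    if (!any(taken[lo:hi])) {
      keep[i] <- TRUE
      taken[lo:hi] <- TRUE
    }
  }
  which(keep)
}

#' Cardiac-gated ensemble averaging over a window
#'
#' Segments the signal at beat fiducials inside a half-open window,
#' resamples every beat segment to a common length, and ensemble-averages
#' the segments into a beat template. Noise that is not synchronous with
#' the cardiac cycle averages away as `1/sqrt(n_beats)`. The gating is
#' what gives the method its artefact robustness: only segments whose
#' length lies within 20% of the window's median beat length enter the
#' ensemble, so spurious detections and gaps caused by motion transients
#' are excluded from the template rather than averaged into it. The AC
#' amplitude is the peak-to-trough span of the template; the DC level is
#' the plain mean of the raw (ambient-corrected, unfiltered) signal over
#' the window.
#'
#' @param ac Band-passed series (template source).
#' @param raw Ambient-corrected, unfiltered series (DC source).
#' @param fs Sampling rate (samples/s).
#' @param beats Beat indices from [detect_beats()] (full-recording
#'   indices).
#' @param i_start,i_end Window sample range, half-open:
#'   `i_start <= i < i_end`.
#' @return List with `ac_amplitude`, `dc_level`, `n_beats` (number of
#'   beat segments used) and `template` (numeric vector, or `NULL` when
#'   fewer than two beats fall inside the window, in which case
#'   `n_beats = 0` signals "too few beats").
#' @examples
#' fs <- 100; t <- seq(0, 40 - 1 / fs, by = 1 / fs)
#' x <- sin(2 * pi * t)
#' b <- detect_beats(x, fs, processing_params())
#' cardiac_gated_average(x, x + 1000, fs, b, 1, length(x) + 1)$dc_level
#' @export
cardiac_gated_average <- function(ac, raw, fs, beats, i_start, i_end) {
  idx <- i_start:(i_end - 1L)
  dc <- mean(raw[idx])
  bw <- beats[beats >= i_start & beats < i_end]
  if (length(bw) < 2)
    return(list(ac_amplitude = NA_real_, dc_level = dc, n_beats = 0L,
                template = NULL))
  lens <- diff(bw)
  med_len <- stats::median(lens)
  use <- which(abs(lens - med_len) <= 0.2 * med_len)
  if (length(use) < 1)
    return(list(ac_amplitude = NA_real_, dc_level = dc, n_beats = 0L,
                template = NULL))
  L <- max(2L, round(med_len))
  segs <- matrix(0, nrow = L, ncol = length(use))
  for (jj in seq_along(use)) {
    j <- use[jj]
    seg <- ac[bw[j]:(bw[j + 1L] - 1L)]
    if (length(seg) == L) {
      segs[, jj] <- seg
    } else {
      segs[, jj] <- stats::approx(seq(0, 1, length.out = length(seg)), seg,
                                  seq(0, 1, length.out = L))$y
    }
  }
  ## Robust ensemble: a 20%-trimmed mean per phase point tolerates a few
  ## high-amplitude artefact segments that survived the length gate, at a
  ## negligible efficiency cost on clean windows.
  template <- if (ncol(segs) >= 5)
    apply(segs, 1, mean, trim = 0.1) else rowMeans(segs)
  list(ac_amplitude = max(template) - min(template),
       dc_level = dc,
       n_beats = ncol(segs),
       template = template)
}

#' Ratio of signals (ROS)
#'
#' The two-wavelength pulse-oximetry predictor:
#' `ROS = (AC_red / DC_red) / (AC_ir / DC_ir)`. Dimensionless and
#' invariant to rescaling either channel (AC and DC together).
#'
#' @param ac_red,dc_red,ac_ir,dc_ir Window-level AC amplitudes and DC
#'   levels of the red and infrared channels.
#' @return The ROS value.
#' @examples
#' compute_ros(2, 100, 1, 100)  # 2
#' @export
compute_ros <- function(ac_red, dc_red, ac_ir, dc_ir) {
  if (!is.finite(dc_red) || !is.finite(dc_ir) || dc_red <= 0 || dc_ir <= 0)
    stop("degenerate window: DC levels must be positive")
  if (!is.finite(ac_ir) || ac_ir <= 0)
    stop("degenerate window: infrared AC amplitude must be positive")
  (ac_red / dc_red) / (ac_ir / dc_ir)
}

#' Signal-quality index of a processed window
#'
#' A 0--100 surrogate quality score with the contract needed for
#' rejection accounting: maximal on clean, regular signal and monotone
#' non-increasing (in expectation) under added broadband noise. It is the
#' product of two factors: the (non-negative part of the) correlation
#' between the red and infrared beat templates, and the fraction of
#' inter-beat intervals within 20% of the window's median interval.
#'
#' @param template_red,template_ir Beat templates from
#'   [cardiac_gated_average()] (equal length, or `NULL`).
#' @param ibi_s Inter-beat intervals of the window (s).
#' @return SQI in \[0, 100\]; 0 when fewer than two beats were available.
#' @examples
#' tpl <- sin(seq(0, 2 * pi, length.out = 50))
#' compute_sqi(tpl, tpl, rep(1, 10))  # 100
#' @export
compute_sqi <- function(template_red, template_ir, ibi_s) {
  if (is.null(template_red) || is.null(template_ir) || length(ibi_s) < 1)
    return(0)
  if (stats::sd(template_red) < 1e-12 || stats::sd(template_ir) < 1e-12)
    return(0)
  rho <- suppressWarnings(stats::cor(template_red, template_ir))
  if (!is.finite(rho)) rho <- 0
  rho <- max(0, rho)
  med <- stats::median(ibi_s)
  reg <- mean(abs(ibi_s - med) <= 0.2 * med)
  min(100, max(0, 100 * rho * reg))
}

#' Process a recording into per-window estimates
#'
#' Runs the full window-level chain on a raw recording: ambient
#' correction of both optical channels, AC extraction, beat detection on
#' the infrared channel, then sliding 40-s windows (hop `hop_s`,
#' half-open `[t_start, t_end)`) in which both channels are
#' cardiac-gated-averaged with the shared beat set, ROS and SQI are
#' computed, and rejection flags are assigned: `too_few_beats` when fewer
#' than `min_beats_per_window` beat segments are available, `low_sqi`
#' when the SQI is strictly below the threshold (an SQI exactly at the
#' threshold is retained).
#'
#' @param rec A `ppg_recording`.
#' @param params A [processing_params()] object.
#' @return A data frame of class `window_estimates` with one row per
#'   window: `subject_id`, `t_start_s`, `t_end_s`, `ac_red`, `dc_red`,
#'   `ac_ir`, `dc_ir`, `ros`, `sqi`, `n_beats`, `activity` (dominant
#'   label, ties broken toward the more movement-intensive activity),
#'   `rejected`, `rejection_reason`. A recording shorter than one window
#'   yields zero rows.
#' @examples
#' cfg <- sim_config(seed = 2)
#' win <- process_recording(synthesize_recording(build_truth(cfg), cfg))
#' table(win$rejection_reason)
#' @export
process_recording <- function(rec, params = processing_params()) {
  stopifnot(inherits(rec, "ppg_recording"))
  fs <- rec$sampling_rate_hz
  n <- length(rec$time_s)
  dur <- n / fs
  empty <- data.frame(subject_id = character(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), ac_red = numeric(0),
                      dc_red = numeric(0), ac_ir = numeric(0),
                      dc_ir = numeric(0), ros = numeric(0),
                      sqi = numeric(0), n_beats = integer(0),
                      activity = character(0), rejected = logical(0),
                      rejection_reason = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("window_estimates", "data.frame")
  if (dur < params$window_s) return(empty)

  red_c <- correct_ambient(rec$ppg_red, rec$ambient, fs,
                           params$ambient_lowpass_hz)
  ir_c <- correct_ambient(rec$ppg_ir, rec$ambient, fs,
                          params$ambient_lowpass_hz)
  ac_red <- extract_ac(red_c, fs, params)
  ac_ir <- extract_ac(ir_c, fs, params)
  beats <- detect_beats(ac_ir, fs, params)

  starts <- seq(0, dur - params$window_s + 1e-9, by = params$hop_s)
  act <- as.character(rec$activity)
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    t0 <- starts[k]
    t1 <- t0 + params$window_s
    i0 <- round(t0 * fs) + 1L
    i1 <- min(n + 1L, round(t1 * fs) + 1L)   # half-open [i0, i1)

    g_ir <- cardiac_gated_average(ac_ir, ir_c, fs, beats, i0, i1)
    g_red <- cardiac_gated_average(ac_red, red_c, fs, beats, i0, i1)
    bw <- beats[beats >= i0 & beats < i1]
    sqi <- compute_sqi(g_red$template, g_ir$template, diff(bw) / fs)

    ros <- NA_real_
    ok_ros <- g_ir$n_beats > 0 && is.finite(g_ir$ac_amplitude) &&
      g_ir$ac_amplitude > 0 && g_ir$dc_level > 0 && g_red$dc_level > 0
    if (ok_ros)
      ros <- compute_ros(g_red$ac_amplitude, g_red$dc_level,
                         g_ir$ac_amplitude, g_ir$dc_level)

    ## Dominant activity: modal label, ties toward more movement.
    tab <- table(act[i0:(i1 - 1L)])
    cand <- names(tab)[tab == max(tab)]
    a_dom <- cand[which.max(activity_severity[cand])]

    if (g_ir$n_beats < params$min_beats_per_window) {
      reason <- "too_few_beats"
    } else if (!ok_ros || sqi < params$sqi_threshold_pct) {
      reason <- "low_sqi"
    } else {
      reason <- "none"
    }

    rows[[k]] <- data.frame(subject_id = rec$subject_id, t_start_s = t0,
                            t_end_s = t1, ac_red = g_red$ac_amplitude,
                            dc_red = g_red$dc_level,
                            ac_ir = g_ir$ac_amplitude,
                            dc_ir = g_ir$dc_level, ros = ros, sqi = sqi,
                            n_beats = g_ir$n_beats, activity = a_dom,
                            rejected = reason != "none",
                            rejection_reason = reason,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("window_estimates", "data.frame")
  out
}
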