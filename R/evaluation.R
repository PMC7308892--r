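#' Discard windows without a stable reference
#'
#' Marks windows whose continuous-reference SpO2 is not stable over the
#' window: the within-window reference range (max - min) exceeds
#' `max_range_pct`, or reference samples are missing. Such windows gain
#' `rejection_reason = "unstable_reference"`; windows already rejected
#' for signal quality keep their original reason so the per-reason counts
#' stay a partition.
#'
#' @param windows A `window_estimates` data frame.
#' @param ref The subject's `reference_series`.
#' @param max_range_pct Stability criterion in SpO2 percentage points
#'   (default 2, the usual clinical-significance threshold; `Inf`
#'   disables the filter).
#' @return `windows` with updated `rejected` / `rejection_reason`.
#' @examples
#' # see ?run_pipeline for the full chain
#' @export
filter_stable_reference <- function(windows, ref, max_range_pct = 2) {
  stopifnot(inherits(ref, "reference_series"))
  if (nrow(windows) == 0) return(windows)
  dt <- if (length(ref$time_s) > 1) stats::median(diff(ref$time_s)) else 1
  for (k in seq_len(nrow(windows))) {
    sel <- ref$time_s >= windows$t_start_s[k] &
      ref$time_s < windows$t_end_s[k]
    vals <- ref$spo2_ref[sel]
    n_expected <- floor((windows$t_end_s[k] - windows$t_start_s[k]) / dt -
                        1e-9) + 1L
    unstable <- length(vals) < n_expected || anyNA(vals) ||
      (length(vals) > 0 && diff(range(vals)) > max_range_pct)
    if (unstable && !windows$rejected[k]) {
      windows$rejected[k] <- TRUE
      windows$rejection_reason[k] <- "unstable_reference"
    }
  }
  windows
}

#' Rejection accounting
#'
#' Tallies how many windows survived quality screening, the overall
#' rejection rate, and the partition of rejected windows by reason.
#'
#' @param windows A `window_estimates` data frame (possibly from several
#'   subjects).
#' @return List with `n_total`, `n_retained`, `rejection_rate_pct` and
#'   `per_reason` (named integer vector over rejection reasons).
#' @examples
#' w <- data.frame(rejected = c(TRUE, FALSE, FALSE),
#'                 rejection_reason = c("low_sqi", "none", "none"))
#' rejection_accounting(w)$rejection_rate_pct
#' @export
rejection_accounting <- function(windows) {
  n_total <- nrow(windows)
  if (n_total == 0)
    stop("rejection rate undefined: no windows")
  n_retained <- sum(!windows$rejected)
  reasons <- windows$rejection_reason[windows$rejected]
  list(n_total = n_total,
       n_retained = n_retained,
       rejection_rate_pct = 100 * (n_total - n_retained) / n_total,
       per_reason = table(factor(reasons,
                                 levels = c("low_sqi", "too_few_beats",
                                            "unstable_reference"))))
}

## Window-mean of the continuous reference over each window's span.
window_reference_mean <- function(windows, ref) {
  vapply(seq_len(nrow(windows)), function(k) {
    sel <- ref$time_s >= windows$t_start_s[k] &
      ref$time_s < windows$t_end_s[k]
    if (!any(sel)) return(NA_real_)
    mean(ref$spo2_ref[sel])
  }, numeric(1))
}

#' Pair calibrated windows with a reference
#'
#' Builds the paired measurements the accuracy statistics are computed
#' on. `kind = "continuous"` pairs every retained window with the mean of
#' the continuous reference over the window. `kind = "abga"` pairs each
#' arterial blood-gas sample with the nearest retained window whose
#' centre lies within `max_gap_s`; blood-gas samples with no such window
#' are dropped (they correspond to measurements of insufficient signal
#' quality).
#'
#' @param windows A `window_estimates` data frame carrying a `spo2_est`
#'   column (apply a calibration first).
#' @param ref The subject's `reference_series`.
#' @param kind `"continuous"` or `"abga"`.
#' @param max_gap_s Maximum blood-gas-to-window-centre distance (s).
#' @return Data frame with columns `subject_id`, `t_window` (window
#'   centre, s), `spo2_est`, `spo2_ref`, `activity`, `reference_kind`.
#' @examples
#' # see ?run_pipeline for the full chain
#' @export
pair_with_reference <- function(windows, ref,
                                kind = c("continuous", "abga"),
                                max_gap_s = 30) {
  kind <- match.arg(kind)
  if (!"spo2_est" %in% names(windows))
    stop("windows must carry calibrated estimates in 'spo2_est'")
  keep <- !windows$rejected & is.finite(windows$spo2_est)
  w <- windows[keep, , drop = FALSE]
  centre <- (w$t_start_s + w$t_end_s) / 2
  empty <- data.frame(subject_id = character(0), t_window = numeric(0),
                      spo2_est = numeric(0), spo2_ref = numeric(0),
                      activity = character(0),
                      reference_kind = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(w) == 0) return(empty)

  if (kind == "continuous") {
    refm <- window_reference_mean(w, ref)
    ok <- is.finite(refm)
    data.frame(subject_id = w$subject_id[ok], t_window = centre[ok],
               spo2_est = w$spo2_est[ok], spo2_ref = refm[ok],
               activity = w$activity[ok],
               reference_kind = "continuous", stringsAsFactors = FALSE)
  } else {
    if (!length(ref$abga_times_s)) return(empty)
    rows <- lapply(seq_along(ref$abga_times_s), function(j) {
      d <- abs(centre - ref$abga_times_s[j])
      i <- which.min(d)
      if (!length(i) || d[i] > max_gap_s) return(NULL)
      data.frame(subject_id = w$subject_id[i], t_window = centre[i],
                 spo2_est = w$spo2_est[i], spo2_ref = ref$sao2_abga[j],
                 activity = w$activity[i], reference_kind = "abga",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty else out
  }
}

#' Agreement statistics for paired SpO2 measurements
#'
#' The ISO-style accuracy panel for a set of (estimate, reference) pairs:
#' bias (mean error), precision (sample sd of the error, n-1), accuracy
#' root-mean-square error `A_RMS = sqrt(mean((est - ref)^2))` (n
#' denominator, by its definition), Pearson correlation with a two-sided
#' p-value, and Bland-Altman mean difference with 1.96-sd limits of
#' agreement. The identity
#' `A_RMS^2 = bias^2 + (n-1)/n * precision_sd^2` links the conventions.
#'
#' @param pairs Data frame with columns `spo2_est` and `spo2_ref` (e.g.
#'   from [pair_with_reference()]).
#' @return List of class `accuracy_stats` with `n_pairs`, `bias`,
#'   `precision_sd`, `arms`, `pearson_r`, `pearson_p`, `bland_altman`
#'   (`mean_diff`, `loa_low`, `loa_high`). Correlation is `NA` (flagged
#'   by `r_defined = FALSE`) when either series has zero variance.
#' @examples
#' p <- data.frame(spo2_est = c(92, 88), spo2_ref = c(90, 90))
#' compute_accuracy_stats(p)$arms  # 2
#' @export
compute_accuracy_stats <- function(pairs) {
  est <- pairs$spo2_est
  ref <- pairs$spo2_ref
  n <- length(est)
  if (n < 1) stop("no pairs to evaluate")
  d <- est - ref
  bias <- mean(d)
  prec <- if (n >= 2) stats::sd(d) else NA_real_
  arms <- sqrt(mean(d^2))
  r <- NA_real_; pval <- NA_real_; r_defined <- FALSE
  if (n >= 3 && stats::sd(est) > 0 && stats::sd(ref) > 0) {
    ct <- stats::cor.test(est, ref)
    r <- unname(ct$estimate); pval <- ct$p.value; r_defined <- TRUE
  }
  sd_d <- if (n >= 2) stats::sd(d) else 0
  structure(list(n_pairs = n,
                 bias = bias,
                 precision_sd = prec,
                 arms = arms,
                 pearson_r = r,
                 pearson_p = pval,
                 r_defined = r_defined,
                 bland_altman = list(mean_diff = bias,
                                     loa_low = bias - 1.96 * sd_d,
                                     loa_high = bias + 1.96 * sd_d)),
            class = "accuracy_stats")
}

#' @export
print.accuracy_stats <- function(x, ...) {
  cat(sprintf("n = %d | bias %.1f%% (sd %.1f) | A_RMS %.2f%% | r %s\n",
              x$n_pairs, x$bias,
              if (is.na(x$precision_sd)) NA else x$precision_sd, x$arms,
              if (x$r_defined) sprintf("%.2f", x$pearson_r) else "n/a"))
  cat(sprintf("Bland-Altman: %.1f [%.1f, %.1f]%%\n",
              x$bland_altman$mean_diff, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}

#' Activity-stratified evaluation
#'
#' Splits the paired measurements into `overall`, `walking` and
#' `stationary` (every non-walking activity) strata and computes the
#' accuracy panel independently per stratum. When the windows the pairs
#' came from are supplied, each stratum additionally gets its rejection
#' accounting computed from that stratum's own windows (per-stratum
#' denominators). Empty strata are absent from the result rather than
#' reported as zeros.
#'
#' @param pairs Paired measurements (with an `activity` column).
#' @param windows Optional `window_estimates` rows (all windows, not just
#'   retained ones) used for per-stratum rejection rates.
#' @return Named list of strata; each element carries `stats`
#'   ([compute_accuracy_stats()]) and, when windows were given,
#'   `rejection` ([rejection_accounting()]).
#' @examples
#' # see ?run_pipeline for the full chain
#' @export
stratify <- function(pairs, windows = NULL) {
  groups <- list(overall = rep(TRUE, nrow(pairs)),
                 walking = pairs$activity == "walking",
                 stationary = pairs$activity != "walking")
  out <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!any(sel)) next
    entry <- list(stats = compute_accuracy_stats(pairs[sel, , drop = FALSE]))
    if (!is.null(windows)) {
      wsel <- switch(g,
                     overall = rep(TRUE, nrow(windows)),
                     walking = windows$activity == "walking",
                     stationary = windows$activity != "walking")
      if (any(wsel))
        entry$rejection <- rejection_accounting(windows[wsel, , drop = FALSE])
    }
    out[[g]] <- entry
  }
  out
}
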