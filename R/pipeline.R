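#' Run the full simulation-to-evaluation pipeline
#'
#' Executes one end-to-end experiment: simulate a cohort, process every
#' recording into windows, discard windows without a stable reference,
#' leave-one-out calibrate the ROS-to-SpO2 line across subjects, apply
#' each subject's own cross-fitted model, pair against the continuous and
#' blood-gas references, and compute the stratified accuracy report. The
#' whole run is a deterministic function of the configuration (including
#' its seed). When `config$output_dir` is set, every stage's
#' intermediates are written there (per-subject CSVs, windows, report
#' JSON).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `oximetry_evaluation`: list with
#'   `calibration` (the `loo_calibration`), `windows` (all subjects'
#'   window estimates), `pairs_continuous`, `pairs_abga`, `strata`
#'   (per-activity-group statistics and rejection accounting), `abga`
#'   (accuracy panel against blood gas, when computable), `rejection`
#'   (overall accounting) and `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_subjects = 3, seed = 1)
#' ev <- run_pipeline(cfg)
#' print(ev)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("simulate",
                  make_cohort(config$n_subjects, config$simulation,
                              seed = config$seed))

  win_list <- stage("process", lapply(cohort, function(s)
    process_recording(s$recording, config$processing)))
  win_list <- stage("stable_reference", lapply(names(cohort), function(id)
    filter_stable_reference(win_list[[id]], cohort[[id]]$reference,
                            config$max_range_pct)))
  names(win_list) <- names(cohort)

  ## Calibration pairs: retained windows' ROS against the window-mean
  ## continuous reference.
  pairs_by_subject <- lapply(names(cohort), function(id) {
    w <- win_list[[id]]
    keep <- !w$rejected & is.finite(w$ros)
    w <- w[keep, , drop = FALSE]
    data.frame(ros = w$ros,
               spo2_ref = window_reference_mean(w, cohort[[id]]$reference))
  })
  names(pairs_by_subject) <- names(cohort)
  loo <- stage("calibrate", loo_calibrate(pairs_by_subject))

  for (id in names(cohort)) {
    m <- loo$per_subject_models[[id]]
    est <- apply_calibration(win_list[[id]]$ros, m, clamp = TRUE)
    win_list[[id]]$spo2_est <- as.numeric(est)
    win_list[[id]]$spo2_est_raw <- attr(est, "unclamped")
  }

  pairs_cont <- stage("pair", do.call(rbind, lapply(names(cohort),
    function(id) pair_with_reference(win_list[[id]], cohort[[id]]$reference,
                                     "continuous", config$max_gap_s))))
  pairs_abga <- stage("pair", do.call(rbind, lapply(names(cohort),
    function(id) pair_with_reference(win_list[[id]], cohort[[id]]$reference,
                                     "abga", config$max_gap_s))))

  windows_all <- do.call(rbind, win_list)
  rownames(windows_all) <- NULL

  strata <- stage("evaluate", stratify(pairs_cont, windows_all))
  abga_stats <- if (!is.null(pairs_abga) && nrow(pairs_abga) >= 2)
    stage("evaluate", compute_accuracy_stats(pairs_abga)) else NULL
  rejection <- stage("evaluate", rejection_accounting(windows_all))

  out <- structure(list(calibration = loo,
                        windows = windows_all,
                        pairs_continuous = pairs_cont,
                        pairs_abga = pairs_abga,
                        strata = strata,
                        abga = abga_stats,
                        rejection = rejection,
                        config = config),
                   class = "oximetry_evaluation")

  if (!is.null(config$output_dir))
    write_pipeline_outputs(out, cohort, config$output_dir)
  out
}

## Table-1-style matrix: rows Error / r / A_RMS / Rejection Rate, columns
## Overall / Walking / Stationary. Display rounding only (0.1 for
## percentages, 0.01 for r); internal values keep full precision.
report_table <- function(ev) {
  cols <- c("overall", "walking", "stationary")
  fmt <- function(g, what) {
    s <- ev$strata[[g]]
    if (is.null(s)) return(NA_character_)
    st <- s$stats
    switch(what,
      error = sprintf("%.1f (%.1f)", st$bias, st$precision_sd),
      r = if (st$r_defined) sprintf("%.2f", st$pearson_r) else "n/a",
      arms = sprintf("%.2f", st$arms),
      rej = if (!is.null(s$rejection))
        sprintf("%.1f", s$rejection$rejection_rate_pct) else NA_character_)
  }
  m <- rbind(`Error (%)` = vapply(cols, fmt, "", what = "error"),
             `r` = vapply(cols, fmt, "", what = "r"),
             `A_RMS (%)` = vapply(cols, fmt, "", what = "arms"),
             `Rejection Rate (%)` = vapply(cols, fmt, "", what = "rej"))
  colnames(m) <- c("Overall", "Walking", "Stationary")
  m
}

#' @export
print.oximetry_evaluation <- function(x, ...) {
  cat("Pulse-oximetry accuracy evaluation (",
      x$config$n_subjects, " subjects, ",
      x$config$simulation$protocol, ")\n\n", sep = "")
  print(x$calibration)
  cat("\nPerformance vs continuous reference:\n")
  print(report_table(x), quote = FALSE)
  if (!is.null(x$abga)) {
    cat("\nvs arterial blood gas (n = ", x$abga$n_pairs, "): ", sep = "")
    cat(sprintf("error %.1f%% (SD %.1f%%), A_RMS %.2f%%, r %s\n",
                x$abga$bias, x$abga$precision_sd, x$abga$arms,
                if (x$abga$r_defined) sprintf("%.2f", x$abga$pearson_r)
                else "n/a"))
  }
  cat(sprintf("\nWindows: %d total, %d retained (rejection %.1f%%)\n",
              x$rejection$n_total, x$rejection$n_retained,
              x$rejection$rejection_rate_pct))
  pr <- x$rejection$per_reason
  cat("  by reason: ",
      paste(sprintf("%s %d", names(pr), as.integer(pr)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Bland-Altman plot of an evaluation
#'
#' Difference-versus-mean agreement plot of the continuous-reference
#' pairs, with the bias line and 1.96-sd limits of agreement.
#'
#' @param x An `oximetry_evaluation`.
#' @param which `"continuous"` or `"abga"` pairs.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.oximetry_evaluation <- function(x, which = c("continuous", "abga"),
                                     ...) {
  which <- match.arg(which)
  pairs <- if (which == "continuous") x$pairs_continuous else x$pairs_abga
  if (is.null(pairs) || nrow(pairs) < 2)
    stop("not enough pairs to plot")
  st <- compute_accuracy_stats(pairs)
  m <- (pairs$spo2_est + pairs$spo2_ref) / 2
  d <- pairs$spo2_est - pairs$spo2_ref
  graphics::plot(m, d, xlab = "Mean of estimate and reference SpO2 (%)",
                 ylab = "Estimate - reference (%)",
                 main = sprintf("Bland-Altman (%s reference)", which), ...)
  graphics::abline(h = st$bland_altman$mean_diff, lty = 1)
  graphics::abline(h = c(st$bland_altman$loa_low, st$bland_altman$loa_high),
                   lty = 2)
  invisible(x)
}

## Serialise an evaluation report to a JSON-ready list.
report_to_list <- function(ev) {
  stat_list <- function(st) list(
    n_pairs = st$n_pairs, bias = st$bias, precision_sd = st$precision_sd,
    arms = st$arms,
    pearson_r = if (st$r_defined) st$pearson_r else NULL,
    bland_altman = st$bland_altman)
  strata <- lapply(ev$strata, function(s) {
    out <- list(stats = stat_list(s$stats))
    if (!is.null(s$rejection))
      out$rejection_rate_pct <- s$rejection$rejection_rate_pct
    out
  })
  list(calibration = list(
         mean_a = ev$calibration$coefficient_summary$mean[1],
         sd_a = ev$calibration$coefficient_summary$sd[1],
         mean_b = ev$calibration$coefficient_summary$mean[2],
         sd_b = ev$calibration$coefficient_summary$sd[2]),
       strata = strata,
       abga = if (!is.null(ev$abga)) stat_list(ev$abga) else NULL,
       rejection = list(
         n_total = ev$rejection$n_total,
         n_retained = ev$rejection$n_retained,
         rejection_rate_pct = ev$rejection$rejection_rate_pct,
         per_reason = as.list(ev$rejection$per_reason)))
}

write_pipeline_outputs <- function(ev, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort)) {
    write_recording(cohort[[id]]$recording,
                    file.path(dir, paste0(id, "_recording.csv")))
    write_reference(cohort[[id]]$reference,
                    file.path(dir, paste0(id, "_reference.csv")),
                    file.path(dir, paste0(id, "_abga.csv")))
    write_ground_truth(cohort[[id]]$truth,
                       file.path(dir, paste0(id, "_truth.csv")))
  }
  utils::write.csv(ev$windows, file.path(dir, "windows.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$pairs_continuous, file.path(dir, "pairs_continuous.csv"),
                   row.names = FALSE)
  if (!is.null(ev$pairs_abga))
    utils::write.csv(ev$pairs_abga, file.path(dir, "pairs_abga.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report_to_list(ev), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
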