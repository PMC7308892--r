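#' Fit the linear ROS-to-SpO2 calibration
#'
#' Ordinary least squares of reference SpO2 on the ratio of signals:
#' `SpO2 = a * ROS + b`. The reference saturation is the response, ROS
#' the predictor.
#'
#' @param ros Ratio-of-signals values (dimensionless).
#' @param spo2_ref Reference saturations (%), same length.
#' @param subjects_used Optional character vector recording which
#'   subjects contributed the pairs (fit provenance).
#' @return An object of class `spo2_calibration`: list with `a` (slope,
#'   % per unit ROS), `b` (intercept, %), `n_points`, `subjects_used` and
#'   `residual_sd` (%, n-2 denominator; `NA` for exactly two points).
#' @examples
#' fit <- fit_calibration(c(1, 2), c(90, 60))
#' coef(fit)  # a = -30, b = 120
#' @export
fit_calibration <- function(ros, spo2_ref, subjects_used = character(0)) {
  if (length(ros) != length(spo2_ref))
    stop("ros and spo2_ref must have equal length")
  ok <- is.finite(ros) & is.finite(spo2_ref)
  ros <- ros[ok]; spo2_ref <- spo2_ref[ok]
  n <- length(ros)
  if (n < 2)
    stop("need at least two (ros, spo2) pairs")
  if (length(unique(ros)) < 2)
    stop("degenerate design: all ROS values identical")
  fit <- stats::lm(spo2_ref ~ ros)
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["ros"]),
                 b = unname(cf["(Intercept)"]),
                 n_points = n,
                 subjects_used = subjects_used,
                 residual_sd = if (n > 2)
                   sqrt(sum(stats::residuals(fit)^2) / (n - 2)) else NA_real_),
            class = "spo2_calibration")
}

#' @export
coef.spo2_calibration <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
print.spo2_calibration <- function(x, ...) {
  cat("ROS -> SpO2 calibration: SpO2 = ", signif(x$a, 6), " * ROS + ",
      signif(x$b, 6), "\n", sep = "")
  cat("  n = ", x$n_points, ", residual sd = ",
      if (is.na(x$residual_sd)) "NA" else signif(x$residual_sd, 3),
      "%\n", sep = "")
  if (length(x$subjects_used))
    cat("  fitted on subjects: ", paste(x$subjects_used, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @rdname apply_calibration
#' @param object A `spo2_calibration`.
#' @param ... Unused.
#' @export
predict.spo2_calibration <- function(object, ros, clamp = TRUE, ...) {
  apply_calibration(ros, object, clamp = clamp)
}

#' Apply a calibration line to ROS values
#'
#' Computes `SpO2 = a * ROS + b`. For reporting, values are clamped to
#' \[0, 100\]; the unclamped values are preserved in the `"unclamped"`
#' attribute (and returned directly with `clamp = FALSE`).
#'
#' @param ros ROS values.
#' @param model A [fit_calibration()] object, or any list with elements
#'   `a` and `b`.
#' @param clamp Clamp the reported values into \[0, 100\]?
#' @return SpO2 values (%), vectorised over `ros`.
#' @examples
#' apply_calibration(1, list(a = -26.8, b = 116.9))  # 90.1
#' @export
apply_calibration <- function(ros, model, clamp = TRUE) {
  if (!all(c("a", "b") %in% names(model)))
    stop("model must provide slope 'a' and intercept 'b'")
  raw <- model$a * ros + model$b
  if (!clamp) return(raw)
  out <- pmin(100, pmax(0, raw))
  attr(out, "unclamped") <- raw
  out
}

#' Leave-one-subject-out calibration across a cohort
#'
#' For each subject, fits the ROS-to-SpO2 line on the pooled retained
#' windows of *all other* subjects, so no subject is calibrated on its
#' own data. The coefficient summary reports the mean and sample standard
#' deviation (n-1) of the slope and intercept across the per-subject
#' models, matching the convention of reporting a distribution of
#' calibration coefficients.
#'
#' @param pairs_by_subject Named list, one element per subject, each a
#'   data frame (or list) with components `ros` and `spo2_ref` holding
#'   that subject's retained window pairs.
#' @return An object of class `loo_calibration`: list with
#'   `per_subject_models` (named list of [fit_calibration()] objects) and
#'   `coefficient_summary` (data frame with the mean and sd of `a` and
#'   `b`).
#' @examples
#' p <- list(S1 = data.frame(ros = c(1, 2), spo2_ref = c(90, 60)),
#'           S2 = data.frame(ros = c(1, 1.5), spo2_ref = c(90, 75)))
#' loo <- loo_calibrate(p)
#' coef(loo)
#' @export
loo_calibrate <- function(pairs_by_subject) {
  ids <- names(pairs_by_subject)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("pairs_by_subject must be a named list (one element per subject)")
  if (length(ids) < 2)
    stop("leave-one-out calibration needs at least two subjects")
  models <- vector("list", length(ids))
  names(models) <- ids
  for (i in seq_along(ids)) {
    others <- ids[-i]
    ros <- unlist(lapply(pairs_by_subject[others], function(p) p$ros),
                  use.names = FALSE)
    spo2 <- unlist(lapply(pairs_by_subject[others], function(p) p$spo2_ref),
                   use.names = FALSE)
    ok <- is.finite(ros) & is.finite(spo2)
    if (sum(ok) < 2 || length(unique(ros[ok])) < 2)
      stop("excluding subject '", ids[i], "' leaves fewer than two ",
           "distinct ROS values to calibrate on")
    models[[i]] <- fit_calibration(ros, spo2, subjects_used = others)
  }
  a <- vapply(models, function(m) m$a, numeric(1))
  b <- vapply(models, function(m) m$b, numeric(1))
  structure(list(per_subject_models = models,
                 coefficient_summary = data.frame(
                   coefficient = c("a", "b"),
                   mean = c(mean(a), mean(b)),
                   sd = c(stats::sd(a), stats::sd(b)))),
            class = "loo_calibration")
}

#' @export
coef.loo_calibration <- function(object, ...) {
  t(vapply(object$per_subject_models, coef, numeric(2)))
}

#' @export
print.loo_calibration <- function(x, ...) {
  s <- x$coefficient_summary
  cat("Leave-one-out calibration over ",
      length(x$per_subject_models), " subjects\n", sep = "")
  cat(sprintf("  a = %.1f +/- %.1f,  b = %.1f +/- %.1f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  invisible(x)
}
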