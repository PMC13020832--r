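# External-validation metric suite: agreement between observed and predicted
# 1-year PDC.  The calibration model is
#   observed_i = alpha_cal + lambda_cal * predicted_i + e_i,
# perfect calibration meaning alpha_cal = 0, lambda_cal = 1.  CITL is the
# mean observed minus mean predicted outcome; when lambda_cal = 1 the
# calibration intercept equals CITL.

.check_pairs <- function(observed, predicted) {
  if (length(observed) == 0L || length(observed) != length(predicted))
    stop("`observed` and `predicted` must be non-empty vectors of equal length",
         call. = FALSE)
  if (anyNA(observed) || anyNA(predicted))
    stop("`observed` and `predicted` must not contain missing values",
         call. = FALSE)
  invisible(NULL)
}

#' Calibration-in-the-large
#'
#' Mean observed outcome minus mean predicted outcome; 0 for a model that is
#' calibrated on average.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A single number, `mean(observed) - mean(predicted)`.
#' @examples
#' citl(c(0.5, 0.7), c(0.4, 0.6))  # 0.1
#' @export
citl <- function(observed, predicted) {
  .check_pairs(observed, predicted)
  mean(observed) - mean(predicted)
}

#' Calibration model fit (intercept, slope, slope CI)
#'
#' Ordinary least-squares fit of observed on predicted outcomes.  The 95%
#' (or `level`) confidence interval for the slope uses the normal-theory
#' standard error with n - 2 degrees of freedom; a nonparametric bootstrap
#' percentile interval is available as an option.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 3;
#'   `predicted` must have non-zero variance.
#' @param level Confidence level for the slope interval (default 0.95).
#' @param method `"normal"` (t-based, default) or `"bootstrap"` (percentile).
#' @param boot_reps Bootstrap replicates when `method = "bootstrap"`.
#' @return A list with `intercept` (alpha_cal), `slope` (lambda_cal),
#'   `slope_se`, `slope_ci` (length-2 vector) and the underlying `lm` fit.
#' @examples
#' p <- runif(50); o <- 0.1 + 0.9 * p
#' calibration_fit(o, p)$slope  # 0.9
#' @export
calibration_fit <- function(observed, predicted, level = 0.95,
                            method = c("normal", "bootstrap"),
                            boot_reps = 1000L) {
  method <- match.arg(method)
  .check_pairs(observed, predicted)
  n <- length(observed)
  if (n < 3L) stop("calibration fit needs at least 3 observations",
                   call. = FALSE)
  if (var(predicted) == 0)
    stop("`predicted` has zero variance; calibration slope is undefined",
         call. = FALSE)
  fit <- lm(observed ~ predicted)
  est <- coef(fit)
  slope <- unname(est["predicted"])
  intercept <- unname(est["(Intercept)"])
  # residual SE can be exactly 0 for an exact affine relation; summary.lm
  # then reports NaN standard errors, so compute the SE directly
  sse <- sum(fit$residuals^2)
  sxx <- sum((predicted - mean(predicted))^2)
  slope_se <- sqrt(sse / (n - 2) / sxx)
  if (method == "normal") {
    tq <- qt(1 - (1 - level) / 2, df = n - 2)
    ci <- slope + c(-1, 1) * tq * slope_se
  } else {
    reps <- vapply(seq_len(boot_reps), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (var(predicted[i]) == 0) return(NA_real_)
      unname(coef(lm(observed[i] ~ predicted[i]))[2L])
    }, numeric(1))
    ci <- unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, type = 7))
  }
  list(intercept = intercept, slope = slope, slope_se = slope_se,
       slope_ci = ci, level = level, fit = fit)
}

#' Proportion of variance explained in external validation
#'
#' \eqn{R^2_{val} = 1 - \sum (o_i - p_i)^2 / \sum (o_i - \bar o)^2},
#' computed on the raw predictions without refitting.  Can be negative for a
#' badly miscalibrated model.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 2;
#'   `observed` must have non-zero variance.
#' @return A single number, at most 1.
#' @examples
#' r2_val(c(0, 1), c(0.25, 0.75))  # 0.75
#' @export
r2_val <- function(observed, predicted) {
  .check_pairs(observed, predicted)
  if (length(observed) < 2L || var(observed) == 0)
    stop("`observed` must have non-zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Prediction-error metrics
#'
#' RMSE, MAE, the MAE of a constant baseline predicting `mean(observed)` for
#' everyone, and the relative MAE reduction
#' \eqn{1 - \mathrm{MAE} / \mathrm{MAE}_{baseline}} (the fraction of the
#' baseline's absolute error that the model eliminates).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A list with `rmse`, `mae`, `baseline_mae` and
#'   `relative_mae_reduction` (`NA` when the observed outcome is constant,
#'   making the baseline MAE zero).
#' @examples
#' error_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
#' @export
error_metrics <- function(observed, predicted) {
  .check_pairs(observed, predicted)
  err <- observed - predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  baseline_mae <- mean(abs(observed - mean(observed)))
  reduction <- if (baseline_mae == 0) NA_real_ else 1 - mae / baseline_mae
  list(rmse = rmse, mae = mae, baseline_mae = baseline_mae,
       relative_mae_reduction = reduction)
}

#' Quantile of the absolute prediction error
#'
#' The `q`-quantile of `abs(observed - predicted)` under the
#' linear-interpolation convention (type 7).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param q Probability (or vector of probabilities) in \[0, 1\].
#' @return Numeric vector of quantiles, named by probability.
#' @examples
#' abs_error_quantile(c(0.1, 0.2, 0.3, 0.4), rep(0, 4), 0.5)  # 0.25
#' @export
abs_error_quantile <- function(observed, predicted, q) {
  .check_pairs(observed, predicted)
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  quantile(abs(observed - predicted), probs = q, type = 7, names = TRUE)
}

#' Calibration bins (grouped observed vs predicted means)
#'
#' Partitions the observations into `n_bins` equal-count bins by predicted
#' value (quantile binning) and returns per-bin mean predicted, mean
#' observed and count, in ascending predicted order — the data behind a
#' binned calibration curve.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param n_bins Number of bins (>= 1); default 10 (deciles).
#' @return A data frame with columns `bin`, `mean_predicted`,
#'   `mean_observed`, `count`.
#' @export
calibration_bins <- function(observed, predicted, n_bins = 10L) {
  .check_pairs(observed, predicted)
  .check_number(n_bins, "n_bins", 1)
  n <- length(observed)
  n_bins <- min(as.integer(n_bins), n)
  # equal-count assignment by rank; ties split by first occurrence
  r <- rank(predicted, ties.method = "first")
  bin <- ceiling(r * n_bins / n)
  out <- data.frame(
    bin = seq_len(n_bins),
    mean_predicted = as.numeric(tapply(predicted, bin, mean)),
    mean_observed = as.numeric(tapply(observed, bin, mean)),
    count = as.integer(tapply(observed, bin, length))
  )
  out[order(out$mean_predicted), , drop = FALSE]
}

#' External validation of a PDC prediction model
#'
#' Computes the full external-validation metric suite comparing observed and
#' predicted 1-year PDC: R-squared (1 - SSE/SST on raw predictions, with the
#' squared Pearson correlation and the refitted calibration R-squared as
#' secondary fields), calibration-in-the-large, calibration intercept and
#' slope with confidence interval, RMSE, MAE, baseline MAE, relative MAE
#' reduction, absolute-error quantiles and a binned calibration curve.  The
#' per-observation signed and absolute errors are kept on the object for
#' histograms.
#'
#' @param observed,predicted Equal-length numeric vectors of observed and
#'   predicted proportions.
#' @param n_bins Number of calibration bins (default 10).
#' @param quantiles Probabilities at which to report absolute-error
#'   quantiles.
#' @param level Confidence level for the slope interval.
#' @return An object of class `pdc_validation` with fields `n`, `r2_val`,
#'   `r2_pearson`, `r2_calibration`, `citl`, `cal_intercept`, `cal_slope`,
#'   `cal_slope_se`, `cal_slope_ci95`, `rmse`, `mae`, `baseline_mae`,
#'   `relative_mae_reduction`, `abs_error_quantiles`, `calibration_bins`,
#'   `errors`, `abs_errors`.
#' @examples
#' m <- builtin_models()$statin
#' x <- sample(0:90, 500, replace = TRUE)
#' p <- predict(m, x)
#' o <- pmin(pmax(p + rnorm(500, 0, 0.1), 0), 1)
#' external_validation(o, p)
#' @export
external_validation <- function(observed, predicted, n_bins = 10L,
                                quantiles = c(0.25, 0.5, 0.7, 0.75, 0.9),
                                level = 0.95) {
  .check_pairs(observed, predicted)
  cal <- calibration_fit(observed, predicted, level = level)
  em <- error_metrics(observed, predicted)
  bins <- calibration_bins(observed, predicted, n_bins)
  out <- list(
    n = length(observed),
    r2_val = r2_val(observed, predicted),
    r2_pearson = suppressWarnings(stats::cor(observed, predicted))^2,
    r2_calibration = suppressWarnings(summary(cal$fit)$r.squared),
    citl = citl(observed, predicted),
    cal_intercept = cal$intercept,
    cal_slope = cal$slope,
    cal_slope_se = cal$slope_se,
    cal_slope_ci95 = cal$slope_ci,
    rmse = em$rmse,
    mae = em$mae,
    baseline_mae = em$baseline_mae,
    relative_mae_reduction = em$relative_mae_reduction,
    abs_error_quantiles = abs_error_quantile(observed, predicted, quantiles),
    calibration_bins = bins,
    errors = observed - predicted,
    abs_errors = abs(observed - predicted)
  )
  class(out) <- "pdc_validation"
  out
}

#' @export
print.pdc_validation <- function(x, digits = 3, ...) {
  cat(sprintf("External validation (n = %d)\n", x$n))
  cat(sprintf("  R-squared (1 - SSE/SST):      %.*f\n", digits, x$r2_val))
  cat(sprintf("  Calibration-in-the-large:     %.*f\n", digits, x$citl))
  cat(sprintf("  Calibration slope:            %.*f (95%% CI %.*f, %.*f)\n",
              digits, x$cal_slope, digits, x$cal_slope_ci95[1],
              digits, x$cal_slope_ci95[2]))
  cat(sprintf("  Calibration intercept:        %.*f\n", digits,
              x$cal_intercept))
  cat(sprintf("  RMSE: %.*f   MAE: %.*f   baseline MAE: %.*f\n",
              digits, x$rmse, digits, x$mae, digits, x$baseline_mae))
  if (is.na(x$relative_mae_reduction)) {
    cat("  Relative MAE reduction:       undefined (constant outcome)\n")
  } else {
    cat(sprintf("  Relative MAE reduction:       %.1f%%\n",
                100 * x$relative_mae_reduction))
  }
  invisible(x)
}

#' @export
summary.pdc_validation <- function(object, ...) {
  print(object, ...)
  cat("\nAbsolute-error quantiles:\n")
  print(round(object$abs_error_quantiles, 4))
  cat("\nCalibration bins:\n")
  print(object$calibration_bins, row.names = FALSE)
  invisible(object)
}

#' @export
residuals.pdc_validation <- function(object, ...) object$errors

#' Plot an external-validation report
#'
#' `which = "calibration"` draws the binned calibration curve (mean observed
#' vs mean predicted per bin) with the identity line; `"errors"` and
#' `"abs_errors"` draw histograms of the signed and absolute prediction
#' errors with mean and mean +/- SD reference lines.
#'
#' @param x A `pdc_validation` object.
#' @param which One of `"calibration"`, `"errors"`, `"abs_errors"`.
#' @param ... Passed on to the underlying plotting function.
#' @return The object, invisibly.
#' @export
plot.pdc_validation <- function(x, which = c("calibration", "errors",
                                             "abs_errors"), ...) {
  which <- match.arg(which)
  if (which == "calibration") {
    b <- x$calibration_bins
    plot(b$mean_predicted, b$mean_observed, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "Mean predicted 1-year PDC", ylab = "Mean observed 1-year PDC",
         pch = 19, ...)
    lines(b$mean_predicted, b$mean_observed, col = "steelblue")
    abline(0, 1, lty = 2)
  } else {
    v <- if (which == "errors") x$errors else x$abs_errors
    hist(v, xlab = if (which == "errors") "Observed - predicted PDC"
         else "Absolute error", main = NULL, ...)
    abline(v = mean(v), lwd = 2)
    abline(v = mean(v) + c(-1, 1) * sd(v), lty = 2)
  }
  invisible(x)
}

#' Write an external-validation report to disk
#'
#' Writes `report.json` (all scalar metrics and quantiles), `errors.csv`
#' (per-observation signed and absolute errors) and `calibration_bins.csv`.
#'
#' @param report A `pdc_validation` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "pdc_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scalars <- report[c("n", "r2_val", "r2_pearson", "r2_calibration", "citl",
                      "cal_intercept", "cal_slope", "cal_slope_se", "rmse",
                      "mae", "baseline_mae", "relative_mae_reduction")]
  scalars$cal_slope_ci95 <- as.numeric(report$cal_slope_ci95)
  scalars$abs_error_quantiles <- as.list(report$abs_error_quantiles)
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write.csv(data.frame(error = report$errors, abs_error = report$abs_errors),
            file.path(dir, "errors.csv"), row.names = FALSE)
  write.csv(report$calibration_bins, file.path(dir, "calibration_bins.csv"),
            row.names = FALSE)
  invisible(dir)
}
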