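# Minimum sample size for external validation of a continuous-outcome
# prediction model.  Four criteria: precision of R-squared, of
# calibration-in-the-large, of the calibration slope, and of the residual
# spread of the calibration model; the overall minimum is the largest of the
# four.

#' Sample size to estimate R-squared precisely (criterion i)
#'
#' Minimum number of patients needed so that the standard error of the
#' estimated proportion of explained variance in an external-validation
#' dataset does not exceed a target, using
#' \eqn{n = 4 R^2 (1 - R^2)^2 / \mathrm{SE}^2}.
#'
#' @param r2_val Anticipated R-squared in the validation data, in (0, 1).
#' @param se_r2 Target standard error of the R-squared estimate (> 0).
#' @return A list with `raw` (the real-valued formula result) and `n`
#'   (its ceiling, the minimum integer sample size).
#' @examples
#' n_for_r2(0.5, 0.0255)  # raw 768.93, n 769
#' @export
n_for_r2 <- function(r2_val, se_r2) {
  .check_number(r2_val, "r2_val", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  .check_number(se_r2, "se_r2", 0, strict_lower = TRUE)
  raw <- 4 * r2_val * (1 - r2_val)^2 / se_r2^2
  list(raw = raw, n = as.integer(ceiling(raw)))
}

#' Sample size to estimate calibration-in-the-large precisely (criterion ii)
#'
#' Minimum number of patients so that the standard error of the difference
#' between mean observed and mean predicted outcome (CITL) does not exceed a
#' target, using \eqn{n = \mathrm{var}(Y) (1 - R^2) / \mathrm{SE}^2}.
#'
#' @param var_y Anticipated variance of the outcome (> 0).
#' @param r2_val Anticipated R-squared, in (0, 1).
#' @param se_citl Target standard error of CITL (> 0).
#' @return A list with `raw` and integer `n` (ceiling).
#' @examples
#' n_for_citl(0.04, 0.5, 0.0255)  # raw 30.76, n 31
#' @export
n_for_citl <- function(var_y, r2_val, se_citl) {
  .check_number(var_y, "var_y", 0, strict_lower = TRUE)
  .check_number(r2_val, "r2_val", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  .check_number(se_citl, "se_citl", 0, strict_lower = TRUE)
  raw <- var_y * (1 - r2_val) / se_citl^2
  list(raw = raw, n = as.integer(ceiling(raw)))
}

#' Sample size to estimate the calibration slope precisely (criterion iii)
#'
#' Minimum number of patients so that the standard error of the calibration
#' slope does not exceed a target, using
#' \eqn{n = \lambda^2 (1 - R^2) / (\mathrm{SE}^2 R^2) + 1}.
#'
#' @param lambda_cal Anticipated calibration slope (finite; 0 allowed, giving
#'   the degenerate minimum of 1).
#' @param r2_val Anticipated R-squared of the calibration model, in (0, 1).
#' @param se_lambda Target standard error of the slope (> 0).
#' @return A list with `raw` and integer `n` (ceiling).
#' @examples
#' n_for_slope(1, 0.5, 0.051)  # raw 385.47, n 386
#' @export
n_for_slope <- function(lambda_cal, r2_val, se_lambda) {
  .check_number(lambda_cal, "lambda_cal")
  .check_number(r2_val, "r2_val", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  .check_number(se_lambda, "se_lambda", 0, strict_lower = TRUE)
  raw <- lambda_cal^2 * (1 - r2_val) / (se_lambda^2 * r2_val) + 1
  list(raw = raw, n = as.integer(ceiling(raw)))
}

#' Sample size to estimate the residual spread precisely (criterion iv)
#'
#' Smallest number of patients such that the 95% chi-square confidence
#' interval for the residual standard deviation of the calibration model has
#' multiplicative margin of error at most `moe_resid`: the smallest `n` with
#' \eqn{\sqrt{m / \chi^2_{0.025, m}} \le 1 + \mathrm{moe}} where
#' \eqn{m = n - p - 1} residual degrees of freedom for a calibration model
#' with `p_cal` predictors.
#'
#' @param moe_resid Multiplicative margin of error on the residual-SD scale,
#'   in (0, 1); default 0.10.
#' @param p_cal Number of predictors in the calibration model (>= 1);
#'   default 1 (observed regressed on predicted only).
#' @return A list with `m` (residual degrees of freedom at the solution) and
#'   integer `n`.
#' @examples
#' n_for_residual_sd(0.10, 1)  # n 235 (m = 233)
#' @export
n_for_residual_sd <- function(moe_resid = 0.10, p_cal = 1) {
  .check_number(moe_resid, "moe_resid", 0, 1,
                strict_lower = TRUE, strict_upper = TRUE)
  .check_number(p_cal, "p_cal", 1)
  margin <- function(m) sqrt(m / qchisq(0.025, m))
  m <- 2L
  while (margin(m) > 1 + moe_resid) {
    m <- m + 1L
    if (m > 1e7L) stop("no solution found for `moe_resid`", call. = FALSE)
  }
  list(m = m, n = as.integer(m + p_cal + 1))
}

#' Overall minimum sample size for external validation
#'
#' Evaluates all four minimum-sample-size criteria for external validation of
#' a continuous-outcome prediction model and returns the maximum — the
#' criterion with the highest requirement governs.  Defaults are the worked
#' planning inputs for the post-stroke adherence validation: anticipated
#' R-squared 0.5, SE targets 0.0255 (R-squared and CITL) and 0.051 (slope),
#' outcome variance 0.04, slope 1, 10% residual-SD margin, one calibration
#' predictor — giving criterion sizes 769, 31, 386, 235 and overall 769.
#'
#' @param r2_val Anticipated R-squared in the validation data, in (0, 1).
#' @param se_r2,se_citl,se_lambda Target standard errors for R-squared, CITL
#'   and the calibration slope (> 0).
#' @param var_y Anticipated outcome variance (> 0).
#' @param lambda_cal Anticipated calibration slope.
#' @param moe_resid Residual-SD margin of error, in (0, 1).
#' @param p_cal Number of calibration-model predictors (>= 1).
#' @return An object of class `pdc_samplesize`: a list with `criteria` (a
#'   data frame with one row per criterion: raw value and integer minimum n)
#'   and `overall_n` (the maximum of the per-criterion sizes).
#' @examples
#' validation_samplesize()
#' @export
validation_samplesize <- function(r2_val = 0.5, se_r2 = 0.0255,
                                  var_y = 0.04, se_citl = 0.0255,
                                  lambda_cal = 1, se_lambda = 0.051,
                                  moe_resid = 0.10, p_cal = 1) {
  c1 <- n_for_r2(r2_val, se_r2)
  c2 <- n_for_citl(var_y, r2_val, se_citl)
  c3 <- n_for_slope(lambda_cal, r2_val, se_lambda)
  c4 <- n_for_residual_sd(moe_resid, p_cal)
  criteria <- data.frame(
    criterion = c("r2", "citl", "slope", "residual_sd"),
    raw = c(round(c1$raw, 2), round(c2$raw, 2), round(c3$raw, 2), NA_real_),
    n = c(c1$n, c2$n, c3$n, c4$n),
    stringsAsFactors = FALSE
  )
  out <- list(criteria = criteria,
              overall_n = max(criteria$n),
              inputs = list(r2_val = r2_val, se_r2 = se_r2, var_y = var_y,
                            se_citl = se_citl, lambda_cal = lambda_cal,
                            se_lambda = se_lambda, moe_resid = moe_resid,
                            p_cal = p_cal))
  class(out) <- "pdc_samplesize"
  out
}

#' @export
print.pdc_samplesize <- function(x, ...) {
  cat("Minimum sample size for external validation\n\n")
  labs <- c(r2 = "(i)   precise R-squared",
            citl = "(ii)  precise calibration-in-the-large",
            slope = "(iii) precise calibration slope",
            residual_sd = "(iv)  precise residual SD")
  for (i in seq_len(nrow(x$criteria))) {
    row <- x$criteria[i, ]
    raw <- if (is.na(row$raw)) "" else sprintf(" (raw %.2f)", row$raw)
    cat(sprintf("  %-42s n = %d%s\n", labs[[row$criterion]], row$n, raw))
  }
  cat(sprintf("\nOverall minimum (largest criterion): %d patients\n",
              x$overall_n))
  invisible(x)
}
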