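# Logit-linear (beta-regression mean) adherence prediction models.  Only the
# fitted mean equation is applied: logit(1-year PDC) = intercept +
# slope * (days covered in the first 90 days); predictions are the
# inverse-logit of that linear predictor.

#' Construct a PDC prediction model
#'
#' A `pdc_model` holds the logit-scale intercept and slope of a published
#' beta-regression mean model predicting 1-year PDC from the number of days
#' covered in the first 90 days post-index.
#'
#' @param intercept Logit-scale intercept (finite).
#' @param slope Logit-scale slope per covered day (finite).
#' @param name Model label.
#' @param predictor_name Label of the single predictor.
#' @return An object of class `pdc_model`.
#' @examples
#' m <- pdc_model(-1.65, 0.04, name = "statin")
#' predict(m, c(0, 30, 90))
#' @export
pdc_model <- function(intercept, slope, name = "custom",
                      predictor_name = "days covered at 90") {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept) ||
      !is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("model intercept and slope must be single finite numbers",
         call. = FALSE)
  structure(list(name = as.character(name),
                 intercept = as.numeric(intercept),
                 slope = as.numeric(slope),
                 predictor_name = as.character(predictor_name)),
            class = "pdc_model")
}

#' @export
print.pdc_model <- function(x, ...) {
  cat(sprintf("PDC prediction model '%s'\n", x$name))
  cat(sprintf("  logit(1-year PDC) = %g + %g * (%s)\n",
              x$intercept, x$slope, x$predictor_name))
  invisible(x)
}

#' Built-in published models
#'
#' The two published single-predictor models validated in post-stroke
#' patients: statins with logit-scale intercept -1.65 and slope 0.04, and
#' antiplatelets (aspirin/clopidogrel) with intercept -1.52 and slope 0.04.
#' Read from the plain-JSON model registry shipped with the package, so
#' recalibrated or re-estimated specifications can be added without code
#' changes (see [read_model_registry()]).
#'
#' @return A named list of [pdc_model] objects, `statin` and `antiplatelet`.
#' @examples
#' builtin_models()$statin
#' @export
builtin_models <- function() {
  path <- system.file("extdata", "models.json", package = "pdcval",
                      mustWork = TRUE)
  read_model_registry(path)
}

#' Read a model registry file
#'
#' A registry is a JSON array of objects with fields `name`, `intercept`,
#' `slope` and optionally `predictor_name`.
#'
#' @param path Path to a JSON registry file.
#' @return A named list of [pdc_model] objects.
#' @export
read_model_registry <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(recs, function(r) {
    pdc_model(r$intercept, r$slope, name = r$name,
              predictor_name = r$predictor_name %||% "days covered at 90")
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict 1-year PDC from 90-day adherence
#'
#' Applies the inverse-logit back-transformation
#' \eqn{\mathrm{PDC} = 1 / (1 + e^{-(\beta_0 + \beta_1 x)})} to the number of
#' days covered in the first 90 days.  Predictions lie strictly inside
#' (0, 1), preserving the beta-mean interpretation.
#'
#' @param object A [pdc_model].
#' @param newdata Numeric vector of days covered at 90 days, each in
#'   \[0, 90\] (or a data frame with a `days_covered_90` column).
#' @param range_action What to do when a predictor value falls outside
#'   \[0, 90\]: `"error"` (default), `"warn"`, or `"none"`.
#' @param ... Unused.
#' @return Numeric vector of predicted proportions in (0, 1).
#' @examples
#' predict(builtin_models()$statin, 0)   # ~0.161
#' predict(builtin_models()$statin, 90)  # ~0.875
#' @export
predict.pdc_model <- function(object, newdata,
                              range_action = c("error", "warn", "none"), ...) {
  range_action <- match.arg(range_action)
  if (is.data.frame(newdata)) {
    if (!"days_covered_90" %in% names(newdata))
      stop("`newdata` data frame must have a `days_covered_90` column",
           call. = FALSE)
    newdata <- newdata$days_covered_90
  }
  x <- as.numeric(newdata)
  if (anyNA(x) || any(!is.finite(x)))
    stop("predictor values must be finite", call. = FALSE)
  out_of_range <- x < 0 | x > 90
  if (any(out_of_range)) {
    msg <- sprintf("%d predictor value(s) outside [0, 90]", sum(out_of_range))
    if (range_action == "error") stop(msg, call. = FALSE)
    if (range_action == "warn") warning(msg, call. = FALSE)
  }
  plogis(object$intercept + object$slope * x)
}

#' Mean-shift recalibration
#'
#' Adapts predictions to a population whose mean outcome differs from the
#' development population by adding the difference in means (`delta`) to
#' every prediction on the probability scale, then clipping to \[0, 1\].
#' When no clipping occurs the mean of the output exceeds the mean of the
#' input by exactly `delta`, so recalibrating with `delta` equal to the
#' observed calibration-in-the-large drives CITL to zero.
#'
#' @param predictions Numeric vector of predicted proportions in \[0, 1\].
#' @param delta Mean shift on the probability scale.
#' @return Shifted (and possibly clipped) predictions in \[0, 1\].
#' @examples
#' mean_recalibrate(c(0.4, 0.6), delta = -0.025)
#' @export
mean_recalibrate <- function(predictions, delta) {
  p <- as.numeric(predictions)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("`predictions` must be proportions in [0, 1]", call. = FALSE)
  .check_number(delta, "delta")
  pmin(pmax(p + delta, 0), 1)
}
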