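test_that("CITL is the mean observed minus mean predicted outcome", {
  expect_identical(citl(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(citl(c(0.5, 0.7), c(0.4, 0.6)), 0.1)
  # the published antiplatelet mean pair: 50.6% observed vs 53.1% predicted
  expect_equal(citl(c(0.406, 0.606), c(0.431, 0.631)), -0.025)
  expect_error(citl(c(0.5), c(0.4, 0.6)), "equal length")
  expect_error(citl(numeric(0), numeric(0)), "non-empty")
})

test_that("calibration fit recovers exact affine relations", {
  p <- seq(0.1, 0.9, length.out = 20)
  # observed = predicted exactly: slope 1, intercept 0, zero-width CI
  fit <- calibration_fit(p, p)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(diff(fit$slope_ci), 0, tolerance = 1e-10)
  # exact affine relation
  fit2 <- calibration_fit(0.1 + 0.9 * p, p)
  expect_equal(fit2$slope, 0.9, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.1, tolerance = 1e-12)
  # degenerate inputs
  expect_error(calibration_fit(p, rep(0.5, 20)), "zero variance")
  expect_error(calibration_fit(c(0.1, 0.2), c(0.1, 0.3)), "at least 3")
})

test_that("slope CI matches normal theory and bootstrap agrees roughly", {
  set.seed(5)
  p <- runif(400, 0.1, 0.9)
  o <- pmin(pmax(p + rnorm(400, 0, 0.15), 0), 1)
  fit <- calibration_fit(o, p)
  lmfit <- lm(o ~ p)
  expect_equal(fit$slope, unname(coef(lmfit)[2]))
  expect_equal(unname(fit$slope_ci), unname(confint(lmfit)[2, ]),
               tolerance = 1e-10)
  boot <- calibration_fit(o, p, method = "bootstrap", boot_reps = 400)
  expect_equal(unname(boot$slope_ci), unname(fit$slope_ci), tolerance = 0.1)
})

test_that("R-squared uses raw predictions without refitting", {
  expect_identical(r2_val(c(0.2, 0.8), c(0.2, 0.8)), 1)
  o <- c(0.1, 0.4, 0.7)
  expect_equal(r2_val(o, rep(mean(o), 3)), 0)
  expect_equal(r2_val(c(0, 1), c(0.25, 0.75)), 0.75)
  # a badly miscalibrated model can explain negative variance
  expect_lt(r2_val(c(0.1, 0.2, 0.3), c(0.9, 0.8, 0.7)), 0)
  expect_error(r2_val(rep(0.5, 4), runif(4)), "non-zero variance")
})

test_that("error metrics match hand computation and their identities", {
  o <- c(0, 0.5, 1); p <- c(0.1, 0.5, 0.9)
  em <- error_metrics(o, p)
  expect_equal(em$mae, 0.2 / 3)
  expect_equal(em$rmse, sqrt(0.02 / 3))
  expect_true(em$rmse >= em$mae)
  # perfect predictions eliminate all baseline error
  em0 <- error_metrics(o, o)
  expect_identical(em0$rmse, 0)
  expect_identical(em0$relative_mae_reduction, 1)
  # the constant-mean predictor gains nothing
  emb <- error_metrics(o, rep(mean(o), 3))
  expect_equal(emb$relative_mae_reduction, 0)
  # constant outcome: reduction undefined
  expect_true(is.na(error_metrics(rep(0.4, 3), p)$relative_mae_reduction))
})

test_that("absolute-error quantiles use linear interpolation", {
  o <- c(0.1, 0.2, 0.3, 0.4); p <- rep(0, 4)
  expect_equal(unname(abs_error_quantile(o, p, 0)), 0.1)
  expect_equal(unname(abs_error_quantile(o, p, 0.5)), 0.25)
  expect_equal(unname(abs_error_quantile(o, p, 1)), 0.4)
  expect_equal(unname(abs_error_quantile(rep(0.6, 5), rep(0.5, 5), 0.7)), 0.1)
  expect_error(abs_error_quantile(o, p, 1.5), "\\[0, 1\\]")
})

test_that("calibration bins partition into equal counts by predicted value", {
  set.seed(9)
  p <- runif(100); o <- p
  b <- calibration_bins(o, p, 10)
  expect_identical(nrow(b), 10L)
  expect_true(all(b$count == 10L))
  expect_identical(sum(b$count), 100L)
  expect_true(!is.unsorted(b$mean_predicted))
  # perfectly calibrated exact data: bin means agree
  expect_equal(b$mean_observed, b$mean_predicted)
  b1 <- calibration_bins(o, p, 1)
  expect_identical(b1$count, 100L)
  expect_equal(b1$mean_predicted, mean(p))
})

test_that("the aggregate report is internally consistent", {
  set.seed(13)
  m <- builtin_models()$statin
  x <- sample(0:90, 800, replace = TRUE)
  p <- predict(m, x)
  o <- pmin(pmax(p + rnorm(800, 0, 0.12), 0), 1)
  rep_ <- external_validation(o, p)
  expect_s3_class(rep_, "pdc_validation")
  expect_identical(rep_$n, 800L)
  expect_true(rep_$rmse >= rep_$mae)
  expect_true(rep_$r2_val <= 1)
  expect_identical(sum(rep_$calibration_bins$count), 800L)
  expect_equal(rep_$citl, mean(rep_$errors))
  expect_equal(rep_$abs_errors, abs(rep_$errors))
  expect_true(all(is.finite(unlist(rep_[c("r2_val", "r2_pearson",
                                          "r2_calibration", "citl",
                                          "cal_intercept", "cal_slope",
                                          "rmse", "mae", "baseline_mae",
                                          "relative_mae_reduction")]))))
  # degenerate perfect case
  perf <- external_validation(p, p)
  expect_equal(perf$r2_val, 1)
  expect_equal(perf$citl, 0)
  expect_equal(perf$cal_slope, 1, tolerance = 1e-12)
  expect_identical(perf$rmse, 0)
})

test_that("a unit calibration slope makes the intercept equal CITL", {
  set.seed(17)
  p <- runif(200, 0.2, 0.8)
  o <- p + 0.07                     # slope exactly 1, shift 0.07
  fit <- calibration_fit(o, p)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, citl(o, p), tolerance = 1e-12)
})

test_that("mean-shift recalibration zeroes CITL when nothing clips", {
  set.seed(19)
  p <- runif(300, 0.3, 0.7)
  o <- pmin(pmax(p + rnorm(300, -0.04, 0.1), 0), 1)
  delta <- citl(o, p)
  p2 <- mean_recalibrate(p, delta)
  expect_equal(citl(o, p2), 0, tolerance = 1e-12)
})

test_that("metrics scale correctly under a common rescaling", {
  set.seed(29)
  o <- runif(150); p <- runif(150)
  c_ <- 0.37
  expect_equal(citl(c_ * o, c_ * p), c_ * citl(o, p))
  expect_equal(error_metrics(c_ * o, c_ * p)$rmse,
               c_ * error_metrics(o, p)$rmse)
  expect_equal(error_metrics(c_ * o, c_ * p)$mae,
               c_ * error_metrics(o, p)$mae)
  expect_equal(calibration_fit(c_ * o, c_ * p)$slope,
               calibration_fit(o, p)$slope)
  expect_equal(r2_val(c_ * o, c_ * p), r2_val(o, p))
})

test_that("validation reports round-trip to disk", {
  set.seed(37)
  p <- runif(60, 0.2, 0.8)
  o <- pmin(pmax(p + rnorm(60, 0, 0.1), 0), 1)
  rep_ <- external_validation(o, p, n_bins = 5)
  dir <- withr::local_tempdir()
  write_validation_report(rep_, dir)
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$citl, rep_$citl)
  expect_equal(js$cal_slope, rep_$cal_slope)
  errs <- read.csv(file.path(dir, "errors.csv"))
  expect_identical(nrow(errs), 60L)
  bins <- read.csv(file.path(dir, "calibration_bins.csv"))
  expect_identical(nrow(bins), 5L)
})
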