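Package: pdcval
Title: Proportion of Days Covered and External Validation of Adherence
    Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes gap-adjusted medication adherence (Proportion of Days
    Covered, PDC) from pharmacy claims with carry-over for early refills,
    therapeutic switching within a drug class, a 90-day pre-index look-back
    and hospitalization credit; applies published logit-linear beta-regression
    mean models that predict 1-year PDC from the number of days covered in the
    first 90 days after a stroke or transient ischemic attack; and externally
    validates such models with calibration-in-the-large, calibration slope,
    R-squared, RMSE, MAE, relative MAE reduction, calibration curves and
    error quantiles.  Includes the four minimum-sample-size criteria for
    external validation of continuous-outcome prediction models and a
    synthetic prescription-claims simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
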