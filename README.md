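# pdcval

Claims-based medication-adherence measurement and external validation of
adherence prediction models, for pharmacoepidemiologists and biostatisticians
working with prescription-fill data.

After a stroke or transient ischemic attack, long-term adherence to statins
and antiplatelet agents strongly predicts outcomes, and adherence in the
first 90 days is a powerful single predictor of adherence over the first
year. `pdcval` implements the full computational chain needed to apply and
externally validate such a prediction model on pharmacy claims:

1. **PDC engine.** The Proportion of Days Covered over the first year,

   ```
   PDC = (pre-supply days + gap-adjusted post-index days + in-hospital days)
         / min(days from index to end of observation, 365)
   ```

   with carry-over for early refills (an early refill's supply starts the day
   after current stock runs out), pooling of drug codes within a therapeutic
   class so switches carry over, a 90-day pre-index look-back for supply
   bought before the event, and hospitalization credit. Each calendar day is
   counted at most once, so PDC never exceeds 1.

2. **Cohort rules.** First event per patient; exclusion of patients under
   18, pregnant, dead within 100 days of index, or switching insurer in the
   first year; for antiplatelet cohorts additionally oral-anticoagulant users
   and bleeding events — with an auditable exclusion ledger, plus
   new/prevalent-user classification against a 365-day washout.

3. **Prediction models.** The published beta-regression mean models

   ```
   logit(PDC_1yr) = -1.65 + 0.04 x   (statins)
   logit(PDC_1yr) = -1.52 + 0.04 x   (antiplatelets)
   ```

   where `x` is the number of days covered in the first 90 days, applied via
   the inverse-logit back-transformation, with mean-shift recalibration for
   transporting a model to a population with a different outcome mean.

4. **External validation.** Calibration-in-the-large
   (`CITL = mean(observed) - mean(predicted)`), the calibration model
   `observed_i = α_cal + λ_cal · predicted_i + e_i` with a 95% CI for the
   slope, `R²_val = 1 - SSE/SST` on raw predictions, RMSE, MAE, relative MAE
   reduction against a constant-mean baseline, absolute-error quantiles and
   decile calibration bins.

5. **Sample size.** The four minimum-sample-size criteria for external
   validation of a continuous-outcome model (precision of R², of CITL, of
   the calibration slope, and of the residual SD via an exact chi-square
   search).

6. **Synthetic claims.** A seeded simulator producing either direct
   predictor/outcome pairs from the beta data-generating process, or full
   fill histories (renewal-process refills, refill cycles of 30/60/90 days,
   primary non-adherence, discontinuation, switching, hospitalizations,
   exclusion-triggering attributes) together with a ground-truth covered-day
   set for oracle testing. No real registry data are included; all shipped
   data are synthetic.

## Worked example

```r
library(pdcval)
res <- run_adherence_pipeline(sim_config(n_patients = 2000, seed = 404))
res$ledger
#> Exclusion ledger (statin cohort): 2000 -> 1936 patients
#>   age                  removed 12
#>   pregnancy            removed 11
#>   early_death          removed 24
#>   insurer_switch       removed 17
res$report
#> External validation (n = 1936)
#>   R-squared (1 - SSE/SST):      0.533
#>   Calibration-in-the-large:     -0.116
#>   Calibration slope:            1.016 (95% CI 0.984, 1.049)
#>   Calibration intercept:        -0.125
#>   RMSE: 0.225   MAE: 0.185   baseline MAE: 0.294
#>   Relative MAE reduction:       37.0%
```

The ledger documents the exclusion cascade (2000 simulated index events,
1936 analysed). The report reads as: the statin model explains 53% of the
variance in observed 1-year PDC on this synthetic cohort; predictions
average 11.6 percentage points above observed PDC (the simulator's behaviour
model is not the prediction model, so a calibration offset is expected); the
calibration slope of 1.02 shows predictions are neither over- nor
under-dispersed; and the model removes 37% of the absolute error of simply
predicting the cohort mean. `plot(res$report)` draws the decile calibration
curve; `plot(res$report, "errors")` the error histogram. A miscalibrated
mean can be repaired with `mean_recalibrate(res$predicted, res$report$citl)`,
which drives CITL to zero.

Planning an external validation study:

```r
validation_samplesize()
#> Minimum sample size for external validation
#>
#>   (i)   precise R-squared                    n = 769 (raw 768.94)
#>   (ii)  precise calibration-in-the-large     n = 31 (raw 30.76)
#>   (iii) precise calibration slope            n = 386 (raw 385.47)
#>   (iv)  precise residual SD                  n = 235
#>
#> Overall minimum (largest criterion): 769 patients
```

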