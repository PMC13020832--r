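test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_patients = 0), "range")
  expect_error(sim_config(beta_precision = 0), "positive")
  expect_error(sim_config(refill_cycle_probs = c("30" = 0.5, "60" = 0.4,
                                                 "90" = 0.2)), "summing to 1")
  expect_error(sim_config(refill_cycle_probs = c("30" = 1, "45" = 0)),
               "30/60/90")
  expect_error(sim_config(predictor_weights = c(zero = 0.5, mid = 0.2,
                                                high = 0.2)), "summing to 1")
  expect_error(sim_config(exclusion_rates = c(under18 = 0.1)),
               "exclusion_rates")
  expect_error(sim_config(discontinuation_rate = -0.1), "range")
})

test_that("both generators are byte-identical under equal seeds", {
  m <- builtin_models()$statin
  cfg <- sim_config(n_patients = 150, seed = 77)
  expect_identical(simulate_outcome_pairs(m, cfg),
                   simulate_outcome_pairs(m, cfg))
  s1 <- simulate_fill_histories(cfg)
  s2 <- simulate_fill_histories(cfg)
  expect_identical(s1[c("fills", "stays", "index_events", "truth")],
                   s2[c("fills", "stays", "index_events", "truth")])
  # a different seed perturbs the output
  s3 <- simulate_fill_histories(sim_config(n_patients = 150, seed = 78))
  expect_false(identical(s1$fills, s3$fills))
})

test_that("outcome pairs follow the beta mean model", {
  # degenerate dispersion pins every outcome at the model mean
  flat <- pdc_model(0, 0)
  cfg <- sim_config(n_patients = 400, seed = 3, beta_precision = 1e8,
                    zero_inflation = 0)
  pairs <- simulate_outcome_pairs(flat, cfg)
  expect_true(all(abs(pairs$observed_pdc - 0.5) < 1e-3))
  expect_true(all(pairs$days_covered_90 %in% 0:90))

  # law of total expectation at n = 10000, phi = 5, default mixture:
  # E[y | x] is the model mean, halved at x = 0 by the never-taker mass
  m <- builtin_models()$statin
  cfg2 <- sim_config(n_patients = 10000, seed = 41, beta_precision = 5)
  pairs2 <- simulate_outcome_pairs(m, cfg2)
  mu <- predict(m, pairs2$days_covered_90)
  expected <- mean(ifelse(pairs2$days_covered_90 == 0,
                          (1 - cfg2$zero_inflation) * mu, mu))
  mc_se <- sd(pairs2$observed_pdc) / sqrt(nrow(pairs2))
  expect_lt(abs(mean(pairs2$observed_pdc) - expected), 3 * mc_se)

  # with inflation off the sample mean matches the model-implied mean
  cfg3 <- recovery_config(10000, 42)
  pairs3 <- simulate_outcome_pairs(m, cfg3)
  mu3 <- predict(m, pairs3$days_covered_90)
  expect_lt(abs(mean(pairs3$observed_pdc) - mean(mu3)),
            3 * sd(pairs3$observed_pdc) / sqrt(nrow(pairs3)))

  # predictor mixture: masses at 0 and 85-90 near their weights, median ~30
  frac0 <- mean(pairs2$days_covered_90 == 0)
  expect_lt(abs(frac0 - 0.30), 3 * sqrt(0.3 * 0.7 / 10000))
  frac_high <- mean(pairs2$days_covered_90 >= 85)
  expect_lt(abs(frac_high - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

  expect_error(simulate_outcome_pairs(structure(list(intercept = Inf,
                                                     slope = 0.04),
                                                class = "pdc_model"), cfg),
               "finite")
})

test_that("degenerate propensities produce the expected fill patterns", {
  # near-1 propensity, no delays, no stopping: fills tile the year, PDC = 1
  cfg <- sim_config(n_patients = 25, seed = 8,
                    propensity_alpha = 1e8, propensity_beta = 1e-8,
                    discontinuation_rate = 0, delay_mean = 0,
                    initiation_delay_mean = 0, primary_nonadherence = 0,
                    switch_prob = 0, prevalent_fraction = c(statin = 0,
                                                            antiplatelet = 0),
                    hospitalization_rate = 0, late_death_rate = 0,
                    exclusion_rates = c(under18 = 0, pregnant = 0,
                                        death100 = 0, insurer_switch = 0,
                                        oac = 0, bleeding = 0),
                    refill_cycle_probs = c("30" = 1, "60" = 0, "90" = 0))
  sim <- simulate_fill_histories(cfg)
  ad <- compute_adherence_cohort(sim$fills, sim$stays, sim$index_events,
                                 "statin")
  expect_true(all(ad$pdc_1yr == 1))
  expect_true(all(ad$days_covered_90 == 90L))

  # near-0 propensity after the forced first fill: a single 30-day supply
  cfg0 <- sim_config(n_patients = 25, seed = 8,
                     propensity_alpha = 1e-8, propensity_beta = 1e8,
                     discontinuation_rate = 0, delay_mean = 0,
                     initiation_delay_mean = 0, primary_nonadherence = 0,
                     switch_prob = 0, prevalent_fraction = c(statin = 0,
                                                             antiplatelet = 0),
                     hospitalization_rate = 0, late_death_rate = 0,
                     exclusion_rates = c(under18 = 0, pregnant = 0,
                                         death100 = 0, insurer_switch = 0,
                                         oac = 0, bleeding = 0),
                     refill_cycle_probs = c("30" = 1, "60" = 0, "90" = 0))
  sim0 <- simulate_fill_histories(cfg0)
  ad0 <- compute_adherence_cohort(sim0$fills, sim0$stays, sim0$index_events,
                                  "statin")
  expect_true(all(ad0$days_covered_90 == 30L))
  expect_true(all(abs(ad0$pdc_1yr - 30 / 365) < 1e-12))
  expect_true(all(ad0$user_status == "new"))
})

test_that("generated records satisfy their schema invariants", {
  sim <- simulate_fill_histories(sim_config(n_patients = 300, seed = 12))
  expect_true(all(sim$fills$days_supplied >= 1))
  expect_true(all(sim$fills$drug_class %in% c("statin", "antiplatelet")))
  expect_true(all(sim$stays$admit_date <= sim$stays$discharge_date))
  ev <- sim$index_events
  expect_identical(anyDuplicated(ev$patient_id), 0L)
  expect_true(all(ev$age >= 0))
  has_death <- !is.na(ev$death_date)
  expect_true(all(ev$death_date[has_death] >= ev$index_date[has_death]))
  expect_true(all(sim$fills$patient_id %in% ev$patient_id))
  # every truth day-set sits inside the 1-year window
  days <- unlist(sim$truth)
  expect_true(all(days >= 0 & days <= 364))
})

test_that("the refill-cycle mix is calibrated to the configured shares", {
  sim <- simulate_fill_histories(sim_config(n_patients = 2000, seed = 21))
  f <- sim$fills[sim$fills$drug_class == "statin", ]
  cyc <- tapply(f$days_supplied, f$patient_id, function(s) s[1])
  p30 <- mean(cyc == 30)
  expect_lt(abs(p30 - 0.942), 3 * sqrt(0.942 * 0.058 / length(cyc)))
})

test_that("truth day-sets equal the brute-force expansion of the fills", {
  sim <- simulate_fill_histories(sim_config(n_patients = 120, seed = 33))
  ev <- sim$index_events
  for (i in sample(nrow(ev), 40)) {
    pid <- ev$patient_id[i]
    for (cls in c("statin", "antiplatelet")) {
      f <- sim$fills[sim$fills$patient_id == pid &
                       sim$fills$drug_class == cls, ]
      offs <- as.integer(f$fill_date - ev$index_date[i])
      expect_identical(sim$truth[[pid]][[cls]],
                       oracle_covered(offs, f$days_supplied))
    }
  }
})

test_that("simulations round-trip through the delimited-text formats", {
  sim <- simulate_fill_histories(sim_config(n_patients = 40, seed = 2))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("fills.csv", "stays.csv",
                                               "index.csv", "truth.json")))))
  back <- read_simulation(dir)
  expect_identical(back$fills$fill_date, sim$fills$fill_date)
  expect_identical(back$fills$days_supplied, sim$fills$days_supplied)
  expect_identical(back$index_events$patient_id, sim$index_events$patient_id)
  expect_identical(back$index_events$index_date, sim$index_events$index_date)
  # dates are written ISO-8601
  raw <- readLines(file.path(dir, "fills.csv"), n = 2)
  expect_match(raw[2], "\\d{4}-\\d{2}-\\d{2}")
})
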