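# Brute-force day-set oracle for coverage arithmetic, independent of the
# package's interval code: every fill is expanded one calendar day at a
# time, each day deferred past days already covered, so an early refill's
# supply lands after the current stock runs out.

oracle_expand <- function(offsets, supplies) {
  covered <- integer(0)
  for (i in order(offsets)) {
    d <- offsets[i]
    left <- supplies[i]
    while (left > 0L) {
      while (d %in% covered) d <- d + 1L
      covered <- c(covered, d)
      d <- d + 1L
      left <- left - 1L
    }
  }
  sort(covered)
}

# Covered day offsets (0-based from index) inside the 1-year window, under
# the decomposed cross-index rule: pre-index fills count only through the
# look-back window and only for days landing on/after index; post-index
# fills are expanded fresh.
oracle_covered <- function(offsets, supplies, lookback = 90L, window = 365L) {
  pre <- offsets < 0L
  lb <- pre & offsets >= -lookback
  pre_days <- oracle_expand(offsets[lb], supplies[lb])
  post_days <- oracle_expand(offsets[!pre], supplies[!pre])
  days <- sort(unique(c(pre_days[pre_days >= 0L], post_days)))
  days[days < window]
}

# Random single-patient fill history (offsets relative to index) for
# property tests: mixes pre-index and post-index fills, early refills and
# gaps.
random_history <- function() {
  n_pre <- sample(0:3, 1)
  n_post <- sample(0:8, 1)
  offs <- c(if (n_pre > 0) sort(sample(-120:-1, n_pre)) else integer(0),
            if (n_post > 0) sort(sample(0:400, n_post)) else integer(0))
  data.frame(offset = offs,
             days_supplied = sample(c(7L, 30L, 60L, 90L),
                                    length(offs), replace = TRUE))
}

fills_df <- function(index_date, offsets, supplies,
                     drug_class = "statin", patient_id = "p1") {
  n <- length(offsets)
  data.frame(patient_id = rep(patient_id, n),
             drug_class = rep(drug_class, n),
             drug_code = rep("drug_01", n),
             fill_date = index_date + offsets,
             days_supplied = as.integer(supplies),
             stringsAsFactors = FALSE)
}

no_stays <- data.frame(admit_date = as.Date(character(0)),
                       discharge_date = as.Date(character(0)))

# A correctly-specified generator configuration: the zero-inflation point
# mass is off, so outcomes follow the beta mean model exactly.
recovery_config <- function(n, seed, phi = 5)
  sim_config(n_patients = n, seed = seed, beta_precision = phi,
             zero_inflation = 0)
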