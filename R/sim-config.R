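# Configuration for the synthetic prescription-claims simulator.  Defaults
# reproduce the cohort structure the analysis assumes: ~94% 1-month refill
# cycles, prevalent-user fractions 35.3% (statin) / 15.7% (antiplatelet),
# a U-shaped per-patient adherence propensity producing mass at zero and
# near-complete coverage, and rare exclusion-triggering attributes.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_outcome_pairs()] and
#' [simulate_fill_histories()].
#'
#' @param n_patients Number of patients (>= 1).
#' @param refill_cycle_probs Named probabilities over supply lengths
#'   `"30"`, `"60"`, `"90"` days; must sum to 1.  Default `c(0.942, 0.031,
#'   0.027)`, the observed 1/2/3-month supply mix.
#' @param propensity_alpha,propensity_beta Shape parameters of the Beta
#'   distribution of the per-patient refill propensity on \[0, 1\] among
#'   initiators.  The default (1.2, 0.7) has mean 0.63 with mass near 1;
#'   combined with primary non-adherence it yields a median 1-year PDC of
#'   ~0.41 with quartiles near 0 and ~0.75.
#' @param discontinuation_rate Per-day hazard of permanently stopping
#'   therapy (default 0.001, ~30% stop within a year).
#' @param switch_prob Per-refill probability of switching drug code within
#'   the class (default 0.05).
#' @param prevalent_fraction Named per-class probabilities that a patient has
#'   pre-index fills; default `c(statin = 0.353, antiplatelet = 0.157)`.
#' @param hospitalization_rate Expected hospital stays per patient-year
#'   (default 0.3).
#' @param mean_stay_days Mean hospitalization length in days (default 6).
#' @param exclusion_rates Named probabilities for the exclusion-triggering
#'   attributes `under18`, `pregnant`, `death100` (death before day 100),
#'   `insurer_switch`, `oac` (concurrent oral anticoagulant) and `bleeding`.
#' @param late_death_rate Probability of death between day 100 and day 364
#'   (these patients stay in the cohort with shortened follow-up).
#' @param beta_precision Precision phi of the outcome beta distribution in
#'   the direct generator (> 0); outcomes have shapes `mu*phi` and
#'   `(1-mu)*phi`.  Default 5, which gives outcome spread around the model
#'   mean comparable to the prediction errors seen in claims cohorts.
#' @param predictor_weights Mixture weights for the 90-day predictor in
#'   [simulate_outcome_pairs()]: point mass at 0, spread over 1–84, and mass
#'   over 85–90.  Default `c(zero = 0.30, mid = 0.45, high = 0.25)`, chosen
#'   so the predictor's median is ~30 with IQR ~(0, 86).
#' @param zero_inflation Probability that a patient with predictor 0 gets
#'   outcome exactly 0 (default 0.5), emulating full never-takers; the open
#'   beta support cannot produce exact zeros.  Set to 0 for a
#'   data-generating process that follows the beta mean model exactly.
#' @param primary_nonadherence Probability that a *new* user never fills a
#'   post-index prescription at all (default 0.35); prevalent users always
#'   continue therapy.  Primary non-adherence creates the observed point
#'   mass of patients with zero days covered.
#' @param initiation_delay_mean Mean geometric delay (days) from index to a
#'   new user's first fill (default 21; 0 for index-day initiation).
#'   Prevalent users continue from the index day.
#' @param delay_mean Mean of the geometric delay (in days) between a
#'   scheduled and a realized refill (default 2; 0 disables delays).
#' @param epoch Calendar origin for simulated dates (default
#'   `"2016-01-01"`).
#' @param seed Integer random seed; equal seeds give byte-identical output.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 42)
#' @export
sim_config <- function(n_patients = 2000L,
                       refill_cycle_probs = c("30" = 0.942, "60" = 0.031,
                                              "90" = 0.027),
                       propensity_alpha = 1.2, propensity_beta = 0.7,
                       discontinuation_rate = 0.001,
                       switch_prob = 0.05,
                       prevalent_fraction = c(statin = 0.353,
                                              antiplatelet = 0.157),
                       hospitalization_rate = 0.3,
                       mean_stay_days = 6,
                       exclusion_rates = c(under18 = 0.005, pregnant = 0.004,
                                           death100 = 0.0095,
                                           insurer_switch = 0.01,
                                           oac = 0.095, bleeding = 0.0005),
                       late_death_rate = 0.021,
                       beta_precision = 5,
                       predictor_weights = c(zero = 0.30, mid = 0.45,
                                             high = 0.25),
                       zero_inflation = 0.5,
                       primary_nonadherence = 0.35,
                       initiation_delay_mean = 21,
                       delay_mean = 2,
                       epoch = "2016-01-01",
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              refill_cycle_probs = refill_cycle_probs,
              propensity_alpha = propensity_alpha,
              propensity_beta = propensity_beta,
              discontinuation_rate = discontinuation_rate,
              switch_prob = switch_prob,
              prevalent_fraction = prevalent_fraction,
              hospitalization_rate = hospitalization_rate,
              mean_stay_days = mean_stay_days,
              exclusion_rates = exclusion_rates,
              late_death_rate = late_death_rate,
              beta_precision = beta_precision,
              predictor_weights = predictor_weights,
              zero_inflation = zero_inflation,
              primary_nonadherence = primary_nonadherence,
              initiation_delay_mean = initiation_delay_mean,
              delay_mean = delay_mean,
              epoch = as.Date(epoch),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` candidate list.
#' @export
validate_sim_config <- function(config) {
  .check_number(config$n_patients, "n_patients", 1)
  p <- config$refill_cycle_probs
  if (length(p) != 3L || !setequal(names(p), c("30", "60", "90")))
    stop("`refill_cycle_probs` must be named over supply lengths 30/60/90",
         call. = FALSE)
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-9)
    stop("`refill_cycle_probs` must be probabilities summing to 1",
         call. = FALSE)
  .check_number(config$propensity_alpha, "propensity_alpha", 0,
                strict_lower = TRUE)
  .check_number(config$propensity_beta, "propensity_beta", 0,
                strict_lower = TRUE)
  .check_number(config$discontinuation_rate, "discontinuation_rate", 0, 1)
  .check_number(config$switch_prob, "switch_prob", 0, 1)
  pf <- config$prevalent_fraction
  if (!all(c("statin", "antiplatelet") %in% names(pf)) ||
      any(pf < 0 | pf > 1))
    stop("`prevalent_fraction` must give probabilities for statin and antiplatelet",
         call. = FALSE)
  .check_number(config$hospitalization_rate, "hospitalization_rate", 0)
  .check_number(config$mean_stay_days, "mean_stay_days", 1)
  er <- config$exclusion_rates
  need <- c("under18", "pregnant", "death100", "insurer_switch", "oac",
            "bleeding")
  if (!all(need %in% names(er)) || any(er < 0 | er > 1))
    stop("`exclusion_rates` must give probabilities for: ",
         paste(need, collapse = ", "), call. = FALSE)
  .check_number(config$late_death_rate, "late_death_rate", 0, 1)
  if (!is.numeric(config$beta_precision) || config$beta_precision <= 0 ||
      !is.finite(config$beta_precision))
    stop("`beta_precision` (phi) must be a positive finite number",
         call. = FALSE)
  w <- config$predictor_weights
  if (length(w) != 3L || !setequal(names(w), c("zero", "mid", "high")) ||
      any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("`predictor_weights` must be zero/mid/high probabilities summing to 1",
         call. = FALSE)
  .check_number(config$zero_inflation, "zero_inflation", 0, 1)
  .check_number(config$primary_nonadherence, "primary_nonadherence", 0, 1)
  .check_number(config$initiation_delay_mean, "initiation_delay_mean", 0)
  .check_number(config$delay_mean, "delay_mean", 0)
  .check_number(config$seed, "seed")
  structure(config, class = "sim_config")
}
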