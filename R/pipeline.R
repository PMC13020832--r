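# End-to-end convenience: simulate -> cohort -> PDC -> predict -> validate.

#' Run the full validation pipeline on synthetic claims
#'
#' Chains the whole analysis for one drug class: generate (or accept) a
#' synthetic claims simulation, deduplicate index events and apply the
#' exclusion cascade, compute per-patient adherence records, predict 1-year
#' PDC from the 90-day predictor with a published model, and externally
#' validate the predictions against the observed PDC.
#'
#' @param config A [sim_config], used when `sim` is not supplied.
#' @param drug_class `"statin"` (default) or `"antiplatelet"`.
#' @param model A [pdc_model]; defaults to the built-in model for
#'   `drug_class`.
#' @param sim An existing `pdc_simulation`; overrides `config`.
#' @param n_bins Calibration bins for the validation report.
#' @return A list with `sim`, `cohort`, `ledger`, `adherence` (per-patient
#'   records), `predicted`, and `report` (a `pdc_validation`).
#' @examples
#' \donttest{
#' res <- run_adherence_pipeline(sim_config(n_patients = 300, seed = 11))
#' res$report
#' }
#' @export
run_adherence_pipeline <- function(config = sim_config(),
                                   drug_class = c("statin", "antiplatelet"),
                                   model = NULL, sim = NULL, n_bins = 10L) {
  drug_class <- match.arg(drug_class)
  if (is.null(model)) model <- builtin_models()[[drug_class]]
  if (is.null(sim)) sim <- simulate_fill_histories(config)
  events <- deduplicate_events(sim$index_events)
  excl <- apply_exclusions(events, drug_class)
  adherence <- compute_adherence_cohort(sim$fills, sim$stays, excl$cohort,
                                        drug_class)
  predicted <- predict(model, adherence$days_covered_90)
  report <- external_validation(adherence$pdc_1yr, predicted, n_bins = n_bins)
  list(sim = sim, cohort = excl$cohort, ledger = excl$ledger,
       adherence = adherence, predicted = predicted, report = report)
}
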