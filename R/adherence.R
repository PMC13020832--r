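# Per-patient adherence: the 90-day predictor (days covered at 90 days) and
# the 1-year PDC.
#
#   PDC = (pre-supply days + gap-adjusted post-index days + in-hospital days)
#         / min(days from index to end of observation, 365)
#
# The numerator counts each calendar day at most once (union of the three
# day-sets) and is capped at the denominator, so PDC <= 1 even when hospital
# stays overlap supply coverage.

#' Compute the adherence record for one patient and drug class
#'
#' Computes the 1-year PDC and the 90-day predictor from a patient's fills
#' and hospital stays.  The observation window runs from the index date to
#' `end_of_observation` inclusive, with the denominator capped at
#' `window_days`.  The numerator is the union of (a) pre-supply coverage from
#' fills in the pre-index look-back window, (b) carry-over coverage from
#' post-index fills (pooled across drug codes, so class switches carry
#' over), and (c) hospitalization days (in-hospital supply is assumed), all
#' clipped to the observation window.  The predictor `days_covered_90` is the
#' same union restricted to the first `predictor_days` days.
#'
#' @param fills Data frame of the patient's fills of one class: columns
#'   `fill_date`, `days_supplied` (pre-index fills included; they contribute
#'   only through the look-back).
#' @param stays Data frame of hospital stays: columns `admit_date`,
#'   `discharge_date` (may be empty).
#' @param index_date Index event date (start of follow-up).
#' @param end_of_observation Last day of follow-up — the earliest of
#'   index + `window_days` - 1, death, and administrative end; must be on or
#'   after `index_date`.
#' @param drug_class Class label stored on the record.
#' @param user_status `"new"` or `"prevalent"`, stored on the record (see
#'   [classify_user_status()]).
#' @param patient_id Identifier stored on the record.
#' @param window_days Maximum denominator (default 365).
#' @param predictor_days Length of the early-adherence window (default 90).
#' @param lookback_days Pre-index look-back for pre-supply (default 90).
#' @return A one-row data frame (the adherence record): `patient_id`,
#'   `drug_class`, `days_covered_90`, `pdc_1yr`, `numerator_days`,
#'   `denominator_days`, `presupply_days`, `hospital_days_credited`,
#'   `overlap_days` (excess of the additive three-term sum over the union —
#'   non-zero when hospital stays or pre-supply overlap other coverage) and
#'   `user_status`.
#' @examples
#' idx <- as.Date("2016-06-01")
#' f <- data.frame(fill_date = idx, days_supplied = 30)
#' s <- data.frame(admit_date = idx + 100, discharge_date = idx + 109)
#' compute_adherence(f, s, idx, idx + 364)  # 30 + 10 covered days
#' @export
compute_adherence <- function(fills, stays, index_date, end_of_observation,
                              drug_class = "statin", user_status = "new",
                              patient_id = NA_character_,
                              window_days = 365L, predictor_days = 90L,
                              lookback_days = 90L) {
  index_date <- .as_date(index_date, "index_date")
  end_of_observation <- .as_date(end_of_observation, "end_of_observation")
  if (end_of_observation < index_date)
    stop("`end_of_observation` must be on or after `index_date`",
         call. = FALSE)
  denom <- min(as.integer(end_of_observation - index_date) + 1L,
               as.integer(window_days))
  last <- denom - 1L                     # window offsets 0 .. last

  if (nrow(fills) > 0L && any(fills$days_supplied < 1))
    stop("`days_supplied` must be >= 1", call. = FALSE)
  offsets <- if (nrow(fills) > 0L)
    as.integer(.as_date(fills$fill_date, "fill_date") - index_date)
  else integer(0)

  pre <- offsets < 0L
  pre_mat <- .presupply_intervals(offsets[pre], fills$days_supplied[pre],
                                  lookback_days)
  pre_mat <- .clip_intervals(pre_mat, 0L, last)

  post_mat <- .carryover_intervals(offsets[!pre], fills$days_supplied[!pre])
  post_mat <- .clip_intervals(.merge_intervals(post_mat), 0L, last)

  hosp_mat <- if (nrow(stays) > 0L) {
    adm <- as.integer(.as_date(stays$admit_date, "admit_date") - index_date)
    dis <- as.integer(.as_date(stays$discharge_date, "discharge_date") -
                        index_date)
    if (any(dis < adm))
      stop("`discharge_date` must be on or after `admit_date`", call. = FALSE)
    .clip_intervals(.merge_intervals(cbind(start = adm, end = dis)), 0L, last)
  } else .clip_intervals(cbind(start = integer(0), end = integer(0)), 0L, last)

  presupply_days <- .interval_days(pre_mat)
  hospital_days <- .interval_days(hosp_mat)
  all_mat <- .merge_intervals(rbind(pre_mat, post_mat, hosp_mat))
  numerator <- min(.interval_days(all_mat), denom)
  additive <- presupply_days + .interval_days(post_mat) + hospital_days
  overlap <- additive - .interval_days(all_mat)

  pred_last <- min(as.integer(predictor_days) - 1L, last)
  covered_90 <- .interval_days(.clip_intervals(all_mat, 0L, pred_last))
  covered_90 <- min(covered_90, as.integer(predictor_days))

  data.frame(patient_id = patient_id,
             drug_class = drug_class,
             days_covered_90 = covered_90,
             pdc_1yr = numerator / denom,
             numerator_days = numerator,
             denominator_days = denom,
             presupply_days = presupply_days,
             hospital_days_credited = hospital_days,
             overlap_days = as.integer(overlap),
             user_status = user_status,
             stringsAsFactors = FALSE)
}

#' Compute adherence records for a whole cohort
#'
#' Applies [compute_adherence()] to every patient in a cohort for one drug
#' class.  Follow-up for each patient ends at the earliest of
#' index + `window_days` - 1, the day of death, and `end_of_study`.  Patients
#' with no post-index fills of the class still get a record (PDC can be
#' non-zero through pre-supply or hospitalization credit).  User status is
#' classified from pre-index fills via [classify_user_status()].
#'
#' @param fills Data frame of fill records (`patient_id`, `drug_class`,
#'   `fill_date`, `days_supplied`).
#' @param stays Data frame of hospital stays (`patient_id`, `admit_date`,
#'   `discharge_date`).
#' @param cohort Data frame of index events after exclusions
#'   (`patient_id`, `index_date`, optional `death_date`).
#' @param drug_class Class to analyse (`"statin"` or `"antiplatelet"`).
#' @param end_of_study Administrative censoring date (default: no censoring).
#' @param ... Passed to [compute_adherence()] (`window_days`,
#'   `predictor_days`, `lookback_days`).
#' @return A data frame with one adherence record per cohort patient.
#' @export
compute_adherence_cohort <- function(fills, stays, cohort, drug_class,
                                     end_of_study = NULL, ...) {
  stopifnot(is.data.frame(fills), is.data.frame(cohort))
  cls_fills <- fills[fills$drug_class == drug_class, , drop = FALSE]
  fills_by <- split(cls_fills, cls_fills$patient_id)
  stays_by <- if (nrow(stays) > 0L) split(stays, stays$patient_id) else list()
  empty_stays <- data.frame(admit_date = as.Date(character(0)),
                            discharge_date = as.Date(character(0)))
  end_of_study <- if (is.null(end_of_study)) as.Date("9999-12-31")
                  else .as_date(end_of_study, "end_of_study")
  idx_dates <- .as_date(cohort$index_date, "index_date")
  death <- if ("death_date" %in% names(cohort))
    .as_date(cohort$death_date, "death_date") else as.Date(rep(NA, nrow(cohort)))

  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    idx <- idx_dates[i]
    eoo <- min(idx + 364L, end_of_study,
               if (!is.na(death[i])) death[i] else as.Date("9999-12-31"))
    compute_adherence(
      fills = fills_by[[pid]] %||% cls_fills[integer(0), , drop = FALSE],
      stays = stays_by[[pid]] %||% empty_stays,
      index_date = idx, end_of_observation = eoo,
      drug_class = drug_class,
      user_status = classify_user_status(fills_by[[pid]] %||%
                                           cls_fills[integer(0), , drop = FALSE],
                                         idx, drug_class),
      patient_id = pid, ...)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
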