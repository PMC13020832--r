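# Eligibility and exclusion rules: first event per patient, then a fixed
# exclusion cascade (age < 18, pregnancy, death within 100 days of index,
# insurer switch during the first year; for antiplatelets additionally
# concurrent oral-anticoagulant use and bleeding events), recorded in an
# auditable ledger.

#' Keep only each patient's first index event
#'
#' For patients with more than one qualifying event, retains the earliest by
#' index date; ties are broken by stable input order.  Output rows keep
#' their original relative order.
#'
#' @param events Data frame of index events with columns `patient_id` and
#'   `index_date`.
#' @return The deduplicated data frame, one row per patient.
#' @export
deduplicate_events <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) return(events)
  idx <- .as_date(events$index_date, "index_date")
  ord <- order(idx, seq_len(nrow(events)))           # stable on ties
  first <- ord[!duplicated(events$patient_id[ord])]
  out <- events[sort(first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the study exclusion cascade
#'
#' Removes patients in a fixed order, recording the count removed at each
#' step: (1) age under 18; (2) pregnancy during follow-up; (3) death within
#' `death_days` days of the index date (strict: death on day `death_days`
#' survives); (4) insurer switch within the first `switch_days` days from
#' index; and, for the antiplatelet class only, (5) concurrent oral
#' anticoagulant use and (6) a bleeding event during follow-up.  Because the
#' rules are applied in sequence, a patient failing several rules is counted
#' only under the first; the surviving set does not depend on the order.
#'
#' @param events Deduplicated data frame of index events with columns
#'   `patient_id`, `index_date`, `age`, `pregnant`, and optionally
#'   `death_date`, `insurer_switch_date`, `oac_user`, `bleeding_event`.
#' @param drug_class `"statin"` or `"antiplatelet"`.
#' @param end_of_study Optional administrative end date; recorded on the
#'   ledger for provenance, not used by any exclusion rule.
#' @param death_days Death-exclusion horizon in days (default 100).
#' @param switch_days Insurer-switch horizon in days (default 365).
#' @return A list with `cohort` (the surviving events) and `ledger` (an
#'   `exclusion_ledger` data frame with columns `rule` and `removed`, plus
#'   attributes `initial`, `final`, `drug_class`).
#' @examples
#' ev <- data.frame(patient_id = c("a", "b"), index_date = as.Date("2016-01-01"),
#'                  age = c(17, 70), pregnant = FALSE)
#' apply_exclusions(ev, "statin")$ledger
#' @export
apply_exclusions <- function(events, drug_class = c("statin", "antiplatelet"),
                             end_of_study = NULL,
                             death_days = 100L, switch_days = 365L) {
  if (is.character(drug_class) && length(drug_class) == 1L &&
      !drug_class %in% c("statin", "antiplatelet"))
    stop(sprintf("unknown drug class '%s'", drug_class), call. = FALSE)
  drug_class <- match.arg(drug_class)
  stopifnot(is.data.frame(events))
  idx <- .as_date(events$index_date, "index_date")
  death <- if ("death_date" %in% names(events))
    .as_date(events$death_date, "death_date") else as.Date(rep(NA, nrow(events)))
  switch_d <- if ("insurer_switch_date" %in% names(events))
    .as_date(events$insurer_switch_date, "insurer_switch_date")
  else as.Date(rep(NA, nrow(events)))
  col_or_false <- function(nm)
    if (nm %in% names(events)) isTRUE_vec(events[[nm]]) else
      rep(FALSE, nrow(events))

  rules <- list(
    age = events$age < 18,
    pregnancy = col_or_false("pregnant"),
    early_death = !is.na(death) & as.integer(death - idx) < death_days,
    insurer_switch = !is.na(switch_d) &
      as.integer(switch_d - idx) >= 0L &
      as.integer(switch_d - idx) < switch_days
  )
  if (drug_class == "antiplatelet") {
    rules$oral_anticoagulant <- col_or_false("oac_user")
    rules$bleeding <- col_or_false("bleeding_event")
  }

  alive <- rep(TRUE, nrow(events))
  removed <- integer(length(rules))
  for (k in seq_along(rules)) {
    hit <- alive & rules[[k]]
    removed[k] <- sum(hit)
    alive <- alive & !hit
  }
  ledger <- data.frame(rule = names(rules), removed = removed,
                       stringsAsFactors = FALSE)
  attr(ledger, "initial") <- nrow(events)
  attr(ledger, "final") <- sum(alive)
  attr(ledger, "drug_class") <- drug_class
  if (!is.null(end_of_study))
    attr(ledger, "end_of_study") <- as.character(.as_date(end_of_study,
                                                          "end_of_study"))
  class(ledger) <- c("exclusion_ledger", "data.frame")
  cohort <- events[alive, , drop = FALSE]
  rownames(cohort) <- NULL
  list(cohort = cohort, ledger = ledger)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger (%s cohort): %d -> %d patients\n",
              attr(x, "drug_class"), attr(x, "initial"), attr(x, "final")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s removed %d\n", x$rule[i], x$removed[i]))
  invisible(x)
}

#' Classify a patient as a new or prevalent user
#'
#' A patient is a prevalent user of a drug class if any fill of that class
#' exists in the `washout_days` days strictly before the index date, and a
#' new user otherwise.
#'
#' @param fills Data frame of one patient's fills (`drug_class`,
#'   `fill_date`); may be empty.
#' @param index_date Index event date.
#' @param drug_class Class label to test.
#' @param washout_days Look-back window for prior use (default 365).
#' @return `"new"` or `"prevalent"`.
#' @export
classify_user_status <- function(fills, index_date, drug_class,
                                 washout_days = 365L) {
  index_date <- .as_date(index_date, "index_date")
  if (nrow(fills) == 0L) return("new")
  f <- if (is.null(fills$drug_class)) fills
       else fills[fills$drug_class == drug_class, , drop = FALSE]
  if (nrow(f) == 0L) return("new")
  d <- as.integer(index_date - .as_date(f$fill_date, "fill_date"))
  if (any(d >= 1L & d <= as.integer(washout_days))) "prevalent" else "new"
}

#' Write a cohort and its exclusion ledger to disk
#'
#' @param result The list returned by [apply_exclusions()].
#' @param dir Output directory (created if missing); writes `cohort.csv` and
#'   `ledger.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(result$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  led <- result$ledger
  jsonlite::write_json(
    list(drug_class = attr(led, "drug_class"),
         initial = attr(led, "initial"), final = attr(led, "final"),
         rules = as.data.frame(led)),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
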