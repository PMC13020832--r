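# Synthetic claims generators, at two levels:
#  (A) simulate_outcome_pairs — direct (predictor, outcome) draws from the
#      beta-regression data-generating process, for metric-recovery tests;
#  (B) simulate_fill_histories — full prescription-fill histories with
#      hospitalizations and exclusion-triggering attributes, for end-to-end
#      pipeline tests.  The generator also returns a per-patient ground
#      truth: the exact calendar days it intended as supply-covered,
#      computed by explicit day-by-day expansion (an independent route from
#      the interval arithmetic in the PDC engine).

#' Simulate predictor/outcome pairs from a beta mean model
#'
#' Draws the 90-day predictor from a three-part mixture (point mass at 0,
#' discrete spread over 1–84, mass over 85–90; weights from
#' `config$predictor_weights`) and the 1-year PDC outcome from a beta
#' distribution with mean `plogis(intercept + slope * x)` and precision
#' `phi = config$beta_precision` (shapes `mu*phi`, `(1-mu)*phi`).  With
#' probability `config$zero_inflation`, patients with predictor 0 get
#' outcome exactly 0, emulating full never-takers.
#'
#' @param model A [pdc_model].
#' @param config A [sim_config]; fields used: `n_patients`,
#'   `predictor_weights`, `beta_precision`, `zero_inflation`, `seed`.
#' @return A data frame with integer `days_covered_90` in \[0, 90\] and
#'   `observed_pdc` in \[0, 1); one row per patient.  Identical seeds give
#'   identical output.
#' @examples
#' pairs <- simulate_outcome_pairs(builtin_models()$statin,
#'                                 sim_config(n_patients = 100, seed = 7))
#' @export
simulate_outcome_pairs <- function(model, config) {
  stopifnot(inherits(model, "pdc_model"))
  config <- validate_sim_config(config)
  if (!is.finite(model$intercept) || !is.finite(model$slope))
    stop("model coefficients must be finite", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_patients
  w <- config$predictor_weights[c("zero", "mid", "high")]
  comp <- sample(c("zero", "mid", "high"), n, replace = TRUE, prob = w)
  x <- integer(n)
  n_mid <- sum(comp == "mid"); n_high <- sum(comp == "high")
  if (n_mid > 0) x[comp == "mid"] <- sample(1:84, n_mid, replace = TRUE)
  if (n_high > 0) x[comp == "high"] <- sample(85:90, n_high, replace = TRUE)
  mu <- plogis(model$intercept + model$slope * x)
  phi <- config$beta_precision
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  if (config$zero_inflation > 0) {
    never <- comp == "zero" & runif(n) < config$zero_inflation
    y[never] <- 0
  }
  data.frame(days_covered_90 = x, observed_pdc = y)
}

# Day-by-day expansion of fills under the carry-over rule: each fill starts
# at the later of its own date and the day after the previous supply ends.
# Returns the covered day offsets as an explicit integer set.
.expand_days <- function(offsets, supplies) {
  if (length(offsets) == 0L) return(integer(0))
  o <- order(offsets)
  offsets <- offsets[o]; supplies <- as.integer(supplies[o])
  covered <- vector("list", length(offsets))
  nxt <- -.Machine$integer.max
  for (i in seq_along(offsets)) {
    s <- max(offsets[i], nxt)
    covered[[i]] <- seq.int(s, s + supplies[i] - 1L)
    nxt <- s + supplies[i]
  }
  unlist(covered)
}

# Ground-truth covered days (offsets from index, within 0..364) for one
# patient/class, under the decomposed cross-index rule: pre-index fills
# contribute only through the 90-day look-back, post-index fills start
# fresh; each calendar day counted once.
.truth_days <- function(offsets, supplies, lookback_days = 90L,
                        window_days = 365L) {
  pre <- offsets < 0L
  lb <- pre & offsets >= -as.integer(lookback_days)
  pre_days <- .expand_days(offsets[lb], supplies[lb])
  post_days <- .expand_days(offsets[!pre], supplies[!pre])
  days <- sort(unique(c(pre_days[pre_days >= 0L], post_days)))
  days[days <= as.integer(window_days) - 1L]
}

#' Simulate full prescription-fill histories
#'
#' Generates, per patient: an index date and demographics; a refill cycle
#' length (30/60/90 days) and a Beta-distributed refill propensity; fills as
#' a renewal process — an index-day fill, then refills scheduled every
#' cycle-length days, each realized with probability equal to the
#' propensity, with geometric delays opening gaps, until permanent
#' discontinuation (per-day hazard), death or the end of the 1-year window;
#' pre-index fills for prevalent users, reaching back across the 90-day
#' look-back boundary; drug-code switches within class; hospital stays as a
#' Poisson process with geometric stay lengths; and the
#' exclusion-triggering attributes (age under 18, pregnancy, death before
#' day 100, insurer switch, oral-anticoagulant use, bleeding).
#'
#' Fills are generated for both drug classes with a shared cycle length and
#' independent per-class propensities.
#'
#' @param config A [sim_config].
#' @return A list of class `pdc_simulation`: `fills`, `stays`,
#'   `index_events` (data frames as consumed by the cohort and PDC modules)
#'   and `truth`, a per-patient list with, per class, the integer day
#'   offsets from index (0-based, within the 1-year window) that the
#'   generator intended as supply-covered.  Identical seeds give identical
#'   output.
#' @examples
#' sim <- simulate_fill_histories(sim_config(n_patients = 20, seed = 3))
#' head(sim$fills)
#' @export
simulate_fill_histories <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  epoch <- config$epoch
  er <- config$exclusion_rates
  cycles <- c(30L, 60L, 90L)
  cyc_p <- as.numeric(config$refill_cycle_probs[c("30", "60", "90")])

  pid <- sprintf("P%05d", seq_len(n))
  index_offset <- sample.int(1826L, n, replace = TRUE) - 1L  # 2016..2020
  index_date <- epoch + index_offset
  under18 <- runif(n) < er[["under18"]]
  age <- ifelse(under18, sample(1:17, n, replace = TRUE),
                pmax(18, round(rnorm(n, 70, 13))))
  pregnant <- runif(n) < er[["pregnant"]]
  u_death <- runif(n)
  death_day <- rep(NA_integer_, n)
  early <- u_death < er[["death100"]]
  late <- !early & u_death < er[["death100"]] + config$late_death_rate
  death_day[early] <- sample(0:99, sum(early), replace = TRUE)
  death_day[late] <- sample(100:364, sum(late), replace = TRUE)
  switch_day <- rep(NA_integer_, n)
  has_switch <- runif(n) < er[["insurer_switch"]]
  switch_day[has_switch] <- sample(0:364, sum(has_switch), replace = TRUE)
  oac_user <- runif(n) < er[["oac"]]
  bleeding <- runif(n) < er[["bleeding"]]
  event_type <- sample(c("stroke", "TIA"), n, replace = TRUE,
                       prob = c(0.7, 0.3))
  cycle <- sample(cycles, n, replace = TRUE, prob = cyc_p)

  per_cycle_disc <- 1 - (1 - config$discontinuation_rate)^cycle
  draw_delay <- function() {
    if (config$delay_mean <= 0) 0L
    else rgeom(1L, 1 / (1 + config$delay_mean))
  }
  classes <- c("statin", "antiplatelet")
  n_codes <- c(statin = 4L, antiplatelet = 2L)

  fills_pid <- list(); fills_class <- list(); fills_code <- list()
  fills_day <- list(); fills_supply <- list()
  k <- 0L
  truth <- vector("list", n)
  names(truth) <- pid

  for (i in seq_len(n)) {
    cyc <- cycle[i]
    end_fu <- min(364L, if (is.na(death_day[i])) 364L else death_day[i])
    truth_i <- list()
    for (cls in classes) {
      p <- rbeta(1L, config$propensity_alpha, config$propensity_beta)
      code <- sample.int(n_codes[[cls]], 1L)
      offs <- integer(0); sups <- integer(0); codes <- integer(0)
      # pre-index fills for prevalent users: a renewal chain starting about
      # three cycles before index, crossing the look-back boundary
      prevalent <- runif(1L) < config$prevalent_fraction[[cls]]
      if (prevalent) {
        t <- -(3L * cyc + sample.int(cyc, 1L))
        first_pre <- TRUE
        while (t <= -1L) {
          if (first_pre || runif(1L) < p) {   # chain always starts with a fill
            offs <- c(offs, t); sups <- c(sups, cyc); codes <- c(codes, code)
            first_pre <- FALSE
          }
          t <- t + cyc
        }
      }
      # post-index renewal process; prevalent users continue therapy, new
      # users initiate unless primary non-adherent (prescription never filled)
      initiates <- prevalent || runif(1L) >= config$primary_nonadherence
      # prevalent users refill from the index day; new users initiate after a
      # geometric delay (time to the first pharmacy visit post-discharge)
      t <- if (prevalent || config$initiation_delay_mean <= 0) 0L
           else rgeom(1L, 1 / (1 + config$initiation_delay_mean))
      while (initiates && t <= end_fu) {
        offs <- c(offs, t); sups <- c(sups, cyc); codes <- c(codes, code)
        if (runif(1L) < config$switch_prob)
          code <- sample.int(n_codes[[cls]], 1L)
        nt <- t + cyc
        repeat {
          if (runif(1L) < per_cycle_disc[i]) { nt <- NA_integer_; break }
          if (runif(1L) < p) { nt <- nt + draw_delay(); break }
          nt <- nt + cyc                      # skipped a scheduled refill
          if (nt > end_fu) { nt <- NA_integer_; break }
        }
        if (is.na(nt) || nt > end_fu) break
        t <- nt
      }
      if (length(offs) > 0L) {
        k <- k + 1L
        fills_pid[[k]] <- rep(pid[i], length(offs))
        fills_class[[k]] <- rep(cls, length(offs))
        fills_code[[k]] <- sprintf("%s_%02d", substr(cls, 1L, 4L), codes)
        fills_day[[k]] <- index_offset[i] + offs
        fills_supply[[k]] <- sups
      }
      truth_i[[cls]] <- .truth_days(offs, sups)
    }
    truth[[i]] <- truth_i
  }

  fills <- data.frame(
    patient_id = unlist(fills_pid) %||% character(0),
    drug_class = unlist(fills_class) %||% character(0),
    drug_code = unlist(fills_code) %||% character(0),
    fill_date = epoch + (unlist(fills_day) %||% integer(0)),
    days_supplied = unlist(fills_supply) %||% integer(0),
    stringsAsFactors = FALSE)

  # hospital stays: Poisson count over each patient's follow-up
  fu_days <- ifelse(is.na(death_day), 365L, death_day + 1L)
  n_stays <- rpois(n, config$hospitalization_rate * fu_days / 365)
  stays <- data.frame(patient_id = character(0),
                      admit_date = as.Date(character(0)),
                      discharge_date = as.Date(character(0)))
  if (sum(n_stays) > 0L) {
    who <- rep(seq_len(n), n_stays)
    admit_off <- vapply(who, function(i) sample.int(fu_days[i], 1L) - 1L,
                        integer(1))
    len <- 1L + rgeom(length(who), 1 / config$mean_stay_days)
    stays <- data.frame(
      patient_id = pid[who],
      admit_date = index_date[who] + admit_off,
      discharge_date = index_date[who] + admit_off + len - 1L,
      stringsAsFactors = FALSE)
  }

  index_events <- data.frame(
    patient_id = pid,
    index_date = index_date,
    event_type = event_type,
    age = as.numeric(age),
    pregnant = pregnant,
    death_date = index_date + ifelse(is.na(death_day), NA_integer_, death_day),
    insurer_switch_date = index_date +
      ifelse(is.na(switch_day), NA_integer_, switch_day),
    oac_user = oac_user,
    bleeding_event = bleeding,
    stringsAsFactors = FALSE)

  structure(list(fills = fills, stays = stays, index_events = index_events,
                 truth = truth, config = config),
            class = "pdc_simulation")
}

#' @export
print.pdc_simulation <- function(x, ...) {
  cat(sprintf("Synthetic claims simulation: %d patients, %d fills, %d stays (seed %d)\n",
              nrow(x$index_events), nrow(x$fills), nrow(x$stays),
              x$config$seed))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes `fills.csv`, `stays.csv`, `index.csv` (ISO-8601 dates, header row)
#' and `truth.json` (per-patient covered-day offsets).
#'
#' @param sim A `pdc_simulation` from [simulate_fill_histories()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pdc_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(sim$fills, file.path(dir, "fills.csv"), row.names = FALSE)
  write.csv(sim$stays, file.path(dir, "stays.csv"), row.names = FALSE)
  write.csv(sim$index_events, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read simulated claims tables back from disk
#'
#' @param dir Directory holding `fills.csv`, `stays.csv`, `index.csv` (and
#'   optionally `truth.json`) as written by [write_simulation()].
#' @return A list with `fills`, `stays`, `index_events` and (if present)
#'   `truth`, with date columns parsed as Dates.
#' @export
read_simulation <- function(dir) {
  parse_dates <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
    df
  }
  out <- list(
    fills = parse_dates(read.csv(file.path(dir, "fills.csv")), "fill_date"),
    stays = parse_dates(read.csv(file.path(dir, "stays.csv")),
                        c("admit_date", "discharge_date")),
    index_events = parse_dates(read.csv(file.path(dir, "index.csv")),
                               c("index_date", "death_date",
                                 "insurer_switch_date")))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj))
    out$truth <- jsonlite::fromJSON(tj, simplifyDataFrame = FALSE)
  out
}
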