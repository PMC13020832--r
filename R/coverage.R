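# Interval arithmetic for supply coverage.  A fill on date d with s days
# supplied covers days d .. d+s-1; an early refill is carried over, starting
# the day after the previous supply runs out, so overlapping supplies
# accumulate (stockpiling is uncapped).  Fills are pooled across drug codes
# within a therapeutic class, so switching drugs carries over too.
#
# Internally all dates are integer day offsets; intervals are two-column
# matrices (start, end), inclusive on both sides.

.carryover_intervals <- function(days, supplies) {
  if (length(days) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  o <- order(days)              # stable, preserves input order on ties
  days <- as.integer(days[o])
  supplies <- as.integer(supplies[o])
  start <- integer(length(days))
  end <- integer(length(days))
  nxt <- -.Machine$integer.max
  for (i in seq_along(days)) {
    s <- max(days[i], nxt)
    start[i] <- s
    end[i] <- s + supplies[i] - 1L
    nxt <- end[i] + 1L
  }
  cbind(start = start, end = end)
}

.merge_intervals <- function(mat) {
  if (nrow(mat) <= 1L) return(mat)
  mat <- mat[order(mat[, 1L]), , drop = FALSE]
  start <- mat[, 1L]; end <- mat[, 2L]
  out_s <- start[1L]; out_e <- end[1L]
  k <- 1L
  for (i in 2L:nrow(mat)) {
    if (start[i] <= out_e[k] + 1L) {       # overlapping or adjacent
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]; out_e[k] <- end[i]
    }
  }
  cbind(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

.clip_intervals <- function(mat, lo, hi) {
  if (nrow(mat) == 0L || lo > hi)
    return(mat[integer(0), , drop = FALSE])
  s <- pmax(mat[, 1L], lo)
  e <- pmin(mat[, 2L], hi)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

.interval_days <- function(mat) {
  if (nrow(mat) == 0L) return(0L)
  as.integer(sum(mat[, 2L] - mat[, 1L] + 1L))
}

#' Build gap-adjusted coverage intervals for one patient and drug class
#'
#' Pools the patient's fills across drug codes within the class, sorts them
#' by fill date, and applies the carry-over rule: each fill's coverage starts
#' at the later of its fill date and the day after the previous coverage
#' ends, and lasts `days_supplied` days.  Returns a minimal list of disjoint
#' sorted intervals, optionally truncated at `horizon_end`.  Before
#' truncation the total covered days equal the sum of days supplied.
#'
#' @param fills A data frame of fill records for a single patient and class,
#'   with columns `fill_date` (Date) and `days_supplied` (positive integer).
#' @param horizon_end Optional Date after which coverage is truncated.
#' @return A data frame of coverage intervals with columns `start`, `end`
#'   (Dates, inclusive) and `source` (`"post_index_fill"`).  Empty input
#'   gives an empty data frame.
#' @examples
#' f <- data.frame(fill_date = as.Date("2016-01-01") + c(0, 20),
#'                 days_supplied = c(30, 30))
#' build_coverage(f)  # one interval of 60 days: the early refill carries over
#' @export
build_coverage <- function(fills, horizon_end = NULL) {
  if (nrow(fills) == 0L)
    return(data.frame(start = as.Date(character(0)),
                      end = as.Date(character(0)),
                      source = character(0)))
  if (any(fills$days_supplied < 1))
    stop("`days_supplied` must be >= 1", call. = FALSE)
  dates <- .as_date(fills$fill_date, "fill_date")
  origin <- min(dates)
  mat <- .carryover_intervals(as.integer(dates - origin), fills$days_supplied)
  mat <- .merge_intervals(mat)
  if (!is.null(horizon_end)) {
    hi <- as.integer(.as_date(horizon_end, "horizon_end") - origin)
    mat <- .clip_intervals(mat, min(mat[, 1L], 0L) - 1L, hi)
  }
  data.frame(start = origin + mat[, 1L], end = origin + mat[, 2L],
             source = rep("post_index_fill", nrow(mat)))
}

# Internal: carry-over intervals, in offsets relative to an index date,
# for fills inside the pre-index look-back window.
.presupply_intervals <- function(offsets, supplies, lookback_days = 90L) {
  keep <- offsets >= -as.integer(lookback_days) & offsets <= -1L
  .merge_intervals(.carryover_intervals(offsets[keep], supplies[keep]))
}

#' Pre-supply credit from the look-back window
#'
#' Considers only fills dated within `lookback_days` days strictly before the
#' index date, builds carry-over coverage among them, and counts the covered
#' days that fall on or after the index date — supply purchased before the
#' qualifying event that is still on hand during follow-up.
#'
#' @param pre_index_fills Data frame of fills dated before the index date,
#'   with columns `fill_date` and `days_supplied`.
#' @param index_date The index (qualifying event) date.
#' @param lookback_days Length of the look-back window (default 90).
#' @return Integer number of pre-supply days extending into follow-up.
#' @examples
#' f <- data.frame(fill_date = as.Date("2016-06-01") - 15, days_supplied = 30)
#' presupply_credit(f, as.Date("2016-06-01"))  # 15
#' @export
presupply_credit <- function(pre_index_fills, index_date, lookback_days = 90L) {
  index_date <- .as_date(index_date, "index_date")
  if (nrow(pre_index_fills) == 0L) return(0L)
  dates <- .as_date(pre_index_fills$fill_date, "fill_date")
  if (any(dates >= index_date))
    stop("`pre_index_fills` must be dated strictly before `index_date`",
         call. = FALSE)
  mat <- .presupply_intervals(as.integer(dates - index_date),
                              pre_index_fills$days_supplied, lookback_days)
  .interval_days(.clip_intervals(mat, 0L, .Machine$integer.max %/% 2L))
}
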