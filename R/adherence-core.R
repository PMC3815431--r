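#' Possession timeline of a medication history
#'
#' Derives the covered day intervals of a history on the integer-day axis
#' (day 0 = first fill). Intervals are half-open `[start, end)` and
#' truncated at the observation horizon.
#'
#' With `carryover = TRUE` (the default, standard claims convention),
#' supply left over when a refill arrives before run-out is banked: a fill
#' on day `d` with `s` days of supply extends coverage to
#' `max(previous run-out, d) + s`. With `carryover = FALSE` each fill
#' covers exactly `[d, d + s)` and overlaps merge without banking.
#'
#' @param history A [med_history()].
#' @param carryover Bank unused supply from early refills?
#' @return A tibble of disjoint sorted intervals with columns `start` and
#'   `end`, carrying attributes `horizon` and `carryover`.
#' @examples
#' h <- med_history(c(0, 20), c(30, 30), horizon = 100)
#' possession_timeline(h)                     # [0, 60): 10 days banked
#' possession_timeline(h, carryover = FALSE)  # [0, 50)
#' @export
possession_timeline <- function(history, carryover = TRUE) {
  stopifnot(inherits(history, "med_history"))
  d <- history$fill_days
  s <- history$days_supply
  horizon <- history$horizon

  starts <- integer(0)
  ends <- integer(0)
  cur_start <- d[1L]
  cur_end <- d[1L]
  for (i in seq_along(d)) {
    if (d[i] > cur_end) {
      # supply lapsed before this refill: close the open run
      starts <- c(starts, cur_start)
      ends <- c(ends, cur_end)
      cur_start <- d[i]
      cur_end <- d[i]
    }
    cur_end <- if (carryover) max(cur_end, d[i]) + s[i] else max(cur_end, d[i] + s[i])
  }
  starts <- c(starts, cur_start)
  ends <- c(ends, cur_end)

  keep <- starts < horizon
  intervals <- tibble(
    start = starts[keep],
    end = pmin(ends[keep], horizon)
  )
  intervals <- intervals[intervals$end > intervals$start, ]
  structure(intervals, horizon = horizon, carryover = carryover)
}

#' Running medication possession ratio
#'
#' Computes the MPR at one or more evaluation days: the total days of
#' supply dispensed up to (and including) each day, divided by the days
#' elapsed since the first fill. A fill on day `d` counts from evaluation
#' day `d` onward; the day-0 fill is always included.
#'
#' @param history A [med_history()].
#' @param day Integer evaluation day(s), each `>= 1` (the ratio is
#'   undefined at day 0, when no time has elapsed).
#' @param cap_at_one Cap the ratio at 1 (proportion-of-days-covered
#'   style)? Default `FALSE`: early refills can push the MPR above 1.
#' @return A numeric vector of MPR values, one per `day`.
#' @examples
#' h <- med_history(c(0, 30), c(30, 30), horizon = 60)
#' compute_mpr(h, 60)            # 60 / 60 = 1
#' compute_mpr(med_history(0, 30, 60), 60)  # 30 / 60 = 0.5
#' @export
compute_mpr <- function(history, day, cap_at_one = FALSE) {
  stopifnot(inherits(history, "med_history"))
  day <- as.integer(day)
  if (length(day) == 0L || anyNA(day) || any(day < 1L)) {
    abort("`day` must be >= 1: the MPR denominator is days since the first fill.",
          class = "mpr_domain_error")
  }
  supplied <- vapply(
    day,
    function(d) sum(history$days_supply[history$fill_days <= d]),
    numeric(1)
  )
  mpr <- supplied / day
  if (isTRUE(cap_at_one)) mpr <- pmin(mpr, 1)
  mpr
}

#' Running MPR series over the observation window
#'
#' Evaluates [compute_mpr()] across days `1..horizon`, either at every day
#' (`"dense"`) or only at breakpoints — day 1, fill days and their
#' predecessors, coverage run-outs, and the horizon (`"sparse"`). Between
#' fills the series decays hyperbolically and it jumps upward at each fill
#' day, so the sparse grid captures every local extremum.
#'
#' @inheritParams compute_mpr
#' @param type `"dense"` or `"sparse"`.
#' @return A tibble with columns `day` and `mpr`, of class `"mpr_series"`.
#' @examples
#' mpr_series(med_history(c(0, 30), c(30, 30), horizon = 60), type = "sparse")
#' @export
mpr_series <- function(history, type = c("dense", "sparse"), cap_at_one = FALSE) {
  stopifnot(inherits(history, "med_history"))
  type <- match.arg(type)
  horizon <- history$horizon
  if (horizon < 1L) {
    abort("The history must span at least one day to evaluate an MPR series.",
          class = "mpr_domain_error")
  }
  days <- if (type == "dense") {
    seq_len(horizon)
  } else {
    tl <- possession_timeline(history)
    cand <- c(1L, history$fill_days, history$fill_days - 1L,
              history$fill_days + 1L, tl$end, tl$end - 1L, horizon)
    sort(unique(cand[cand >= 1L & cand <= horizon]))
  }
  structure(
    tibble(day = days, mpr = compute_mpr(history, days, cap_at_one = cap_at_one)),
    class = c("mpr_series", class(tibble())),
    horizon = horizon
  )
}

#' Detect refill gaps
#'
#' Finds the uncovered periods of a history and marks each as an alert
#' when it is strictly longer than `gap_days` (gaps *greater than* 30 days
#' alert under the default). Trailing uncovered time up to the horizon
#' counts as a gap: a patient whose last supply ran out long before the
#' observation end is in a gap now.
#'
#' Two modes are available. `"interval"` (default) takes the complement of
#' the carryover [possession_timeline()], so a qualifying lapse *at any
#' time* in the record alerts. `"cumulative"` is the single end-of-record
#' subtraction — elapsed days minus total dispensed supply — which equals
#' the interval gap total for single-fill histories but cannot localise
#' mid-history lapses.
#'
#' @param x A [med_history()], or a timeline from [possession_timeline()].
#' @param gap_days Alert threshold in days (strict inequality).
#' @param gap_mode `"interval"` or `"cumulative"` (histories only).
#' @param carryover Passed to [possession_timeline()] when `x` is a
#'   history.
#' @return A tibble with columns `start`, `end`, `length`, `alert`;
#'   zero rows when coverage is complete.
#' @examples
#' h <- med_history(0, 30, horizon = 61)
#' detect_gaps(h)   # gap [30, 61), length 31 -> alert
#' detect_gaps(med_history(0, 30, horizon = 60))  # length 30 -> no alert
#' @export
detect_gaps <- function(x, gap_days = 30, gap_mode = c("interval", "cumulative"),
                        carryover = TRUE) {
  gap_mode <- match.arg(gap_mode)
  if (inherits(x, "med_history")) {
    if (gap_mode == "cumulative") {
      gap_len <- x$horizon - sum(x$days_supply)
      if (gap_len <= 0L) return(empty_gaps())
      return(tibble(
        start = x$horizon - gap_len, end = x$horizon,
        length = gap_len, alert = gap_len > gap_days
      ))
    }
    timeline <- possession_timeline(x, carryover = carryover)
  } else {
    timeline <- x
    if (is.null(attr(timeline, "horizon"))) {
      abort("`x` must be a med_history or a possession_timeline.",
            class = "mpr_usage_error")
    }
  }
  horizon <- attr(timeline, "horizon")
  bounds <- c(0L, rbind(timeline$start, timeline$end), horizon)
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  keep <- ends > starts
  gaps <- tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
  if (nrow(gaps) == 0L) return(empty_gaps())
  gaps$length <- gaps$end - gaps$start
  gaps$alert <- gaps$length > gap_days
  gaps
}

empty_gaps <- function() {
  tibble(start = integer(), end = integer(), length = integer(), alert = logical())
}

#' Current-MPR threshold check
#'
#' Evaluates the MPR at the latest observed day and flags the medication
#' when the value is strictly below `mpr_threshold` (the conventional 0.8
#' non-adherence cut-point). A value of exactly 0.8 does not flag.
#'
#' @inheritParams compute_mpr
#' @param mpr_threshold Threshold below which current non-adherence is
#'   flagged.
#' @return A one-row tibble with `day` (the horizon), `mpr`, and `flag`.
#' @examples
#' check_current_mpr(med_history(0, 30, horizon = 60))   # 0.5 -> flagged
#' check_current_mpr(med_history(0, 48, horizon = 60))   # exactly 0.8 -> not
#' @export
check_current_mpr <- function(history, mpr_threshold = 0.8, cap_at_one = FALSE) {
  stopifnot(inherits(history, "med_history"))
  if (history$horizon < 1L) {
    abort("The history must span at least one day for a current-MPR check.",
          class = "mpr_domain_error")
  }
  value <- compute_mpr(history, history$horizon, cap_at_one = cap_at_one)
  tibble(day = history$horizon, mpr = value, flag = value < mpr_threshold)
}

#' @export
tidy.med_history <- function(x, ...) {
  mpr_series(x, ...)
}

#' @export
glance.med_history <- function(x, ...) {
  gaps <- detect_gaps(x)
  cur <- if (x$horizon >= 1L) compute_mpr(x, x$horizon) else NA_real_
  tibble(
    patient_id = x$patient_id,
    medication_id = x$medication_id,
    n_fills = length(x$fill_days),
    total_supply = sum(x$days_supply),
    horizon = x$horizon,
    current_mpr = cur,
    n_gaps = nrow(gaps),
    max_gap = if (nrow(gaps)) max(gaps$length) else 0L,
    gap_alert = any(gaps$alert)
  )
}
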