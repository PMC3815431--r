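#' Assessment options
#'
#' Bundles the thresholds and conventions used by every adherence check.
#' Defaults follow the usual claims-analytics conventions: a refill gap
#' longer than 30 days signals current non-adherence, a medication
#' possession ratio (MPR) below 0.8 at the end of the record signals
#' current non-adherence, and "one year" means 365 days after the first
#' fill.
#'
#' @param gap_days Gap alert threshold in days. A maximal uncovered run
#'   strictly longer than this triggers the gap alert.
#' @param mpr_threshold MPR cut-point; values strictly below it flag
#'   non-adherence.
#' @param year_days Number of days after the first fill that defines the
#'   "1-year" outcome horizon.
#' @param cap_at_one If `TRUE`, running MPR values are capped at 1
#'   (proportion-of-days-covered style). The default leaves MPR uncapped,
#'   so early refills can push it above 1.
#' @param gap_mode `"interval"` (default) detects every maximal uncovered
#'   run on the carryover possession timeline; `"cumulative"` uses the
#'   single end-of-record subtraction, elapsed days minus total dispensed
#'   supply.
#' @param prediction_days Candidate days after the first fill at which the
#'   1-year forecast may be anchored.
#' @param carryover If `TRUE` (default), supply left over when a refill
#'   arrives before run-out is banked and extends later coverage.
#'
#' @return A list of class `"adherence_options"`.
#' @examples
#' adherence_options()
#' adherence_options(gap_mode = "cumulative", cap_at_one = TRUE)
#' @export
adherence_options <- function(gap_days = 30,
                              mpr_threshold = 0.8,
                              year_days = 365,
                              cap_at_one = FALSE,
                              gap_mode = c("interval", "cumulative"),
                              prediction_days = c(60L, 90L, 120L),
                              carryover = TRUE) {
  gap_mode <- match.arg(gap_mode)
  if (!is.numeric(gap_days) || length(gap_days) != 1L || gap_days <= 0) {
    abort("`gap_days` must be a single positive number.", class = "mpr_usage_error")
  }
  if (!is.numeric(mpr_threshold) || length(mpr_threshold) != 1L || mpr_threshold <= 0) {
    abort("`mpr_threshold` must be a single positive number.", class = "mpr_usage_error")
  }
  if (!is.numeric(year_days) || length(year_days) != 1L || year_days < 1) {
    abort("`year_days` must be a single positive number.", class = "mpr_usage_error")
  }
  if (!is.numeric(prediction_days) || length(prediction_days) < 1L ||
      any(prediction_days < 1)) {
    abort("`prediction_days` must be positive day offsets.", class = "mpr_usage_error")
  }
  structure(
    list(
      gap_days = as.integer(gap_days),
      mpr_threshold = as.numeric(mpr_threshold),
      year_days = as.integer(year_days),
      cap_at_one = isTRUE(cap_at_one),
      gap_mode = gap_mode,
      prediction_days = sort(unique(as.integer(prediction_days))),
      carryover = isTRUE(carryover)
    ),
    class = "adherence_options"
  )
}

#' @export
print.adherence_options <- function(x, ...) {
  cat("<adherence_options>\n")
  cat(sprintf("  gap alert        : > %d days (%s mode)\n", x$gap_days, x$gap_mode))
  cat(sprintf("  MPR threshold    : < %.2f\n", x$mpr_threshold))
  cat(sprintf("  1-year horizon   : %d days\n", x$year_days))
  cat(sprintf("  MPR cap at 1     : %s\n", x$cap_at_one))
  cat(sprintf("  prediction days  : %s\n", paste(x$prediction_days, collapse = ", ")))
  cat(sprintf("  supply carryover : %s\n", x$carryover))
  invisible(x)
}
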