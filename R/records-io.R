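#' Read prescription fulfillment records
#'
#' Parses a fulfillment CSV (UTF-8, comma-separated, header required) with
#' one row per dispensing event. Required columns: `patient_id`,
#' `medication_id`, `medication_name`, `fill_date` (ISO 8601
#' `YYYY-MM-DD`), `days_supply` (positive integer days covered by the
#' fill). An optional `age_at_first_fill` column carries the patient's age
#' in years at the first fill of that medication.
#'
#' Rows that are identical on (patient, medication, date) are merged by
#' summing their `days_supply`: partial fills on the same day are one
#' dispensing event for possession purposes.
#'
#' @param file Path to a CSV file, or a connection readable by
#'   [readr::read_csv()].
#' @return A tibble of fills sorted by patient, medication and date, with
#'   `fill_date` parsed to `Date` and `days_supply` integer. An empty file
#'   yields an empty tibble with the full column set.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "patient_id,medication_id,medication_name,fill_date,days_supply",
#'   "p1,rx1,Ramipril,2022-01-01,30",
#'   "p1,rx1,Ramipril,2022-01-31,30"
#' ), csv)
#' read_fulfillments(csv)
#' @seealso [fulfillment_histories()] to group fills into per-medication
#'   histories.
#' @export
read_fulfillments <- function(file) {
  required <- c("patient_id", "medication_id", "medication_name",
                "fill_date", "days_supply")
  all_cols <- c(required, "age_at_first_fill")

  raw <- suppressWarnings(readr::read_csv(
    file,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  if (nrow(raw) == 0L && ncol(raw) <= 1L) {
    return(empty_fills())
  }

  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(
      sprintf("Fulfillment file is missing required column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      class = "mpr_format_error"
    )
  }
  if (nrow(raw) == 0L) {
    return(empty_fills())
  }

  # data row i sits on physical line i + 1 (header is line 1)
  line_no <- seq_len(nrow(raw)) + 1L

  bad_date <- !grepl("^\\d{4}-\\d{2}-\\d{2}$", raw$fill_date) |
    is.na(suppressWarnings(as.Date(raw$fill_date, format = "%Y-%m-%d")))
  if (any(bad_date)) {
    i <- which(bad_date)[1L]
    abort(
      sprintf("Line %d: fill_date '%s' is not a valid ISO 8601 date (YYYY-MM-DD).",
              line_no[i], raw$fill_date[i]),
      class = "mpr_parse_error"
    )
  }

  supply_num <- suppressWarnings(as.numeric(raw$days_supply))
  bad_supply <- is.na(supply_num) | supply_num < 1 | supply_num != round(supply_num)
  if (any(bad_supply)) {
    i <- which(bad_supply)[1L]
    abort(
      sprintf("Line %d: days_supply '%s' is not a positive integer.",
              line_no[i], raw$days_supply[i]),
      class = "mpr_parse_error"
    )
  }

  age <- if ("age_at_first_fill" %in% names(raw)) {
    a <- suppressWarnings(as.numeric(raw$age_at_first_fill))
    bad_age <- !is.na(raw$age_at_first_fill) & (is.na(a) | a < 0)
    if (any(bad_age)) {
      i <- which(bad_age)[1L]
      abort(
        sprintf("Line %d: age_at_first_fill '%s' is not a nonnegative number.",
                line_no[i], raw$age_at_first_fill[i]),
        class = "mpr_parse_error"
      )
    }
    a
  } else {
    rep(NA_real_, nrow(raw))
  }

  fills <- tibble(
    patient_id = raw$patient_id,
    medication_id = raw$medication_id,
    medication_name = raw$medication_name,
    fill_date = as.Date(raw$fill_date),
    days_supply = as.integer(supply_num),
    age_at_first_fill = age
  )

  fills |>
    dplyr::group_by(.data$patient_id, .data$medication_id, .data$fill_date) |>
    dplyr::summarise(
      medication_name = dplyr::first(.data$medication_name),
      days_supply = sum(.data$days_supply),
      age_at_first_fill = dplyr::first(.data$age_at_first_fill[!is.na(.data$age_at_first_fill)], default = NA_real_),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(all_cols)) |>
    dplyr::arrange(.data$patient_id, .data$medication_id, .data$fill_date)
}

empty_fills <- function() {
  tibble(
    patient_id = character(), medication_id = character(),
    medication_name = character(), fill_date = as.Date(character()),
    days_supply = integer(), age_at_first_fill = numeric()
  )
}

#' Construct a single medication history
#'
#' A `med_history` holds the ordered fills of one medication for one
#' patient on an integer-day axis: day 0 is the first fill, `horizon` is
#' the (exclusive) end of observation in days since the first fill.
#'
#' @param fill_days Integer day offsets of fills since the first fill;
#'   must start at 0 and be strictly increasing.
#' @param days_supply Positive integer days of supply per fill, same
#'   length as `fill_days`.
#' @param horizon Observation end in days since the first fill
#'   (`as_of - first_fill_date`); must be `>=` the last fill day.
#' @param patient_id,medication_id,medication_name Identifiers.
#' @param first_fill_date Calendar date of day 0.
#' @param age Patient age in years at the first fill (`NA` if unknown).
#' @return An object of class `"med_history"`.
#' @examples
#' h <- med_history(c(0, 30), c(30, 30), horizon = 90)
#' compute_mpr(h, day = 60)
#' @export
med_history <- function(fill_days, days_supply, horizon,
                        patient_id = "patient",
                        medication_id = "medication",
                        medication_name = medication_id,
                        first_fill_date = as.Date("2000-01-01"),
                        age = NA_real_) {
  fill_days <- as.integer(fill_days)
  days_supply <- as.integer(days_supply)
  horizon <- as.integer(horizon)
  if (length(fill_days) == 0L) {
    abort("A medication history needs at least one fill.", class = "mpr_usage_error")
  }
  if (length(fill_days) != length(days_supply)) {
    abort("`fill_days` and `days_supply` must have equal length.",
          class = "mpr_usage_error")
  }
  if (fill_days[1L] != 0L || is.unsorted(fill_days, strictly = TRUE)) {
    abort("`fill_days` must start at 0 and be strictly increasing.",
          class = "mpr_usage_error")
  }
  if (any(days_supply < 1L)) {
    abort("Every `days_supply` must be >= 1.", class = "mpr_usage_error")
  }
  if (horizon < fill_days[length(fill_days)]) {
    abort("`horizon` must be >= the last fill day.", class = "mpr_usage_error")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      medication_id = as.character(medication_id),
      medication_name = as.character(medication_name),
      fill_days = fill_days,
      days_supply = days_supply,
      horizon = horizon,
      first_fill_date = as.Date(first_fill_date),
      age = as.numeric(age)
    ),
    class = "med_history"
  )
}

#' @export
print.med_history <- function(x, ...) {
  cat(sprintf("<med_history> %s (%s) for patient %s\n",
              x$medication_name, x$medication_id, x$patient_id))
  cat(sprintf("  %d fill(s) over days [0, %d]; total supply %d days; observed to day %d\n",
              length(x$fill_days), max(x$fill_days), sum(x$days_supply), x$horizon))
  invisible(x)
}

#' Group fills into per-medication histories
#'
#' Partitions a fills tibble (as returned by [read_fulfillments()]) into
#' one history per (patient, medication) pair. Dates are converted to
#' integer day offsets from each history's first fill; the observation
#' window ends at `as_of`.
#'
#' @param fills A tibble of fills with the [read_fulfillments()] columns.
#' @param as_of Observation end date. Defaults to the maximum `fill_date`
#'   in `fills`. Must not precede any fill.
#' @return A tibble with one row per (patient, medication): identifier
#'   columns, `age_at_first_fill`, `first_fill_date`, `last_fill_date`,
#'   `n_fills`, `horizon` (days observed), and a `history` list-column of
#'   [med_history()] objects.
#' @examples
#' fills <- tibble::tibble(
#'   patient_id = "p1", medication_id = "rx1", medication_name = "Ramipril",
#'   fill_date = as.Date("2022-01-01") + c(0, 30), days_supply = c(30L, 30L),
#'   age_at_first_fill = 60
#' )
#' fulfillment_histories(fills, as_of = as.Date("2022-04-01"))
#' @export
fulfillment_histories <- function(fills, as_of = NULL) {
  if (nrow(fills) == 0L) {
    return(tibble(
      patient_id = character(), medication_id = character(),
      medication_name = character(), age_at_first_fill = numeric(),
      first_fill_date = as.Date(character()), last_fill_date = as.Date(character()),
      n_fills = integer(), horizon = integer(), history = list()
    ))
  }
  as_of <- as.Date(as_of %||% max(fills$fill_date))
  if (as_of < max(fills$fill_date)) {
    abort(
      sprintf("`as_of` (%s) precedes the latest fill date (%s).",
              format(as_of), format(max(fills$fill_date))),
      class = "mpr_usage_error"
    )
  }

  fills |>
    dplyr::arrange(.data$patient_id, .data$medication_id, .data$fill_date) |>
    dplyr::group_by(.data$patient_id, .data$medication_id) |>
    dplyr::group_map(function(g, key) {
      first_fill <- g$fill_date[1L]
      age <- dplyr::first(g$age_at_first_fill[!is.na(g$age_at_first_fill)],
                          default = NA_real_)
      h <- med_history(
        fill_days = as.integer(g$fill_date - first_fill),
        days_supply = g$days_supply,
        horizon = as.integer(as_of - first_fill),
        patient_id = key$patient_id,
        medication_id = key$medication_id,
        medication_name = g$medication_name[1L],
        first_fill_date = first_fill,
        age = age
      )
      tibble(
        patient_id = key$patient_id,
        medication_id = key$medication_id,
        medication_name = g$medication_name[1L],
        age_at_first_fill = age,
        first_fill_date = first_fill,
        last_fill_date = g$fill_date[nrow(g)],
        n_fills = nrow(g),
        horizon = h$horizon,
        history = list(h)
      )
    }) |>
    purrr::list_rbind()
}
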