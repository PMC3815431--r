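#' Write assessments to JSON or CSV
#'
#' Serialises an assessment tibble. The JSON dialect is lossless — it
#' keeps the reason codes, gap intervals and prediction fields so that
#' [read_assessments()] reconstructs an identical tibble. The CSV form is
#' the flat clinician listing: one row per medication with the status and
#' key numbers; reason codes are joined with `;` and gaps are summarised
#' as a count and a maximum length.
#'
#' @param assessments An assessment tibble from [assess_patient()] or
#'   [assess_fulfillments()].
#' @param path Output file path. With `format = "json"` and `path = NULL`
#'   the JSON string is returned instead.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly (or the JSON string when `path` is `NULL`).
#' @examples
#' a <- assess_patient(med_history(0, 30, horizon = 61))
#' cat(write_assessments(a, path = NULL))
#' @export
write_assessments <- function(assessments, path, format = c("json", "csv")) {
  if (length(format) > 1L) format <- format[1L]
  if (length(format) != 1L || !format %in% c("json", "csv")) {
    abort(sprintf("Unknown assessment format '%s'; use \"json\" or \"csv\".",
                  paste(format, collapse = ",")),
          class = "mpr_usage_error")
  }
  if (format == "csv") {
    flat <- flatten_assessments(assessments)
    readr::write_csv(flat, path, na = "")
    return(invisible(path))
  }
  records <- purrr::map(seq_len(nrow(assessments)), function(i) {
    row <- assessments[i, ]
    gaps <- row$gaps[[1L]]
    rec <- list(
      patient_id = row$patient_id,
      medication_id = row$medication_id,
      medication_name = row$medication_name,
      drug_class = row$drug_class,
      status = row$status,
      reasons = as.list(row$reasons[[1L]]),
      current_mpr = row$current_mpr,
      first_fill_date = format(row$first_fill_date),
      last_fill_date = format(row$last_fill_date),
      observation_days = row$observation_days,
      n_fills = row$n_fills,
      gap_alert = row$gap_alert,
      gaps = purrr::map(seq_len(nrow(gaps)), function(j) {
        list(start = gaps$start[j], end = gaps$end[j],
             length = gaps$length[j], alert = gaps$alert[j])
      })
    )
    if (!is.na(row$prediction_day)) {
      rec$prediction <- list(
        drug_class = row$drug_class,
        prediction_day = row$prediction_day,
        mpr_at_prediction_day = row$mpr_at_prediction_day,
        probability_poor = row$probability_poor,
        predicted_poor = row$predicted_poor
      )
    }
    rec
  })
  json <- jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read assessments back from the JSON dialect
#'
#' @param path Path to a file written by [write_assessments()] with
#'   `format = "json"`, or a JSON string.
#' @return The reconstructed assessment tibble.
#' @export
read_assessments <- function(path) {
  records <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                                simplifyVector = FALSE)
  if (length(records) == 0L) return(empty_assessments())
  rows <- purrr::map(records, function(rec) {
    gaps <- if (length(rec$gaps) == 0L) empty_gaps() else {
      tibble(
        start = vapply(rec$gaps, function(g) as.integer(g$start), integer(1)),
        end = vapply(rec$gaps, function(g) as.integer(g$end), integer(1)),
        length = vapply(rec$gaps, function(g) as.integer(g$length), integer(1)),
        alert = vapply(rec$gaps, function(g) isTRUE(g$alert), logical(1))
      )
    }
    pred <- rec$prediction
    tibble(
      patient_id = rec$patient_id,
      medication_id = rec$medication_id,
      medication_name = rec$medication_name,
      drug_class = rec$drug_class %||% NA_character_,
      status = rec$status,
      reasons = list(as.character(unlist(rec$reasons))),
      current_mpr = as.numeric(rec$current_mpr %||% NA_real_),
      first_fill_date = as.Date(rec$first_fill_date),
      last_fill_date = as.Date(rec$last_fill_date),
      observation_days = as.integer(rec$observation_days),
      n_fills = as.integer(rec$n_fills),
      gap_alert = isTRUE(rec$gap_alert),
      gaps = list(gaps),
      prediction_day = if (is.null(pred)) NA_integer_ else as.integer(pred$prediction_day),
      mpr_at_prediction_day = if (is.null(pred)) NA_real_ else as.numeric(pred$mpr_at_prediction_day),
      probability_poor = if (is.null(pred)) NA_real_ else as.numeric(pred$probability_poor),
      predicted_poor = if (is.null(pred)) NA else isTRUE(pred$predicted_poor)
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("adherence_assessment", class(tibble()))
  out
}

flatten_assessments <- function(assessments) {
  tibble(
    patient_id = assessments$patient_id,
    medication_id = assessments$medication_id,
    medication_name = assessments$medication_name,
    drug_class = assessments$drug_class,
    status = assessments$status,
    reasons = vapply(assessments$reasons, paste, "", collapse = ";"),
    current_mpr = assessments$current_mpr,
    first_fill_date = assessments$first_fill_date,
    last_fill_date = assessments$last_fill_date,
    observation_days = assessments$observation_days,
    n_fills = assessments$n_fills,
    gap_alert = assessments$gap_alert,
    n_gaps = vapply(assessments$gaps, nrow, integer(1)),
    max_gap_days = vapply(assessments$gaps, function(g) {
      if (nrow(g) == 0L) 0L else max(g$length)
    }, integer(1)),
    prediction_day = assessments$prediction_day,
    mpr_at_prediction_day = assessments$mpr_at_prediction_day,
    probability_poor = assessments$probability_poor,
    predicted_poor = assessments$predicted_poor
  )
}
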