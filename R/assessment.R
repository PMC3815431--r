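#' Classify one medication's adherence status
#'
#' Runs the three non-adherence checks on a single medication history and
#' combines them into a clinician-style status flag:
#'
#' * **RED** — current non-adherence: a refill gap longer than
#'   `gap_days` at any time in the record, or a current MPR below
#'   `mpr_threshold`. These two checks run on every medication,
#'   regardless of drug class.
#' * **YELLOW** — predicted non-adherence: the drug-class logistic model,
#'   anchored at the latest reached prediction day, predicts a 1-year
#'   MPR below threshold.
#' * **GREEN** — adherence: either a full observed year with 1-year MPR
#'   at or above threshold (the observed outcome supersedes any
#'   forecast), or the model predicts acceptable adherence.
#' * **NONE** — no current problem and no verdict is possible (unmapped
#'   drug class, no configured model, or the record is too short to
#'   anchor a prediction).
#'
#' Precedence is RED > YELLOW > GREEN > NONE. A RED medication never
#' carries a prediction: the forecast only runs on medications that pass
#' the gap check. The `reasons` column records machine-readable evidence
#' codes (`GAP_OVER_30`, `CURRENT_MPR_BELOW_0_8`, `PREDICTED_POOR_1Y`,
#' `PREDICTED_OK_1Y`, `ACTUAL_1Y_OK`, `NO_MODEL`, `SPAN_TOO_SHORT`).
#'
#' @param history A [med_history()].
#' @param class_map A [read_drug_class_map()] result, or `NULL`.
#' @param models A [read_model_config()] result, or `NULL`.
#' @param options An [adherence_options()] bundle.
#' @param age Patient age in years at first fill; defaults to the age
#'   stored on the history.
#' @return A one-row assessment tibble (see [assess_patient()] for the
#'   column set).
#' @examples
#' h <- med_history(0, 30, horizon = 200, medication_name = "Cyclobenzaprine")
#' classify_medication(h)  # 170-day trailing gap -> RED
#' @export
classify_medication <- function(history, class_map = NULL, models = NULL,
                                options = adherence_options(),
                                age = history$age) {
  stopifnot(inherits(history, "med_history"))
  horizon <- history$horizon
  reasons <- character(0)

  gaps <- if (horizon >= 1L) {
    detect_gaps(history, gap_days = options$gap_days, gap_mode = options$gap_mode,
                carryover = options$carryover)
  } else {
    empty_gaps()
  }
  gap_alert <- any(gaps$alert)
  if (gap_alert) reasons <- c(reasons, "GAP_OVER_30")

  current_mpr <- NA_real_
  mpr_flag <- FALSE
  if (horizon >= 1L) {
    cur <- check_current_mpr(history, mpr_threshold = options$mpr_threshold,
                             cap_at_one = options$cap_at_one)
    current_mpr <- cur$mpr
    mpr_flag <- cur$flag
  }
  if (mpr_flag) reasons <- c(reasons, "CURRENT_MPR_BELOW_0_8")

  drug_class <- if (is.null(class_map)) NA_character_ else {
    drug_class_of(class_map, history$medication_id, history$medication_name)
  }

  status <- NA_character_
  prediction <- NULL

  if (gap_alert || mpr_flag) {
    status <- "RED"
  } else {
    if (horizon >= options$year_days) {
      year_mpr <- compute_mpr(history, options$year_days,
                              cap_at_one = options$cap_at_one)
      if (year_mpr >= options$mpr_threshold) {
        status <- "GREEN"
        reasons <- c(reasons, "ACTUAL_1Y_OK")
      }
    }
    if (is.na(status)) {
      if (horizon < min(options$prediction_days)) {
        status <- "NONE"
        reasons <- c(reasons, "SPAN_TOO_SHORT")
      } else if (is.na(drug_class)) {
        status <- "NONE"
        reasons <- c(reasons, "NO_MODEL")
      } else {
        pday <- select_prediction_day(horizon, options$prediction_days)
        model <- find_model(models, drug_class, pday)
        if (is.null(model) || is.na(age)) {
          status <- "NONE"
          reasons <- c(reasons, "NO_MODEL")
        } else {
          mpr_at <- compute_mpr(history, pday, cap_at_one = FALSE)
          prediction <- predict_one_year(age, mpr_at, model)
          if (prediction$predicted_poor) {
            status <- "YELLOW"
            reasons <- c(reasons, "PREDICTED_POOR_1Y")
          } else {
            status <- "GREEN"
            reasons <- c(reasons, "PREDICTED_OK_1Y")
          }
        }
      }
    }
  }

  out <- tibble(
    patient_id = history$patient_id,
    medication_id = history$medication_id,
    medication_name = history$medication_name,
    drug_class = drug_class,
    status = status,
    reasons = list(reasons),
    current_mpr = current_mpr,
    first_fill_date = history$first_fill_date,
    last_fill_date = history$first_fill_date + max(history$fill_days),
    observation_days = horizon,
    n_fills = length(history$fill_days),
    gap_alert = gap_alert,
    gaps = list(gaps),
    prediction_day = if (is.null(prediction)) NA_integer_ else prediction$prediction_day,
    mpr_at_prediction_day = if (is.null(prediction)) NA_real_ else prediction$mpr_at_prediction_day,
    probability_poor = if (is.null(prediction)) NA_real_ else prediction$probability_poor,
    predicted_poor = if (is.null(prediction)) NA else prediction$predicted_poor
  )
  class(out) <- c("adherence_assessment", class(tibble()))
  out
}

#' Assess all medications of one patient
#'
#' Classifies every medication history of a single patient and orders the
#' result the way a medication-list view presents it: medications in drug
#' classes with configured predictions first (classes alphabetical,
#' medications alphabetical within class), then unmapped medications
#' alphabetically.
#'
#' @param histories A histories tibble from [fulfillment_histories()]
#'   (all rows one patient), or a list of [med_history()] objects.
#' @inheritParams classify_medication
#' @return An assessment tibble, one row per medication.
#' @export
assess_patient <- function(histories, class_map = NULL, models = NULL,
                           options = adherence_options()) {
  hs <- if (inherits(histories, "med_history")) {
    list(histories)
  } else if (is.data.frame(histories)) {
    histories$history
  } else {
    histories
  }
  if (length(hs) == 0L) return(empty_assessments())
  pid <- unique(vapply(hs, `[[`, "", "patient_id"))
  if (length(pid) > 1L) {
    abort("`assess_patient()` expects histories of a single patient.",
          class = "mpr_usage_error")
  }
  out <- purrr::map(hs, classify_medication, class_map = class_map,
                    models = models, options = options) |>
    purrr::list_rbind()
  out <- out[order(is.na(out$drug_class),
                   ifelse(is.na(out$drug_class), "", out$drug_class),
                   tolower(out$medication_name)), ]
  class(out) <- c("adherence_assessment", class(tibble()))
  out
}

#' Assess a whole fulfillment file
#'
#' Convenience pipeline: group fills into histories, then run
#' [assess_patient()] per patient.
#'
#' @param fills A fills tibble from [read_fulfillments()].
#' @param as_of Observation end date (default: latest fill date in the
#'   file).
#' @inheritParams classify_medication
#' @return An assessment tibble, one row per (patient, medication),
#'   patients in sorted order.
#' @examples
#' fills <- generate_cohort(4, seed = 1)$fills
#' assess_fulfillments(fills,
#'   class_map = read_drug_class_map(
#'     system.file("extdata", "drug-classes.tsv", package = "mprmonitor")),
#'   models = read_model_config(
#'     system.file("extdata", "models-synthetic.json", package = "mprmonitor")))
#' @export
assess_fulfillments <- function(fills, class_map = NULL, models = NULL,
                                as_of = NULL, options = adherence_options()) {
  histories <- fulfillment_histories(fills, as_of = as_of)
  if (nrow(histories) == 0L) return(empty_assessments())
  out <- histories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_map(~ assess_patient(.x$history, class_map = class_map,
                                      models = models, options = options)) |>
    purrr::list_rbind()
  class(out) <- c("adherence_assessment", class(tibble()))
  out
}

empty_assessments <- function() {
  out <- tibble(
    patient_id = character(), medication_id = character(),
    medication_name = character(), drug_class = character(),
    status = character(), reasons = list(), current_mpr = numeric(),
    first_fill_date = as.Date(character()), last_fill_date = as.Date(character()),
    observation_days = integer(), n_fills = integer(), gap_alert = logical(),
    gaps = list(), prediction_day = integer(), mpr_at_prediction_day = numeric(),
    probability_poor = numeric(), predicted_poor = logical()
  )
  class(out) <- c("adherence_assessment", class(tibble()))
  out
}

#' @export
glance.adherence_assessment <- function(x, ...) {
  tibble(
    n_medications = nrow(x),
    n_patients = dplyr::n_distinct(x$patient_id),
    n_red = sum(x$status == "RED"),
    n_yellow = sum(x$status == "YELLOW"),
    n_green = sum(x$status == "GREEN"),
    n_none = sum(x$status == "NONE"),
    mean_current_mpr = mean(x$current_mpr, na.rm = TRUE)
  )
}

#' Export plot data for one medication
#'
#' Builds the structured payload behind a fulfillment-history plot: the
#' running MPR series (the blue line), fill events (circles), gap
#' shading intervals (gray dropout regions), and the adherence threshold
#' line. The payload mirrors the adherence computations exactly and can
#' be serialised to JSON for any front end.
#'
#' @param history A [med_history()].
#' @param assessment Optional one-row assessment for the same medication;
#'   computed on the fly when absent.
#' @inheritParams classify_medication
#' @param series_type `"dense"` (default) or `"sparse"`.
#' @return A list of class `"mpr_plot_data"` with elements `meta`,
#'   `series`, `fills`, `gaps`, and `threshold`.
#' @export
export_plot_data <- function(history, assessment = NULL,
                             options = adherence_options(),
                             series_type = c("dense", "sparse")) {
  stopifnot(inherits(history, "med_history"))
  series_type <- match.arg(series_type)
  if (is.null(assessment)) {
    assessment <- classify_medication(history, options = options)
  }
  series <- if (history$horizon >= 1L) {
    mpr_series(history, type = series_type, cap_at_one = options$cap_at_one)
  } else {
    tibble(day = integer(), mpr = numeric())
  }
  fills <- tibble(
    day = history$fill_days,
    days_supply = history$days_supply,
    mpr = compute_mpr(history, pmax(history$fill_days, 1L),
                      cap_at_one = options$cap_at_one)
  )
  structure(
    list(
      meta = list(
        patient_id = history$patient_id,
        medication_id = history$medication_id,
        medication_name = history$medication_name,
        first_fill_date = format(history$first_fill_date),
        horizon = history$horizon,
        status = assessment$status
      ),
      series = as.data.frame(tibble(day = series$day, mpr = series$mpr)),
      fills = as.data.frame(fills),
      gaps = as.data.frame(assessment$gaps[[1L]]),
      threshold = options$mpr_threshold
    ),
    class = "mpr_plot_data"
  )
}

#' Plot a medication possession history
#'
#' Renders the standard adherence view with ggplot2: gray rectangles for
#' gaps (darker when the gap alerts), the running MPR as a blue line,
#' fill events as circles, and a dashed line at the adherence threshold.
#'
#' @param object A [med_history()].
#' @param ... Passed to [export_plot_data()] (e.g. `options`).
#' @return A ggplot object.
#' @examples
#' autoplot(med_history(c(0, 40, 80), c(30, 30, 30), horizon = 180))
#' @export
autoplot.med_history <- function(object, ...) {
  payload <- export_plot_data(object, ...)
  p <- ggplot2::ggplot()
  if (nrow(payload$gaps) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = payload$gaps,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, alpha = .data$alert),
      fill = "grey40", show.legend = FALSE
    ) +
      ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.15, `TRUE` = 0.35))
  }
  p +
    ggplot2::geom_hline(yintercept = payload$threshold,
                        linetype = "dashed", colour = "red3") +
    ggplot2::geom_line(data = payload$series,
                       ggplot2::aes(x = .data$day, y = .data$mpr),
                       colour = "#1f77e0", linewidth = 0.8) +
    ggplot2::geom_point(data = payload$fills,
                        ggplot2::aes(x = .data$day, y = .data$mpr),
                        shape = 21, size = 2.5, fill = "white",
                        colour = "#1f77e0") +
    ggplot2::labs(
      title = sprintf("%s — %s", payload$meta$medication_name,
                      payload$meta$status),
      x = "Days since first fill", y = "Running MPR"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.med_history <- function(x, ...) print(autoplot(x, ...))
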