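#' Read a drug-class map
#'
#' Loads the external drug-class file: a two-column tab-separated table
#' mapping a key (a medication code or a case-insensitive name pattern)
#' to a drug class, e.g. `antihyperlipidemics`, `antihypertensives`,
#' `oral_hypoglycemics`. Lines starting with `#` are comments; an
#' optional `key<TAB>drug_class` header line is tolerated. Ambiguity is
#' fatal: the same key mapped to two different classes is a
#' configuration error. Medications with no matching key are legal and
#' simply have no class.
#'
#' @param file Path to the TSV file.
#' @return A tibble with columns `key` (lowercased) and `drug_class`, of
#'   class `"drug_class_map"`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("# demo map", "ramipril\tantihypertensives"), tsv)
#' map <- read_drug_class_map(tsv)
#' drug_class_of(map, "rx1", "Ramipril 5mg")
#' @export
read_drug_class_map <- function(file) {
  lines <- readr::read_lines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(structure(tibble(key = character(), drug_class = character()),
                     class = c("drug_class_map", class(tibble()))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(
      sprintf("Drug-class map line is not `key<TAB>drug_class`: '%s'.",
              lines[which(bad)[1L]]),
      class = "mpr_config_error"
    )
  }
  map <- tibble(
    key = tolower(vapply(parts, `[[`, "", 1L)),
    drug_class = trimws(vapply(parts, `[[`, "", 2L))
  )
  if (identical(map$key[1L], "key") && identical(map$drug_class[1L], "drug_class")) {
    map <- map[-1L, ]
  }
  map <- dplyr::distinct(map)
  dup <- map$key[duplicated(map$key)]
  if (length(dup) > 0L) {
    abort(
      sprintf("Drug-class map key '%s' maps to more than one class.", dup[1L]),
      class = "mpr_config_error"
    )
  }
  structure(map, class = c("drug_class_map", class(tibble())))
}

#' Look up the drug class of a medication
#'
#' A map key matches a medication if it equals the medication code
#' (case-insensitively) or if the medication's display name contains the
#' key as a case-insensitive substring, so the key `ramipril` matches
#' "Ramipril 5mg tablet". An exact code match wins over a name match;
#' among name matches the longest key wins. Unmapped medications return
#' `NA`.
#'
#' @param map A [read_drug_class_map()] result.
#' @param medication_id Medication code.
#' @param medication_name Display name (optional).
#' @return The drug class string, or `NA_character_` when unmapped.
#' @export
drug_class_of <- function(map, medication_id, medication_name = medication_id) {
  if (is.null(map) || nrow(map) == 0L) return(NA_character_)
  id <- tolower(medication_id)
  hit <- map$drug_class[map$key == id]
  if (length(hit) == 1L) return(hit)
  name <- tolower(medication_name)
  matched <- map[vapply(map$key, function(k) grepl(k, name, fixed = TRUE), logical(1)), ]
  if (nrow(matched) == 0L) return(NA_character_)
  matched <- matched[order(-nchar(matched$key)), ]
  best <- matched[nchar(matched$key) == nchar(matched$key[1L]), ]
  classes <- unique(best$drug_class)
  if (length(classes) > 1L) {
    abort(
      sprintf("Medication '%s' matches keys of equal length with conflicting classes: %s.",
              medication_name, paste(classes, collapse = ", ")),
      class = "mpr_config_error"
    )
  }
  classes
}

#' Read logistic model coefficients
#'
#' Loads the external model configuration: a JSON array of objects, one
#' per (drug class, prediction day) pair, each with `drug_class`,
#' `prediction_day` (one of 60, 90, 120 days after the first fill),
#' `intercept`, `beta_age` (per year of age), `beta_mpr` (per unit MPR),
#' and an optional `classification_threshold` (probability cut-point,
#' default 0.5). The model predicts the probability that a medication's
#' 1-year MPR falls below 0.8 ("poor adherence") from the patient's age
#' and the running MPR on the prediction day.
#'
#' The package ships an example configuration with clearly-labelled
#' synthetic placeholder coefficients at
#' `system.file("extdata", "models-synthetic.json", package = "mprmonitor")`;
#' real coefficients are supplied by the user as external data.
#'
#' @param file Path to the JSON file.
#' @return A tibble with one row per model, of class `"model_config"`.
#' @examples
#' models <- read_model_config(
#'   system.file("extdata", "models-synthetic.json", package = "mprmonitor")
#' )
#' models
#' @export
read_model_config <- function(file) {
  records <- tryCatch(
    jsonlite::fromJSON(file, simplifyDataFrame = FALSE, simplifyVector = FALSE),
    error = function(e) abort(
      sprintf("Model configuration is not valid JSON: %s", conditionMessage(e)),
      class = "mpr_config_error"
    )
  )
  if (!is.list(records)) {
    abort("Model configuration must be a JSON array of objects.",
          class = "mpr_config_error")
  }
  required <- c("drug_class", "prediction_day", "intercept", "beta_age", "beta_mpr")
  rows <- purrr::map(records, function(rec) {
    missing_fields <- setdiff(required, names(rec))
    if (length(missing_fields) > 0L) {
      abort(
        sprintf("Model record is missing field(s): %s.",
                paste(missing_fields, collapse = ", ")),
        class = "mpr_config_error"
      )
    }
    day <- rec$prediction_day
    if (!is.numeric(day) || length(day) != 1L || !day %in% c(60, 90, 120)) {
      abort(
        sprintf("prediction_day must be one of 60, 90, 120 (got '%s').",
                paste(day, collapse = ",")),
        class = "mpr_config_error"
      )
    }
    thr <- rec$classification_threshold %||% 0.5
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      abort("classification_threshold must lie strictly between 0 and 1.",
            class = "mpr_config_error")
    }
    for (f in c("intercept", "beta_age", "beta_mpr")) {
      if (!is.numeric(rec[[f]]) || length(rec[[f]]) != 1L || !is.finite(rec[[f]])) {
        abort(sprintf("Model field '%s' must be a finite number.", f),
              class = "mpr_config_error")
      }
    }
    tibble(
      drug_class = as.character(rec$drug_class),
      prediction_day = as.integer(day),
      intercept = as.numeric(rec$intercept),
      beta_age = as.numeric(rec$beta_age),
      beta_mpr = as.numeric(rec$beta_mpr),
      classification_threshold = as.numeric(thr)
    )
  })
  models <- purrr::list_rbind(rows)
  if (nrow(models) > 0L) {
    key <- paste(models$drug_class, models$prediction_day)
    if (anyDuplicated(key)) {
      abort(
        sprintf("Duplicate model for (%s).", key[duplicated(key)][1L]),
        class = "mpr_config_error"
      )
    }
  } else {
    models <- tibble(
      drug_class = character(), prediction_day = integer(),
      intercept = numeric(), beta_age = numeric(), beta_mpr = numeric(),
      classification_threshold = numeric()
    )
  }
  structure(models, class = c("model_config", class(tibble())))
}

#' Select the prediction day for an observation span
#'
#' The forecast is anchored at the latest available prediction day (60,
#' 90, or 120 days after the first fill by default) that the record has
#' already reached. Spans shorter than the earliest day yield `NA`: no
#' prediction is possible yet. A record observed beyond 120 days still
#' uses the 120-day model — predictions are never anchored later.
#'
#' @param observation_span_days Nonnegative integer day span(s) since the
#'   first fill.
#' @param available_days Candidate prediction days.
#' @return An integer vector: the chosen day per span, `NA` where no day
#'   is reached.
#' @examples
#' select_prediction_day(c(59, 60, 100, 365))  # NA 60 90 120
#' @export
select_prediction_day <- function(observation_span_days,
                                  available_days = c(60L, 90L, 120L)) {
  if (any(observation_span_days < 0, na.rm = TRUE)) {
    abort("`observation_span_days` must be nonnegative.", class = "mpr_usage_error")
  }
  available_days <- sort(as.integer(available_days))
  vapply(as.integer(observation_span_days), function(span) {
    ok <- available_days[available_days <= span]
    if (length(ok) == 0L) NA_integer_ else max(ok)
  }, integer(1))
}

#' Predict poor adherence at one year
#'
#' Applies a two-covariate logistic model: the probability that the
#' medication's 1-year MPR falls below 0.8 is
#' `1 / (1 + exp(-(intercept + beta_age * age + beta_mpr * mpr)))`,
#' where `age` is the patient's age in years at the first fill and `mpr`
#' the uncapped running MPR at the prediction day. The binary call
#' `predicted_poor` compares the probability against the model's
#' classification threshold (`>=` flags poor).
#'
#' @param age Age in years at first fill.
#' @param mpr_at_day Running MPR at the model's prediction day.
#' @param model A one-row model tibble (a row of [read_model_config()]).
#' @return A one-row tibble: `drug_class`, `prediction_day`,
#'   `mpr_at_prediction_day`, `probability_poor`, `predicted_poor`.
#' @examples
#' m <- tibble::tibble(drug_class = "demo", prediction_day = 60L,
#'                     intercept = 0, beta_age = 0, beta_mpr = -2,
#'                     classification_threshold = 0.5)
#' predict_one_year(age = 50, mpr_at_day = 1, model = m)  # 1/(1+e^2)
#' @export
predict_one_year <- function(age, mpr_at_day, model) {
  if (nrow(model) != 1L) {
    abort("`model` must be a single model row.", class = "mpr_usage_error")
  }
  if (is.na(age) || age < 0) {
    abort("`age` must be a nonnegative number of years.", class = "mpr_usage_error")
  }
  if (is.na(mpr_at_day) || mpr_at_day < 0) {
    abort("`mpr_at_day` must be nonnegative.", class = "mpr_usage_error")
  }
  eta <- model$intercept + model$beta_age * age + model$beta_mpr * mpr_at_day
  p <- plogis(eta)
  tibble(
    drug_class = model$drug_class,
    prediction_day = model$prediction_day,
    mpr_at_prediction_day = as.numeric(mpr_at_day),
    probability_poor = p,
    predicted_poor = p >= model$classification_threshold
  )
}

find_model <- function(models, drug_class, prediction_day) {
  if (is.null(models) || nrow(models) == 0L || is.na(drug_class) ||
      is.na(prediction_day)) {
    return(NULL)
  }
  hit <- models[models$drug_class == drug_class &
                  models$prediction_day == prediction_day, ]
  if (nrow(hit) == 0L) NULL else hit
}
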