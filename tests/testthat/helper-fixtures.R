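write_fills_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

fills_header <- "patient_id,medication_id,medication_name,fill_date,days_supply"

example_class_map <- function() {
  read_drug_class_map(
    system.file("extdata", "drug-classes.tsv", package = "mprmonitor")
  )
}

example_models <- function() {
  read_model_config(
    system.file("extdata", "models-synthetic.json", package = "mprmonitor")
  )
}

# a forced-outcome model set: intercept-only models so the binary call is
# known regardless of age and MPR
forced_models <- function(classes, poor = TRUE, days = c(60L, 90L, 120L)) {
  grid <- expand.grid(drug_class = classes, prediction_day = days,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    drug_class = grid$drug_class,
    prediction_day = as.integer(grid$prediction_day),
    intercept = if (poor) 10 else -10,
    beta_age = 0, beta_mpr = 0,
    classification_threshold = 0.5
  )
}

single_key_map <- function(key = "rx-test", drug_class = "testclass") {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t%s", key, drug_class), tsv)
  read_drug_class_map(tsv)
}
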