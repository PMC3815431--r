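test_that("drug-class map loads, matches case-insensitively, and rejects ambiguity", {
  map <- example_class_map()
  expect_equal(drug_class_of(map, "ramipril"), "antihypertensives")
  expect_equal(drug_class_of(map, "RAMIPRIL"), "antihypertensives")
  expect_equal(drug_class_of(map, "rx-999", "Ramipril 5mg tablet"),
               "antihypertensives")
  expect_true(is.na(drug_class_of(map, "cyclobenzaprine")))

  empty <- tempfile(fileext = ".tsv")
  writeLines("# nothing here", empty)
  empty_map <- read_drug_class_map(empty)
  expect_equal(nrow(empty_map), 0L)
  expect_true(is.na(drug_class_of(empty_map, "anything")))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("ramipril\tantihypertensives", "ramipril\toral_hypoglycemics"), dup)
  expect_error(read_drug_class_map(dup), "ramipril", class = "mpr_config_error")
})

test_that("model configuration loads 3 classes x 3 days and validates records", {
  models <- example_models()
  expect_equal(nrow(models), 9L)
  expect_setequal(unique(models$prediction_day), c(60L, 90L, 120L))
  expect_setequal(unique(models$drug_class),
                  c("antihyperlipidemics", "antihypertensives",
                    "oral_hypoglycemics"))
  expect_true(all(models$classification_threshold == 0.5))

  bad_day <- tempfile(fileext = ".json")
  writeLines('[{"drug_class":"x","prediction_day":45,"intercept":0,"beta_age":0,"beta_mpr":0}]',
             bad_day)
  expect_error(read_model_config(bad_day), "60, 90, 120",
               class = "mpr_config_error")

  missing_beta <- tempfile(fileext = ".json")
  writeLines('[{"drug_class":"x","prediction_day":60,"intercept":0,"beta_age":0}]',
             missing_beta)
  expect_error(read_model_config(missing_beta), "beta_mpr",
               class = "mpr_config_error")

  dup <- tempfile(fileext = ".json")
  writeLines(paste0('[{"drug_class":"x","prediction_day":60,"intercept":0,',
                    '"beta_age":0,"beta_mpr":0},{"drug_class":"x",',
                    '"prediction_day":60,"intercept":1,"beta_age":0,"beta_mpr":0}]'),
             dup)
  expect_error(read_model_config(dup), class = "mpr_config_error")
})

test_that("the prediction day is the latest one the record has reached", {
  expect_identical(
    select_prediction_day(c(59, 60, 89, 90, 100, 119, 120, 365)),
    c(NA, 60L, 60L, 90L, 90L, 90L, 120L, 120L)
  )
  expect_error(select_prediction_day(-1), class = "mpr_usage_error")
})

test_that("logistic predictions obey closed-form identities", {
  zero <- tibble::tibble(drug_class = "z", prediction_day = 60L, intercept = 0,
                         beta_age = 0, beta_mpr = 0,
                         classification_threshold = 0.5)
  expect_equal(predict_one_year(37, 0.4, zero)$probability_poor, 0.5)

  m <- tibble::tibble(drug_class = "z", prediction_day = 60L, intercept = 0,
                      beta_age = 0, beta_mpr = -2,
                      classification_threshold = 0.5)
  expect_equal(predict_one_year(50, 1.0, m)$probability_poor, 1 / (1 + exp(2)),
               tolerance = 1e-15)

  withr::with_seed(81, {
    for (rep in 1:50) {
      coefs <- round(c(runif(1, -4, 4), runif(1, -0.1, 0.1), runif(1, -4, 4)), 3)
      age <- round(runif(1, 18, 90), 1)
      mpr <- round(runif(1, 0, 1.5), 3)
      m1 <- tibble::tibble(drug_class = "z", prediction_day = 90L,
                           intercept = coefs[1], beta_age = coefs[2],
                           beta_mpr = coefs[3], classification_threshold = 0.5)
      m2 <- m1
      m2[1, c("intercept", "beta_age", "beta_mpr")] <- as.list(-coefs)
      p1 <- predict_one_year(age, mpr, m1)$probability_poor
      p2 <- predict_one_year(age, mpr, m2)$probability_poor
      eta <- coefs[1] + coefs[2] * age + coefs[3] * mpr
      expect_equal(p1, 1 / (1 + exp(-eta)), tolerance = 1e-12)
      expect_equal(p1 + p2, 1, tolerance = 1e-12)
      expect_true(p1 > 0 && p1 < 1)
    }
  })
})

test_that("probability is monotone in MPR and age with the coefficient's sign", {
  grid <- seq(0, 1.5, by = 0.05)
  for (beta in c(-3.1, 2.4)) {
    m <- tibble::tibble(drug_class = "z", prediction_day = 60L, intercept = 0.5,
                        beta_age = 0.02, beta_mpr = beta,
                        classification_threshold = 0.5)
    p <- vapply(grid, function(x) predict_one_year(55, x, m)$probability_poor,
                numeric(1))
    expect_true(all(sign(diff(p)) == sign(beta)))
  }
  ages <- seq(20, 90, by = 5)
  for (beta_age in c(-0.05, 0.05)) {
    m <- tibble::tibble(drug_class = "z", prediction_day = 60L, intercept = 0.5,
                        beta_age = beta_age, beta_mpr = -1,
                        classification_threshold = 0.5)
    p <- vapply(ages, function(a) predict_one_year(a, 0.9, m)$probability_poor,
                numeric(1))
    expect_true(all(sign(diff(p)) == sign(beta_age)))
  }
})

test_that("classification threshold is configurable and >= flags poor", {
  m <- tibble::tibble(drug_class = "z", prediction_day = 60L, intercept = 0,
                      beta_age = 0, beta_mpr = 0,
                      classification_threshold = 0.5)
  expect_true(predict_one_year(50, 1, m)$predicted_poor)   # p = 0.5 exactly
  m$classification_threshold <- 0.6
  expect_false(predict_one_year(50, 1, m)$predicted_poor)
})
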