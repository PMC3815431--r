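test_that("every check combination yields the unique documented status", {
  map <- single_key_map("medication", "testclass")
  pred_configs <- list(
    poor = forced_models("testclass", poor = TRUE),
    ok = forced_models("testclass", poor = FALSE),
    none = NULL
  )
  for (case in truth_table_cases()) {
    # the recipe must realize its target component outcomes
    gaps <- detect_gaps(case$h)
    expect_identical(any(gaps$alert), case$gap)
    expect_identical(unname(compute_mpr(case$h, case$h$horizon) < 0.8),
                     case$curlow)
    if (case$year != "absent") {
      expect_gte(case$h$horizon, 365)
      expect_identical(compute_mpr(case$h, 365) >= 0.8, case$year == "ok")
    } else {
      expect_lt(case$h$horizon, 365)
    }
    for (pred in names(pred_configs)) {
      a <- classify_medication(case$h, class_map = map,
                               models = pred_configs[[pred]], age = 55)
      expect_identical(
        a$status, expected_status(case$gap, case$curlow, case$year, pred),
        label = sprintf("status for gap=%s curlow=%s year=%s pred=%s",
                        case$gap, case$curlow, case$year, pred)
      )
      # RED medications never carry a prediction
      if (a$status == "RED") {
        expect_true(is.na(a$prediction_day))
        expect_true(is.na(a$probability_poor))
      }
      if (a$status == "YELLOW") expect_true("PREDICTED_POOR_1Y" %in% a$reasons[[1]])
      if (a$status == "RED") {
        expect_true(any(c("GAP_OVER_30", "CURRENT_MPR_BELOW_0_8") %in% a$reasons[[1]]))
      }
    }
  }
})

test_that("documented reason codes track the triggering checks", {
  # 196-day trailing gap: red regardless of class
  long_gap <- classify_medication(med_history(c(0, 30), c(30, 30), 256),
                                  class_map = example_class_map(),
                                  models = example_models())
  expect_equal(long_gap$status, "RED")
  expect_true("GAP_OVER_30" %in% long_gap$reasons[[1]])
  expect_equal(long_gap$gaps[[1]]$length, 196L)

  # clean, unmapped, under a year: no verdict
  unmapped <- classify_medication(
    med_history(seq(0, 180, 30), rep(30L, 7), 200,
                medication_name = "Cyclobenzaprine"),
    class_map = example_class_map(), models = example_models(), age = 55
  )
  expect_equal(unmapped$status, "NONE")
  expect_true("NO_MODEL" %in% unmapped$reasons[[1]])

  # full observed year above threshold: green from the observed outcome
  actual_ok <- classify_medication(
    med_history(seq(0, 360, 30), rep(30L, 13), 380,
                medication_name = "Ramipril"),
    class_map = example_class_map(), models = example_models(), age = 62
  )
  expect_equal(actual_ok$status, "GREEN")
  expect_true("ACTUAL_1Y_OK" %in% actual_ok$reasons[[1]])
  expect_true(is.na(actual_ok$prediction_day))

  # clean but too short for any prediction day
  short <- classify_medication(med_history(0, 45, 50), class_map = NULL, age = 55)
  expect_equal(short$status, "NONE")
  expect_true("SPAN_TOO_SHORT" %in% short$reasons[[1]])
})

test_that("patient assessment is total and groups mapped classes first", {
  hs <- list(
    med_history(seq(0, 180, 30), rep(30L, 7), 200, patient_id = "p1",
                medication_id = "rx-z", medication_name = "Zopiclone"),
    med_history(seq(0, 180, 30), rep(30L, 7), 200, patient_id = "p1",
                medication_id = "rx-a", medication_name = "Atorvastatin", age = 50),
    med_history(seq(0, 180, 30), rep(30L, 7), 200, patient_id = "p1",
                medication_id = "rx-l", medication_name = "Lisinopril", age = 50)
  )
  a <- assess_patient(hs, class_map = example_class_map(),
                      models = example_models())
  expect_equal(nrow(a), 3L)
  expect_equal(a$medication_name, c("Atorvastatin", "Lisinopril", "Zopiclone"))
  expect_equal(is.na(a$drug_class), c(FALSE, FALSE, TRUE))
  expect_equal(nrow(assess_patient(list())), 0L)
  expect_error(
    assess_patient(list(hs[[1]],
                        med_history(0, 30, 60, patient_id = "other"))),
    class = "mpr_usage_error"
  )
})

test_that("classification is deterministic on identical inputs", {
  cohort <- generate_cohort(8, seed = 5)
  a1 <- assess_fulfillments(cohort$fills, class_map = example_class_map(),
                            models = example_models())
  a2 <- assess_fulfillments(cohort$fills, class_map = example_class_map(),
                            models = example_models())
  expect_identical(a1, a2)
})

test_that("plot payload mirrors the adherence computations exactly", {
  h <- med_history(c(0, 40, 80), c(30L, 30L, 30L), 180)
  a <- classify_medication(h)
  payload <- export_plot_data(h, a)
  expect_equal(payload$gaps, as.data.frame(detect_gaps(h)))
  expect_equal(payload$fills$day, h$fill_days)
  expect_equal(payload$series$day, 1:180)
  expect_equal(payload$series$mpr, compute_mpr(h, 1:180))
  expect_equal(payload$threshold, 0.8)

  perfect <- med_history(seq(0, 150, 30), rep(30L, 6), 180)
  flat <- export_plot_data(perfect, options = adherence_options(cap_at_one = TRUE))
  expect_equal(nrow(flat$gaps), 0L)
  expect_true(all(flat$series$mpr == 1))

  p <- autoplot(h)
  expect_s3_class(p, "ggplot")
})
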