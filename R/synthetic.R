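#' Specify a synthetic refill behavior
#'
#' Describes one prescription-filling behavior pattern for the seeded
#' generator. Patterns:
#'
#' * `perfect` — refill exactly at run-out, for the whole horizon.
#' * `fixed_delay` — refill `delay` days after each run-out.
#' * `random_delay` — refill after a delay drawn per refill from a
#'   geometric distribution with mean `delay_mean` days (memoryless
#'   procrastination).
#' * `discontinue` — refill perfectly, but no fills on or after
#'   `discontinue_day`.
#' * `early_refill` — refill `refill_lead` days *before* run-out, so
#'   unused supply banks up.
#'
#' @param pattern One of the five pattern names.
#' @param days_supply Days of supply per fill.
#' @param horizon_days Observation span in days after the first fill.
#' @param delay Fixed delay in days (`fixed_delay`).
#' @param delay_mean Mean delay in days (`random_delay`).
#' @param discontinue_day First day on which no further fills occur
#'   (`discontinue`); must be `>= 1` so the day-0 fill exists.
#' @param refill_lead Days before run-out at which refills happen
#'   (`early_refill`); must be `< days_supply`.
#' @return A list of class `"behavior_spec"`.
#' @examples
#' behavior_spec("discontinue", discontinue_day = 30, horizon_days = 100)
#' @export
behavior_spec <- function(pattern = c("perfect", "fixed_delay", "random_delay",
                                      "discontinue", "early_refill"),
                          days_supply = 30, horizon_days = 365,
                          delay = 10, delay_mean = 7,
                          discontinue_day = 60, refill_lead = 5) {
  if (length(pattern) != 1L ||
      !pattern %in% c("perfect", "fixed_delay", "random_delay",
                      "discontinue", "early_refill")) {
    abort(sprintf("Unknown behavior pattern '%s'.", paste(pattern, collapse = ",")),
          class = "mpr_usage_error")
  }
  if (days_supply < 1 || horizon_days < 1) {
    abort("`days_supply` and `horizon_days` must be >= 1.", class = "mpr_usage_error")
  }
  if (delay < 0 || delay_mean < 0 || refill_lead < 0) {
    abort("Pattern parameters must be nonnegative.", class = "mpr_usage_error")
  }
  if (pattern == "discontinue" && discontinue_day < 1) {
    abort("`discontinue_day` must be >= 1 (day 0 is always a fill).",
          class = "mpr_usage_error")
  }
  if (pattern == "early_refill" && refill_lead >= days_supply) {
    abort("`refill_lead` must be smaller than `days_supply`.",
          class = "mpr_usage_error")
  }
  structure(
    list(pattern = pattern, days_supply = as.integer(days_supply),
         horizon_days = as.integer(horizon_days), delay = as.integer(delay),
         delay_mean = as.numeric(delay_mean),
         discontinue_day = as.integer(discontinue_day),
         refill_lead = as.integer(refill_lead)),
    class = "behavior_spec"
  )
}

#' Generate one synthetic medication history with ground truth
#'
#' Constructs the fill schedule a [behavior_spec()] implies and, in the
#' same pass, the analytic ground truth of the construction: the lapse
#' between each run-out and the next fill, the trailing lapse up to the
#' horizon, whether any lapse exceeds 30 days, and the end-of-record MPR
#' (total supply over the horizon). The truth is derived from the
#' schedule arithmetic alone, independently of the package's
#' interval-based analyzers, so it can serve as an external check on
#' them.
#'
#' @param spec A [behavior_spec()].
#' @param seed Optional integer seed. When supplied, the schedule is a
#'   pure function of `spec` and `seed`; when `NULL`, the current RNG
#'   stream is used (for use inside [generate_cohort()]).
#' @param patient_id,medication_id,medication_name,first_fill_date,age
#'   Identity fields passed through to the history.
#' @return A list with `history` (a [med_history()]), `fills` (a tibble
#'   in the fulfillment-CSV dialect), and `truth` (a one-row tibble with
#'   `pattern`, `n_fills`, `total_supply`, `true_gap_lengths` (list),
#'   `true_max_gap`, `true_gap_alert`, `true_current_mpr`).
#' @examples
#' g <- generate_history(behavior_spec("perfect", horizon_days = 365))
#' g$truth
#' @export
generate_history <- function(spec, seed = NULL,
                             patient_id = "sim-patient",
                             medication_id = "sim-med",
                             medication_name = medication_id,
                             first_fill_date = as.Date("2022-01-01"),
                             age = 55) {
  stopifnot(inherits(spec, "behavior_spec"))
  build <- function() {
    s <- spec$days_supply
    fill_days <- integer(0)
    delays <- numeric(0)
    d <- 0L
    repeat {
      if (spec$pattern == "discontinue" && d >= spec$discontinue_day) break
      fill_days <- c(fill_days, d)
      nxt <- switch(
        spec$pattern,
        perfect = d + s,
        discontinue = d + s,
        fixed_delay = d + s + spec$delay,
        random_delay = d + s + rgeom(1L, prob = 1 / (1 + spec$delay_mean)),
        early_refill = d + s - spec$refill_lead
      )
      nxt <- as.integer(nxt)
      if (nxt > spec$horizon_days) break
      delays <- c(delays, nxt - (d + s))
      d <- nxt
    }
    list(fill_days = fill_days, delays = delays)
  }
  sched <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())

  fill_days <- sched$fill_days
  n <- length(fill_days)
  supplies <- rep(spec$days_supply, n)
  horizon <- spec$horizon_days

  # analytic truth from the schedule arithmetic (no interval machinery):
  # a positive delay between run-out and the next fill is a lapse, and for
  # the early_refill pattern coverage is continuous from day 0 so the bank
  # equals total supply.
  inter_gaps <- sched$delays[sched$delays > 0]
  analytic_end <- if (spec$pattern == "early_refill") {
    min(sum(supplies), horizon)
  } else {
    min(fill_days[n] + spec$days_supply, horizon)
  }
  trailing <- horizon - analytic_end
  gap_lengths <- c(inter_gaps, if (trailing > 0) trailing)
  truth <- tibble(
    pattern = spec$pattern,
    n_fills = n,
    total_supply = sum(supplies),
    true_gap_lengths = list(as.integer(gap_lengths)),
    true_max_gap = if (length(gap_lengths)) as.integer(max(gap_lengths)) else 0L,
    true_gap_alert = any(gap_lengths > 30),
    true_current_mpr = sum(supplies) / horizon
  )

  history <- med_history(
    fill_days = fill_days, days_supply = supplies, horizon = horizon,
    patient_id = patient_id, medication_id = medication_id,
    medication_name = medication_name, first_fill_date = first_fill_date,
    age = age
  )
  fills <- tibble(
    patient_id = patient_id,
    medication_id = medication_id,
    medication_name = medication_name,
    fill_date = first_fill_date + fill_days,
    days_supply = supplies,
    age_at_first_fill = as.numeric(age)
  )
  list(history = history, fills = fills, truth = truth)
}

medication_catalog <- function() {
  tibble(
    medication_id = c("rx-simvastatin", "rx-atorvastatin",
                      "rx-lisinopril", "rx-ramipril", "rx-furosemide",
                      "rx-metformin", "rx-glipizide",
                      "rx-cyclobenzaprine", "rx-ibuprofen"),
    medication_name = c("Simvastatin", "Atorvastatin",
                        "Lisinopril", "Ramipril", "Furosemide",
                        "Metformin", "Glipizide",
                        "Cyclobenzaprine", "Ibuprofen"),
    drug_class = c("antihyperlipidemics", "antihyperlipidemics",
                   "antihypertensives", "antihypertensives", "antihypertensives",
                   "oral_hypoglycemics", "oral_hypoglycemics",
                   NA, NA)
  )
}

apportion <- function(n, proportions) {
  # largest-remainder apportionment: exact for round proportions
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic patient cohort
#'
#' Builds a seeded cohort of patients, one medication each, with refill
#' behaviors drawn from `behavior_mix` and medications drawn from a
#' built-in catalog according to `classes_mix`. Emits the fulfillment-CSV
#' dialect of [read_fulfillments()] plus a truth table carrying each
#' patient's generating pattern and analytic ground-truth flags, so that
#' detection performance can be scored exactly.
#'
#' First-fill dates are jittered across patients, and every patient's
#' effective horizon is extended so that the whole cohort shares a single
#' observation end date, returned as `as_of`. Ground truth is computed at
#' that date; pass it as `as_of` when re-analyzing the emitted CSV (the
#' latest fill date can fall a few days short of it when no patient fills
#' on the final day).
#'
#' @param n_patients Number of patients (`>= 1`).
#' @param behavior_mix Named proportions over [behavior_spec()] pattern
#'   names; must sum to 1.
#' @param classes_mix Named proportions over
#'   `antihyperlipidemics`, `antihypertensives`, `oral_hypoglycemics`,
#'   `unmapped`; must sum to 1.
#' @param pattern_args Named list of argument lists passed to
#'   [behavior_spec()] per pattern, e.g.
#'   `list(discontinue = list(discontinue_day = 30, horizon_days = 200))`.
#' @param age_mean,age_sd Age distribution (normal, rounded, clipped to
#'   18–95 years).
#' @param jitter_days Maximum first-fill jitter in days.
#' @param seed Integer seed; the cohort is a pure function of the
#'   arguments and this seed.
#' @param base_date Calendar date of the earliest possible first fill.
#' @param dir If non-`NULL`, `fills.csv` and `truth.csv` are written
#'   there (byte-deterministic per seed).
#' @return A list with `fills`, `truth`, and `paths` (when `dir` given).
#' @examples
#' cohort <- generate_cohort(10, seed = 42)
#' table(cohort$truth$pattern)
#' @export
generate_cohort <- function(n_patients,
                            behavior_mix = c(perfect = 0.4, fixed_delay = 0.2,
                                             random_delay = 0.2, discontinue = 0.2),
                            classes_mix = c(antihyperlipidemics = 0.3,
                                            antihypertensives = 0.3,
                                            oral_hypoglycemics = 0.3,
                                            unmapped = 0.1),
                            pattern_args = list(),
                            age_mean = 55, age_sd = 12,
                            jitter_days = 21,
                            seed = 1L,
                            base_date = as.Date("2022-01-01"),
                            dir = NULL) {
  if (n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "mpr_usage_error")
  }
  check_mix <- function(mix, what) {
    if (is.null(names(mix)) || any(!nzchar(names(mix))) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-9) {
      abort(sprintf("`%s` must be named nonnegative proportions summing to 1.", what),
            class = "mpr_usage_error")
    }
  }
  check_mix(behavior_mix, "behavior_mix")
  check_mix(classes_mix, "classes_mix")
  known_classes <- c("antihyperlipidemics", "antihypertensives",
                     "oral_hypoglycemics", "unmapped")
  if (!all(names(classes_mix) %in% known_classes)) {
    abort(sprintf("`classes_mix` names must be among: %s.",
                  paste(known_classes, collapse = ", ")),
          class = "mpr_usage_error")
  }

  specs <- purrr::imap(behavior_mix, function(p, nm) {
    do.call(behavior_spec, c(list(pattern = nm), pattern_args[[nm]] %||% list()))
  })

  result <- withr::with_seed(as.integer(seed), {
    patterns <- rep(names(behavior_mix), apportion(n_patients, behavior_mix))
    classes <- rep(names(classes_mix), apportion(n_patients, classes_mix))
    patterns <- sample(patterns)
    classes <- sample(classes)
    ages <- pmin(pmax(round(rnorm(n_patients, age_mean, age_sd)), 18), 95)
    jitter <- if (jitter_days > 0) sample(0:jitter_days, n_patients, replace = TRUE)
              else rep(0L, n_patients)
    catalog <- medication_catalog()

    # one shared observation end for the whole cohort (see @details)
    pattern_horizons <- vapply(specs, `[[`, integer(1), "horizon_days")
    target_end <- max(jitter + pattern_horizons[patterns])

    rows <- purrr::map(seq_len(n_patients), function(i) {
      spec <- specs[[patterns[i]]]
      spec$horizon_days <- as.integer(target_end - jitter[i])
      pool <- if (classes[i] == "unmapped") catalog[is.na(catalog$drug_class), ]
              else catalog[!is.na(catalog$drug_class) & catalog$drug_class == classes[i], ]
      med <- pool[sample.int(nrow(pool), 1L), ]
      g <- generate_history(
        spec, seed = NULL,
        patient_id = sprintf("P%04d", i),
        medication_id = med$medication_id,
        medication_name = med$medication_name,
        first_fill_date = base_date + jitter[i],
        age = ages[i]
      )
      truth <- dplyr::bind_cols(
        tibble(patient_id = sprintf("P%04d", i),
               medication_id = med$medication_id,
               medication_name = med$medication_name,
               drug_class = ifelse(is.na(med$drug_class), "unmapped", med$drug_class),
               age_at_first_fill = as.numeric(ages[i]),
               first_fill_date = base_date + jitter[i],
               horizon_days = spec$horizon_days),
        g$truth
      )
      list(fills = g$fills, truth = truth)
    })
    list(
      fills = purrr::list_rbind(purrr::map(rows, "fills")),
      truth = purrr::list_rbind(purrr::map(rows, "truth")),
      as_of = base_date + target_end
    )
  })

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fills = file.path(dir, "fills.csv"),
                  truth = file.path(dir, "truth.csv"))
    readr::write_csv(result$fills, paths$fills)
    truth_flat <- result$truth
    truth_flat$true_gap_lengths <- vapply(truth_flat$true_gap_lengths,
                                          paste, "", collapse = ";")
    readr::write_csv(truth_flat, paths$truth)
  }
  list(fills = result$fills, truth = result$truth, as_of = result$as_of,
       paths = paths)
}
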