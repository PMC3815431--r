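# mprmonitor

Pharmacy claims and EHR prescription-fulfillment histories carry a strong
signal about whether a patient is actually taking a chronic medication: a
patient who stops refilling has, at best, stopped possessing the drug.
`mprmonitor` turns a flat file of fill events into the per-medication
adherence assessments a clinician-facing dashboard would display — current
non-adherence flags, refill-gap localisation, and an early forecast of
poor adherence one year after the first fill. It is aimed at health-IT
developers and adherence researchers who need the analytics layer of a
medication-adherence monitor without any EHR plumbing.

## The measures and checks

The running **medication possession ratio** of one medication, evaluated
`t` days after the first fill, is

```
MPR(t) = (total days of supply dispensed up to day t) / t
```

i.e. fills × days-supply-per-fill over days elapsed since the first fill.
`mprmonitor` leaves the ratio uncapped by default (early refills push it
above 1) and offers a cap-at-one option (the proportion-of-days-covered
convention). Three checks combine into one status per medication:

1. **Gap check (RED)** — build the possession timeline with supply
   carryover (a refill before run-out banks the leftover days) and flag
   any maximal uncovered run *strictly longer than 30 days*, including
   the trailing run up to the observation end.
2. **Current-MPR check (RED)** — flag when `MPR(now) < 0.8`, the
   conventional non-adherence cut-point.
3. **1-year forecast (YELLOW/GREEN)** — for medications that pass the gap
   check and belong to a drug class with a configured model
   (antihyperlipidemics, antihypertensives, oral hypoglycemics in the
   shipped example config), apply a two-covariate logistic model

   ```
   P(1-year MPR < 0.8) = 1 / (1 + exp(-(b0 + b_age * age + b_mpr * MPR(d))))
   ```

   anchored at the latest prediction day `d ∈ {60, 90, 120}` the record
   has reached. Coefficients are external configuration (a JSON file);
   the package ships clearly-labelled **synthetic placeholder values**
   only.

A full observed year with `MPR(365) >= 0.8` is GREEN outright (the
observed outcome supersedes any forecast); a medication with no current
problem and no possible verdict is NONE. Precedence is
RED > YELLOW > GREEN > NONE, and a RED medication never carries a
forecast.

A seeded synthetic-cohort generator (`generate_cohort()`) produces
fulfillment files with analytic ground truth (refill procrastination,
discontinuation, early-refill stockpiling, …) for testing and demos.

## Worked example

```r
library(mprmonitor)

fills   <- read_fulfillments(system.file("extdata", "example-fills.csv",  package = "mprmonitor"))
classes <- read_drug_class_map(system.file("extdata", "drug-classes.tsv", package = "mprmonitor"))
models  <- read_model_config(system.file("extdata", "models-synthetic.json", package = "mprmonitor"))

assessments <- assess_fulfillments(fills, class_map = classes, models = models)
dplyr::select(assessments, medication_name, drug_class, status,
              current_mpr, observation_days)
#> # A tibble: 3 × 5
#>   medication_name drug_class        status current_mpr observation_days
#>   <chr>           <chr>             <chr>        <dbl>            <int>
#> 1 Furosemide      antihypertensives RED          0.656              183
#> 2 Ramipril        antihypertensives GREEN        1.08               390
#> 3 Cyclobenzaprine <NA>              NONE         0.889              135
```

Furosemide is RED because its current MPR (0.656, reason code
`CURRENT_MPR_BELOW_0_8`) is under 0.8: the patient has been refilling
late. Ramipril is GREEN with reason `ACTUAL_1Y_OK` — a full year is
observed and `MPR(365) >= 0.8`, so no forecast is needed. Cyclobenzaprine
has no current problem, but it belongs to no modelled drug class
(`NO_MODEL`), so no verdict is possible. `glance(assessments)` summarises
the cohort (here: 1 red, 1 green, 1 none; mean current MPR 0.874), and

```r
h <- fulfillment_histories(fills)
autoplot(h$history[[2]])   # MPR line, fill markers, gap shading, 0.8 line
```

draws the possession plot. `run_report()` (or the
`inst/scripts/mpr-monitor` command line) writes the same assessments as
JSON, CSV, or a static HTML report with inline possession plots, and
`run_simulate()` emits seeded synthetic cohorts plus their truth tables.

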