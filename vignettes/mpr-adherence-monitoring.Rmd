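---
title: "Monitoring medication adherence with possession ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring medication adherence with possession ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprmonitor)
```

## The problem

Non-adherence to chronic medications — statins, antihypertensives, oral
hypoglycemics — is common, costly, and largely invisible during a visit.
Prescription fulfillment records offer an indirect but practical window:
a patient who stops refilling cannot be taking the drug. `mprmonitor`
implements the analytics of a refill-based adherence monitor as a plain
library over flat files: it does not talk to an EHR, it scores whatever
fulfillment table it is given.

All computation happens on an integer-day axis per medication: day 0 is
the first fill of that medication for that patient, and the observation
window is the half-open interval `[0, horizon)` with
`horizon = as_of − first_fill_date` in days. Working in integer days
removes timezone and clock ambiguity, and half-open intervals make
length arithmetic exact.

## The possession model

Each fill dispenses `days_supply` days of medication. Two coverage
conventions are supported:

* **carryover** (default): supply is banked. A fill on day *d* with *s*
  days of supply extends coverage to `max(previous run-out, d) + s`.
  This is the standard claims-analytics convention — a patient who
  refills a week early does not lose that week.
* **no carryover**: each fill covers exactly `[d, d + s)` and overlaps
  merge without banking.

The covered intervals, truncated at the horizon, form the *possession
timeline*; their complement in `[0, horizon)` are the *gaps*. The
equivalence of this interval arithmetic with a literal day-by-day
simulation (a daily supply counter) is enforced by a property test over
1,000 randomized histories and re-measured by `scripts/acceptance.R`.

The running medication possession ratio at day `t >= 1` is

$$\mathrm{MPR}(t) = \frac{\sum_{d_i \le t} s_i}{t},$$

the total supply dispensed by day *t* over the days elapsed. Two
conventions here were genuinely open and are fixed as follows:

* **Fill-day inclusion.** A fill on day *d* counts from evaluation day
  *d* onward: the patient possesses medication on the day it is
  dispensed. A consequence worth knowing: on a perfectly refilled
  history the *uncapped* ratio sits at or slightly above 1 between
  refills (the numerator always includes the fill that is currently
  being consumed), while the capped series is identically 1.
* **No cap by default.** The ratio is reported uncapped, so early
  refills push it above 1; `cap_at_one = TRUE` gives the
  proportion-of-days-covered style value. The cap never changes any
  threshold comparison at 0.8, only the reported magnitude.
* **Day 0 is excluded**: the denominator is zero there, so series start
  at day 1.

## The three checks and the status flag

1. **Gap check.** Any maximal uncovered run strictly longer than
   `gap_days` (default 30) raises the alert, including the trailing run
   up to the horizon — a patient whose supply ran out 40 days ago is in
   a gap *now*. The strictness matters at the boundary: a 30-day gap
   does not alert, a 31-day gap does. Besides this interval mode, a
   `cumulative` mode implements the single end-of-record subtraction
   (elapsed days minus total dispensed supply). The two agree exactly on
   single-fill histories; on multi-fill histories only the interval mode
   can localise a mid-history lapse, which is why it is the default.
2. **Current-MPR check.** `MPR(horizon) < 0.8` flags current
   non-adherence; exactly 0.8 does not flag.
3. **1-year forecast.** For medications that pass the gap check, belong
   to a mapped drug class, and have been observed at least 60 days, a
   logistic model of the patient's age at first fill (years) and the
   uncapped MPR at the prediction day gives the probability that the
   1-year MPR falls below 0.8. The prediction day is the *latest* of
   {60, 90, 120} the record has reached, and is never re-anchored on
   later data: a record observed 200 days still uses the 120-day model.
   The binary call compares the probability against the model's
   classification threshold (default 0.5, `>=` flags poor).

Statuses combine with precedence RED > YELLOW > GREEN > NONE:

| status | meaning |
|---|---|
| RED | gap alert or current MPR below threshold (run on every medication, regardless of class) |
| YELLOW | forecast predicts poor adherence at one year |
| GREEN | a full observed year with `MPR(365) >= 0.8`, or the forecast predicts acceptable adherence |
| NONE | no current problem, no verdict possible (unmapped class, no model, or span under 60 days) |

Two resolutions of genuinely open points: "one year" is fixed at 365
days after the first fill, and an observed year takes precedence over
the model — when `MPR(365)` is already measurable and acceptable, that
fact is reported rather than a forecast. A RED medication never carries
a forecast (the forecast population is defined by passing the gap
check), but its series and gaps are still exported for plotting. In the
medication listing, classes with configured predictions come first
(alphabetically), then unmapped medications; ordering within groups is
alphabetical by name, a package convention.

## Configuration as data

Drug classes and coefficients are deliberately external files, so the
monitor can be extended without code changes: a TSV maps medication
codes or case-insensitive name substrings to classes, and a JSON array
supplies one record per (class, prediction day) with `intercept`,
`beta_age` (per year), `beta_mpr` (per unit MPR) and an optional
threshold. Ambiguity is fatal at load time (duplicate keys, duplicate
(class, day) pairs). The shipped
`extdata/models-synthetic.json` contains **synthetic placeholder
coefficients** chosen only to be directionally sensible (higher early
MPR lowers predicted risk); they were not estimated from any dataset and
must be replaced with externally estimated values for real use.

## The synthetic generator

`generate_history()` builds one fill schedule per behavior pattern —
`perfect` (refill at run-out), `fixed_delay` (run-out + *k* days),
`random_delay` (geometric delays; geometric because it is the natural
one-parameter memoryless model of refill procrastination),
`discontinue` (no fills on or after a stated day), `early_refill`
(refill before run-out, banking supply). Ground truth (gap lengths, gap
alert, end-of-record MPR) is computed from the schedule arithmetic
itself, independently of the interval analyzers, so generator and
analyzer can check each other exactly.

`generate_cohort()` draws patients from a behavior mix and a drug-class
mix (largest-remainder apportionment, so a 50/50 mix of 100 patients is
exactly 50/50), jitters first-fill dates, and extends each patient's
effective horizon so the whole cohort shares one observation end date,
returned as `as_of`. Ground truth is computed at that date; re-analyses
of the emitted CSV should pass it explicitly, since the latest fill date
can fall a few days short of it. All randomness flows from one explicit
seed through an isolated RNG scope; identical arguments and seed yield
byte-identical CSVs.

What the generator does *not* emulate: claim reversals, 90-day
mail-order mixed with 30-day retail, therapeutic switching, dose
changes, or multiple concurrent strengths of one ingredient (distinct
medication codes are distinct histories). Passing tests on synthetic
cohorts therefore demonstrate correctness of the arithmetic and the
flag logic under the stated behavioral model, not robustness to real
claims-data quirks.

## Numerical and degenerate-input choices

* Same-day duplicate fill rows are summed (partial fills), not
  rejected.
* `as_of` defaults to the latest fill date in the file; an `as_of`
  before any fill is an error rather than a silent truncation.
* A history observed zero days (single fill on `as_of`) yields a NONE
  assessment with `SPAN_TOO_SHORT`; the MPR is undefined there.
* A missing patient age, or a mapped class with no configured model,
  downgrades to NONE with `NO_MODEL` rather than erroring: every
  history yields an assessment.
* The logistic is evaluated via `stats::plogis`, which is exactly
  `1/(1 + e^{-\eta})`; identity checks in the tests hold to 1e-12.
* Reports contain no timestamps, so identical inputs produce
  byte-identical JSON/CSV/HTML output.

## Problem sizes used in the checks

The property suites use 1,000 random histories for the
oracle-equivalence check (fills ≤ 10, supplies ≤ 90 days, horizons up to
about 660 days), 200 random coefficient draws for the logistic
identities, a 12-case constructed truth table crossed with three model
configurations, and a 100-patient 50/50 perfect/discontinuer cohort
(discontinuation at day 30, observed 200 days) for recovery and
reproducibility. These sizes exercise every code path and boundary while
keeping the whole suite fast enough to run on every change.

## Limitations

The monitor measures *possession*, not ingestion; it inherits every
caveat of refill-based adherence measures. Coefficients are applied, not
estimated: model validity rests entirely on the supplied configuration.
The 30-day, 0.8, {60, 90, 120} and 365-day constants are conventional
defaults, surfaced as options because such criteria evolve.
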