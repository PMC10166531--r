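---
title: "Measuring clinic accessibility and evaluating new sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clinic accessibility and evaluating new sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinicplan)
library(dplyr)
```

## The problem

Specialist services for chronic conditions — the motivating case is adult
congenital heart disease (ACHD) care in New South Wales — are concentrated
in metropolitan centres, while the patient population is dispersed across a
large state. Service planners need to know how accessible the current
clinics are to the people who actually attend them, and how accessibility
would change if a satellite clinic opened at a particular rural hospital.

`clinicplan` answers both questions with a simple, auditable model:

* every patient is assigned to a small statistical area through a
  postcode/suburb concordance;
* every area carries a precomputed **driving time** to every hospital, from
  an origin–destination matrix (a road-network measure; the package never
  computes times from geometry);
* a patient's access is the driving time from their area to the **nearest
  open clinic**, minimised over the clinic set;
* coverage is the share of patients strictly within a threshold (default
  one hour), and the mean and maximum drive times are **patient-weighted**:
  each patient inherits their area's time, so populous areas dominate the
  mean. The paper-style statement "x% of patients are within a one-hour
  drive" forces this convention, because times exist at area level while
  percentages are quoted over patients.

Formally, with clinic set $C$, travel matrix $t(a, c)$ and $n_a$ patients in
area $a$:

$$ T_a = \min_{c \in C} t(a, c), \qquad
   \text{coverage} = 100 \cdot
   \frac{\sum_a n_a \, [T_a < \tau]}{\sum_a n_a}, \qquad
   \bar T = \frac{\sum_a n_a T_a}{\sum_a n_a}, $$

with $\tau$ the threshold in hours and the maximum taken over areas holding
at least one in-scope patient. "Within one hour" is strict (`<`): an area at
exactly 1.0 h is outside, matching the "less than 1-hour drive" reading;
`threshold_hours` is a parameter everywhere it appears.

### Missing travel data

Some areas have no driving-time data at all (they render grey on the
published maps). These areas are **uncovered**: their patients are excluded
from the coverage percentage and the mean/maximum, and reported separately
(`n_patients_uncovered`). Missing times are never imputed and never
conflated with zero — `travel_time()` returns `NA` for an absent pair.
Missingness is treated as a property of the *area* (all facilities or
none). This matters for the monotonicity guarantee below: if single pairs
could be missing, opening a clinic could pull a previously uncovered,
far-away population into the covered pool and raise the conditional mean.
With area-level missingness, growing the clinic set can only shrink each
area's nearest time, so coverage never falls and the mean and maximum never
rise. The property suite verifies exactly this.

## Cohort selection

Raw patient records pass through a fixed three-stage filter, each patient
counted at the first stage that removes them:

1. **age** — under 18 at the end of the study window (default
   2000-01-01 to 2022-07-01). The cutoff uses calendar-exact completed
   years: someone born exactly 18 years before the window end is an adult.
   (A 29 February birthday counts from 1 March in non-leap years.)
2. **address** — the (postcode, suburb) pair does not resolve through the
   concordance. Resolution takes the highest-weight matching row, ties
   broken by the smallest area id, with every ambiguous match logged for
   audit; a postcode-only fallback applies only when the suburb is missing.
3. **encounter** — no clinic attendance inside the window.

The `selection_flow` object records the count at every stage and satisfies
`input_total = included + sum(exclusions)` by construction; a property test
checks it over randomized contaminated cohorts.

**Follow-up.** The gap since care is measured from the most recent
attendance to the window end — or to the **date of death** for deceased
patients, so someone who died a year after their last visit is not
penalised for the years after death. A patient is lost to follow-up when
the gap strictly exceeds three years; exactly three years is retained.
Durations use a 365.25 days/year convention (no convention is stated for
the source analysis; this one is applied uniformly). The alive/deceased
distinction is otherwise purely a filter: death dates keep their role as
the follow-up reference even when the display is restricted to alive
patients.

## Privacy: the public branch

The tool has two output branches. Private mode is the identity. Public mode
suppresses any **geographic or per-clinic patient count** that is positive
and below five (the threshold is a `mask_policy()` parameter, minimum 2):
per-area totals, severity and diagnosis breakdowns, lost-to-follow-up
counts, and the per-clinic reach cells. Three deliberate policy choices:

* **Zeros are displayed.** The rule suppresses information *below five
  individuals*; a zero describes no individual.
* **Complementary suppression.** Severity counts sum to the displayed area
  total, so a single suppressed cell could be recovered by subtraction. In
  that case the smallest non-zero unmasked sibling is also suppressed (or
  the total itself when all siblings are zero). Diagnosis counts are not
  complementary to the total (patients carry several diagnoses), so primary
  masking suffices there.
* **Whole-cohort tabulations are not masked.** The demographic summary
  (the Table-1-style output) and the accessibility percentages/means are
  population-level statistics of the kind published directly in the source
  study, which itself prints cells as small as 1; masking applies to
  *geographic* patient information. The disclosure scan
  (`small_count_violations()`) therefore targets per-area and per-clinic
  count fields in serialized artifacts.

The masked sentinel serializes as the string `"masked"`, never a number, in
CSV, JSON and the report. Masking is idempotent, and the suite scans every
public artifact type over randomized fixtures.

## The synthetic world

Real inputs (census boundaries and attributes, the national driving-time
dataset, the clinical database) are access-controlled, so the package ships
a seeded generator that emulates their structure and the published marginal
distributions. The generator's defaults *are* the study conditions; they
are set once, here, and the test suite treats them as fixed.

* **Areas** form a rectangular grid of square lon/lat polygons. Geometric
  realism is irrelevant — the accessibility engine only consumes the
  matrix — and the grid makes oracle checks trivial. Remoteness classes are
  assigned by distance rank from a designated "city" corner with area-count
  mix 20/25/30/15/10%; populations decay with distance from the corner
  (about 26,000 near the city to about 1,500 far out, lognormal noise), so
  the *population* concentrates in the MajorCities class the way roughly
  three quarters of the real state population does. Regions are contiguous
  index blocks, 15/5/80%, putting the metro region at the city corner.
  Disadvantage deciles are uniform; Indigenous population share rises with
  remoteness.
* **Travel times** are centroid distance × a winding factor (1.3) ×
  hours-per-cell (0.25 h), plus a small lognormal noise floor; zero noise
  gives exact linearity for tests. These two constants were chosen once so
  the synthetic state shows the qualitative pattern of the real one — high
  metro coverage, low rural coverage, patient-weighted mean near one hour —
  and are not fitted to any published value. A configurable fraction (10%)
  of Remote/VeryRemote areas loses all travel rows, emulating the grey
  areas.
* **Patients** default to the published cohort structure: severity mix
  40.25/29.25/14.92/15.58%, 49.21% female, ages from a left-truncated
  normal bounded at 18. A truncated N(43.70, 16.65) has mean ≈ 45.9, so the
  latent location and scale are calibrated numerically (memoized
  Nelder–Mead on the truncated-moment equations) so that the *realized*
  truncated mean and SD equal the configured 43.70 and 16.65 — the
  generator's contract is to reproduce the printed marginals, not the
  latent parameters. Attendance counts are `1 + Poisson(mean − 1)` with
  per-severity means 2.29/4.27/5.86/1.9, keeping every patient attending at
  least once while matching the means exactly. (The source reports two
  different overall attendance SDs in text and table; the generator targets
  the tabulated per-severity means and lets the SD follow.) Follow-up gaps
  come from a two-component mixture — recent gaps uniform on [0, 3) years,
  lost gaps uniform on (3, 15] — mixed at the per-severity
  lost-to-follow-up targets 68.13/34.00/21.71/4.62%; this is the simplest
  mechanism that hits the printed fractions. A 12.3% deceased fraction
  (death dates inside the window) mirrors the included versus
  included-alive split of the selection flowchart; published marginals are
  checked on the alive subset, as in the source. Severity and area are
  independent by default (no joint distribution is published).
* **Contamination** records — minors, unmappable postcodes, attendances
  entirely before the window — are appended at configurable rates
  (5/3/3%), each violating exactly one rule, so the selection flow is
  exercised end to end.

Everything is deterministic given the seed: identical configurations yield
byte-identical CSV/GeoJSON output, which the suite asserts.

What passing tests on this world *do not* show: spatial autocorrelation of
disease prevalence, severity–remoteness interaction, realistic road
topology, or the true joint distribution of the clinical database. Results
on synthetic data demonstrate correctness of the machinery, not estimates
for the real service.

## Reports and reproducibility

`build_report()` is a pure function of a `tool_state()` (filters, scope,
layer, clinic sets, focus areas, privacy policy, threshold) plus the input
bundle. Every table is recomputed from scratch at render time — templates
contain no arithmetic — so the disclosure scan over the rendered document is
sound. The document has exactly five content sections in fixed order
(Patient Data, Area Data, Current Clinics, New Clinics, Area Focus) behind
a provenance block (state hash, seed, timestamp); bodies are byte-identical
across runs up to the timestamp line, and `report_body()` strips that line
so purity can be asserted. Focus areas accumulate in selection order.

## Numerical and tie-break conventions

* Nearest-clinic ties break to the lexicographically smallest facility id.
* Concordance ties break by weight, then smallest area id, logged.
* The coverage threshold comparison is strict; the lost-to-follow-up
  threshold comparison is strict.
* Sample SDs use n − 1 and are reported missing for strata of size 1;
  an empty cohort summarises to N = 0 with missing moments, and a scope
  with zero covered patients reports missing statistics rather than NaN.
* Clinic reach rows are deliberately non-disjoint across clinics (a patient
  can be within an hour of two clinics); assignment-based partitioning is
  available only through `nearest_clinic_time()`.
* The maximum drive time is taken over areas containing at least one
  in-scope patient — identical to a patient-level maximum whenever every
  such area holds a patient, which is how the headline "longest drive"
  figures should be read.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
bundle_dir <- tempfile()
b <- simulate_bundle(cfg, bundle_dir)

sel <- select_cohort(b$patients, cfg$window, b$concordance)
alive <- sel$cohort |>
  map_diagnoses(b$diagnosis_map, quiet = TRUE) |>
  apply_global_filters(global_filters(vital_statuses = "alive"), cfg$window)

agg <- aggregate_to_areas(alive, b$areas, cfg$window)
current <- b$facilities$facility_id[b$facilities$role == "current_clinic"]

accessibility_summary(agg, b$ttm, current, b$areas,
                      threshold_hours = 1, scope = "RestOfState")

cand <- worst_served_candidates(agg, b$ttm, b$facilities, current, b$areas)
evaluate_candidates(agg, b$ttm, current, cand, b$areas)
```

The problem sizes used throughout the suite — a 120-area grid, 12
facilities, cohorts of a few hundred to 3,484 records with one 3,000-record
marginal-recovery check — were chosen as the smallest sizes at which the
statistical checks (3-standard-error agreement) are meaningful.

## Limitations

* The matrix is a fixed directed area→facility lookup; no time-of-day or
  direction effects (none are present in the source data either).
* Candidate evaluation is what-if analysis over user-selected sites
  (`worst_served_candidates()` is a demonstration heuristic); optimal
  facility-location search (p-median, maximal covering) is out of scope.
* Severity classification is consumed as an input column, never computed.
* Street-address geocoding is out of scope: linkage starts at the
  postcode/suburb level.
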