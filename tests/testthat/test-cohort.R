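w22 <- study_window("2000-01-01", "2022-07-01")

test_that("link_area resolves exact matches, weights, ties and fallbacks", {
  conc <- tiny_concordance()
  p_exact <- make_patient("P1", postcode = "2000", suburb = "Sydney")
  expect_equal(link_area(p_exact, conc), "A1")

  # two candidate areas: highest weight wins, with an audit warning
  p_multi <- make_patient("P2", postcode = "2100", suburb = "North")
  expect_warning(got <- link_area(p_multi, conc),
                 class = "cp_ambiguous_linkage")
  expect_equal(got, "A2")

  # equal weights: lexicographically smallest area_id
  tie <- tibble::tibble(postcode = "2500", suburb = "Tie",
                        area_id = c("A9", "A3"), weight = c(0.5, 0.5))
  p_tie <- make_patient("P3", postcode = "2500", suburb = "Tie")
  expect_warning(got_tie <- link_area(p_tie, tie),
                 class = "cp_ambiguous_linkage")
  expect_equal(got_tie, "A3")

  # postcode-only fallback applies only when the suburb is missing
  p_nosub <- make_patient("P4", postcode = "2200", suburb = NA_character_)
  expect_equal(link_area(p_nosub, tiny_concordance()), "A4")
  p_wrongsub <- make_patient("P5", postcode = "2200", suburb = "Elsewhere")
  expect_true(is.na(link_area(p_wrongsub, tiny_concordance())))
})

test_that("select_cohort applies age, address, encounter in order", {
  conc <- tiny_concordance()
  recs <- dplyr::bind_rows(
    lapply(1:6, function(i) make_patient(paste0("OK", i))),
    make_patient("MIN1", dob = as.Date("2010-01-01")),
    make_patient("MIN2", dob = as.Date("2012-05-05")),
    make_patient("BAD", postcode = "9999"),
    make_patient("OLD", attendances = list(as.Date("1999-06-01")))
  )
  res <- select_cohort(recs, w22, conc)
  f <- res$flow
  expect_equal(f$input_total, 10L)
  expect_equal(f$excluded_under_18, 2L)
  expect_equal(f$excluded_no_valid_address, 1L)
  expect_equal(f$excluded_no_encounter_in_window, 1L)
  expect_equal(f$included, 6L)
  expect_equal(f$input_total,
               f$included + f$excluded_under_18 +
                 f$excluded_no_valid_address +
                 f$excluded_no_encounter_in_window)

  # a record failing several rules is counted at the first failing stage
  multi <- make_patient("M", dob = as.Date("2015-01-01"), postcode = "9999",
                        attendances = list(as.Date("1998-01-01")))
  f2 <- select_cohort(dplyr::bind_rows(recs, multi), w22, conc)$flow
  expect_equal(f2$excluded_under_18, 3L)
  expect_equal(f2$excluded_no_valid_address, 1L)
})

test_that("the adult cutoff is calendar-exact at the window end", {
  conc <- tiny_concordance()
  exactly18 <- make_patient("E18", dob = as.Date("2004-07-01"))
  just_under <- make_patient("U18", dob = as.Date("2004-07-02"))
  seventeen <- make_patient("S17", dob = as.Date("2005-07-01"))
  res <- select_cohort(dplyr::bind_rows(exactly18, just_under, seventeen),
                       w22, conc)
  expect_equal(res$cohort$patient_id, "E18")
  expect_equal(res$flow$excluded_under_18, 2L)
})

test_that("empty input yields an empty cohort with a zeroed flow", {
  res <- select_cohort(make_patient("x")[0, ], w22, tiny_concordance())
  expect_equal(nrow(res$cohort), 0)
  expect_equal(res$flow$input_total, 0L)
  expect_equal(res$flow$included, 0L)
})

test_that("time since last attendance uses death date for the deceased", {
  # last visit at the window end: zero gap
  p0 <- make_patient("P0", attendances = list(as.Date("2022-07-01")))
  expect_equal(time_since_last_attendance(p0, w22), 0)

  # alive: referenced to the window end
  p3 <- make_patient("P3", attendances = list(as.Date("2019-07-01")))
  expect_equal(time_since_last_attendance(p3, w22), 3.0, tolerance = 1e-2)

  # deceased: referenced to the death date, not the window end
  pd <- make_patient("PD", vital = "deceased",
                     death = as.Date("2015-01-01"),
                     attendances = list(as.Date("2014-01-01")))
  expect_equal(time_since_last_attendance(pd, w22), 1.0, tolerance = 1e-2)

  # attendance after the reference clamps to zero with a warning
  pa <- make_patient("PA", vital = "deceased", death = as.Date("2010-01-01"),
                     attendances = list(as.Date("2012-01-01")))
  expect_warning(gap <- time_since_last_attendance(pa, w22),
                 class = "cp_negative_gap")
  expect_equal(gap, 0)

  none <- make_patient("PN", attendances = list(as.Date(character(0))))
  expect_error(time_since_last_attendance(none, w22),
               class = "cp_no_attendance")
})

test_that("lost to follow-up is strictly greater than three years", {
  end <- w22$end
  # a gap exactly equal to the threshold is retained (strict comparison);
  # whole days force the threshold to a representable value
  gap_days <- 1096
  thr <- gap_days / 365.25
  exact <- make_patient("EX", attendances = list(end - gap_days))
  expect_false(flag_lost_to_follow_up(exact, w22, threshold_years = thr))
  over <- make_patient("OV", attendances = list(end - gap_days - 1))
  expect_true(flag_lost_to_follow_up(over, w22, threshold_years = thr))
  # and at the default three-year threshold, a 2.998-year gap is retained
  expect_false(flag_lost_to_follow_up(
    make_patient("U3", attendances = list(end - 1095)), w22))

  five <- make_patient("FV", attendances = list(end - round(5 * 365.25)))
  expect_true(flag_lost_to_follow_up(five, w22))

  # deceased long ago but seen within a year of death: not lost
  dead <- make_patient("DD", vital = "deceased",
                       death = as.Date("2010-01-01"),
                       attendances = list(as.Date("2009-06-01")))
  expect_false(flag_lost_to_follow_up(dead, w22))
})

test_that("diagnosis mapping standardizes, deduplicates and flags unknowns", {
  map <- tibble::tibble(source_code = c("C01", "C02", "C03"),
                        standard_label = c("VSD", "VSD", "ASD"))
  coh <- dplyr::bind_rows(
    make_patient("P1", diagnoses = list(c("C01", "C02"))),
    make_patient("P2", diagnoses = list(c("C03", "ZZZ")))
  )
  expect_warning(got <- map_diagnoses(coh, map),
                 class = "cp_unmapped_diagnosis")
  expect_equal(got$diagnoses[[1]], "VSD")  # two codes, one label
  expect_setequal(got$diagnoses[[2]], c("ASD", "Unmapped"))
})

test_that("global filters intersect criteria and never grow the cohort", {
  conc <- tiny_concordance()
  set.seed(42)
  recs <- dplyr::bind_rows(lapply(1:20, function(i) {
    make_patient(
      paste0("P", i),
      dob = as.Date("1950-01-01") + round(runif(1, 0, 18000)),
      sex = sample(c("female", "male"), 1),
      vital = "alive",
      severity = sample(c("Simple", "Moderate", "Complex", "Unknown"), 1),
      attendances = list(as.Date("2015-01-01") + round(runif(1, 0, 2500)))
    )
  }))
  coh <- select_cohort(recs, w22, conc)$cohort

  expect_identical(apply_global_filters(coh, global_filters(), w22), coh)

  sev <- apply_global_filters(coh, global_filters(severities = "Complex"), w22)
  expect_equal(nrow(sev), sum(coh$severity == "Complex"))

  composed <- apply_global_filters(
    apply_global_filters(coh, global_filters(sexes = "female"), w22),
    global_filters(age_min = 40), w22
  )
  conj <- apply_global_filters(
    coh, global_filters(sexes = "female", age_min = 40), w22
  )
  expect_equal(composed$patient_id, conj$patient_id)
  expect_lte(nrow(conj), nrow(coh))

  expect_error(global_filters(age_min = 50, age_max = 40),
               class = "cp_invalid_filters")
})

test_that("vital-status filter removes the deceased but keeps their reference",
{
  conc <- tiny_concordance()
  recs <- dplyr::bind_rows(
    make_patient("A1x"),
    make_patient("D1x", vital = "deceased", death = as.Date("2012-01-01"),
                 attendances = list(as.Date("2011-06-01")))
  )
  coh <- select_cohort(recs, w22, conc)$cohort
  alive <- apply_global_filters(coh, global_filters(vital_statuses = "alive"),
                                w22)
  expect_equal(alive$patient_id, "A1x")
  # the deceased patient's gap is to death, short, so not lost to follow-up
  expect_false(flag_lost_to_follow_up(coh[coh$patient_id == "D1x", ], w22))
})

test_that("attendance-period filter requires a visit inside the filter window",
{
  conc <- tiny_concordance()
  recs <- dplyr::bind_rows(
    make_patient("IN", attendances = list(as.Date("2018-06-01"))),
    make_patient("OUT", attendances = list(as.Date("2021-06-01")))
  )
  coh <- select_cohort(recs, w22, conc)$cohort
  got <- apply_global_filters(
    coh, global_filters(attended_from = "2018-01-01",
                        attended_to = "2018-12-31"), w22
  )
  expect_equal(got$patient_id, "IN")
})

test_that("aggregation conserves counts and errors on unknown areas", {
  areas <- tiny_areas(4)
  conc <- tiny_concordance()
  set.seed(7)
  recs <- dplyr::bind_rows(lapply(1:20, function(i) {
    pcsb <- list(c("2000", "Sydney"), c("2200", "West"))[[sample(1:2, 1)]]
    make_patient(paste0("P", i), postcode = pcsb[1], suburb = pcsb[2],
                 severity = sample(c("Simple", "Moderate", "Complex",
                                     "Unknown"), 1),
                 attendances = list(as.Date("2010-01-01") +
                                      round(runif(1, 0, 4000))))
  }))
  coh <- select_cohort(recs, w22, conc)$cohort
  agg <- aggregate_to_areas(coh, areas, w22)

  expect_equal(nrow(agg), 4)  # zero rows for patient-free areas
  expect_equal(sum(agg$n_patients), nrow(coh))
  expect_equal(agg$n_patients,
               agg$n_simple + agg$n_moderate + agg$n_complex + agg$n_unknown)
  expect_true(all(agg$n_lost_to_follow_up <= agg$n_patients))

  # hand-tally one area
  a1 <- sum(coh$area_id == "A1")
  expect_equal(agg$n_patients[agg$area_id == "A1"], a1)

  rogue <- coh
  rogue$area_id[1] <- "ZZ"
  expect_error(aggregate_to_areas(rogue, areas, w22),
               regexp = rogue$patient_id[1], class = "cp_unknown_area")
})

test_that("cohort summary reports strata that add up and sane moments", {
  conc <- tiny_concordance()
  one <- select_cohort(
    make_patient("P1", dob = w22$end - round(40 * 365.25)), w22, conc
  )$cohort
  s1 <- summarize_cohort(one, w22)
  expect_equal(s1$age_mean[s1$stratum == "All"], 40, tolerance = 1e-3)
  expect_true(is.na(s1$age_sd[s1$stratum == "All"]))  # single patient

  set.seed(11)
  recs <- dplyr::bind_rows(lapply(1:30, function(i) {
    make_patient(paste0("P", i),
                 dob = as.Date("1960-01-01") + round(runif(1, 0, 12000)),
                 sex = sample(c("female", "male"), 1),
                 severity = sample(c("Simple", "Moderate", "Complex",
                                     "Unknown"), 1),
                 attendances = list(as.Date("2012-01-01") +
                                      round(runif(1, 0, 3600))))
  }))
  coh <- select_cohort(recs, w22, conc)$cohort
  s <- summarize_cohort(coh, w22)
  expect_equal(s$n[s$stratum == "All"],
               sum(s$n[s$stratum != "All"]))
  expect_equal(s$pct_female[s$stratum == "All"],
               100 * sum(coh$sex == "female") / nrow(coh))

  s0 <- summarize_cohort(coh[0, ], w22)
  expect_equal(s0$n[s0$stratum == "All"], 0)
  expect_true(is.na(s0$age_mean[1]))
})

test_that("selection-flow conservation holds over random contaminated cohorts",
{
  for (seed in 1:25) {
    set.seed(1000 + seed)
    cfg <- generator_config(
      seed = seed, n_areas = 16, cohort_size = 30,
      contamination = c(minors = runif(1, 0, 0.2),
                        invalid_address = runif(1, 0, 0.2),
                        no_encounter = runif(1, 0, 0.2))
    )
    areas <- generate_areas(cfg)
    coh <- generate_cohort(areas, cfg)
    f <- select_cohort(coh$patients, cfg$window, coh$concordance)$flow
    expect_equal(f$input_total,
                 f$included + f$excluded_under_18 +
                   f$excluded_no_valid_address +
                   f$excluded_no_encounter_in_window)
    expect_lte(f$included_alive, f$included)
  }
})
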