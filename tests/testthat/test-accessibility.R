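test_that("nearest clinic picks the minimum with deterministic tie-breaks", {
  ttm <- tiny_ttm(tibble::tibble(
    area_id = c("A1", "A1", "A2", "A2"),
    facility_id = c("H1", "H2", "H1", "H2"),
    hours = c(1.2, 0.9, 0.7, 0.7)
  ))
  got <- nearest_clinic_time(ttm, c("A1", "A2", "A3"), c("H1", "H2"))
  expect_equal(got$nearest_facility_id[1], "H2")
  expect_equal(got$nearest_time[1], 0.9)
  expect_equal(got$nearest_facility_id[2], "H1")  # tie: smallest id
  expect_false(got$covered[3])                    # no data: uncovered
  expect_true(is.na(got$nearest_time[3]))

  expect_error(nearest_clinic_time(ttm, "A1", character(0)),
               class = "cp_empty_clinic_set")
})

test_that("engine matches the brute-force oracle on random fixtures", {
  for (seed in 1:40) {
    fx <- random_fixture(seed, max_areas = 20, max_fac = 6)
    clinics <- sample(fx$facilities, sample(seq_along(fx$facilities), 1))
    got <- nearest_clinic_time(fx$ttm, fx$areas$area_id, clinics)
    want <- brute_force_nearest(fx$ttm, fx$areas$area_id, clinics)
    expect_equal(got$nearest_time, want$nearest_time)
    expect_equal(got$nearest_facility_id, want$nearest_facility_id)
  }
})

test_that("the worked coverage example reproduces exactly", {
  # three areas holding 2, 3 and 5 patients at 0.5, 1.2 and 2.0 hours
  areas <- tiny_areas(3, region = rep("RestOfState", 3))
  agg <- counts_aggregates(c("A1", "A2", "A3"), c(2, 3, 5))
  ttm <- tiny_ttm(tibble::tibble(area_id = c("A1", "A2", "A3"),
                                 facility_id = "H1",
                                 hours = c(0.5, 1.2, 2.0)))
  s <- accessibility_summary(agg, ttm, "H1", areas, threshold_hours = 1)
  expect_equal(s$pct_within_threshold, 20.0)
  expect_equal(s$mean_time, 1.46)
  expect_equal(s$max_time, 2.0)
})

test_that("an area at exactly the threshold is outside coverage", {
  areas <- tiny_areas(1)
  agg <- counts_aggregates("A1", 10)
  ttm <- tiny_ttm(tibble::tibble(area_id = "A1", facility_id = "H1",
                                 hours = 1.0))
  at <- accessibility_summary(agg, ttm, "H1", areas, threshold_hours = 1)
  expect_equal(at$pct_within_threshold, 0)
  just_over <- accessibility_summary(agg, ttm, "H1", areas,
                                     threshold_hours = 1 + 1e-9)
  expect_equal(just_over$pct_within_threshold, 100)
})

test_that("uncovered patients are excluded from statistics and counted", {
  areas <- tiny_areas(2)
  agg <- counts_aggregates(c("A1", "A2"), c(4, 6))
  ttm <- tiny_ttm(tibble::tibble(area_id = "A1", facility_id = "H1",
                                 hours = 0.5))
  s <- accessibility_summary(agg, ttm, "H1", areas)
  expect_equal(s$n_patients_uncovered, 6L)
  expect_equal(s$n_patients_covered, 4L)
  expect_equal(s$pct_within_threshold, 100)
  expect_equal(s$max_time, 0.5)

  none <- accessibility_summary(agg[0, ], ttm, "H1", areas)
  expect_true(is.na(none$mean_time))  # reported missing, not NaN
})

test_that("clinic reach is per-facility, strict, and non-disjoint", {
  agg <- counts_aggregates("A1", 10, n_ltf = 3)
  ttm1 <- tiny_ttm(tibble::tibble(area_id = "A1", facility_id = "H1",
                                  hours = 0.4))
  r <- clinic_reach(agg, ttm1, "H1")
  expect_equal(r$n_patients_within_threshold, 10L)
  expect_equal(r$n_ltf_within_threshold, 3L)

  ttm2 <- tiny_ttm(tibble::tibble(area_id = "A1", facility_id = "H1",
                                  hours = 1.0))
  r2 <- clinic_reach(agg, ttm2, "H1")
  expect_equal(r2$n_patients_within_threshold, 0L)

  # one area within an hour of two clinics counts in both rows
  both <- tiny_ttm(tibble::tibble(area_id = c("A1", "A1"),
                                  facility_id = c("H1", "H2"),
                                  hours = c(0.4, 0.8)))
  rr <- clinic_reach(agg, both, c("H1", "H2"))
  expect_equal(rr$n_patients_within_threshold, c(10L, 10L))

  expect_warning(r0 <- clinic_reach(agg, both, "H9"),
                 class = "cp_facility_uncovered")
  expect_equal(r0$n_patients_within_threshold, 0L)
})

test_that("candidate evaluation: empty candidates are a no-op, overlap errors",
{
  fx <- random_fixture(5)
  cur <- fx$facilities[1:2]
  cmp <- evaluate_candidates(fx$aggregates, fx$ttm, cur, character(0),
                             fx$areas)
  expect_true(all(cmp$patients_gained == 0))
  expect_true(all(cmp$delta_mean == 0 | is.na(cmp$delta_mean)))
  expect_error(
    evaluate_candidates(fx$aggregates, fx$ttm, cur, cur[1], fx$areas),
    class = "cp_clinic_overlap"
  )
})

test_that("adding a clinic inside the worst-served area strictly helps", {
  areas <- tiny_areas(3, region = rep("RestOfState", 3))
  agg <- counts_aggregates(c("A1", "A2", "A3"), c(5, 5, 5))
  ttm <- tiny_ttm(tibble::tibble(
    area_id = c("A1", "A2", "A3", "A3"),
    facility_id = c("H1", "H1", "H1", "H2"),
    hours = c(0.3, 1.5, 4.0, 0.2)
  ))
  cmp <- evaluate_candidates(agg, ttm, "H1", "H2", areas)
  all_row <- cmp[cmp$scope == "All", ]
  expect_gt(all_row$pct_after, all_row$pct_before)
  expect_lt(all_row$mean_after, all_row$mean_before)
  expect_lt(all_row$max_after, all_row$max_before)
  expect_equal(all_row$patients_gained, 5L)
})

test_that("clinic-set monotonicity holds across random fixtures", {
  for (seed in 1:30) {
    fx <- random_fixture(seed + 100, max_areas = 25, max_fac = 8)
    n_cur <- sample(seq_len(length(fx$facilities) - 1), 1)
    cur <- fx$facilities[seq_len(n_cur)]
    cand <- sample(setdiff(fx$facilities, cur),
                   sample(seq_len(length(fx$facilities) - n_cur), 1))

    before <- nearest_clinic_time(fx$ttm, fx$areas$area_id, cur)
    after <- nearest_clinic_time(fx$ttm, fx$areas$area_id, c(cur, cand))
    # pointwise: never worse, never newly uncovered
    expect_true(all(after$nearest_time <= before$nearest_time, na.rm = TRUE))
    expect_true(all(!before$covered | after$covered))

    cmp <- evaluate_candidates(fx$aggregates, fx$ttm, cur, cand, fx$areas)
    ok <- !is.na(cmp$pct_before) & !is.na(cmp$pct_after)
    expect_true(all(cmp$pct_after[ok] >= cmp$pct_before[ok]))
    okm <- !is.na(cmp$delta_mean)
    expect_true(all(cmp$delta_mean[okm] <= 1e-12))
    okx <- !is.na(cmp$delta_max)
    expect_true(all(cmp$delta_max[okx] <= 1e-12))
  }
})

test_that("per-region means combine to the overall mean over covered patients",
{
  fx <- random_fixture(321)
  clinics <- fx$facilities[1:3]
  regions <- c("GreaterSydney", "ACT", "RestOfState")
  per <- lapply(regions, function(r) {
    accessibility_summary(fx$aggregates, fx$ttm, clinics, fx$areas, scope = r)
  })
  per <- dplyr::bind_rows(per)
  all_s <- accessibility_summary(fx$aggregates, fx$ttm, clinics, fx$areas)
  covered <- per$n_patients_covered
  have <- covered > 0
  expect_equal(
    sum(per$mean_time[have] * covered[have]) / sum(covered[have]),
    all_s$mean_time,
    tolerance = 1e-12
  )
})

test_that("drive-time layer equals per-area minima and feeds the choropleth", {
  fx <- random_fixture(77, max_areas = 15, max_fac = 5)
  clinics <- fx$facilities[1:2]
  layer <- drive_time_layer(fx$areas, fx$ttm, clinics)
  want <- brute_force_nearest(fx$ttm, fx$areas$area_id, clinics)
  expect_equal(layer$nearest_time, want$nearest_time)

  txt <- write_choropleth(fx$areas,
                          tibble::tibble(area_id = layer$area_id,
                                         value = layer$nearest_time),
                          "drive_time_hours")
  got <- read_choropleth(txt, "drive_time_hours")
  expect_equal(suppressWarnings(as.numeric(got$value)), layer$nearest_time)
})
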