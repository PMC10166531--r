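# Hand-built fixtures shared across the suite. All randomized fixtures take
# an explicit seed so every test is reproducible.

`%||%` <- function(x, y) if (is.null(x)) y else x

default_window <- function() study_window("2000-01-01", "2022-07-01")

square_geom <- function(x, y, d = 1) {
  list(type = "Polygon",
       coordinates = list(list(c(x, y), c(x + d, y), c(x + d, y + d),
                               c(x, y + d), c(x, y))))
}

tiny_areas <- function(n = 4, region = NULL) {
  ids <- sprintf("A%d", seq_len(n))
  tibble::tibble(
    area_id = ids,
    name = paste("Area", seq_len(n)),
    region = region %||% rep(c("GreaterSydney", "RestOfState"),
                             length.out = n),
    remoteness = rep(c("MajorCities", "OuterRegional"), length.out = n),
    irsd_decile = rep(5L, n),
    indigenous_pct = rep(2.5, n),
    population = rep(10000L, n),
    geometry = lapply(seq_len(n) - 1, function(i) square_geom(i, 0)),
    has_geometry = TRUE,
    has_attributes = TRUE
  ) |> as_area_set()
}

tiny_ttm <- function(df) {
  as_travel_times(df)
}

# one patient record row; defaults give an included adult
make_patient <- function(id, dob = as.Date("1980-06-15"), sex = "female",
                         vital = "alive", death = as.Date(NA),
                         postcode = "2000", suburb = "Sydney",
                         severity = "Simple",
                         diagnoses = list("C01"),
                         attendances = list(as.Date("2021-05-01"))) {
  tibble::tibble(
    patient_id = id, date_of_birth = dob, sex = sex, vital_status = vital,
    date_of_death = death, postcode = postcode, suburb = suburb,
    state = "NSW", severity = severity,
    diagnoses = diagnoses, attendance_dates = attendances
  )
}

tiny_concordance <- function() {
  tibble::tibble(
    postcode = c("2000", "2100", "2100", "2200"),
    suburb = c("Sydney", "North", "North", "West"),
    area_id = c("A1", "A2", "A3", "A4"),
    weight = c(1, 0.7, 0.3, 1)
  )
}

# simple aggregates table for accessibility tests: counts only
counts_aggregates <- function(area_ids, n_patients, n_ltf = 0L) {
  n <- length(area_ids)
  tibble::tibble(
    area_id = area_ids,
    n_patients = as.integer(n_patients),
    n_simple = as.integer(n_patients), n_moderate = 0L, n_complex = 0L,
    n_unknown = 0L,
    n_lost_to_follow_up = as.integer(rep(n_ltf, length.out = n)),
    diagnoses = replicate(n, tibble::tibble(diagnosis = character(0),
                                            n = integer(0)),
                          simplify = FALSE),
    masked = FALSE
  )
}

# random fixture: areas, facilities, sparse travel matrix, aggregates
random_fixture <- function(seed, max_areas = 50, max_fac = 10) {
  set.seed(seed)
  n_a <- sample(2:max_areas, 1)
  n_f <- sample(2:max_fac, 1)
  area_ids <- sprintf("A%02d", seq_len(n_a))
  fac_ids <- sprintf("H%02d", seq_len(n_f))
  grid <- expand.grid(area_id = area_ids, facility_id = fac_ids,
                      stringsAsFactors = FALSE)
  # missingness is per area (grey areas have no driving-time data at all),
  # so the covered patient pool is stable under clinic-set growth
  grey <- area_ids[runif(n_a) < 0.15]
  keep <- !(grid$area_id %in% grey)
  ttm <- as_travel_times(tibble::tibble(
    area_id = grid$area_id[keep],
    facility_id = grid$facility_id[keep],
    hours = round(runif(sum(keep), 0, 6), 3)
  ))
  areas <- tibble::tibble(
    area_id = area_ids,
    name = area_ids,
    region = sample(c("GreaterSydney", "ACT", "RestOfState"), n_a,
                    replace = TRUE),
    remoteness = sample(c("MajorCities", "InnerRegional", "OuterRegional",
                          "Remote", "VeryRemote"), n_a, replace = TRUE),
    irsd_decile = sample(1:10, n_a, replace = TRUE),
    indigenous_pct = runif(n_a, 0, 30),
    population = sample(1000:20000, n_a),
    geometry = lapply(seq_len(n_a) - 1, function(i) square_geom(i %% 8, i %/% 8)),
    has_geometry = TRUE, has_attributes = TRUE
  ) |> as_area_set()
  n_pat <- sample(0:40, n_a, replace = TRUE)
  agg <- counts_aggregates(area_ids, n_pat,
                           n_ltf = pmin(n_pat, sample(0:10, n_a, replace = TRUE)))
  list(areas = areas, ttm = ttm, facilities = fac_ids, aggregates = agg)
}

# independent brute-force nearest-clinic oracle: plain loops over the
# travel table, no package machinery
brute_force_nearest <- function(ttm, area_ids, clinics) {
  out <- lapply(area_ids, function(aid) {
    best_t <- Inf
    best_f <- NA_character_
    for (f in sort(clinics)) {
      hit <- which(ttm$area_id == aid & ttm$facility_id == f)
      if (length(hit) == 1) {
        t <- ttm$hours[hit]
        if (t < best_t) {
          best_t <- t
          best_f <- f
        }
      }
    }
    tibble::tibble(area_id = aid,
                   nearest_facility_id = best_f,
                   nearest_time = if (is.infinite(best_t)) NA_real_ else best_t)
  })
  dplyr::bind_rows(out)
}

# matrix-based exhaustive oracle: same contract as brute_force_nearest but
# fast enough for the large sweeps; still independent of the engine's
# long-table path
oracle_nearest <- function(ttm, area_ids, clinics) {
  clinics <- sort(clinics)
  M <- matrix(NA_real_, nrow = length(area_ids), ncol = length(clinics),
              dimnames = list(area_ids, clinics))
  sub <- ttm[ttm$area_id %in% area_ids & ttm$facility_id %in% clinics, ]
  M[cbind(sub$area_id, sub$facility_id)] <- sub$hours
  t_min <- rep(NA_real_, length(area_ids))
  f_min <- rep(NA_character_, length(area_ids))
  for (i in seq_along(area_ids)) {
    row <- M[i, ]
    if (all(is.na(row))) next
    t_min[i] <- min(row, na.rm = TRUE)
    f_min[i] <- clinics[which(row == t_min[i])[1]]  # columns sorted: tie-break
  }
  tibble::tibble(area_id = area_ids, nearest_facility_id = f_min,
                 nearest_time = t_min)
}

# random aggregates with small cells for privacy tests
random_masked_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  ids <- sprintf("A%02d", seq_len(n))
  sev <- matrix(rpois(4 * n, 2.2), nrow = n)
  agg <- tibble::tibble(
    area_id = ids,
    n_patients = as.integer(rowSums(sev)),
    n_simple = as.integer(sev[, 1]), n_moderate = as.integer(sev[, 2]),
    n_complex = as.integer(sev[, 3]), n_unknown = as.integer(sev[, 4]),
    n_lost_to_follow_up = as.integer(pmin(rowSums(sev),
                                          rpois(n, 1.5))),
    diagnoses = lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      tibble::tibble(diagnosis = paste0("D", seq_len(k)),
                     n = as.integer(sample(1:8, k, replace = TRUE)))
    }),
    masked = FALSE
  )
  agg
}

write_tiny_bundle_files <- function(dir, areas) {
  write_areas_geojson(areas, file.path(dir, "areas.geojson"))
  write_area_attributes(areas, file.path(dir, "area_attributes.csv"))
}
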