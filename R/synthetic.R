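#' Configuration for the synthetic data generator
#'
#' Bundles every knob of the synthetic world: a seeded grid of square areas
#' with region blocks and distance-ranked remoteness classes, facilities at
#' area centroids, a distance-based travel-time matrix, and a patient
#' cohort whose marginal distributions default to the published summary of
#' the study population (age 43.70 (16.65) years, 49.21% female, severity
#' mix 1230/894/456/476 over Simple/Moderate/Complex/Unknown, per-severity
#' attendance means 2.29/4.27/5.86/1.9 and lost-to-follow-up fractions
#' 68.13/34.00/21.71/4.62%). The seed fully determines every output.
#'
#' @param seed Integer seed; drives all randomness.
#' @param n_areas Number of grid areas.
#' @param n_facilities Total facilities (current clinics + hospitals).
#' @param n_current_clinics How many facilities are current clinics,
#'   placed nearest the city corner.
#' @param region_mix Named fractions over the three regions (sum to 1);
#'   regions are contiguous blocks of grid indices.
#' @param remoteness_mix Fractions over the five remoteness classes (sum
#'   to 1), assigned by distance rank from the city corner.
#' @param cell_deg Grid cell size in degrees.
#' @param hours_per_cell Driving hours per cell of centroid distance.
#' @param winding Road winding factor multiplying straight-line distance.
#' @param noise_sdlog Log-sd of multiplicative lognormal travel-time noise;
#'   0 disables noise.
#' @param noise_meanlog Log-mean of the additive noise floor, hours.
#' @param min_hours Minimum travel time floor, hours.
#' @param missing_travel_frac Fraction of Remote/VeryRemote areas whose
#'   travel-time rows are dropped entirely (uncovered "grey" areas).
#' @param cohort_size Number of patient records before contamination.
#' @param deceased_frac Fraction of the cohort deceased (death dates drawn
#'   inside the window).
#' @param age_mean,age_sd Target mean/SD of age at the window end, years.
#' @param min_age Lower truncation bound for cohort ages, years.
#' @param female_frac Probability a patient is female.
#' @param severity_mix Named fractions over the four severity classes.
#' @param attendance_means Named per-severity mean attendance counts.
#' @param ltf_frac Named per-severity target lost-to-follow-up fractions.
#' @param second_diagnosis_prob Probability of a second diagnosis draw.
#' @param rural_thinning Multiplier on the placement weight of areas
#'   outside the MajorCities class (1 = purely population-proportional).
#' @param contamination Named counts-as-fractions of `cohort_size` of
#'   appended records that the selection flow must exclude: `minors`,
#'   `invalid_address`, `no_encounter`.
#' @param window The [study_window()] the cohort is generated for.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_areas = 120,
    n_facilities = 12,
    n_current_clinics = 3,
    region_mix = c(GreaterSydney = 0.15, ACT = 0.05, RestOfState = 0.80),
    remoteness_mix = c(MajorCities = 0.20, InnerRegional = 0.25,
                       OuterRegional = 0.30, Remote = 0.15,
                       VeryRemote = 0.10),
    cell_deg = 0.25,
    hours_per_cell = 0.25,
    winding = 1.3,
    noise_sdlog = 0.35,
    noise_meanlog = log(0.08),
    min_hours = 0.05,
    missing_travel_frac = 0.10,
    cohort_size = 3484,
    deceased_frac = 428 / 3484,
    age_mean = 43.70,
    age_sd = 16.65,
    min_age = 18,
    female_frac = 0.4921,
    severity_mix = c(Simple = 1230, Moderate = 894, Complex = 456,
                     Unknown = 476) / 3056,
    attendance_means = c(Simple = 2.29, Moderate = 4.27, Complex = 5.86,
                         Unknown = 1.9),
    ltf_frac = c(Simple = 0.6813, Moderate = 0.3400, Complex = 0.2171,
                 Unknown = 0.0462),
    second_diagnosis_prob = 0.25,
    rural_thinning = 0.4,
    contamination = c(minors = 0.05, invalid_address = 0.03,
                      no_encounter = 0.03),
    window = study_window("2000-01-01", "2022-07-01")) {
  check_mix <- function(x, k, what) {
    if (length(x) != k || abs(sum(x) - 1) > 1e-9) {
      cp_abort(paste0(what, " fractions must have length ", k,
                      " and sum to 1"), "cp_invalid_config")
    }
  }
  check_mix(region_mix, 3, "region")
  check_mix(remoteness_mix, 5, "remoteness")
  check_mix(severity_mix, 4, "severity")
  if (n_areas < 1 || cohort_size < 1) {
    cp_abort("n_areas and cohort_size must be at least 1", "cp_invalid_config")
  }
  structure(
    list(seed = as.integer(seed), n_areas = as.integer(n_areas),
         n_facilities = as.integer(n_facilities),
         n_current_clinics = as.integer(n_current_clinics),
         region_mix = region_mix, remoteness_mix = remoteness_mix,
         cell_deg = cell_deg, hours_per_cell = hours_per_cell,
         winding = winding, noise_sdlog = noise_sdlog,
         noise_meanlog = noise_meanlog, min_hours = min_hours,
         missing_travel_frac = missing_travel_frac,
         cohort_size = as.integer(cohort_size),
         deceased_frac = deceased_frac,
         age_mean = age_mean, age_sd = age_sd, min_age = min_age,
         female_frac = female_frac, severity_mix = severity_mix,
         attendance_means = attendance_means, ltf_frac = ltf_frac,
         second_diagnosis_prob = second_diagnosis_prob,
         rural_thinning = rural_thinning, contamination = contamination,
         window = window),
    class = "generator_config"
  )
}

# grid coordinates for area index i (0-based row/col), city corner at (0, 0)
grid_layout <- function(config) {
  n <- config$n_areas
  nc <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  tibble(
    idx = i + 1L,
    row = i %/% nc,
    col = i %% nc,
    dist_cells = sqrt((i %/% nc)^2 + (i %% nc)^2)
  )
}

# centroid lon/lat per area, recovered from the square geometry
area_centroids <- function(areas) {
  cent <- t(vapply(areas$geometry, function(g) {
    ring <- g$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring[-length(ring)], function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    colMeans(pts)
  }, numeric(2)))
  tibble(area_id = areas$area_id, lon = cent[, 1], lat = cent[, 2])
}

#' Generate a synthetic grid of areas
#'
#' A rectangular grid of square lon/lat polygons emulating small
#' statistical areas. Regions are contiguous blocks of grid indices in the
#' configured proportions; remoteness classes are assigned by distance
#' rank from the "city" corner (nearest areas are MajorCities); populations
#' decay with distance from the city so that most of the population lives
#' in the MajorCities class; disadvantage deciles are uniform; Indigenous
#' population share rises with remoteness. Deterministic under the seed.
#'
#' @param config A [generator_config()].
#' @return An `area_set` tibble with geometry.
#' @export
generate_areas <- function(config) {
  set.seed(config$seed)
  g <- grid_layout(config)
  n <- config$n_areas

  region_counts <- apportion(n, config$region_mix)
  regions <- rep(cp_regions, region_counts)

  rem_counts <- apportion(n, config$remoteness_mix)
  empty <- rem_counts == 0 & config$remoteness_mix > 0
  if (any(empty)) {
    cp_warn(paste0("remoteness class(es) dropped (round to zero areas): ",
                   paste(cp_remoteness[empty], collapse = ", ")),
            "cp_class_dropped")
  }
  remoteness <- character(n)
  remoteness[order(g$dist_cells)] <- rep(cp_remoteness, rem_counts)

  lon0 <- 141; lat0 <- -38
  geometry <- lapply(seq_len(n), function(i) {
    x <- lon0 + g$col[i] * config$cell_deg
    y <- lat0 + g$row[i] * config$cell_deg
    d <- config$cell_deg
    list(type = "Polygon",
         coordinates = list(list(c(x, y), c(x + d, y), c(x + d, y + d),
                                 c(x, y + d), c(x, y))))
  })

  indig_base <- c(MajorCities = 2, InnerRegional = 5, OuterRegional = 10,
                  Remote = 18, VeryRemote = 30)
  areas <- tibble(
    area_id = sprintf("A%03d", g$idx),
    name = sprintf("Area %03d", g$idx),
    region = regions,
    remoteness = remoteness,
    irsd_decile = sample(1:10, n, replace = TRUE),
    indigenous_pct = pmin(100, indig_base[remoteness] *
                            rlnorm(n, 0, 0.4)),
    population = as.integer(round(pmax(
      200, (1500 + 25000 * exp(-g$dist_cells / 2.2)) * rlnorm(n, 0, 0.2)
    ))),
    geometry = geometry,
    has_geometry = TRUE,
    has_attributes = TRUE
  )
  as_area_set(areas)
}

#' Generate facilities at area centroids
#'
#' Current clinics occupy the areas nearest the city corner; the remaining
#' facilities are hospitals (potential candidate sites) spread evenly over
#' the distance ranks so that rural blocks also contain candidate sites.
#'
#' @param areas Output of [generate_areas()].
#' @param config A [generator_config()].
#' @return A facility tibble (`facility_id,name,lon,lat,role`).
#' @export
generate_facilities <- function(areas, config) {
  cent <- area_centroids(areas)
  corner <- c(min(cent$lon), min(cent$lat))
  d <- sqrt((cent$lon - corner[1])^2 + (cent$lat - corner[2])^2)
  ord <- order(d, cent$area_id)
  n_cur <- config$n_current_clinics
  n_hosp <- config$n_facilities - n_cur
  cur_idx <- ord[seq_len(n_cur)]
  # hospitals at evenly spaced distance ranks over the remaining areas
  rest <- setdiff(ord, cur_idx)
  hosp_idx <- rest[unique(round(seq(1, length(rest), length.out = n_hosp)))]
  idx <- c(cur_idx, hosp_idx)
  tibble(
    facility_id = sprintf("H%02d", seq_along(idx)),
    name = paste0("Hospital at ", areas$name[idx]),
    lon = cent$lon[idx],
    lat = cent$lat[idx],
    role = c(rep("current_clinic", n_cur), rep("hospital", length(hosp_idx)))
  )
}

#' Generate a travel-time matrix
#'
#' Driving time is straight-line centroid distance (in grid cells) times a
#' road winding factor times hours-per-cell, plus a lognormal noise floor,
#' bounded below by `min_hours`. With `noise_sdlog = 0` the time is purely
#' linear in distance. A configured fraction of Remote/VeryRemote areas
#' lose all their rows, emulating areas with no driving-time data.
#' Deterministic under the seed.
#'
#' @param areas Output of [generate_areas()].
#' @param facilities Output of [generate_facilities()].
#' @param config A [generator_config()].
#' @return A `travel_times` tibble.
#' @export
generate_travel_matrix <- function(areas, facilities, config) {
  set.seed(config$seed + 1L)
  cent <- area_centroids(areas)
  grid <- tidyr::expand_grid(area_id = cent$area_id,
                             facility_id = facilities$facility_id)
  grid <- left_join(grid, cent, by = "area_id")
  grid <- left_join(grid,
                    dplyr::select(facilities, "facility_id",
                                  flon = "lon", flat = "lat"),
                    by = "facility_id")
  dist_cells <- sqrt((grid$lon - grid$flon)^2 +
                       (grid$lat - grid$flat)^2) / config$cell_deg
  base <- dist_cells * config$winding * config$hours_per_cell
  noise <- if (config$noise_sdlog > 0) {
    rlnorm(nrow(grid), config$noise_meanlog, config$noise_sdlog)
  } else {
    0
  }
  hours <- pmax(base + noise, if (config$noise_sdlog > 0) config$min_hours else base)

  remote_ids <- areas$area_id[areas$remoteness %in% c("Remote", "VeryRemote")]
  n_drop <- round(config$missing_travel_frac * length(remote_ids))
  drop_ids <- if (n_drop > 0) sort(sample(remote_ids, n_drop)) else character(0)

  out <- tibble(area_id = grid$area_id, facility_id = grid$facility_id,
                hours = hours)
  out <- out[!(out$area_id %in% drop_ids), , drop = FALSE]
  as_travel_times(out)
}

# latent (mu, sigma) of a normal left-truncated at `lower` whose truncated
# mean/sd equal the targets; memoized, the solve is deterministic
.tn_cache <- new.env(parent = emptyenv())

trunc_normal_params <- function(mean, sd, lower) {
  key <- paste(mean, sd, lower, sep = "|")
  hit <- .tn_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- trunc_normal_solve(mean, sd, lower)
  .tn_cache[[key]] <- out
  out
}

trunc_normal_solve <- function(mean, sd, lower) {
  moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    ms <- moments(par[1], exp(par[2]))
    (ms[1] - mean)^2 + (ms[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc_normal <- function(n, mu, sigma, lower) {
  p0 <- pnorm((lower - mu) / sigma)
  mu + sigma * stats::qnorm(runif(n, p0, 1))
}

# per-severity diagnosis label distributions (fractions of stratum N for the
# five most common defects, remainder pooled as Other)
diagnosis_probs <- function() {
  labels <- c("Bicuspid Aortic Valve", "Ventricular Septal Defect",
              "Atrial Septal Defect", "Tetralogy of Fallot",
              "Patent Foramen Ovale", "Other CHD")
  p <- rbind(
    Simple   = c(35.12, 15.04, 24.15, 0.08, 15.20, NA),
    Moderate = c(17.33, 13.87, 12.08, 30.76, 3.91, NA),
    Complex  = c(1.32, 47.81, 14.25, 6.14, 3.51, NA),
    Unknown  = c(10.08, 18.45, 15.75, 7.98, 1.45, NA)
  ) / 100
  p[, 6] <- pmax(0, 1 - rowSums(p[, 1:5]))
  colnames(p) <- labels
  p
}

synthetic_diagnosis_map <- function() {
  labels <- colnames(diagnosis_probs())
  tibble(source_code = sprintf("IH%02d", seq_along(labels)),
         standard_label = labels)
}

#' Generate a synthetic patient cohort and concordance
#'
#' Draws `cohort_size` patients with the configured marginal structure:
#' calibrated truncated-normal ages (so the realized truncated mean/SD hit
#' the configured targets despite the adult lower bound), Bernoulli sex,
#' multinomial severity, per-severity attendance counts of
#' `1 + Poisson(mean - 1)` (every patient attends at least once), and a
#' two-component gap mixture — recent gaps uniform on [0, 3) years, lost
#' gaps uniform on (3, 15] — mixed at the per-severity lost-to-follow-up
#' target, referenced to the death date for deceased patients. Patients are
#' placed into areas with probability proportional to population, rural
#' areas down-weighted by `rural_thinning`. Contamination records (minors,
#' unmappable postcodes, attendances outside the window) are appended to
#' exercise the selection flow; each contaminated record violates exactly
#' one rule. Deterministic under the seed.
#'
#' @param areas Output of [generate_areas()].
#' @param config A [generator_config()].
#' @return A list: `patients` (raw records), `concordance`,
#'   `diagnosis_map`.
#' @export
generate_cohort <- function(areas, config) {
  set.seed(config$seed + 2L)
  w <- config$window
  n <- config$cohort_size

  concordance <- tibble(
    postcode = sprintf("2%03d", seq_len(nrow(areas))),
    suburb = areas$name,
    area_id = areas$area_id,
    weight = 1
  )
  dmap <- synthetic_diagnosis_map()
  dprob <- diagnosis_probs()
  label_to_code <- setNames(dmap$source_code, dmap$standard_label)

  place_weight <- areas$population *
    ifelse(areas$remoteness == "MajorCities", 1, config$rural_thinning)

  draw_block <- function(nn, age_range = NULL, bad_address = FALSE,
                         pre_window = FALSE) {
    sev <- sample(cp_severities, nn, replace = TRUE,
                  prob = config$severity_mix)
    sex <- ifelse(runif(nn) < config$female_frac, "female", "male")
    age <- if (is.null(age_range)) {
      tp <- trunc_normal_params(config$age_mean, config$age_sd,
                                config$min_age)
      rtrunc_normal(nn, tp$mu, tp$sigma, config$min_age)
    } else {
      runif(nn, age_range[1], age_range[2])
    }
    # ceiling keeps the realized age at or above the drawn age, so an
    # adult draw can never fall under the age cutoff through rounding
    dob <- w$end - ceiling(age * days_per_year)
    deceased <- runif(nn) < config$deceased_frac & !pre_window
    death <- as.Date(ifelse(
      deceased,
      w$end - round(runif(nn, 0, 8) * days_per_year),
      NA_real_
    ), origin = "1970-01-01")
    ref <- as.Date(ifelse(deceased, as.numeric(death), as.numeric(w$end)),
                   origin = "1970-01-01")

    lost <- runif(nn) < config$ltf_frac[sev]
    gap <- ifelse(lost, runif(nn, 3, 15), runif(nn, 0, 3))
    k <- 1L + rpois(nn, pmax(config$attendance_means[sev] - 1, 0))

    area_idx <- sample.int(nrow(areas), nn, replace = TRUE,
                           prob = place_weight)
    attendances <- lapply(seq_len(nn), function(i) {
      if (pre_window) {
        last <- w$start - round(runif(1, 200, 1800))
        first <- last - 3650
      } else {
        last <- max(ref[i] - round(gap[i] * days_per_year), w$start,
                    dob[i] + 1)
        first <- max(w$start, dob[i] + 1)
      }
      extra <- if (k[i] > 1) {
        first + round(runif(k[i] - 1, 0, max(as.numeric(last - first), 0)))
      } else {
        as.Date(character(0))
      }
      sort(c(extra, last))
    })
    diagnoses <- lapply(seq_len(nn), function(i) {
      p <- dprob[sev[i], ]
      lab <- sample(colnames(dprob), 1, prob = p)
      if (runif(1) < config$second_diagnosis_prob) {
        lab <- c(lab, sample(colnames(dprob), 1, prob = p))
      }
      unname(label_to_code[unique(lab)])
    })
    tibble(
      date_of_birth = dob,
      sex = sex,
      vital_status = ifelse(deceased, "deceased", "alive"),
      date_of_death = death,
      postcode = if (bad_address) "0000" else concordance$postcode[area_idx],
      suburb = if (bad_address) "Nowhere" else concordance$suburb[area_idx],
      state = "NSW",
      severity = sev,
      diagnoses = diagnoses,
      attendance_dates = attendances
    )
  }

  main <- draw_block(n)
  contam <- round(config$contamination * n)
  minors <- if (contam[["minors"]] > 0) {
    draw_block(contam[["minors"]], age_range = c(5, 17.5))
  }
  invalid <- if (contam[["invalid_address"]] > 0) {
    draw_block(contam[["invalid_address"]], bad_address = TRUE)
  }
  noenc <- if (contam[["no_encounter"]] > 0) {
    draw_block(contam[["no_encounter"]], pre_window = TRUE)
  }
  patients <- dplyr::bind_rows(main, minors, invalid, noenc)
  patients <- dplyr::mutate(patients,
                            patient_id = sprintf("P%05d", row_number()),
                            .before = 1)
  list(patients = as_patients(patients), concordance = concordance,
       diagnosis_map = dmap)
}

#' Write area geometry as GeoJSON
#'
#' @param areas An `area_set` with geometry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_areas_geojson <- function(areas, path) {
  features <- lapply(seq_len(nrow(areas)), function(i) {
    list(type = "Feature",
         geometry = areas$geometry[[i]],
         properties = list(area_id = areas$area_id[i],
                           name = areas$name[i]))
  })
  txt <- jsonlite::toJSON(list(type = "FeatureCollection",
                               features = features),
                          auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(txt, path)
  invisible(path)
}

#' Write area attributes as CSV
#'
#' @param areas An `area_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_attributes <- function(areas, path) {
  readr::write_csv(
    as_tibble(areas)[, c("area_id", "name", "region", "remoteness",
                         "irsd_decile", "indigenous_pct", "population")],
    path, na = ""
  )
  invisible(path)
}

#' Simulate a complete input bundle
#'
#' Generates areas, facilities, travel times, patients, concordance and
#' diagnosis map, and writes them to `dir` in the package's standard file
#' dialects, together with a `config.yaml` echo of the generator
#' configuration for provenance. Identical configurations produce
#' byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file `paths`.
#' @export
simulate_bundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  areas <- generate_areas(config)
  facilities <- generate_facilities(areas, config)
  ttm <- generate_travel_matrix(areas, facilities, config)
  coh <- generate_cohort(areas, config)

  paths <- list(
    areas_geojson = file.path(dir, "areas.geojson"),
    area_attributes = file.path(dir, "area_attributes.csv"),
    facilities = file.path(dir, "facilities.csv"),
    travel_times = file.path(dir, "travel_times.csv"),
    patients = file.path(dir, "patients.csv"),
    concordance = file.path(dir, "concordance.csv"),
    diagnosis_map = file.path(dir, "diagnosis_map.csv"),
    config = file.path(dir, "config.yaml")
  )
  write_areas_geojson(areas, paths$areas_geojson)
  write_area_attributes(areas, paths$area_attributes)
  readr::write_csv(facilities, paths$facilities)
  readr::write_csv(as_tibble(ttm), paths$travel_times)
  write_patients(coh$patients, paths$patients)
  readr::write_csv(coh$concordance, paths$concordance)
  readr::write_csv(coh$diagnosis_map, paths$diagnosis_map)

  cfg <- unclass(config)
  cfg$window <- list(start = format(config$window$start),
                     end = format(config$window$end))
  yaml::write_yaml(cfg, paths$config)

  invisible(list(areas = areas, facilities = facilities, ttm = ttm,
                 patients = coh$patients, concordance = coh$concordance,
                 diagnosis_map = coh$diagnosis_map, config = config,
                 paths = paths))
}

#' Load an input bundle from disk
#'
#' Reads the files written by [simulate_bundle()] (or real inputs in the
#' same dialects) back into validated objects.
#'
#' @param dir Directory holding the bundle.
#' @return A list: `areas`, `facilities`, `ttm`, `patients`, `concordance`,
#'   `diagnosis_map`, `window`.
#' @export
read_bundle <- function(dir) {
  window <- study_window("2000-01-01", "2022-07-01")
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    if (!is.null(cfg$window)) {
      window <- study_window(cfg$window$start, cfg$window$end)
    }
  }
  list(
    areas = read_areas(file.path(dir, "areas.geojson"),
                       file.path(dir, "area_attributes.csv")),
    facilities = read_facilities(file.path(dir, "facilities.csv")),
    ttm = read_travel_matrix(file.path(dir, "travel_times.csv")),
    patients = read_patients(file.path(dir, "patients.csv")),
    concordance = read_concordance(file.path(dir, "concordance.csv")),
    diagnosis_map = read_diagnosis_map(file.path(dir, "diagnosis_map.csv")),
    window = window
  )
}
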