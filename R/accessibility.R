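#' Nearest open clinic for each area
#'
#' For each requested area, the minimum stored driving time over the clinic
#' set, with ties broken by the lexicographically smallest facility id. An
#' area with no travel-time entry for any clinic in the set is uncovered:
#' `nearest_time` is `NA` and `covered` is `FALSE`. Missing data is never
#' imputed.
#'
#' @param ttm A `travel_times` tibble.
#' @param area_ids Character vector of areas to evaluate.
#' @param clinics Non-empty character vector of open facility ids.
#' @return A tibble `area_id`, `nearest_facility_id`, `nearest_time`,
#'   `covered`, one row per requested area in input order.
#' @export
nearest_clinic_time <- function(ttm, area_ids, clinics) {
  if (length(clinics) == 0) {
    cp_abort("clinic set is empty", "cp_empty_clinic_set")
  }
  keep <- ttm$facility_id %in% clinics & ttm$area_id %in% area_ids
  a <- ttm$area_id[keep]
  f <- ttm$facility_id[keep]
  h <- ttm$hours[keep]
  # order by time then facility_id so the first row per area is the
  # tie-broken minimum
  o <- order(a, h, f)
  first <- o[!duplicated(a[o])]
  hit <- match(as.character(area_ids), a[first])
  res <- tibble(
    area_id = as.character(area_ids),
    nearest_facility_id = f[first][hit],
    nearest_time = h[first][hit]
  )
  res$covered <- !is.na(res$nearest_time)
  res
}

#' Drive-time choropleth layer
#'
#' [nearest_clinic_time()] over every area in the area set; the standard
#' input for the "driving time to nearest clinic" map overlay. Uncovered
#' areas (no travel-time data for any open clinic) are flagged rather than
#' given a number.
#'
#' @param areas The area set.
#' @param ttm A `travel_times` tibble.
#' @param clinics Non-empty character vector of open facility ids.
#' @return A tibble of class `drive_time_layer`.
#' @export
drive_time_layer <- function(areas, ttm, clinics) {
  out <- nearest_clinic_time(ttm, areas$area_id, clinics)
  class(out) <- unique(c("drive_time_layer", class(out)))
  out
}

scope_area_ids <- function(areas, scope) {
  if (scope == "All") return(areas$area_id)
  if (!scope %in% cp_regions) {
    cp_abort(paste0("unknown scope: ", scope), "cp_invalid_scope")
  }
  areas$area_id[!is.na(areas$region) & areas$region == scope]
}

#' Patient-weighted accessibility summary
#'
#' Every patient inherits the nearest-clinic driving time of their area;
#' the summary then reports, over patients in scope living in covered
#' areas: the percentage strictly within the threshold ("within a 1-hour
#' drive" means `time < threshold`, so an area at exactly the threshold is
#' outside), the patient-weighted mean time, and the maximum time over
#' areas containing at least one in-scope patient. Patients in uncovered
#' areas are excluded from those three statistics and reported separately
#' as `n_patients_uncovered`.
#'
#' @param aggregates Per-area counts from [aggregate_to_areas()].
#' @param ttm A `travel_times` tibble.
#' @param clinics Non-empty character vector of open facility ids.
#' @param areas The area set (supplies regions for scoping).
#' @param threshold_hours Coverage threshold, hours (> 0; default 1).
#' @param scope `"All"` or one of the region names.
#' @return A one-row tibble of class `accessibility_summary`: `scope`,
#'   `threshold_hours`, `n_patients_in_scope`, `n_patients_covered`,
#'   `n_patients_uncovered`, `n_within_threshold`, `pct_within_threshold`,
#'   `mean_time`, `max_time`. With zero covered patients in scope the three
#'   statistics are reported missing (`NA`), not `NaN`.
#' @export
accessibility_summary <- function(aggregates, ttm, clinics, areas,
                                  threshold_hours = 1, scope = "All") {
  if (threshold_hours <= 0) {
    cp_abort("threshold_hours must be positive", "cp_invalid_threshold")
  }
  ids <- scope_area_ids(areas, scope)
  agg <- aggregates[aggregates$area_id %in% ids, , drop = FALSE]
  acc <- nearest_clinic_time(ttm, agg$area_id, clinics)
  d <- left_join(as_tibble(agg)[, c("area_id", "n_patients")], acc,
                 by = "area_id")
  n_scope <- sum(d$n_patients)
  cov <- d[d$covered, , drop = FALSE]
  n_cov <- sum(cov$n_patients)
  n_unc <- n_scope - n_cov
  if (n_cov == 0) {
    out <- tibble(scope = scope, threshold_hours = threshold_hours,
                  n_patients_in_scope = n_scope, n_patients_covered = 0L,
                  n_patients_uncovered = n_unc, n_within_threshold = 0L,
                  pct_within_threshold = NA_real_, mean_time = NA_real_,
                  max_time = NA_real_)
  } else {
    n_within <- sum(cov$n_patients[cov$nearest_time < threshold_hours])
    out <- tibble(
      scope = scope,
      threshold_hours = threshold_hours,
      n_patients_in_scope = as.integer(n_scope),
      n_patients_covered = as.integer(n_cov),
      n_patients_uncovered = as.integer(n_unc),
      n_within_threshold = as.integer(n_within),
      pct_within_threshold = 100 * n_within / n_cov,
      mean_time = weighted.mean(cov$nearest_time, cov$n_patients),
      # n_cov > 0 guarantees at least one covered area holds a patient
      max_time = max(cov$nearest_time[cov$n_patients > 0])
    )
  }
  class(out) <- unique(c("accessibility_summary", class(out)))
  out
}

#' Per-clinic reach table
#'
#' For each facility, the number of patients (and of lost-to-follow-up
#' patients) living in areas whose *direct* driving time to that facility is
#' strictly under the threshold. Reach is independent of other clinics, so
#' rows are deliberately not disjoint: a patient within an hour of two
#' clinics counts in both rows. A facility with no travel-time column gets
#' a zero row with a warning.
#'
#' @param aggregates Per-area counts from [aggregate_to_areas()].
#' @param ttm A `travel_times` tibble.
#' @param facility_ids Facilities to tabulate.
#' @param threshold_hours Reach threshold, hours (default 1).
#' @return A tibble `facility_id`, `n_patients_within_threshold`,
#'   `n_ltf_within_threshold`, one row per facility in input order.
#' @export
clinic_reach <- function(aggregates, ttm, facility_ids, threshold_hours = 1) {
  rows <- lapply(facility_ids, function(fid) {
    col <- ttm[ttm$facility_id == fid, , drop = FALSE]
    if (nrow(col) == 0) {
      cp_warn(paste0("facility ", fid, " has no travel-time data"),
              "cp_facility_uncovered")
      return(tibble(facility_id = fid, n_patients_within_threshold = 0L,
                    n_ltf_within_threshold = 0L))
    }
    near <- col$area_id[col$hours < threshold_hours]
    agg <- aggregates[aggregates$area_id %in% near, , drop = FALSE]
    tibble(
      facility_id = fid,
      n_patients_within_threshold = as.integer(sum(agg$n_patients)),
      n_ltf_within_threshold = as.integer(sum(agg$n_lost_to_follow_up))
    )
  })
  dplyr::bind_rows(rows)
}

#' Compare accessibility before and after adding candidate clinics
#'
#' Computes [accessibility_summary()] per scope (All plus each region) for
#' the current clinic set and for current plus candidates, and the deltas:
#' patients newly within the threshold, change in mean and in maximum
#' drive time. Adding clinics can only shrink nearest times, so per scope
#' the percentage within threshold never decreases and mean/max never
#' increase.
#'
#' @param aggregates Per-area counts from [aggregate_to_areas()].
#' @param ttm A `travel_times` tibble.
#' @param current,candidates Facility id vectors; must be disjoint.
#' @param areas The area set.
#' @param threshold_hours Coverage threshold, hours.
#' @param scopes Scopes to evaluate (default All plus every region).
#' @return A tibble of class `candidate_comparison`, one row per scope,
#'   with `pct_before/pct_after`, `n_within_before/n_within_after`,
#'   `patients_gained`, `mean_before/mean_after/delta_mean`,
#'   `max_before/max_after/delta_max`.
#' @export
evaluate_candidates <- function(aggregates, ttm, current, candidates, areas,
                                threshold_hours = 1,
                                scopes = c("All", cp_regions)) {
  overlap <- intersect(current, candidates)
  if (length(overlap)) {
    cp_abort(paste0("candidate clinics overlap current clinics: ",
                    paste(overlap, collapse = ", ")), "cp_clinic_overlap")
  }
  combined <- c(current, candidates)
  rows <- lapply(scopes, function(sc) {
    before <- accessibility_summary(aggregates, ttm, current, areas,
                                    threshold_hours, sc)
    after <- accessibility_summary(aggregates, ttm, combined, areas,
                                   threshold_hours, sc)
    tibble(
      scope = sc,
      n_patients_in_scope = before$n_patients_in_scope,
      pct_before = before$pct_within_threshold,
      pct_after = after$pct_within_threshold,
      n_within_before = before$n_within_threshold,
      n_within_after = after$n_within_threshold,
      patients_gained = after$n_within_threshold - before$n_within_threshold,
      mean_before = before$mean_time,
      mean_after = after$mean_time,
      delta_mean = after$mean_time - before$mean_time,
      max_before = before$max_time,
      max_after = after$max_time,
      delta_max = after$max_time - before$max_time
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold_hours") <- threshold_hours
  attr(out, "current") <- current
  attr(out, "candidates") <- candidates
  class(out) <- unique(c("candidate_comparison", class(out)))
  out
}

#' @export
tidy.candidate_comparison <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-c("scope", "n_patients_in_scope"),
                        names_to = "statistic", values_to = "value")
}

#' @export
glance.candidate_comparison <- function(x, ...) {
  as_tibble(x[x$scope == "All", , drop = FALSE])
}
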