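#' Candidate sites nearest the worst-served patients
#'
#' A convenience for what-if demonstrations: finds the in-scope covered area
#' with at least one patient whose nearest-clinic time is currently largest,
#' then returns the `n` non-clinic facilities closest to that area by
#' travel time. Placing clinics there is the manual "pick hospitals in the
#' worst-served block" workflow; it is a heuristic for scenario building,
#' not an optimal facility-location search.
#'
#' @param aggregates Per-area counts from [aggregate_to_areas()].
#' @param ttm A `travel_times` tibble.
#' @param facilities Facility tibble.
#' @param current Current clinic ids.
#' @param areas The area set.
#' @param n How many candidate sites to return.
#' @param scope Region to target (default `"RestOfState"`).
#' @return Character vector of up to `n` facility ids, disjoint from
#'   `current`.
#' @export
worst_served_candidates <- function(aggregates, ttm, facilities, current,
                                    areas, n = 3, scope = "RestOfState") {
  ids <- scope_area_ids(areas, scope)
  agg <- aggregates[aggregates$area_id %in% ids & aggregates$n_patients > 0, ,
                    drop = FALSE]
  acc <- nearest_clinic_time(ttm, agg$area_id, current)
  acc <- acc[acc$covered, , drop = FALSE]
  if (nrow(acc) == 0) {
    cp_abort("no covered in-scope area with patients", "cp_invalid_scope")
  }
  worst <- acc$area_id[which.max(acc$nearest_time)]
  pool <- setdiff(facilities$facility_id, current)
  t_to_worst <- travel_time(ttm, rep(worst, length(pool)), pool)
  ord <- order(t_to_worst, pool, na.last = TRUE)
  utils::head(pool[ord], n)
}
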