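#' Validate and class a long-format travel-time table
#'
#' The origin-destination matrix is stored long: one row per known
#' (area, facility) pair with the driving time in hours. Missingness is
#' meaningful — a pair with no row has *no data*, which is distinct from a
#' time of zero, and an area with no row for any facility is "uncovered"
#' (the grey areas on a drive-time map). Times are never imputed.
#'
#' @param ttm A data frame with columns `area_id`, `facility_id`, `hours`.
#' @return The input as a tibble with class `travel_times`.
#' @export
as_travel_times <- function(ttm) {
  ttm <- as_tibble(ttm)
  need <- c("area_id", "facility_id", "hours")
  if (!all(need %in% names(ttm))) {
    cp_abort("travel matrix needs columns area_id, facility_id, hours",
             "cp_invalid_travel")
  }
  ttm$area_id <- as.character(ttm$area_id)
  ttm$facility_id <- as.character(ttm$facility_id)
  if (any(is.na(ttm$hours))) {
    cp_abort("travel matrix hours must not be NA (omit the row instead)",
             "cp_invalid_travel")
  }
  if (any(ttm$hours < 0)) {
    cp_abort("negative driving time in travel matrix", "cp_negative_time")
  }
  key <- paste(ttm$area_id, ttm$facility_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    cp_abort(paste0("duplicate (area_id, facility_id) pair: ",
                    gsub("\r", ", ", dup)), "cp_duplicate_travel_pair")
  }
  class(ttm) <- unique(c("travel_times", class(ttm)))
  ttm
}

#' Read an origin-destination driving-time matrix
#'
#' Long-format CSV with header `area_id,facility_id,hours`. Ids are kept as
#' opaque strings; cross-validation against the area set and facility list
#' happens where the matrix is used.
#'
#' @param csv_path Path to the CSV.
#' @return A `travel_times` tibble (see [as_travel_times()]).
#' @export
read_travel_matrix <- function(csv_path) {
  ttm <- readr::read_csv(
    csv_path,
    col_types = readr::cols(
      area_id = readr::col_character(),
      facility_id = readr::col_character(),
      hours = readr::col_double()
    ),
    progress = FALSE
  )
  as_travel_times(ttm)
}

#' Look up driving times for (area, facility) pairs
#'
#' Total lookup: returns the stored time for each requested pair, or `NA`
#' when the pair has no data. `NA` here means "absent", never zero and never
#' a default.
#'
#' @param ttm A `travel_times` tibble.
#' @param area_id,facility_id Vectors of equal length (or length 1, recycled).
#' @return Numeric hours with `NA` for absent pairs.
#' @export
travel_time <- function(ttm, area_id, facility_id) {
  q <- tibble(area_id = as.character(area_id),
              facility_id = as.character(facility_id))
  res <- left_join(q, ttm, by = c("area_id", "facility_id"))
  res$hours
}

#' Areas with no travel-time data for any facility
#'
#' @param ttm A `travel_times` tibble.
#' @param areas An area set; areas absent from the matrix entirely are
#'   uncovered.
#' @return Character vector of uncovered `area_id`s.
#' @export
uncovered_areas <- function(ttm, areas) {
  setdiff(areas$area_id, unique(ttm$area_id))
}
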