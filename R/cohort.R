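#' Age in decimal years at a reference date
#'
#' @param date_of_birth,ref `Date` vectors.
#' @return Numeric years (365.25 days/year).
#' @export
age_at <- function(date_of_birth, ref) {
  years_between(date_of_birth, ref)
}

#' Age in completed years at a reference date
#'
#' Calendar-exact age: the number of birthdays reached by `ref`. Someone
#' born exactly 18 years before `ref` is 18 on that day. (A 29 February
#' birthday counts from 1 March in non-leap years.) This is the convention
#' used for the adult cutoff and the age filter; summary statistics use the
#' decimal [age_at()].
#'
#' @inheritParams age_at
#' @return Integer vector of completed years.
#' @export
completed_years <- function(date_of_birth, ref) {
  y <- as.integer(format(ref, "%Y")) - as.integer(format(date_of_birth, "%Y"))
  not_reached <- format(ref, "%m%d") < format(date_of_birth, "%m%d")
  as.integer(y - not_reached)
}

#' Link patients to areas through a postcode/suburb concordance
#'
#' Resolution rules, applied per patient:
#' an exact (postcode, suburb) match wins; when several concordance rows
#' match, the highest-weight row wins with ties broken by the
#' lexicographically smallest `area_id` (the ambiguity is logged as a
#' warning for audit); when the patient's suburb is missing, any row with
#' the patient's postcode is eligible (postcode-only fallback); otherwise
#' the patient is unresolved (`NA`), which is a value, not an error —
#' cohort selection treats it as an invalid address.
#'
#' @param patients Patient tibble with `postcode` and `suburb`.
#' @param concordance Concordance tibble (`postcode,suburb,area_id,weight`).
#' @param quiet Suppress the ambiguity warning.
#' @return Character vector of `area_id`s aligned with `patients` rows, `NA`
#'   where unresolved.
#' @export
link_area <- function(patients, concordance, quiet = FALSE) {
  conc <- dplyr::arrange(concordance, dplyr::desc(.data$weight), .data$area_id)
  ambiguous <- character(0)
  out <- vapply(seq_len(nrow(patients)), function(i) {
    pc <- patients$postcode[i]
    sb <- patients$suburb[i]
    if (is.na(pc)) return(NA_character_)
    rows <- if (is.na(sb)) {
      conc[conc$postcode == pc, ]
    } else {
      conc[conc$postcode == pc & !is.na(conc$suburb) & conc$suburb == sb, ]
    }
    if (nrow(rows) == 0) return(NA_character_)
    if (nrow(rows) > 1) {
      ambiguous <<- c(ambiguous, paste0(pc, "/", if (is.na(sb)) "" else sb))
    }
    rows$area_id[1]
  }, character(1))
  if (length(ambiguous) && !quiet) {
    cp_warn(paste0("ambiguous concordance match resolved by weight for: ",
                   paste(unique(ambiguous), collapse = ", ")),
            "cp_ambiguous_linkage")
  }
  out
}

#' Select the study cohort and record the selection flow
#'
#' Applies the selection flow to raw patient records: keep patients who are
#' (a) at least 18 years old at the end of the study window, (b) resolvable
#' to an in-scope area through the concordance, and (c) attended at least
#' once inside the window. Each excluded patient is counted at the *first*
#' stage that removes them, in the fixed order age, then address, then
#' encounter.
#'
#' @param records Patient tibble ([read_patients()]).
#' @param window A [study_window()].
#' @param concordance Concordance tibble.
#' @return A list with `cohort` (included patients, plus resolved `area_id`
#'   and `age_years` at the window end) and `flow`, a `selection_flow`
#'   object whose counts satisfy
#'   `input_total = included + sum(exclusions)`.
#' @export
select_cohort <- function(records, window, concordance) {
  if (!inherits(window, "study_window")) {
    cp_abort("window must be a study_window", "cp_invalid_window")
  }
  records <- as_patients(records)
  n_in <- nrow(records)
  if (n_in == 0) {
    flow <- new_selection_flow(0L, 0L, 0L, 0L, 0L, 0L)
    cohort <- dplyr::mutate(records, area_id = character(0),
                            age_years = numeric(0))
    return(list(cohort = cohort, flow = flow))
  }

  age <- age_at(records$date_of_birth, window$end)
  is_minor <- completed_years(records$date_of_birth, window$end) < 18
  area_id <- link_area(records, concordance, quiet = TRUE)
  bad_address <- is.na(area_id)
  has_encounter <- vapply(records$attendance_dates, function(d) {
    any(d >= window$start & d <= window$end)
  }, logical(1))

  # first-match exclusion in the declared order
  stage <- rep("included", n_in)
  stage[!has_encounter] <- "encounter"
  stage[bad_address] <- "address"
  stage[is_minor] <- "age"

  keep <- stage == "included"
  cohort <- records[keep, , drop = FALSE]
  cohort$area_id <- area_id[keep]
  cohort$age_years <- age[keep]

  flow <- new_selection_flow(
    input_total = n_in,
    excluded_under_18 = sum(stage == "age"),
    excluded_no_valid_address = sum(stage == "address"),
    excluded_no_encounter_in_window = sum(stage == "encounter"),
    included = sum(keep),
    included_alive = sum(keep & records$vital_status == "alive")
  )
  list(cohort = cohort, flow = flow)
}

new_selection_flow <- function(input_total, excluded_under_18,
                               excluded_no_valid_address,
                               excluded_no_encounter_in_window,
                               included, included_alive) {
  structure(
    list(
      input_total = as.integer(input_total),
      excluded_under_18 = as.integer(excluded_under_18),
      excluded_no_valid_address = as.integer(excluded_no_valid_address),
      excluded_no_encounter_in_window =
        as.integer(excluded_no_encounter_in_window),
      included = as.integer(included),
      included_alive = as.integer(included_alive)
    ),
    class = "selection_flow"
  )
}

#' @export
print.selection_flow <- function(x, ...) {
  cat("Patient selection flow\n")
  cat("  input:                    ", x$input_total, "\n")
  cat("  excluded, under 18:       ", x$excluded_under_18, "\n")
  cat("  excluded, invalid address:", x$excluded_no_valid_address, "\n")
  cat("  excluded, no encounter:   ", x$excluded_no_encounter_in_window, "\n")
  cat("  included:                 ", x$included, "\n")
  cat("  included and alive:       ", x$included_alive, "\n")
  invisible(x)
}

#' @export
tidy.selection_flow <- function(x, ...) {
  tibble(stage = names(unclass(x)), count = unlist(unclass(x), use.names = FALSE))
}

#' Years since last clinic attendance
#'
#' For each patient, the elapsed time between their most recent attendance
#' and a reference date: the date of death for deceased patients, otherwise
#' the end of the study window. Attendances recorded after the reference
#' clamp to 0 with a warning.
#'
#' @param cohort Patient tibble; every patient must have at least one
#'   attendance (guaranteed after [select_cohort()]).
#' @param window A [study_window()].
#' @return Numeric years, never negative.
#' @export
time_since_last_attendance <- function(cohort, window) {
  if (any(vapply(cohort$attendance_dates, length, integer(1)) == 0)) {
    cp_abort("patient without attendance dates", "cp_no_attendance")
  }
  last <- as.Date(vapply(cohort$attendance_dates,
                         function(d) as.numeric(max(d)), numeric(1)),
                  origin = "1970-01-01")
  ref <- as.Date(ifelse(cohort$vital_status == "deceased",
                        as.numeric(cohort$date_of_death),
                        as.numeric(window$end)),
                 origin = "1970-01-01")
  gap <- years_between(last, ref)
  if (any(gap < 0)) {
    cp_warn("attendance after the follow-up reference date; clamping to 0",
            "cp_negative_gap")
    gap <- pmax(gap, 0)
  }
  gap
}

#' Flag patients lost to follow-up
#'
#' A patient is lost to follow-up when the gap since their last attendance
#' (referenced to the study end, or their death date if deceased) is
#' strictly longer than `threshold_years`. A gap of exactly the threshold
#' is *not* lost to follow-up.
#'
#' @inheritParams time_since_last_attendance
#' @param threshold_years Gap threshold in years (default 3).
#' @return Logical vector.
#' @export
flag_lost_to_follow_up <- function(cohort, window, threshold_years = 3) {
  time_since_last_attendance(cohort, window) > threshold_years
}

#' Map source diagnosis codes to standard labels
#'
#' Replaces each source code with its standard label from the mapping
#' table; codes absent from the table become `"Unmapped"` (with one warning
#' listing them); labels are de-duplicated per patient.
#'
#' @param cohort Patient tibble with a `diagnoses` list-column of source codes.
#' @param mapping Mapping tibble (`source_code,standard_label`).
#' @param quiet Suppress the unmapped-code warning.
#' @return The cohort with `diagnoses` replaced by standard labels.
#' @export
map_diagnoses <- function(cohort, mapping, quiet = FALSE) {
  lut <- setNames(mapping$standard_label, mapping$source_code)
  unmapped <- character(0)
  cohort$diagnoses <- lapply(cohort$diagnoses, function(codes) {
    if (length(codes) == 0) return(character(0))
    hit <- lut[codes]
    miss <- codes[is.na(hit)]
    if (length(miss)) unmapped <<- c(unmapped, miss)
    hit[is.na(hit)] <- "Unmapped"
    unique(unname(hit))
  })
  if (length(unmapped) && !quiet) {
    cp_warn(paste0("unmapped diagnosis code(s): ",
                   paste(unique(unmapped), collapse = ", ")),
            "cp_unmapped_diagnosis")
  }
  cohort
}

#' Construct a set of global patient filters
#'
#' All criteria are optional; `NULL` (or an empty subset) means no
#' restriction. Age is evaluated at the end of the study window, the same
#' reference used by cohort selection. The attendance-period criterion
#' keeps patients with at least one visit inside `[attended_from,
#' attended_to]`; `max_years_since_last_visit` bounds
#' [time_since_last_attendance()].
#'
#' @param age_min,age_max Age bounds in years (inclusive), non-negative.
#' @param sexes,vital_statuses,severities Character subsets of the
#'   respective vocabularies.
#' @param attended_from,attended_to Dates bounding the attendance-period
#'   criterion.
#' @param max_years_since_last_visit Upper bound in years (inclusive).
#' @return A `global_filters` object.
#' @export
global_filters <- function(age_min = NULL, age_max = NULL, sexes = NULL,
                           vital_statuses = NULL, severities = NULL,
                           attended_from = NULL, attended_to = NULL,
                           max_years_since_last_visit = NULL) {
  if (!is.null(age_min) && age_min < 0) {
    cp_abort("age_min must be non-negative", "cp_invalid_filters")
  }
  if (!is.null(age_min) && !is.null(age_max) && age_min > age_max) {
    cp_abort("age_min exceeds age_max", "cp_invalid_filters")
  }
  if (!is.null(attended_from)) attended_from <- as.Date(attended_from)
  if (!is.null(attended_to)) attended_to <- as.Date(attended_to)
  if (!is.null(attended_from) && !is.null(attended_to) &&
      attended_from > attended_to) {
    cp_abort("attendance-period start exceeds end", "cp_invalid_filters")
  }
  check_subset <- function(x, vocab, what) {
    if (!is.null(x) && length(setdiff(x, vocab))) {
      cp_abort(paste0("unknown ", what, ": ",
                      paste(setdiff(x, vocab), collapse = ", ")),
               "cp_invalid_filters")
    }
  }
  check_subset(sexes, cp_sexes, "sex")
  check_subset(vital_statuses, cp_vital, "vital status")
  check_subset(severities, cp_severities, "severity")
  structure(
    list(age_min = age_min, age_max = age_max, sexes = sexes,
         vital_statuses = vital_statuses, severities = severities,
         attended_from = attended_from, attended_to = attended_to,
         max_years_since_last_visit = max_years_since_last_visit),
    class = "global_filters"
  )
}

#' Apply global filters to a cohort
#'
#' Keeps the intersection of all active criteria; inactive criteria are
#' identity. Never increases cohort size, and composing two filter calls
#' equals applying their conjunction.
#'
#' @param cohort Selected cohort tibble.
#' @param filters A [global_filters()] object.
#' @param window The [study_window()] (reference for age and follow-up gap).
#' @return The filtered cohort tibble.
#' @export
apply_global_filters <- function(cohort, filters, window) {
  if (!inherits(filters, "global_filters")) {
    cp_abort("filters must be built with global_filters()", "cp_invalid_filters")
  }
  if (nrow(cohort) == 0) return(cohort)
  keep <- rep(TRUE, nrow(cohort))
  age <- completed_years(cohort$date_of_birth, window$end)
  if (!is.null(filters$age_min)) keep <- keep & age >= filters$age_min
  if (!is.null(filters$age_max)) keep <- keep & age <= filters$age_max
  if (!is.null(filters$sexes) && length(filters$sexes)) {
    keep <- keep & cohort$sex %in% filters$sexes
  }
  if (!is.null(filters$vital_statuses) && length(filters$vital_statuses)) {
    keep <- keep & cohort$vital_status %in% filters$vital_statuses
  }
  if (!is.null(filters$severities) && length(filters$severities)) {
    keep <- keep & cohort$severity %in% filters$severities
  }
  if (!is.null(filters$attended_from) || !is.null(filters$attended_to)) {
    from <- filters$attended_from %||% as.Date("0001-01-01")
    to <- filters$attended_to %||% as.Date("9999-12-31")
    keep <- keep & vapply(cohort$attendance_dates, function(d) {
      any(d >= from & d <= to)
    }, logical(1))
  }
  if (!is.null(filters$max_years_since_last_visit)) {
    gap <- time_since_last_attendance(cohort, window)
    keep <- keep & gap <= filters$max_years_since_last_visit
  }
  cohort[keep, , drop = FALSE]
}
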