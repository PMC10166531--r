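#' Define a study window
#'
#' @param start,end Dates (or ISO-8601 strings); `start` must precede `end`.
#' @return A list with `start` and `end` of class `study_window`.
#' @export
#' @examples
#' study_window("2000-01-01", "2022-07-01")
study_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || !(start < end)) {
    cp_abort("study window start must precede end", "cp_invalid_window")
  }
  structure(list(start = start, end = end), class = "study_window")
}

parse_date_list <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(as.Date(character(0)))
    sort(as.Date(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
}

parse_code_list <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Read patient records
#'
#' Expects the flat patient CSV dialect
#' `patient_id,date_of_birth,sex,vital_status,date_of_death,postcode,`
#' `suburb,state,severity,diagnosis_codes,attendance_dates` with ISO-8601
#' dates; `diagnosis_codes` and `attendance_dates` are semicolon-delimited
#' lists. Attendance dates are sorted ascending on ingestion. A date of
#' death must be present exactly when `vital_status` is `deceased`.
#'
#' @param csv_path Path to the CSV.
#' @return A tibble with list-columns `diagnoses` (source codes) and
#'   `attendance_dates`.
#' @export
read_patients <- function(csv_path) {
  raw <- readr::read_csv(
    csv_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date_of_birth = readr::col_date(),
      sex = readr::col_character(),
      vital_status = readr::col_character(),
      date_of_death = readr::col_date(),
      postcode = readr::col_character(),
      suburb = readr::col_character(),
      state = readr::col_character(),
      severity = readr::col_character(),
      diagnosis_codes = readr::col_character(),
      attendance_dates = readr::col_character()
    ),
    progress = FALSE
  )
  as_patients(dplyr::mutate(
    raw,
    diagnoses = parse_code_list(.data$diagnosis_codes),
    attendance_dates = parse_date_list(.data$attendance_dates)
  ) |> dplyr::select(-"diagnosis_codes"))
}

#' Validate a patient table
#'
#' @param patients A data frame shaped like [read_patients()] output.
#' @return The validated tibble.
#' @export
as_patients <- function(patients) {
  patients <- as_tibble(patients)
  if (anyDuplicated(patients$patient_id)) {
    cp_abort("duplicate patient_id", "cp_invalid_patients")
  }
  bad_sex <- setdiff(unique(patients$sex), cp_sexes)
  if (length(bad_sex)) {
    cp_abort(paste0("unknown sex value(s): ", paste(bad_sex, collapse = ", ")),
             "cp_invalid_patients")
  }
  bad_vs <- setdiff(unique(patients$vital_status), cp_vital)
  if (length(bad_vs)) {
    cp_abort(paste0("unknown vital_status value(s): ",
                    paste(bad_vs, collapse = ", ")), "cp_invalid_patients")
  }
  bad_sev <- setdiff(unique(patients$severity), cp_severities)
  if (length(bad_sev)) {
    cp_abort(paste0("unknown severity value(s): ",
                    paste(bad_sev, collapse = ", ")), "cp_invalid_patients")
  }
  dead <- patients$vital_status == "deceased"
  if (any(dead & is.na(patients$date_of_death)) ||
      any(!dead & !is.na(patients$date_of_death))) {
    cp_abort("date_of_death must be present exactly for deceased patients",
             "cp_invalid_patients")
  }
  patients$attendance_dates <- lapply(patients$attendance_dates, sort)
  patients
}

#' Read a postcode/suburb to area concordance
#'
#' Columns `postcode,suburb,area_id,weight`; a (postcode, suburb)
#' combination may map to several areas with weights, resolved by
#' [link_area()].
#'
#' @param csv_path Path to the CSV.
#' @return A tibble.
#' @export
read_concordance <- function(csv_path) {
  readr::read_csv(
    csv_path,
    col_types = readr::cols(
      postcode = readr::col_character(),
      suburb = readr::col_character(),
      area_id = readr::col_character(),
      weight = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Read a diagnosis-code mapping table
#'
#' Maps source ("in-house") diagnosis codes to a standard short-list label;
#' the table contents are supplied by the user.
#'
#' @param csv_path Path to a CSV with columns `source_code,standard_label`.
#' @return A tibble.
#' @export
read_diagnosis_map <- function(csv_path) {
  readr::read_csv(
    csv_path,
    col_types = readr::cols(
      source_code = readr::col_character(),
      standard_label = readr::col_character()
    ),
    progress = FALSE
  )
}

# flatten list-columns back to the CSV dialect
format_patients <- function(patients) {
  dplyr::mutate(
    patients,
    diagnosis_codes = vapply(.data$diagnoses, paste, character(1),
                             collapse = ";"),
    attendance_dates = vapply(.data$attendance_dates,
                              function(d) paste(format(d), collapse = ";"),
                              character(1))
  ) |>
    dplyr::select("patient_id", "date_of_birth", "sex", "vital_status",
                  "date_of_death", "postcode", "suburb", "state", "severity",
                  "diagnosis_codes", "attendance_dates")
}

#' Write patient records in the flat CSV dialect
#'
#' @param patients Patient tibble with list-columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  readr::write_csv(format_patients(patients), path, na = "")
  invisible(path)
}
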