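#' Aggregate a cohort into per-area counts
#'
#' Produces one row per area in the area set: total patient count, counts by
#' severity class, lost-to-follow-up count, and per-diagnosis counts (a
#' nested tibble; a patient with several diagnoses contributes to each, so
#' diagnosis counts may sum above `n_patients`). Areas with no patients get
#' explicit zero rows. Counts are conserved: `sum(n_patients)` equals the
#' cohort size.
#'
#' @param cohort Selected cohort with resolved `area_id` (and, if
#'   [map_diagnoses()] was applied, standardized labels in `diagnoses`).
#' @param areas The area set.
#' @param window The [study_window()], used for the lost-to-follow-up flag.
#' @param ltf_threshold_years Gap threshold passed to
#'   [flag_lost_to_follow_up()].
#' @return A tibble of class `area_aggregates` with columns `area_id`,
#'   `n_patients`, `n_simple`, `n_moderate`, `n_complex`, `n_unknown`,
#'   `n_lost_to_follow_up`, `diagnoses` (list of tibbles `diagnosis`, `n`)
#'   and `masked` (all `FALSE`; see [mask_aggregates()]).
#' @export
aggregate_to_areas <- function(cohort, areas, window,
                               ltf_threshold_years = 3) {
  unknown <- setdiff(unique(cohort$area_id), areas$area_id)
  if (length(unknown)) {
    offenders <- cohort$patient_id[cohort$area_id %in% unknown]
    cp_abort(paste0("patient(s) resolved to unknown area(s): ",
                    paste(head(offenders, 5), collapse = ", "),
                    " (area ", paste(unknown, collapse = ", "), ")"),
             "cp_unknown_area")
  }
  n <- nrow(cohort)
  ltf <- if (n) flag_lost_to_follow_up(cohort, window, ltf_threshold_years)
         else logical(0)

  per_area <- lapply(areas$area_id, function(aid) {
    idx <- which(cohort$area_id == aid)
    sev <- cohort$severity[idx]
    dx <- unlist(cohort$diagnoses[idx], use.names = FALSE)
    dx_tbl <- if (length(dx)) {
      tab <- table(dx)
      tibble(diagnosis = names(tab), n = as.integer(tab))
    } else {
      tibble(diagnosis = character(0), n = integer(0))
    }
    tibble(
      area_id = aid,
      n_patients = length(idx),
      n_simple = sum(sev == "Simple"),
      n_moderate = sum(sev == "Moderate"),
      n_complex = sum(sev == "Complex"),
      n_unknown = sum(sev == "Unknown"),
      n_lost_to_follow_up = sum(ltf[idx]),
      diagnoses = list(dx_tbl),
      masked = FALSE
    )
  })
  out <- dplyr::bind_rows(per_area)
  out <- dplyr::mutate(out, across(dplyr::starts_with("n_"), as.integer))
  class(out) <- unique(c("area_aggregates", class(out)))
  out
}

severity_count_cols <- c("n_simple", "n_moderate", "n_complex", "n_unknown")

#' Summarize a cohort in the style of a demographic summary table
#'
#' One row for the whole cohort plus one per severity stratum: N, mean/SD
#' age (at the window end), female N and %, mean/SD clinic attendances,
#' mean/SD years since last attendance, % lost to follow-up, and nested
#' per-diagnosis counts with stratum percentages. SDs are sample SDs
#' (n - 1) and are reported missing (`NA`) for strata of size 1; an empty
#' cohort yields N = 0 rows with all moments missing.
#'
#' @param cohort Selected cohort tibble.
#' @param window The [study_window()].
#' @param ltf_threshold_years Lost-to-follow-up gap threshold in years.
#' @return A tibble of class `cohort_summary`, one row per stratum
#'   (`All`, then each severity class), with a `diagnoses` list-column.
#' @export
summarize_cohort <- function(cohort, window, ltf_threshold_years = 3) {
  strata <- c("All", cp_severities)
  n_all <- nrow(cohort)
  age <- if (n_all) age_at(cohort$date_of_birth, window$end) else numeric(0)
  gap <- if (n_all) time_since_last_attendance(cohort, window) else numeric(0)
  att <- if (n_all) vapply(cohort$attendance_dates, length, integer(1))
         else integer(0)
  ltf <- gap > ltf_threshold_years

  one <- function(stratum) {
    idx <- if (stratum == "All") seq_len(n_all)
           else which(cohort$severity == stratum)
    n <- length(idx)
    dx <- unlist(cohort$diagnoses[idx], use.names = FALSE)
    dx_tbl <- if (length(dx)) {
      tab <- sort(table(dx), decreasing = TRUE)
      tibble(diagnosis = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / n)
    } else {
      tibble(diagnosis = character(0), n = integer(0), pct = numeric(0))
    }
    msd <- function(x) {
      if (length(x) == 0) c(NA_real_, NA_real_)
      else c(mean(x), if (length(x) > 1) sd(x) else NA_real_)
    }
    a <- msd(age[idx]); at <- msd(att[idx]); g <- msd(gap[idx])
    tibble(
      stratum = stratum,
      n = n,
      age_mean = a[1], age_sd = a[2],
      n_female = sum(cohort$sex[idx] == "female"),
      pct_female = if (n) 100 * sum(cohort$sex[idx] == "female") / n
                   else NA_real_,
      attendances_mean = at[1], attendances_sd = at[2],
      years_since_last_mean = g[1], years_since_last_sd = g[2],
      pct_lost_to_follow_up = if (n) 100 * sum(ltf[idx]) / n else NA_real_,
      diagnoses = list(dx_tbl)
    )
  }
  out <- dplyr::bind_rows(lapply(strata, one))
  class(out) <- unique(c("cohort_summary", class(out)))
  out
}

#' @export
tidy.cohort_summary <- function(x, ...) {
  dplyr::select(as_tibble(x), -"diagnoses") |>
    tidyr::pivot_longer(-"stratum", names_to = "statistic",
                        values_to = "value")
}

#' @export
glance.cohort_summary <- function(x, ...) {
  dplyr::select(as_tibble(x[x$stratum == "All", ]), -"diagnoses")
}
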