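#' Capture the full state of a planning session
#'
#' A tool state is everything a front end would let the user set: global
#' patient filters, the map scope and active layer, the current and
#' candidate clinic sets, the focus areas selected so far, the privacy
#' policy and the coverage threshold. Report generation is a pure function
#' of a tool state plus the input bundle, which is what makes a session
#' reproducible.
#'
#' @param current_clinics Character vector of open clinic facility ids.
#' @param window The [study_window()].
#' @param filters A [global_filters()] object.
#' @param scope `"All"` or a region name.
#' @param layer `"achd_population"` or `"drive_time"`.
#' @param candidate_clinics Candidate facility ids (disjoint from current).
#' @param focus_areas Area ids in selection order.
#' @param policy A [mask_policy()].
#' @param threshold_hours Coverage threshold in hours.
#' @param seed Optional integer recorded in report provenance.
#' @return A `tool_state` object.
#' @export
tool_state <- function(current_clinics, window,
                       filters = global_filters(),
                       scope = "All",
                       layer = c("achd_population", "drive_time"),
                       candidate_clinics = character(0),
                       focus_areas = character(0),
                       policy = mask_policy(),
                       threshold_hours = 1,
                       seed = NULL) {
  layer <- match.arg(layer)
  overlap <- intersect(current_clinics, candidate_clinics)
  if (length(overlap)) {
    cp_abort(paste0("candidate clinics overlap current clinics: ",
                    paste(overlap, collapse = ", ")), "cp_clinic_overlap")
  }
  structure(
    list(current_clinics = as.character(current_clinics),
         window = window, filters = filters, scope = scope, layer = layer,
         candidate_clinics = as.character(candidate_clinics),
         focus_areas = as.character(focus_areas), policy = policy,
         threshold_hours = threshold_hours, seed = seed),
    class = "tool_state"
  )
}

#' Serialize / deserialize a tool state as YAML
#'
#' @param state A [tool_state()].
#' @param path File path.
#' @return `write_tool_state` returns `path` invisibly; `read_tool_state`
#'   returns the `tool_state`.
#' @export
write_tool_state <- function(state, path) {
  f <- state$filters
  doc <- list(
    current_clinics = as.list(state$current_clinics),
    candidate_clinics = as.list(state$candidate_clinics),
    focus_areas = as.list(state$focus_areas),
    scope = state$scope,
    layer = state$layer,
    threshold_hours = state$threshold_hours,
    window = list(start = format(state$window$start),
                  end = format(state$window$end)),
    policy = list(threshold = state$policy$threshold,
                  mode = state$policy$mode),
    filters = list(
      age_min = f$age_min, age_max = f$age_max,
      sexes = as.list(f$sexes), vital_statuses = as.list(f$vital_statuses),
      severities = as.list(f$severities),
      attended_from = if (is.null(f$attended_from)) NULL
                      else format(f$attended_from),
      attended_to = if (is.null(f$attended_to)) NULL
                    else format(f$attended_to),
      max_years_since_last_visit = f$max_years_since_last_visit
    ),
    seed = state$seed
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_tool_state
#' @export
read_tool_state <- function(path) {
  doc <- yaml::read_yaml(path)
  unl <- function(x) if (is.null(x) || !length(x)) NULL else unlist(x)
  f <- doc$filters %||% list()
  tool_state(
    current_clinics = unl(doc$current_clinics) %||% character(0),
    window = study_window(doc$window$start, doc$window$end),
    filters = global_filters(
      age_min = f$age_min, age_max = f$age_max, sexes = unl(f$sexes),
      vital_statuses = unl(f$vital_statuses),
      severities = unl(f$severities),
      attended_from = f$attended_from, attended_to = f$attended_to,
      max_years_since_last_visit = f$max_years_since_last_visit
    ),
    scope = doc$scope %||% "All",
    layer = doc$layer %||% "achd_population",
    candidate_clinics = unl(doc$candidate_clinics) %||% character(0),
    focus_areas = unl(doc$focus_areas) %||% character(0),
    policy = mask_policy(doc$policy$threshold %||% 5,
                         doc$policy$mode %||% "private"),
    threshold_hours = doc$threshold_hours %||% 1,
    seed = doc$seed
  )
}

#' Area-focus summary for selected areas
#'
#' Per selected area (in selection order: each new selection is appended):
#' the patient count (masked as the policy requires), per-diagnosis counts,
#' and the area's socio-demographic attributes (disadvantage decile,
#' remoteness, Indigenous population share, total population).
#'
#' @param aggregates Per-area counts from [aggregate_to_areas()].
#' @param areas The area set.
#' @param area_ids Selected areas, in selection order.
#' @param policy A [mask_policy()].
#' @return A tibble, one row per selected area, with a `diagnoses`
#'   list-column.
#' @export
area_focus <- function(aggregates, areas, area_ids, policy = mask_policy()) {
  unknown <- setdiff(area_ids, areas$area_id)
  if (length(unknown)) {
    cp_abort(paste0("unknown area id(s) in focus selection: ",
                    paste(unknown, collapse = ", ")), "cp_unknown_area")
  }
  masked <- mask_aggregates(aggregates, policy)
  rows <- lapply(area_ids, function(aid) {
    a <- areas[areas$area_id == aid, , drop = FALSE]
    m <- masked[masked$area_id == aid, , drop = FALSE]
    tibble(
      area_id = aid,
      name = a$name,
      n_patients = as.character(m$n_patients),
      n_lost_to_follow_up = as.character(m$n_lost_to_follow_up),
      irsd_decile = a$irsd_decile,
      remoteness = a$remoteness,
      indigenous_pct = a$indigenous_pct,
      population = a$population,
      diagnoses = m$diagnoses
    )
  })
  dplyr::bind_rows(rows)
}

summary_section_table <- function(cs) {
  tibble(
    Statistic = c("N", "Age, years (mean (SD))", "Female (N (%))",
                  "Clinic attendances (mean (SD))",
                  "Years since last attendance (mean (SD))",
                  "Lost to follow-up (%)"),
    !!!setNames(lapply(seq_len(nrow(cs)), function(i) {
      c(as.character(cs$n[i]),
        paste0(fmt_num(cs$age_mean[i]), " (", fmt_num(cs$age_sd[i]), ")"),
        paste0(cs$n_female[i], " (", fmt_num(cs$pct_female[i]), ")"),
        paste0(fmt_num(cs$attendances_mean[i]), " (",
               fmt_num(cs$attendances_sd[i]), ")"),
        paste0(fmt_num(cs$years_since_last_mean[i]), " (",
               fmt_num(cs$years_since_last_sd[i]), ")"),
        fmt_num(cs$pct_lost_to_follow_up[i]))
    }), cs$stratum)
  )
}

accessibility_section_table <- function(cmp) {
  tibble(
    Scope = cmp$scope,
    `Patients in scope` = cmp$n_patients_in_scope,
    `% within threshold (current)` = fmt_num(cmp$pct_before),
    `% within threshold (with candidates)` = fmt_num(cmp$pct_after),
    `Patients gained` = cmp$patients_gained,
    `Mean drive (h, current)` = fmt_num(cmp$mean_before),
    `Mean drive (h, with candidates)` = fmt_num(cmp$mean_after),
    `Max drive (h, current)` = fmt_num(cmp$max_before),
    `Max drive (h, with candidates)` = fmt_num(cmp$max_after)
  )
}

#' Build the five-section planning report
#'
#' Recomputes every number from the tool state and the input bundle —
#' nothing is cached — and renders a self-contained Markdown document with
#' exactly five content sections in fixed order: Patient Data, Area Data,
#' Current Clinics, New Clinics, and Area Focus, preceded by a provenance
#' block (configuration hash, seed, timestamp). Re-running with the same
#' state and inputs yields an identical body; only the timestamp line
#' differs. In public mode every patient count in the document has passed
#' small-cell masking.
#'
#' @param state A [tool_state()].
#' @param inputs An input bundle as returned by [read_bundle()] /
#'   [simulate_bundle()]: `areas`, `facilities`, `ttm`, `patients`,
#'   `concordance`, `diagnosis_map`.
#' @return The report as a single Markdown string of class `clinic_report`.
#' @export
build_report <- function(state, inputs) {
  overlap <- intersect(state$current_clinics, state$candidate_clinics)
  if (length(overlap)) {
    cp_abort("candidate clinics overlap current clinics", "cp_clinic_overlap")
  }
  w <- state$window
  sel <- select_cohort(inputs$patients, w, inputs$concordance)
  cohort <- map_diagnoses(sel$cohort, inputs$diagnosis_map, quiet = TRUE)
  cohort <- apply_global_filters(cohort, state$filters, w)
  agg <- aggregate_to_areas(cohort, inputs$areas, w)
  magg <- mask_aggregates(agg, state$policy)
  cs <- summarize_cohort(cohort, w)

  current <- clinic_set(inputs$facilities, state$current_clinics)
  cand <- clinic_set(inputs$facilities, state$candidate_clinics)

  reach_cur <- clinic_reach(agg, inputs$ttm, current, state$threshold_hours)
  reach_tbl <- function(r) {
    n <- as.character(r$n_patients_within_threshold)
    l <- as.character(r$n_ltf_within_threshold)
    if (state$policy$mode == "public") {
      n <- mask_cell(n, state$policy$threshold)
      l <- mask_cell(l, state$policy$threshold)
    }
    tibble(facility_id = r$facility_id, Patients = n, ltf = l)
  }

  sec_patient <- paste0(
    "## Patient Data\n\n",
    md_table(tidy(sel$flow)), "\n",
    md_table(summary_section_table(cs))
  )

  n_display <- if (state$policy$mode == "public") {
    magg$n_patients
  } else {
    as.character(agg$n_patients)
  }
  area_tbl <- tibble(
    area_id = agg$area_id,
    region = inputs$areas$region[match(agg$area_id, inputs$areas$area_id)],
    n_patients = n_display,
    n_lost_to_follow_up = if (state$policy$mode == "public")
      magg$n_lost_to_follow_up else as.character(agg$n_lost_to_follow_up)
  )
  area_tbl <- area_tbl[order(area_tbl$area_id), ]
  sec_area <- paste0("## Area Data\n\n",
                     "Active layer: ", state$layer, "; scope: ", state$scope,
                     "; privacy mode: ", state$policy$mode, ".\n\n",
                     md_table(area_tbl))

  sec_current <- paste0("## Current Clinics\n\n",
                        md_table(reach_tbl(reach_cur)))

  if (length(cand)) {
    reach_new <- clinic_reach(agg, inputs$ttm, cand, state$threshold_hours)
    cmp <- evaluate_candidates(agg, inputs$ttm, current, cand, inputs$areas,
                               state$threshold_hours)
    sec_new <- paste0("## New Clinics\n\n",
                      md_table(reach_tbl(reach_new)), "\n",
                      md_table(accessibility_section_table(cmp)))
  } else {
    sec_new <- "## New Clinics\n\nNo candidate clinics selected.\n"
  }

  if (length(state$focus_areas)) {
    af <- area_focus(agg, inputs$areas, state$focus_areas, state$policy)
    af_flat <- dplyr::mutate(
      dplyr::select(af, -"diagnoses"),
      indigenous_pct = fmt_num(.data$indigenous_pct, 1)
    )
    dx_lines <- vapply(seq_len(nrow(af)), function(i) {
      d <- af$diagnoses[[i]]
      if (nrow(d) == 0) return(paste0("- ", af$area_id[i], ": no diagnoses"))
      paste0("- ", af$area_id[i], ": ",
             paste(paste0(d$diagnosis, " = ", d$n), collapse = "; "))
    }, character(1))
    sec_focus <- paste0("## Area Focus\n\n", md_table(af_flat), "\n",
                        "Diagnosis counts:\n\n",
                        paste(dx_lines, collapse = "\n"), "\n")
  } else {
    sec_focus <- "## Area Focus\n\nNo areas selected.\n"
  }

  state_hash <- rlang::hash(list(
    state$current_clinics, state$candidate_clinics, state$focus_areas,
    state$scope, state$layer, state$threshold_hours,
    format(w$start), format(w$end),
    unclass(state$filters), unclass(state$policy), state$seed
  ))
  provenance <- paste0(
    "Configuration hash: ", state_hash, "\n\n",
    "Seed: ", state$seed %||% "not set", "\n\n",
    "Study window: ", format(w$start), " to ", format(w$end), "\n\n",
    "Generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"), "\n"
  )

  body <- paste0(
    "# Clinic Planning Report\n\n", provenance, "\n",
    sec_patient, "\n", sec_area, "\n", sec_current, "\n",
    sec_new, "\n", sec_focus
  )
  structure(body, class = c("clinic_report", "character"))
}

#' @export
print.clinic_report <- function(x, ...) {
  cat(x)
  invisible(x)
}

#' Write a report to a Markdown file
#'
#' @param report A `clinic_report` from [build_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  writeLines(unclass(report), path)
  invisible(path)
}

#' Report body with the timestamp line removed
#'
#' Two reports built from the same tool state and inputs have identical
#' bodies; only the generation timestamp differs. This helper strips that
#' line so the purity property can be asserted.
#'
#' @param report A `clinic_report`.
#' @return Character scalar.
#' @export
report_body <- function(report) {
  lines <- strsplit(unclass(report), "\n", fixed = TRUE)[[1]]
  paste(lines[!grepl("^Generated: ", lines)], collapse = "\n")
}
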