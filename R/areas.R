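#' Validate and class an area table
#'
#' An area set is a tibble with one row per small statistical area: an
#' opaque `area_id`, a display `name`, the planning `region`
#' (GreaterSydney / ACT / RestOfState), the five-class `remoteness`
#' category, socio-economic disadvantage decile `irsd_decile` (1 = most
#' disadvantaged, 10 = least; may be missing), `indigenous_pct` (0-100),
#' `population`, and an optional `geometry` list-column holding parsed
#' GeoJSON geometry (lon/lat, WGS84).
#'
#' @param areas A data frame with at least `area_id`; attribute columns are
#'   validated when present.
#' @return The input as a tibble with class `area_set`.
#' @export
as_area_set <- function(areas) {
  areas <- as_tibble(areas)
  if (!"area_id" %in% names(areas)) {
    cp_abort("areas must have an `area_id` column", "cp_invalid_areas")
  }
  areas$area_id <- as.character(areas$area_id)
  if (anyDuplicated(areas$area_id)) {
    dup <- unique(areas$area_id[duplicated(areas$area_id)])
    cp_abort(paste0("duplicate area_id: ", paste(dup, collapse = ", ")),
             "cp_duplicate_area_id")
  }
  if ("region" %in% names(areas)) {
    bad <- setdiff(unique(areas$region[!is.na(areas$region)]), cp_regions)
    if (length(bad)) {
      cp_abort(paste0("unknown region value(s): ", paste(bad, collapse = ", ")),
               "cp_invalid_areas")
    }
  }
  if ("remoteness" %in% names(areas)) {
    bad <- setdiff(unique(areas$remoteness[!is.na(areas$remoteness)]),
                   cp_remoteness)
    if (length(bad)) {
      cp_abort(paste0("unknown remoteness value(s): ",
                      paste(bad, collapse = ", ")), "cp_invalid_areas")
    }
  }
  if ("irsd_decile" %in% names(areas)) {
    v <- areas$irsd_decile
    ok <- is.na(v) | (v %in% 1:10)
    if (!all(ok)) {
      cp_abort("irsd_decile must be an integer 1-10 or missing",
               "cp_invalid_areas")
    }
  }
  if ("indigenous_pct" %in% names(areas)) {
    v <- areas$indigenous_pct
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      cp_abort("indigenous_pct must lie in [0, 100]", "cp_invalid_areas")
    }
  }
  if ("population" %in% names(areas)) {
    v <- areas$population
    if (any(!is.na(v) & v < 0)) {
      cp_abort("population must be non-negative", "cp_invalid_areas")
    }
  }
  class(areas) <- unique(c("area_set", class(areas)))
  areas
}

# parse one GeoJSON feature's geometry; NULL is allowed (geometry optional)
check_geometry <- function(geom, feature_label) {
  if (is.null(geom)) return(NULL)
  if (!is.list(geom) || is.null(geom$type) ||
      !geom$type %in% c("Polygon", "MultiPolygon") ||
      is.null(geom$coordinates)) {
    cp_abort(paste0("malformed polygon geometry in feature ", feature_label),
             "cp_malformed_geometry")
  }
  rings <- if (geom$type == "Polygon") geom$coordinates else
    unlist(geom$coordinates, recursive = FALSE)
  for (ring in rings) {
    if (!is.list(ring) || length(ring) < 4 ||
        !all(vapply(ring, function(p) length(p) >= 2, logical(1)))) {
      cp_abort(paste0("malformed polygon ring in feature ", feature_label),
               "cp_malformed_geometry")
    }
  }
  geom
}

#' Read an area set from GeoJSON boundaries plus an attribute table
#'
#' Boundaries come from an RFC 7946 FeatureCollection whose features carry an
#' `area_id` property; area-level attributes come from a CSV keyed by
#' `area_id` (columns `area_id,name,region,remoteness,irsd_decile,`
#' `indigenous_pct,population`). The two sources are joined on `area_id`.
#' Areas present in only one source are kept and flagged (`has_geometry`,
#' `has_attributes`), with a warning listing the mismatch, so upstream data
#' problems surface instead of silently dropping areas.
#'
#' @param geojson_path Path to the FeatureCollection.
#' @param attributes_csv_path Path to the attribute CSV.
#' @return An [as_area_set()] tibble with `geometry`, `has_geometry` and
#'   `has_attributes` columns.
#' @export
read_areas <- function(geojson_path, attributes_csv_path) {
  doc <- jsonlite::fromJSON(geojson_path, simplifyVector = FALSE)
  if (is.null(doc$type) || doc$type != "FeatureCollection") {
    cp_abort("GeoJSON input is not a FeatureCollection", "cp_invalid_geojson")
  }
  feats <- doc$features %||% list()
  ids <- vapply(seq_along(feats), function(i) {
    id <- feats[[i]]$properties$area_id
    if (is.null(id)) {
      cp_abort(paste0("feature ", i, " has no area_id property"),
               "cp_invalid_geojson")
    }
    as.character(id)
  }, character(1))
  if (anyDuplicated(ids)) {
    cp_abort(paste0("duplicate area_id in GeoJSON: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "cp_duplicate_area_id")
  }
  geoms <- lapply(seq_along(feats), function(i) {
    check_geometry(feats[[i]]$geometry, ids[i])
  })
  geo <- tibble(area_id = ids, geometry = geoms, has_geometry = TRUE)

  attrs <- readr::read_csv(
    attributes_csv_path,
    col_types = readr::cols(
      area_id = readr::col_character(),
      name = readr::col_character(),
      region = readr::col_character(),
      remoteness = readr::col_character(),
      irsd_decile = readr::col_integer(),
      indigenous_pct = readr::col_double(),
      population = readr::col_integer()
    ),
    progress = FALSE
  )
  if (anyDuplicated(attrs$area_id)) {
    cp_abort(paste0("duplicate area_id in attribute CSV: ",
                    paste(unique(attrs$area_id[duplicated(attrs$area_id)]),
                          collapse = ", ")),
             "cp_duplicate_area_id")
  }
  only_geo <- setdiff(geo$area_id, attrs$area_id)
  only_attr <- setdiff(attrs$area_id, geo$area_id)
  if (length(only_geo)) {
    cp_warn(paste0(length(only_geo), " area(s) in GeoJSON missing from the ",
                   "attribute CSV: ", paste(only_geo, collapse = ", ")),
            "cp_attributes_missing")
  }
  if (length(only_attr)) {
    cp_warn(paste0(length(only_attr), " area(s) in the attribute CSV missing ",
                   "from the GeoJSON: ", paste(only_attr, collapse = ", ")),
            "cp_geometry_missing")
  }

  joined <- dplyr::full_join(geo, attrs, by = "area_id")
  joined$geometry[!(joined$area_id %in% geo$area_id)] <- list(NULL)
  joined$has_geometry <- !vapply(joined$geometry, is.null, logical(1))
  joined$has_attributes <- joined$area_id %in% attrs$area_id
  joined <- joined[, c("area_id", "name", "region", "remoteness",
                       "irsd_decile", "indigenous_pct", "population",
                       "geometry", "has_geometry", "has_attributes")]
  as_area_set(joined)
}

#' Read a facility list
#'
#' Facilities are hospitals and clinics: `facility_id,name,lon,lat,role`
#' where `role` is one of `current_clinic` (always open), `candidate`
#' (open only when selected) or `hospital` (a potential candidate site).
#'
#' @param csv_path Path to the facilities CSV.
#' @return A tibble with one row per facility.
#' @export
read_facilities <- function(csv_path) {
  fac <- readr::read_csv(
    csv_path,
    col_types = readr::cols(
      facility_id = readr::col_character(),
      name = readr::col_character(),
      lon = readr::col_double(),
      lat = readr::col_double(),
      role = readr::col_character()
    ),
    progress = FALSE
  )
  if (anyDuplicated(fac$facility_id)) {
    cp_abort("duplicate facility_id in facilities CSV", "cp_duplicate_facility")
  }
  bad <- setdiff(unique(fac$role), cp_facility_roles)
  if (length(bad)) {
    cp_abort(paste0("unknown facility role(s): ", paste(bad, collapse = ", ")),
             "cp_invalid_facility")
  }
  fac
}

#' Validate a clinic set against a facility table
#'
#' A clinic set is an ordered vector of facility ids treated as open
#' clinics. Ids must be unique and resolve to known facilities.
#'
#' @param facilities Facility tibble (see [read_facilities()]).
#' @param ids Character vector of facility ids.
#' @return `ids`, validated.
#' @export
clinic_set <- function(facilities, ids) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    cp_abort("clinic set contains duplicate facility ids", "cp_invalid_clinic_set")
  }
  unknown <- setdiff(ids, facilities$facility_id)
  if (length(unknown)) {
    cp_abort(paste0("unknown facility id(s) in clinic set: ",
                    paste(unknown, collapse = ", ")), "cp_invalid_clinic_set")
  }
  ids
}

# normalize `values` to a tibble(area_id, value); value may be numeric or
# character (the masked sentinel survives as a string)
normalize_layer_values <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("area_id", "value") %in% names(values)))
    tibble(area_id = as.character(values$area_id), value = values$value)
  } else {
    if (is.null(names(values))) {
      cp_abort("values must be a data frame or a named vector",
               "cp_invalid_layer")
    }
    tibble(area_id = names(values), value = unname(values))
  }
}

#' Write a choropleth layer as GeoJSON
#'
#' Emits a FeatureCollection carrying each area's geometry plus a property
#' named `layer_name` holding that area's value. Areas without a value get
#' `null`; masked values (see [mask_policy()]) are written as the string
#' `"masked"`, never as a number. Geometry is passed through exactly as
#' read, so a write/read cycle preserves vertex counts and coordinates.
#'
#' @param areas An [as_area_set()] tibble with a `geometry` column.
#' @param values A tibble with columns `area_id`, `value`, or a named
#'   vector; every `area_id` must exist in `areas`.
#' @param layer_name Property name for the value.
#' @param path Optional file path; when given the document is written there.
#' @return The GeoJSON text, invisibly when `path` is given.
#' @export
write_choropleth <- function(areas, values, layer_name, path = NULL) {
  vals <- normalize_layer_values(values)
  unknown <- setdiff(vals$area_id, areas$area_id)
  if (length(unknown)) {
    cp_abort(paste0("unknown area_id in layer values: ",
                    paste(unknown, collapse = ", ")), "cp_unknown_area")
  }
  lookup <- setNames(seq_len(nrow(vals)), vals$area_id)
  features <- lapply(seq_len(nrow(areas)), function(i) {
    aid <- areas$area_id[i]
    v <- if (aid %in% names(lookup)) {
      raw <- vals$value[[lookup[[aid]]]]
      if (is.na(raw)) {
        NULL
      } else if (is.character(raw) && raw != masked_sentinel() &&
                 !is.na(suppressWarnings(as.numeric(raw)))) {
        as.numeric(raw)  # an unmasked count travels as a number
      } else {
        raw
      }
    } else NULL
    props <- list(area_id = aid)
    if (!is.null(areas$name) && !is.na(areas$name[i])) props$name <- areas$name[i]
    props[[layer_name]] <- v
    geom <- if ("geometry" %in% names(areas)) areas$geometry[[i]] else NULL
    list(type = "Feature", geometry = geom, properties = props)
  })
  doc <- list(type = "FeatureCollection", features = features)
  txt <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                       null = "null"))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a choropleth layer back from GeoJSON
#'
#' Inverse of [write_choropleth()]: returns the per-area values of one
#' property. `"masked"` stays a string; `null` becomes `NA`.
#'
#' @param path Path or GeoJSON text.
#' @param layer_name Property to extract.
#' @return A tibble `area_id`, `value` (list-column collapsed to atomic when
#'   possible).
#' @export
read_choropleth <- function(path, layer_name) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- doc$features %||% list()
  vals <- lapply(feats, function(f) f$properties[[layer_name]])
  tibble(
    area_id = vapply(feats, function(f) as.character(f$properties$area_id),
                     character(1)),
    value = vapply(vals, function(v) {
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  )
}

# vertex count of a feature geometry, used by round-trip checks
geometry_vertex_count <- function(geom) {
  if (is.null(geom)) return(0L)
  rings <- if (geom$type == "Polygon") geom$coordinates else
    unlist(geom$coordinates, recursive = FALSE)
  sum(vapply(rings, length, integer(1)))
}
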