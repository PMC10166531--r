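#' Choropleth plot of an area layer
#'
#' Draws the area polygons filled by a per-area value: patient counts, the
#' drive-time layer, or any other area-keyed number. Masked or missing
#' values draw as grey, matching the convention that areas with no data are
#' grey on the map.
#'
#' @param areas An `area_set` with geometry.
#' @param values A tibble `area_id`, `value` or a named vector; character
#'   values (e.g. the masked sentinel) plot as missing.
#' @param layer_name Legend title.
#' @return A ggplot object.
#' @export
plot_choropleth <- function(areas, values, layer_name = "value") {
  vals <- normalize_layer_values(values)
  vals$value <- suppressWarnings(as.numeric(as.character(vals$value)))
  coords <- lapply(seq_len(nrow(areas)), function(i) {
    g <- areas$geometry[[i]]
    if (is.null(g)) return(NULL)
    ring <- g$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    tibble(area_id = areas$area_id[i], lon = pts[, 1], lat = pts[, 2])
  })
  df <- dplyr::bind_rows(coords)
  df <- left_join(df, vals, by = "area_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   group = .data$area_id,
                                   fill = .data$value)) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(na.value = "grey70", name = layer_name) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @describeIn plot_choropleth Autoplot method for a drive-time layer;
#'   requires the matching `areas` object.
#' @param object A `drive_time_layer`.
#' @param ... Unused.
#' @export
autoplot.drive_time_layer <- function(object, areas, ...) {
  plot_choropleth(areas,
                  tibble(area_id = object$area_id,
                         value = object$nearest_time),
                  layer_name = "hours to nearest clinic")
}

#' Dumbbell-style plot of a candidate comparison
#'
#' Shows the per-scope mean drive time before and after adding the
#' candidate clinics.
#'
#' @param object A `candidate_comparison` from [evaluate_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.candidate_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("scope", "mean_before", "mean_after")],
    -"scope", names_to = "when", values_to = "mean_time"
  )
  df$when <- ifelse(df$when == "mean_before", "current", "with candidates")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_time, y = .data$scope,
                                   colour = .data$when)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "patient-weighted mean drive time (h)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
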