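#' Binarise a suitability grid at a threshold
#'
#' Cells with suitability `>= t` are suitable (1), others unsuitable (0);
#' nodata cells stay `NA`.
#'
#' @param suitability an [eco_grid] of suitability in \[0, 1\].
#' @param t threshold in \[0, 1\] (typically the MTSS threshold).
#' @param scenario_tag label carried on the result (e.g. `"current"`,
#'   `"SSP5-8.5/2081-2100"`).
#' @return A `binary_map`: an [eco_grid] of 0/1 with attributes
#'   `threshold_used` and `scenario_tag`.
#' @export
binarize <- function(suitability, t, scenario_tag = "current") {
  stopifnot(is_eco_grid(suitability), t >= 0, t <= 1)
  b <- suitability
  b$values <- (suitability$values >= t) + 0
  attr(b, "threshold_used") <- t
  attr(b, "scenario_tag") <- scenario_tag
  class(b) <- c("binary_map", class(b))
  b
}

#' Suitable habitat area (total or per zone)
#'
#' Area = suitable-cell count x `cell_area_km2`, adopting the constant
#' per-cell area convention (default 4.5 km^2 for a 2.5-arcmin cell at the
#' equator). An optional cosine-of-latitude correction is available but off
#' by default.
#'
#' @param b a `binary_map` (or 0/1 [eco_grid]).
#' @param cell_area_km2 area of one grid cell in km^2.
#' @param zones optional `zone_set` (see [make_zones()]); when given, one
#'   area per zone is returned.
#' @param latitude_correction multiply each cell's area by the cosine of
#'   its centre latitude.
#' @return Without zones, a single number (km^2); with zones, a tibble
#'   `zone_id`, `name`, `suitable_area_km2`.
#' @export
suitable_area <- function(b, cell_area_km2 = 4.5, zones = NULL,
                          latitude_correction = FALSE) {
  stopifnot(is_eco_grid(b), cell_area_km2 > 0)
  m <- b$values
  w <- matrix(cell_area_km2, nrow = nrow(m), ncol = ncol(m))
  if (latitude_correction) {
    lat <- b$yll + (nrow(m) - seq_len(nrow(m)) + 0.5) * b$cellsize
    w <- w * cos(lat * pi / 180)
  }
  suit <- !is.na(m) & m != 0
  if (is.null(zones)) return(sum(w[suit]))
  stopifnot(inherits(zones, "zone_set"))
  z <- zones$raster$values
  labels <- sort(unique(z[!is.na(z) & z != 0]))
  unknown <- setdiff(labels, zones$table$zone_id)
  if (length(unknown) > 0)
    stop(sprintf("zone label(s) missing from the zone table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  areas <- vapply(zones$table$zone_id, function(id)
    sum(w[suit & !is.na(z) & z == id]), numeric(1))
  tibble::tibble(zone_id = zones$table$zone_id, name = zones$table$name,
                 suitable_area_km2 = areas)
}

#' Percent change in suitable area between periods
#'
#' `100 * (future - current) / current`. When the current area is zero the
#' ratio is undefined: the result is `NA` and the companion
#' `new_colonization` flag from [change_summary()] marks zones that gain
#' habitat from nothing.
#'
#' @param area_future,area_current areas in km^2 (vectorised).
#' @return Percent change (negative = loss); `NA` where `area_current == 0`.
#' @export
percent_change <- function(area_future, area_current) {
  ifelse(area_current > 0,
         100 * (area_future - area_current) / area_current,
         NA_real_)
}

#' Zonal mean suitability
#'
#' Arithmetic mean of the (cloglog) suitability over *all* valid cells of
#' each zone, including unsuitable ones.
#'
#' @param suitability an [eco_grid].
#' @param zones a `zone_set` aligned with the grid.
#' @return A tibble `zone_id`, `name`, `mean_suitability`, `n_cells`
#'   (`NA` mean for zones with no valid cell).
#' @export
zonal_mean_suitability <- function(suitability, zones) {
  stopifnot(is_eco_grid(suitability), inherits(zones, "zone_set"))
  if (!same_geometry(suitability, zones$raster))
    stop("zone raster is not aligned with the suitability grid",
         call. = FALSE)
  s <- suitability$values
  z <- zones$raster$values
  rows <- purrr::map(seq_len(nrow(zones$table)), function(i) {
    id <- zones$table$zone_id[i]
    in_zone <- !is.na(z) & z == id & !is.na(s)
    tibble::tibble(
      zone_id = id, name = zones$table$name[i],
      mean_suitability = if (any(in_zone)) mean(s[in_zone]) else NA_real_,
      n_cells = sum(in_zone))
  })
  dplyr::bind_rows(rows)
}

#' Classify mean suitability into four categories
#'
#' Categories follow the conventional quartile cut points read as half-open
#' continuous intervals: low `<= 0.25`, moderate `(0.25, 0.50]`, high
#' `(0.50, 0.75]`, very high `> 0.75`.
#'
#' @param mean_suitability numeric vector in \[0, 1\] (NAs pass through).
#' @return An ordered factor with levels low < moderate < high < very_high.
#' @export
classify_suitability <- function(mean_suitability) {
  stopifnot(all(is.na(mean_suitability) |
                  (mean_suitability >= 0 & mean_suitability <= 1)))
  cut(mean_suitability, breaks = c(-Inf, 0.25, 0.50, 0.75, Inf),
      labels = c("low", "moderate", "high", "very_high"),
      right = TRUE, ordered_result = TRUE)
}

#' Zonal habitat-change summary across scenarios
#'
#' The accounting table behind habitat-change reporting: for every zone and
#' every scenario grid, the suitable area at the shared threshold, the
#' percent change relative to the `"current"` grid, the zonal mean
#' suitability, and its suitability category. A grand-total row
#' (`zone_id = 0`, name `"TOTAL"`) aggregates over all zones.
#'
#' @param grids named list of suitability [eco_grid]s; must contain
#'   `"current"`. Names are the scenario tags.
#' @param threshold binarisation threshold (MTSS).
#' @param zones a `zone_set`.
#' @param cell_area_km2 per-cell area (default 4.5).
#' @return A `suitability_summary` tibble: `zone_id`, `zone`,
#'   `total_area_km2`, `scenario`, `suitable_area_km2`,
#'   `percent_change_vs_current`, `new_colonization`, `mean_suitability`,
#'   `category`.
#' @export
change_summary <- function(grids, threshold, zones, cell_area_km2 = 4.5) {
  if (!"current" %in% names(grids))
    stop('`grids` must contain a "current" scenario', call. = FALSE)
  ref <- grids[["current"]]
  for (nm in names(grids))
    if (!same_geometry(ref, grids[[nm]]))
      stop(sprintf("scenario grid '%s' is not aligned with 'current'", nm),
           call. = FALSE)
  per_scenario <- purrr::map(names(grids), function(tag) {
    g <- grids[[tag]]
    b <- binarize(g, threshold, scenario_tag = tag)
    ar <- suitable_area(b, cell_area_km2 = cell_area_km2, zones = zones)
    mu <- zonal_mean_suitability(g, zones)
    tot <- tibble::tibble(
      zone_id = 0L, name = "TOTAL",
      suitable_area_km2 = sum(ar$suitable_area_km2),
      mean_suitability = {
        ok <- !is.na(g$values) & !is.na(zones$raster$values) &
          zones$raster$values != 0
        if (any(ok)) mean(g$values[ok]) else NA_real_
      })
    dplyr::bind_rows(
      dplyr::left_join(ar, mu[, c("zone_id", "mean_suitability")],
                       by = "zone_id"),
      tot) |>
      dplyr::mutate(scenario = tag)
  })
  long <- dplyr::bind_rows(per_scenario)
  cur <- long |>
    dplyr::filter(.data$scenario == "current") |>
    dplyr::select("zone_id", current_area = "suitable_area_km2")
  totals <- dplyr::bind_rows(
    dplyr::select(zones$table, "zone_id", "name", "total_area_km2"),
    tibble::tibble(zone_id = 0L, name = "TOTAL",
                   total_area_km2 = sum(zones$table$total_area_km2)))
  out <- long |>
    dplyr::left_join(cur, by = "zone_id") |>
    dplyr::left_join(totals[, c("zone_id", "total_area_km2")],
                     by = "zone_id") |>
    dplyr::mutate(
      percent_change_vs_current = percent_change(.data$suitable_area_km2,
                                                 .data$current_area),
      new_colonization = .data$current_area == 0 &
        .data$suitable_area_km2 > 0,
      category = classify_suitability(.data$mean_suitability)) |>
    dplyr::select("zone_id", zone = "name", "total_area_km2", "scenario",
                  "suitable_area_km2", "percent_change_vs_current",
                  "new_colonization", "mean_suitability", "category")
  attr(out, "threshold") <- threshold
  attr(out, "cell_area_km2") <- cell_area_km2
  class(out) <- c("suitability_summary", class(out))
  out
}

#' Plot a habitat-change summary
#'
#' Bar chart of suitable area per zone and scenario.
#'
#' @param object a `suitability_summary` from [change_summary()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot suitability_summary
#' @export
autoplot.suitability_summary <- function(object, ...) {
  df <- dplyr::filter(object, .data$zone != "TOTAL")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone,
                                   y = .data$suitable_area_km2,
                                   fill = .data$scenario)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(Suitable~area~(km^2)),
                  fill = "Scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
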