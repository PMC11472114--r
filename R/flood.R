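#' Flood depth at each building
#'
#' Looks up the depth-grid value of the cell containing each building point
#' under half-open cell ownership (a point on a shared edge belongs to the
#' cell to its north-east). No-data cells count as dry (depth 0), the
#' convention of flood grids that omit dry cells; buildings outside the grid
#' extent get depth 0 and are counted in the `n_outside` attribute.
#'
#' @param grid A depth [hazard_grid()] in metres.
#' @param buildings Data frame with `x`, `y` columns (projected metres, same
#'   system as the grid).
#' @return Numeric depths in metres, one per building, with attributes
#'   `n_outside` and `n_nodata`.
#' @export
building_depths <- function(grid, buildings) {
  if (nrow(buildings) == 0L) stop("building set is empty", call. = FALSE)
  idx <- point_cell_index(grid, buildings$x, buildings$y)
  outside <- is.na(idx)
  depth <- rep(0, nrow(buildings))
  v <- grid$values[idx[!outside]]
  n_nodata <- sum(is.na(v))
  v[is.na(v)] <- 0
  depth[!outside] <- v
  structure(depth, n_outside = sum(outside), n_nodata = n_nodata)
}

#' Flag buildings flooded above a depth threshold
#'
#' A building is flooded when its depth strictly exceeds the threshold: a
#' depth exactly at the 0.10 m default is not flooded.
#'
#' @param depths Numeric depths in metres (non-negative).
#' @param threshold_m Threshold in metres, > 0 (default 0.10).
#' @return Logical vector.
#' @export
flag_flooded <- function(depths, threshold_m = 0.10) {
  if (threshold_m <= 0) stop("`threshold_m` must be positive", call. = FALSE)
  if (any(depths < 0, na.rm = TRUE)) {
    stop("negative flood depths are not valid", call. = FALSE)
  }
  as.vector(depths) > threshold_m
}

#' Per-area flooded-building proportion and decile
#'
#' Aggregates building flood flags to areas: the proportion of an area's
#' buildings that are flooded, and the decile of that proportion across
#' areas (10 = most exposed). Areas with no buildings get a missing
#' proportion, take no part in the decile ranking, and are reported via the
#' `n_no_building_areas` attribute.
#'
#' @param flooded Logical flags, one per building.
#' @param building_area_id Area id of each building (`NA` = outside all
#'   areas).
#' @param area_id Character vector of all area ids (defines the output rows).
#' @param scenario Optional [flood_scenario()] carried into the output.
#' @return Data frame: `area_id`, `n_buildings`, `n_flooded`,
#'   `proportion_flooded`, `decile`, and scenario columns when supplied.
#' @export
area_flood_exposure <- function(flooded, building_area_id, area_id,
                                scenario = NULL) {
  stopifnot(length(flooded) == length(building_area_id))
  f <- factor(building_area_id, levels = area_id)
  n_b <- as.integer(table(f))
  n_f <- as.integer(tapply(flooded, f, sum, default = 0L))
  prop <- ifelse(n_b > 0, n_f / n_b, NA_real_)
  out <- data.frame(area_id = area_id, n_buildings = n_b, n_flooded = n_f,
                    proportion_flooded = prop, stringsAsFactors = FALSE)
  out$decile <- decile_rank(prop)
  if (!is.null(scenario)) {
    out$return_period_years <- scenario$return_period_years
    out$climate_pathway <- scenario$climate_pathway
    out$horizon_year <- scenario$horizon_year
    out$scenario_role <- scenario$role
  }
  structure(out,
            n_no_building_areas = sum(n_b == 0L),
            n_outside_buildings = sum(is.na(building_area_id)))
}

#' Flood exposure pipeline for one scenario grid
#'
#' Convenience wrapper: [building_depths()], [flag_flooded()] at the
#' configured threshold, then [area_flood_exposure()].
#'
#' @param grid Depth [hazard_grid()] (its metadata scenario, if any, is
#'   carried through).
#' @param buildings Data frame with `x`, `y`, `area_id`.
#' @param area_id All area ids.
#' @param config A [pipeline_config()].
#' @return See [area_flood_exposure()].
#' @export
flood_exposure <- function(grid, buildings, area_id,
                           config = pipeline_config()) {
  depths <- building_depths(grid, buildings)
  flooded <- flag_flooded(depths, config$flood_depth_threshold_m)
  area_flood_exposure(flooded, buildings$area_id, area_id,
                      scenario = grid$metadata$scenario)
}
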