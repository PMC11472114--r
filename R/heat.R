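#' Per-cell summer mean of daily maximum temperature
#'
#' Arithmetic mean of the daily maxima over every day of the configured
#' season months and years (default June-August 2015-2019); layers outside
#' the window are ignored.
#'
#' @param daily_tmax A [grid_stack()] of daily maximum temperatures (deg C).
#' @param config A [pipeline_config()].
#' @return A [hazard_grid()] of per-cell means.
#' @export
cell_mean_summer_tmax <- function(daily_tmax, config = pipeline_config()) {
  keep <- season_mask(daily_tmax$dates, config)
  if (!any(keep)) {
    stop("no days in the stack fall in the configured season/years",
         call. = FALSE)
  }
  m <- apply(daily_tmax$values[, , keep, drop = FALSE], c(1, 2), mean)
  stack_layer_grid(daily_tmax, m)
}

#' Per-cell fraction of warm days
#'
#' Fraction of in-season days whose daily mean temperature strictly exceeds
#' the threshold (default 15 deg C, the daily-mean level above which
#' temperature-related mortality risk rises in the region the default
#' configuration targets). A day exactly at the threshold does not count.
#'
#' @param daily_tmean A [grid_stack()] of daily mean temperatures (deg C).
#' @param threshold_c Threshold in degrees C.
#' @param config A [pipeline_config()].
#' @return A [hazard_grid()] of per-cell fractions in `[0, 1]`.
#' @export
cell_exceedance_fraction <- function(daily_tmean,
                                     threshold_c = 15.0,
                                     config = pipeline_config()) {
  keep <- season_mask(daily_tmean$dates, config)
  if (!any(keep)) {
    stop("no days in the stack fall in the configured season/years",
         call. = FALSE)
  }
  m <- apply(daily_tmean$values[, , keep, drop = FALSE] > threshold_c,
             c(1, 2), mean)
  stack_layer_grid(daily_tmean, m)
}

# Cells whose rectangle intersects the half-open area rectangle
# [xmin, xmax) x [ymin, ymax); used for the zero-building fallback.
area_cell_indices <- function(grid, xmin, ymin, xmax, ymax) {
  cs <- grid$cell_size
  c1 <- max(1L, floor((xmin - grid$origin[1]) / cs) + 1L)
  c2 <- min(ncol(grid$values), ceiling((xmax - grid$origin[1]) / cs))
  r1 <- max(1L, floor((ymin - grid$origin[2]) / cs) + 1L)
  r2 <- min(nrow(grid$values), ceiling((ymax - grid$origin[2]) / cs))
  if (c2 < c1 || r2 < r1) return(integer(0))
  as.vector(outer(r1:r2, (c1:c2 - 1L) * nrow(grid$values), `+`))
}

#' Building-weighted mean of a cell field over each area
#'
#' Zonal reduction that mirrors where people actually are: for area `a`,
#' `sum_c w_ac * v_c / sum_c w_ac`, where `w_ac` is the number of area-`a`
#' buildings falling in cell `c` (half-open cell ownership). Areas with no
#' buildings fall back to the unweighted mean over the cells intersecting the
#' area rectangle, flagged in the `fallback` column; an area intersecting no
#' cells gets a missing value.
#'
#' @param cell_values A [hazard_grid()] of per-cell values.
#' @param buildings Data frame with `x`, `y`, `area_id`.
#' @param areas Data frame with `area_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @return Data frame: `area_id`, `value`, `n_buildings` (weight used),
#'   `fallback` (logical).
#' @export
building_weighted_area_value <- function(cell_values, buildings, areas) {
  idx <- point_cell_index(cell_values, buildings$x, buildings$y)
  ok <- !is.na(idx)
  v_b <- cell_values$values[idx[ok]]
  f <- factor(buildings$area_id[ok], levels = areas$area_id)
  num <- tapply(v_b, f, sum, default = 0)
  n_b <- as.integer(table(f))
  value <- ifelse(n_b > 0, num / n_b, NA_real_)
  fallback <- n_b == 0L
  for (i in which(fallback)) {
    cells <- area_cell_indices(cell_values, areas$xmin[i], areas$ymin[i],
                               areas$xmax[i], areas$ymax[i])
    value[i] <- if (length(cells)) mean(cell_values$values[cells],
                                        na.rm = TRUE) else NA_real_
  }
  data.frame(area_id = areas$area_id, value = as.numeric(value),
             n_buildings = n_b, fallback = fallback,
             stringsAsFactors = FALSE)
}

#' Per-area heat exposure table
#'
#' Computes both heat metrics — summer mean daily-maximum temperature and
#' the warm-day exceedance fraction — reduces each to areas with
#' [building_weighted_area_value()], and ranks each independently into
#' deciles (10 = hottest / most exceedance).
#'
#' @param daily_tmax,daily_tmean [grid_stack()]s on a shared georeference.
#' @param buildings Data frame with `x`, `y`, `area_id`.
#' @param areas Data frame with `area_id` and bounding-box columns.
#' @param config A [pipeline_config()].
#' @return Data frame: `area_id`, `mean_summer_tmax`, `exceedance_fraction`,
#'   `decile_tmax`, `decile_exceed`, `n_buildings`, `fallback`.
#' @export
heat_exposure_table <- function(daily_tmax, daily_tmean, buildings, areas,
                                config = pipeline_config()) {
  tmax_cells <- cell_mean_summer_tmax(daily_tmax, config)
  exc_cells <- cell_exceedance_fraction(
    daily_tmean, config$heat_exceedance_threshold_c, config)
  a_tmax <- building_weighted_area_value(tmax_cells, buildings, areas)
  a_exc <- building_weighted_area_value(exc_cells, buildings, areas)
  data.frame(area_id = areas$area_id,
             mean_summer_tmax = a_tmax$value,
             exceedance_fraction = a_exc$value,
             decile_tmax = decile_rank(a_tmax$value),
             decile_exceed = decile_rank(a_exc$value),
             n_buildings = a_tmax$n_buildings,
             fallback = a_tmax$fallback,
             stringsAsFactors = FALSE)
}
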