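two_day_stack <- function(vals_by_day, dates, cell_size = 10) {
  a <- array(unlist(vals_by_day), c(1, 2, length(vals_by_day)))
  grid_stack(a, dates, cell_size = cell_size)
}

test_that("summer tmax mean averages in-season days and masks the rest", {
  cfg <- pipeline_config(years = 2015L)
  st <- two_day_stack(list(c(18, 18), c(22, 22)),
                      as.Date(c("2015-06-01", "2015-07-01")))
  expect_equal(as.vector(cell_mean_summer_tmax(st, cfg)$values), c(20, 20))
  # out-of-season layers are ignored entirely
  st2 <- two_day_stack(list(c(18, 18), c(22, 22), c(99, 99)),
                       as.Date(c("2015-06-01", "2015-07-01", "2015-05-01")))
  expect_equal(cell_mean_summer_tmax(st2, cfg)$values,
               cell_mean_summer_tmax(st, cfg)$values)
  st3 <- two_day_stack(list(c(1, 1)), as.Date("2014-06-01"))
  expect_error(cell_mean_summer_tmax(st3, cfg), "season")
})

test_that("exceedance counts strictly-above-threshold days only", {
  cfg <- pipeline_config(years = 2015L)
  st <- two_day_stack(list(c(16, 15), c(16, 14.9), c(16, 15.2)),
                      as.Date(c("2015-06-01", "2015-06-02", "2015-06-03")))
  f <- cell_exceedance_fraction(st, 15.0, cfg)
  expect_equal(as.vector(f$values), c(1, 1 / 3))   # 15.0 exactly not counted
  # non-increasing in the threshold
  f2 <- cell_exceedance_fraction(st, 15.5, cfg)
  expect_true(all(f2$values <= f$values))
  expect_true(all(f$values >= 0 & f$values <= 1))
})

test_that("building-weighted reduction matches hand-computed weights", {
  cells <- hazard_grid(matrix(c(10, 20), 1, 2), cell_size = 10)
  areas <- data.frame(area_id = "a", xmin = 0, ymin = 0, xmax = 20, ymax = 10)
  b <- data.frame(x = c(5, 15, 15, 15), y = rep(5, 4), area_id = "a")
  out <- building_weighted_area_value(cells, b, areas)
  expect_equal(out$value, 17.5)                    # (1*10 + 3*20) / 4
  expect_false(out$fallback)
  # all buildings in one cell: exactly that cell's value
  b1 <- data.frame(x = rep(15, 3), y = rep(5, 3), area_id = "a")
  expect_equal(building_weighted_area_value(cells, b1, areas)$value, 20)
  # equal counts per cell degenerate to the unweighted mean
  b2 <- data.frame(x = c(5, 15), y = c(5, 5), area_id = "a")
  expect_equal(building_weighted_area_value(cells, b2, areas)$value, 15)
})

test_that("zero-building areas fall back to the unweighted cell mean, flagged", {
  cells <- hazard_grid(matrix(c(10, 20), 1, 2), cell_size = 10)
  areas <- data.frame(area_id = c("a", "b"),
                      xmin = c(0, 100), ymin = 0, xmax = c(20, 120), ymax = 10)
  b <- data.frame(x = 5, y = 5, area_id = "a")
  out <- building_weighted_area_value(cells, b, areas)
  expect_equal(out$value[1], 10)
  expect_equal(out$fallback, c(FALSE, TRUE))
  expect_true(is.na(out$value[2]))                 # area intersects no cells
})

test_that("heat deciles track planted building density and not a null field", {
  r <- fixture_region(10, 11)
  cfg <- pipeline_config(years = 2015:2016)
  tp <- generate_daily_temperatures(r, cfg, uhi_strength = 3, seed = 6,
                                    cell_size = 500)
  h <- heat_exposure_table(tp$tmax, tp$tmean, r$buildings, r$areas, cfg)
  dens <- r$areas$building_count / r$areas$area_km2
  expect_gt(cor(h$decile_tmax, dens, method = "spearman"), 0.7)
  expect_true(all(h$exceedance_fraction >= 0 & h$exceedance_fraction <= 1))
  tp0 <- generate_daily_temperatures(r, cfg, uhi_strength = 0, seed = 6,
                                     cell_size = 500)
  h0 <- heat_exposure_table(tp0$tmax, tp0$tmean, r$buildings, r$areas, cfg)
  expect_lt(abs(cor(h0$decile_tmax, dens, method = "spearman")), 0.25)
})

test_that("deciles are invariant under strictly increasing transforms", {
  r <- fixture_region(6, 42)
  cfg <- pipeline_config(years = 2015L)
  tp <- generate_daily_temperatures(r, cfg, uhi_strength = 3, seed = 6,
                                    cell_size = 1000)
  cells <- cell_mean_summer_tmax(tp$tmax, cfg)
  v <- building_weighted_area_value(cells, r$buildings, r$areas)$value
  expect_identical(decile_rank(v), decile_rank(exp(v / 10) + 3 * v))
})
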