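test_that("generate_region builds the requested lattice deterministically", {
  r <- fixture_region(6, 42)
  expect_equal(nrow(r$areas), 36L)
  expect_true(all(r$areas$population >= 1000 & r$areas$population <= 3000))
  expect_equal(nrow(generate_region(2, seed = 7)$areas), 4L)
  expect_error(generate_region(1, seed = 1), ">= 2")
  # determinism: identical object on repeat call
  expect_identical(generate_region(4, seed = 3), generate_region(4, seed = 3))
  # latent factor is standardised and spatially smooth
  expect_equal(mean(r$areas$latent), 0, tolerance = 1e-10)
  expect_equal(sd(r$areas$latent), 1, tolerance = 1e-10)
})

test_that("every building lies inside exactly its own area and counts conserve", {
  r <- fixture_region(6, 42)
  b <- r$buildings
  a <- r$areas[match(b$area_id, r$areas$area_id), ]
  expect_true(all(b$x >= a$xmin & b$x < a$xmax &
                    b$y >= a$ymin & b$y < a$ymax))
  expect_equal(as.integer(table(factor(b$area_id, levels = r$areas$area_id))),
               as.integer(r$areas$building_count))
  expect_equal(sum(r$areas$building_count), nrow(b))
})

test_that("census counts respect binomial support and carry the planted signal", {
  reg <- fixture_registry()
  r <- fixture_region(6, 42)
  cen <- generate_census_counts(r, reg, effect_size = 1, seed = 5)
  for (i in seq_len(nrow(reg$metrics))) {
    num <- cen[[reg$metrics$numerator_field[i]]]
    den <- cen[[reg$metrics$denominator_field[i]]]
    expect_true(all(num >= 0 & num <= den))
  }
  # positive-polarity metrics correlate positively with the latent factor
  rho <- vapply(seq_len(nrow(reg$metrics)), function(i) {
    p <- cen[[reg$metrics$numerator_field[i]]] /
      cen[[reg$metrics$denominator_field[i]]]
    cor(p, r$areas$latent, method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0))
})

test_that("zero effect size yields no association with the latent factor", {
  reg <- fixture_registry()
  r <- fixture_region(10, 11)   # 100 areas for a stable null
  cen <- generate_census_counts(r, reg, effect_size = 0, seed = 5)
  p <- cen$n_health_bad / cen$population
  expect_lt(abs(cor(p, r$areas$latent, method = "spearman")), 0.25)
  expect_error(generate_census_counts(r, reg, effect_size = -1, seed = 1),
               ">= 0")
})

test_that("flood depths decay from the channel, clamp to dry, and repeat exactly", {
  r <- fixture_region(6, 42)
  g <- generate_flood_depths(r, cell_size = 100, seed = 9, h0 = 1.2,
                             decay = 1e-3, noise_sd = 0.15)
  expect_identical(g$values,
                   generate_flood_depths(r, cell_size = 100, seed = 9,
                                         h0 = 1.2, decay = 1e-3,
                                         noise_sd = 0.15)$values)
  nr <- nrow(g$values)
  cy <- (seq_len(nr) - 0.5) * g$cell_size
  dist <- abs(cy - 3000)             # channel runs along y = 3000
  # beyond the deterministic reach h0/decay the grid is exactly dry
  expect_true(any(dist > 1.2 / 1e-3))
  expect_true(all(g$values[dist > 1.2 / 1e-3, ] == 0))
  # rows at the channel are deeper on average than rows near the reach edge
  row_mean <- rowMeans(g$values)
  expect_gt(mean(row_mean[dist < 500]), mean(row_mean[dist > 1000]))
  expect_error(generate_flood_depths(r, cell_size = 0, seed = 1), "positive")
})

test_that("temperature stacks cover the configured calendar with tmax >= tmean", {
  r <- fixture_region(4, 2)
  cfg <- pipeline_config()
  tp <- generate_daily_temperatures(r, cfg, uhi_strength = 3, seed = 4,
                                    cell_size = 1000)
  expect_equal(dim(tp$tmax$values)[3], 92L * 5L)     # JJA x 2015-2019
  expect_identical(tp$tmax$dates, tp$tmean$dates)
  expect_true(all(tp$tmax$values >= tp$tmean$values))
  cfg1 <- pipeline_config(years = 2015L)
  expect_equal(dim(generate_daily_temperatures(
    r, cfg1, 0, seed = 4, cell_size = 1000)$tmax$values)[3], 92L)
  expect_error(generate_daily_temperatures(
    r, pipeline_config(season_months = 2L, years = integer(0)), 3, seed = 1),
    "no days")
  expect_error(generate_daily_temperatures(r, cfg, uhi_strength = -1,
                                           seed = 1), ">= 0")
})

test_that("urban-heat-island strength controls the spatial temperature signal", {
  r <- fixture_region(6, 42)
  cfg <- pipeline_config(years = 2015L)
  flat <- generate_daily_temperatures(r, cfg, uhi_strength = 0, seed = 4,
                                      cell_size = 1000)
  warm <- generate_daily_temperatures(r, cfg, uhi_strength = 3, seed = 4,
                                      cell_size = 1000)
  dens <- warm$truth$building_density
  mean_flat <- apply(flat$tmean$values, c(1, 2), mean)
  mean_warm <- apply(warm$tmean$values, c(1, 2), mean)
  # with no UHI the expected field is flat: cell means vary only by noise
  expect_lt(diff(range(mean_flat)), 0.5)
  # with UHI building density drives the seasonal mean field
  expect_gt(cor(as.vector(mean_warm), as.vector(dens)), 0.9)
  expect_gt(mean_warm[which.max(dens)], mean_warm[which.min(dens)])
})
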