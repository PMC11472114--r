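test_that("default registry has the published hierarchy shape and is valid", {
  reg <- fixture_registry()
  expect_equal(nrow(reg$metrics), 33L)
  expect_equal(nrow(reg$sub_domains), 9L)
  expect_equal(nrow(reg$domains), 4L)
  expect_equal(nrow(reg$separate_metrics), 2L)
  expect_setequal(reg$domains$domain_id,
                  c("adaptive_capacity", "health", "sensitivity",
                    "living_environment"))
  expect_length(validate_registry(reg), 0L)
  # equal weights at every level, normalised to sum one per sibling group
  expect_equal(sum(reg$domains$weight), 1)
  for (d in reg$domains$domain_id) {
    expect_equal(sum(reg$sub_domains$weight[reg$sub_domains$domain_id == d]), 1)
  }
  for (s in reg$sub_domains$sub_domain_id) {
    w <- reg$metrics$weight[reg$metrics$sub_domain_id == s]
    expect_equal(sum(w), 1)
    expect_true(all(abs(w - w[1]) < 1e-12))
  }
  expect_setequal(reg$separate_metrics$metric_id,
                  c("female", "population_density"))
})

test_that("registry serialisation round-trips through YAML exactly", {
  reg <- fixture_registry()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_registry(reg, tmp)
  expect_equal(load_registry(tmp), reg)
  shipped <- system.file("extdata", "default_registry.yaml",
                         package = "vulnmap")
  expect_equal(load_registry(shipped), reg)
})

test_that("load_registry normalises weights and names offenders on failure", {
  mini <- fixture_mini_registry()
  expect_equal(mini$sub_domains$weight[mini$sub_domains$domain_id == "d1"],
               c(0.5, 0.5))
  bad <- paste(
    "domains:",
    "- {domain_id: d1, label: D1, weight: 1}",
    "sub_domains:",
    "- {sub_domain_id: s1, label: S1, domain_id: d1, weight: 1}",
    "metrics:",
    "- {metric_id: m1, label: M1, sub_domain_id: sX}",
    sep = "\n")
  expect_error(load_registry(bad), "sX")
  dup <- paste(
    "domains:",
    "- {domain_id: d1, label: D1, weight: 1}",
    "sub_domains:",
    "- {sub_domain_id: s1, label: S1, domain_id: d1, weight: 1}",
    "metrics:",
    "- {metric_id: m1, label: M1, sub_domain_id: s1}",
    "- {metric_id: m1, label: M1b, sub_domain_id: s1}",
    sep = "\n")
  expect_error(load_registry(dup), "duplicate")
  neg <- paste(
    "domains:",
    "- {domain_id: d1, label: D1, weight: 1}",
    "sub_domains:",
    "- {sub_domain_id: s1, label: S1, domain_id: d1, weight: 1}",
    "metrics:",
    "- {metric_id: m1, label: M1, sub_domain_id: s1, weight: -1}",
    sep = "\n")
  expect_error(load_registry(neg), "negative weight")
})

test_that("validate_registry returns violations instead of throwing", {
  reg <- fixture_registry()
  broken <- reg
  broken$metrics$sub_domain_id[1] <- "nowhere"
  v <- validate_registry(broken)
  expect_true(any(grepl("nowhere", v)))
  broken2 <- reg
  broken2$domains$weight[1] <- -1
  expect_true(any(grepl("negative weight", validate_registry(broken2))))
  broken3 <- reg
  broken3$separate_metrics$metric_id[1] <- reg$metrics$metric_id[1]
  expect_true(any(grepl("both as indexed and separate",
                        validate_registry(broken3))))
})

test_that("pipeline config and scenario constructors enforce their domains", {
  cfg <- pipeline_config()
  expect_equal(cfg$flood_depth_threshold_m, 0.10)
  expect_equal(cfg$heat_exceedance_threshold_c, 15.0)
  expect_equal(cfg$season_months, c(6L, 7L, 8L))
  expect_equal(cfg$years, 2015:2019)
  expect_error(pipeline_config(flood_depth_threshold_m = 0), "positive")
  expect_error(pipeline_config(season_months = c(6, 13)), "months")
  expect_error(flood_scenario(return_period_years = 0), ">= 1")
  expect_equal(flood_scenario(1000, role = "disaster")$role, "disaster")
})
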