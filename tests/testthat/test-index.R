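ind_fixture <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(area_id = sprintf("a%02d", 1:n),
             m1 = runif(n), m2 = runif(n), m3 = runif(n), m4 = runif(n),
             stringsAsFactors = FALSE)
}

test_that("a one-metric sub-domain is the transform of that metric's rank", {
  reg <- fixture_mini_registry()
  ind <- ind_fixture()
  s1 <- aggregate_subdomain(ind, reg, "s1")
  expect_equal(s1, exponential_transform(as.numeric(rank_normalise(ind$m1)),
                                         reg$transform_scale))
})

test_that("an area strictly highest on every member metric scores 100", {
  reg <- fixture_mini_registry()
  ind <- ind_fixture()
  ind[3, c("m2", "m3")] <- 2    # strictly above all others on both s2 metrics
  s2 <- aggregate_subdomain(ind, reg, "s2")
  expect_equal(s2[3], 100)
  expect_true(all(s2[-3] < 100))
})

test_that("missing metrics renormalise weights; fully missing areas drop out", {
  reg <- fixture_mini_registry()
  ind <- ind_fixture()
  ind$m2[1] <- NA               # s2 falls back to m3 alone for area 1
  s2 <- aggregate_subdomain(ind, reg, "s2")
  expect_false(is.na(s2[1]))
  ind$m3[1] <- NA               # area 1 now missing the whole sub-domain
  s2b <- aggregate_subdomain(ind, reg, "s2")
  expect_true(is.na(s2b[1]))
  expect_error(aggregate_subdomain(ind, reg, "sX"), "no metrics")
})

test_that("domain aggregation is the weighted mean of sub-domain scores", {
  reg <- fixture_mini_registry()
  sub <- cbind(s1 = c(40, 10), s2 = c(60, 30), s3 = c(5, 7))
  expect_equal(aggregate_domain(sub, reg, "d1"), c(50, 20))
  # single-sub-domain domain passes through unchanged
  expect_equal(aggregate_domain(sub, reg, "d2"), c(5, 7))
  # weights {1, 0} select the first sub-domain
  reg2 <- reg
  reg2$sub_domains$weight <- c(1, 0, 1)
  expect_equal(aggregate_domain(sub, reg2, "d1"), c(40, 10))
  expect_error(aggregate_domain(sub[, 1:2], reg, "d2"), "s3")
})

test_that("compose_index tops out at 100, ranks, and preserves ties", {
  reg <- fixture_mini_registry()
  ind <- ind_fixture()
  ind[5, c("m1", "m2", "m3", "m4")] <- 3   # strictly most vulnerable overall
  ind[2, ] <- ind[7, ] <- ind[1, ]         # three identical areas
  ind$area_id <- sprintf("a%02d", seq_len(nrow(ind)))
  v <- vulnerability_index(ind, reg)
  expect_equal(v$index[5], 100)
  expect_equal(v$tercile[5], 3L)
  expect_equal(v$rank[5], 1L)
  expect_equal(v$index[2], v$index[1])
  expect_equal(v$index[7], v$index[1])
  expect_true(all(v$index >= 0 & v$index <= 100))
  expect_true(all(v[, startsWith(names(v), "sub_")] <= 100))
})

test_that("raising one +1-polarity metric never lowers that area's index", {
  reg <- fixture_mini_registry()
  set.seed(33)
  for (rep in 1:10) {
    ind <- ind_fixture(n = 12, seed = rep)
    i <- sample(12, 1); mcol <- sample(c("m1", "m2", "m3", "m4"), 1)
    v0 <- vulnerability_index(ind, reg)
    ind2 <- ind
    ind2[[mcol]][i] <- ind2[[mcol]][i] + runif(1, 0.1, 2)
    v1 <- vulnerability_index(ind2, reg)
    expect_gte(v1$index[i], v0$index[i] - 1e-9)
  }
})

test_that("the index recovers a planted latent factor and not a null one", {
  reg <- fixture_registry()
  r <- fixture_region(10, 11)
  cen <- generate_census_counts(r, reg, effect_size = 1, seed = 2)
  v <- vulnerability_index(compute_indicators(cen, reg), reg)
  expect_gt(cor(v$index, r$areas$latent, method = "spearman"), 0.8)
  cen0 <- generate_census_counts(r, reg, effect_size = 0, seed = 2)
  v0 <- vulnerability_index(compute_indicators(cen0, reg), reg)
  expect_lt(abs(cor(v0$index, r$areas$latent, method = "spearman")), 0.25)
  # no randomness in the index path: recomputation is identical
  expect_identical(v, vulnerability_index(compute_indicators(cen, reg), reg))
})

test_that("the second transform is switchable and changes only the scale", {
  reg <- fixture_mini_registry()
  ind <- ind_fixture()
  ind[4, c("m1", "m2", "m3", "m4")] <- 5   # strictly top everywhere
  v1 <- vulnerability_index(ind, reg, second_transform = TRUE)
  v2 <- vulnerability_index(ind, reg, second_transform = FALSE)
  expect_false(isTRUE(all.equal(v1$index, v2$index)))
  expect_true(all(v2$index >= 0 & v2$index <= 100))
  # the strictly-most-vulnerable area tops both variants
  expect_equal(which.max(v1$index), 4L)
  expect_equal(which.max(v2$index), 4L)
})
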