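# Shared fixtures built in code. The heavier synthetic objects are created
# once per test run and reused across files.

fixture_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- default_registry()
    reg
  }
})

# A mid-sized region with planted signal, shared by index/hazard tests.
fixture_region <- local({
  cache <- list()
  function(n_side = 6, seed = 42) {
    key <- paste(n_side, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_region(n_side, seed = seed)
    }
    cache[[key]]
  }
})

# Independent sort-free oracle for decile/tercile binning: normalised mean
# rank by direct counting, bin by linear search over bin edges.
oracle_bin <- function(v, k) {
  n <- sum(!is.na(v))
  vapply(v, function(x) {
    if (is.na(x)) return(NA_integer_)
    R <- (sum(v < x, na.rm = TRUE) + (sum(v == x, na.rm = TRUE) + 1) / 2) / n
    which(R <= (1:k) / k + 1e-12)[1L]
  }, integer(1))
}

# Small two-cell depth grid: left cell 0.05 m, right cell 0.25 m, 10 m cells.
fixture_two_cell_grid <- function() {
  hazard_grid(matrix(c(0.05, 0.25), 1, 2), origin = c(0, 0), cell_size = 10)
}

# Tiny registry: two sub-domains in one domain plus a second domain,
# convenient for hand-checkable aggregation tests.
fixture_mini_registry <- function() {
  yaml_text <- paste(
    "transform_scale: 23",
    "domains:",
    "- {domain_id: d1, label: D1, weight: 1}",
    "- {domain_id: d2, label: D2, weight: 1}",
    "sub_domains:",
    "- {sub_domain_id: s1, label: S1, domain_id: d1, weight: 1}",
    "- {sub_domain_id: s2, label: S2, domain_id: d1, weight: 1}",
    "- {sub_domain_id: s3, label: S3, domain_id: d2, weight: 1}",
    "metrics:",
    "- {metric_id: m1, label: M1, sub_domain_id: s1}",
    "- {metric_id: m2, label: M2, sub_domain_id: s2}",
    "- {metric_id: m3, label: M3, sub_domain_id: s2}",
    "- {metric_id: m4, label: M4, sub_domain_id: s3}",
    sep = "\n")
  load_registry(yaml_text)
}
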