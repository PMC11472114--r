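#' @title Metric registry: the vulnerability-index hierarchy
#' @description A `vulnmap_registry` holds the three-level hierarchy that the
#'   vulnerability index aggregates over — metrics grouped into sub-domains
#'   grouped into domains — plus any "separate" metrics that are mapped as
#'   standalone layers rather than folded into the index, and the spread
#'   parameter of the exponential rank transform.
#'
#' @details Each metric records the census-table column holding its numerator,
#'   the denominator base it is expressed against (`population`, `households`
#'   or `area_km2` for rate-type metrics such as population density), its
#'   polarity (+1 if a larger proportion means more vulnerable) and a source
#'   tag. Weights are stored per entity and renormalised to sum to one within
#'   each sibling group at construction time.
#' @name vulnmap_registry
NULL

new_registry <- function(domains, sub_domains, metrics, separate_metrics,
                         transform_scale = 23) {
  norm_within <- function(df, group) {
    if (nrow(df) == 0L) return(df)
    for (g in unique(df[[group]])) {
      i <- df[[group]] == g
      s <- sum(df$weight[i])
      if (s > 0) df$weight[i] <- df$weight[i] / s
    }
    df
  }
  domains$weight <- if (sum(domains$weight) > 0)
    domains$weight / sum(domains$weight) else domains$weight
  sub_domains <- norm_within(sub_domains, "domain_id")
  metrics <- norm_within(metrics, "sub_domain_id")
  structure(
    list(domains = domains, sub_domains = sub_domains, metrics = metrics,
         separate_metrics = separate_metrics,
         transform_scale = transform_scale),
    class = "vulnmap_registry")
}

metric_row <- function(metric_id, label, sub_domain_id,
                       denominator_field = "population", polarity = 1L,
                       source_tag = "census2021", is_rate = FALSE,
                       weight = 1, numerator_field = paste0("n_", metric_id)) {
  data.frame(metric_id = metric_id, label = label,
             numerator_field = numerator_field,
             denominator_field = denominator_field,
             sub_domain_id = sub_domain_id, polarity = as.integer(polarity),
             source_tag = source_tag, is_rate = is_rate, weight = weight,
             stringsAsFactors = FALSE)
}

#' Default metric registry
#'
#' The shipped hierarchy: 33 indexed metrics in 9 sub-domains under 4 domains
#' (sensitivity, adaptive capacity, health, living environment), plus 2
#' separate metrics (% female and population density) kept outside the index
#' and emitted as standalone layers. All weights are equal within each level;
#' every aspect is configurable through [load_registry()].
#'
#' Person-based metrics (age, language, income deprivation, unpaid care,
#' health, disability) use the resident population as denominator;
#' household-based metrics (car access, living alone, tenure, housing
#' condition) use the household count; population density is a rate over the
#' area in square kilometres.
#'
#' @return A `vulnmap_registry`.
#' @examples
#' reg <- default_registry()
#' nrow(reg$metrics)       # 33
#' nrow(reg$sub_domains)   # 9
#' @export
default_registry <- function() {
  domains <- data.frame(
    domain_id = c("sensitivity", "adaptive_capacity", "health",
                  "living_environment"),
    label = c("Sensitivity", "Adaptive capacity", "Health",
              "Living environment"),
    weight = 1, stringsAsFactors = FALSE)

  sd_row <- function(id, label, domain) {
    data.frame(sub_domain_id = id, label = label, domain_id = domain,
               weight = 1, stringsAsFactors = FALSE)
  }
  sub_domains <- rbind(
    sd_row("younger_people", "Younger people", "sensitivity"),
    sd_row("older_people", "Older people", "sensitivity"),
    sd_row("language", "Language", "adaptive_capacity"),
    sd_row("income", "Income", "adaptive_capacity"),
    sd_row("helping_others", "Helping others", "adaptive_capacity"),
    sd_row("health", "Health", "health"),
    sd_row("short_term_adaptation", "Short-term adaptation",
           "living_environment"),
    sd_row("longer_term_adaptation", "Longer-term adaptation",
           "living_environment"),
    sd_row("housing_condition", "Housing condition", "living_environment"))

  metrics <- rbind(
    metric_row("age_under5", "<5 years old", "younger_people"),
    metric_row("age_over65", ">65 years old", "older_people"),
    metric_row("age_over85", ">=85 years old", "older_people"),
    metric_row("eng_not_well",
               "Main language is not English: cannot speak English well",
               "language"),
    metric_row("eng_cannot",
               "Main language is not English: cannot speak English",
               "language"),
    metric_row("no_qualifications", "No qualifications", "income"),
    metric_row("quals_level1", "Level 1 qualifications", "income"),
    metric_row("quals_level2", "Level 2 qualifications", "income"),
    metric_row("inc_income_support",
               "Adults and children in Income Support families", "income",
               source_tag = "imd2019"),
    metric_row("inc_jsa",
               "Adults and children in income-based Jobseeker's Allowance families",
               "income", source_tag = "imd2019"),
    metric_row("inc_esa",
               "Adults and children in income-based Employment and Support Allowance families",
               "income", source_tag = "imd2019"),
    metric_row("inc_pension_credit",
               "Adults and children in Pension Credit (Guarantee) families",
               "income", source_tag = "imd2019"),
    metric_row("inc_universal_credit",
               "Adults and children in Universal Credit families (no work requirements group)",
               "income", source_tag = "imd2019"),
    metric_row("inc_tax_credits",
               "Adults and children in Working/Child Tax Credit families below 60% median income",
               "income", source_tag = "imd2019"),
    metric_row("inc_asylum_support",
               "Asylum seekers in receipt of subsistence and/or accommodation support",
               "income", source_tag = "imd2019"),
    metric_row("care_1_9", "Provides 9 h or less unpaid care a week",
               "helping_others"),
    metric_row("care_10_19", "Provides 10-19 h unpaid care a week",
               "helping_others"),
    metric_row("care_20_34", "Provides 20-34 h unpaid care a week",
               "helping_others"),
    metric_row("care_35_49", "Provides 35-49 h unpaid care a week",
               "helping_others"),
    metric_row("care_50plus", "Provides 50 or more hours unpaid care a week",
               "helping_others"),
    metric_row("health_bad", "Bad health", "health"),
    metric_row("health_very_bad", "Very bad health", "health"),
    metric_row("disab_limited_lot",
               "Disabled under the Equality Act: activities limited a lot",
               "health"),
    metric_row("disab_limited_little",
               "Disabled under the Equality Act: activities limited a little",
               "health"),
    metric_row("disab_condition_not_limited",
               "Long-term condition but day-to-day activities not limited",
               "health"),
    metric_row("no_car", "No cars or vans in household",
               "short_term_adaptation", denominator_field = "households"),
    metric_row("living_alone_66plus", "One-person household: aged 66+",
               "short_term_adaptation", denominator_field = "households"),
    metric_row("living_alone_other", "One-person household: other",
               "short_term_adaptation", denominator_field = "households"),
    metric_row("tenure_social_la",
               "Social rented: council or Local Authority",
               "longer_term_adaptation", denominator_field = "households"),
    metric_row("tenure_social_other", "Social rented: other social rented",
               "longer_term_adaptation", denominator_field = "households"),
    metric_row("tenure_private_landlord",
               "Private rented: private landlord or letting agency",
               "longer_term_adaptation", denominator_field = "households"),
    metric_row("tenure_private_other", "Private rented: other private rented",
               "longer_term_adaptation", denominator_field = "households"),
    metric_row("housing_poor_condition",
               "Homes failing the Decent Homes standard (modelled)",
               "housing_condition", denominator_field = "households",
               source_tag = "imd2019"))

  separate <- rbind(
    metric_row("female", "% female", NA_character_),
    metric_row("population_density", "Residents per km^2", NA_character_,
               denominator_field = "area_km2", is_rate = TRUE,
               numerator_field = "population"))

  new_registry(domains, sub_domains, metrics, separate)
}

#' Validate a metric registry
#'
#' Checks the structural invariants of a registry and returns the violations
#' found (an empty character vector means the registry is valid): unique
#' metric ids, resolvable sub-domain and domain references, non-negative
#' weights, legal polarities, numerator distinct from denominator, non-empty
#' sibling groups, separate metrics disjoint from indexed metrics, and a
#' positive transform scale.
#'
#' @param registry A `vulnmap_registry`.
#' @return Character vector of violation messages, each naming the offending
#'   entity and rule; empty if valid.
#' @export
validate_registry <- function(registry) {
  v <- character()
  m <- registry$metrics; sd <- registry$sub_domains; d <- registry$domains
  dup <- unique(m$metric_id[duplicated(m$metric_id)])
  for (id in dup) v <- c(v, sprintf("metric '%s': duplicate metric_id", id))
  orphan <- setdiff(m$sub_domain_id, sd$sub_domain_id)
  for (id in orphan) {
    bad <- m$metric_id[m$sub_domain_id %in% id]
    v <- c(v, sprintf("metric '%s': unresolved sub_domain_id '%s'",
                      bad, id))
  }
  orphan_sd <- setdiff(sd$domain_id, d$domain_id)
  for (id in orphan_sd) {
    bad <- sd$sub_domain_id[sd$domain_id %in% id]
    v <- c(v, sprintf("sub-domain '%s': unresolved domain_id '%s'", bad, id))
  }
  empty_sd <- setdiff(sd$sub_domain_id, m$sub_domain_id)
  for (id in empty_sd) v <- c(v, sprintf("sub-domain '%s': has no metrics", id))
  empty_d <- setdiff(d$domain_id, sd$domain_id)
  for (id in empty_d) v <- c(v, sprintf("domain '%s': has no sub-domains", id))
  for (tbl in list(m = m, sd = sd, d = d)) {
    neg <- tbl$weight < 0
    if (any(neg)) {
      nm <- tbl[[1L]][neg]
      v <- c(v, sprintf("'%s': negative weight", nm))
    }
  }
  bad_pol <- !m$polarity %in% c(-1L, 1L)
  for (id in m$metric_id[bad_pol]) {
    v <- c(v, sprintf("metric '%s': polarity must be +1 or -1", id))
  }
  same <- m$numerator_field == m$denominator_field
  for (id in m$metric_id[same]) {
    v <- c(v, sprintf("metric '%s': numerator_field equals denominator_field", id))
  }
  shared <- intersect(m$metric_id, registry$separate_metrics$metric_id)
  for (id in shared) {
    v <- c(v, sprintf("metric '%s': listed both as indexed and separate", id))
  }
  if (!is.numeric(registry$transform_scale) || registry$transform_scale <= 0) {
    v <- c(v, "registry: transform_scale must be positive")
  }
  v
}

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(x) if (is.na(x)) NULL else unname(x))
  })
}

records_to_df <- function(records, template) {
  rows <- lapply(records, function(r) {
    out <- template
    for (nm in names(template)) {
      val <- r[[nm]]
      if (!is.null(val)) out[[nm]] <- val
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a registry to a YAML configuration file
#'
#' @param registry A `vulnmap_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_registry()]
#' @export
write_registry <- function(registry, path) {
  doc <- list(
    transform_scale = registry$transform_scale,
    domains = df_to_records(registry$domains),
    sub_domains = df_to_records(registry$sub_domains),
    metrics = df_to_records(registry$metrics),
    separate_metrics = df_to_records(registry$separate_metrics))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Load and validate a registry from YAML
#'
#' Reads a metric-hierarchy configuration (the same shape that
#' [write_registry()] emits and that ships as
#' `system.file("extdata", "default_registry.yaml", package = "vulnmap")`),
#' normalises weights to sum to one within each level, and stops with the
#' full list of violations if any invariant fails.
#'
#' @param path Path to a YAML document (or a character scalar of YAML text).
#' @return A validated `vulnmap_registry`.
#' @export
load_registry <- function(path) {
  is_path <- length(path) == 1L && !grepl("\n", path, fixed = TRUE) &&
    file.exists(path)
  doc <- if (is_path) yaml::read_yaml(path) else yaml::yaml.load(path)
  m_template <- list(metric_id = NA_character_, label = NA_character_,
                     numerator_field = NA_character_,
                     denominator_field = "population",
                     sub_domain_id = NA_character_, polarity = 1L,
                     source_tag = "census2021", is_rate = FALSE, weight = 1)
  metrics <- records_to_df(doc$metrics, m_template)
  metrics$polarity <- as.integer(metrics$polarity)
  separate <- if (length(doc$separate_metrics))
    records_to_df(doc$separate_metrics, m_template) else
      records_to_df(list(), m_template)
  if (!is.null(separate)) separate$polarity <- as.integer(separate$polarity)
  sub_domains <- records_to_df(
    doc$sub_domains,
    list(sub_domain_id = NA_character_, label = NA_character_,
         domain_id = NA_character_, weight = 1))
  domains <- records_to_df(
    doc$domains,
    list(domain_id = NA_character_, label = NA_character_, weight = 1))
  scale <- if (is.null(doc$transform_scale)) 23 else doc$transform_scale
  miss_num <- is.na(metrics$numerator_field)
  metrics$numerator_field[miss_num] <- paste0("n_", metrics$metric_id[miss_num])
  reg <- new_registry(domains, sub_domains, metrics, separate, scale)
  v <- validate_registry(reg)
  if (length(v)) {
    stop("invalid registry configuration:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  }
  reg
}

#' @export
print.vulnmap_registry <- function(x, ...) {
  cat(sprintf(
    "<vulnmap_registry> %d metrics in %d sub-domains in %d domains; %d separate; scale = %g\n",
    nrow(x$metrics), nrow(x$sub_domains), nrow(x$domains),
    nrow(x$separate_metrics), x$transform_scale))
  invisible(x)
}

#' Flood scenario metadata
#'
#' Describes the flood grid being consumed: the return period, climate
#' pathway and horizon year it encodes, and whether it plays the "typical"
#' planning role (by convention a 1-in-100-year event under RCP 8.5 at 2050)
#' or the "disaster" role (1-in-1000-year, same projection).
#'
#' @param return_period_years Positive integer return period.
#' @param climate_pathway Label such as `"RCP8.5"`.
#' @param horizon_year Projection year.
#' @param role `"typical"` or `"disaster"`.
#' @return A `vulnmap_scenario` list.
#' @export
flood_scenario <- function(return_period_years = 100L,
                           climate_pathway = "RCP8.5",
                           horizon_year = 2050L,
                           role = c("typical", "disaster")) {
  role <- match.arg(role)
  if (return_period_years < 1) {
    stop("`return_period_years` must be >= 1", call. = FALSE)
  }
  structure(list(return_period_years = as.integer(return_period_years),
                 climate_pathway = climate_pathway,
                 horizon_year = as.integer(horizon_year), role = role),
            class = "vulnmap_scenario")
}

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the exposure pipeline: the flood-depth
#' cutoff above which a building counts as flooded (strictly greater than,
#' default 0.10 m), the daily-mean temperature above which a day counts as a
#' mortality-relevant exceedance (strictly greater than, default 15 degrees
#' C), the summer season window (months 6-8 of 2015-2019 by default), the
#' decile/tercile counts, the heat metric fed to the risk matrix, and the two
#' flood scenarios.
#'
#' @param flood_depth_threshold_m Depth threshold in metres, > 0.
#' @param heat_exceedance_threshold_c Daily-mean temperature threshold, deg C.
#' @param season_months Integer months (subset of 1..12).
#' @param years Integer years of the temperature record.
#' @param n_deciles,n_terciles Number of rank bins for hazard display and
#'   risk-matrix classification.
#' @param heat_metric Which heat metric feeds the risk matrix:
#'   `"mean_tmax"` (default) or `"exceedance"`.
#' @param second_transform Apply the exponential transform again when domain
#'   scores are combined into the overall index (default `TRUE`).
#' @param rng_seed Integer seed for synthetic runs.
#' @param scenario_typical,scenario_disaster [flood_scenario()] metadata.
#' @return A `vulnmap_config` list.
#' @export
pipeline_config <- function(flood_depth_threshold_m = 0.10,
                            heat_exceedance_threshold_c = 15.0,
                            season_months = c(6L, 7L, 8L),
                            years = 2015:2019,
                            n_deciles = 10L, n_terciles = 3L,
                            heat_metric = c("mean_tmax", "exceedance"),
                            second_transform = TRUE,
                            rng_seed = 1L,
                            scenario_typical = flood_scenario(100L, role = "typical"),
                            scenario_disaster = flood_scenario(1000L, role = "disaster")) {
  heat_metric <- match.arg(heat_metric)
  if (flood_depth_threshold_m <= 0 || heat_exceedance_threshold_c <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (!all(season_months %in% 1:12)) {
    stop("`season_months` must be months in 1..12", call. = FALSE)
  }
  structure(list(flood_depth_threshold_m = flood_depth_threshold_m,
                 heat_exceedance_threshold_c = heat_exceedance_threshold_c,
                 season_months = as.integer(season_months),
                 years = as.integer(years),
                 n_deciles = as.integer(n_deciles),
                 n_terciles = as.integer(n_terciles),
                 heat_metric = heat_metric,
                 second_transform = isTRUE(second_transform),
                 rng_seed = as.integer(rng_seed),
                 scenario_typical = scenario_typical,
                 scenario_disaster = scenario_disaster),
            class = "vulnmap_config")
}
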