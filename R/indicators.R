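#' Compute per-area metric indicators from census counts
#'
#' Converts raw counts into the per-area proportions (or rates) the index and
#' hazard modules consume: `numerator / denominator` for every metric in the
#' registry (indexed and separate). A zero denominator yields a missing value
#' and the area is retained. Proportions marginally outside `[0, 1]` from
#' floating error are clipped; a numerator genuinely exceeding its
#' denominator is a data error naming the area and metric. Rate-type metrics
#' (population density, residents per km^2) are not range-restricted.
#'
#' @param census Data frame with `area_id`, every denominator base column and
#'   every numerator column named by the registry.
#' @param registry A `vulnmap_registry`.
#' @return Data frame with `area_id` and one column per metric id.
#' @examples
#' reg <- default_registry()
#' region <- generate_region(3, seed = 1)
#' census <- generate_census_counts(region, reg, effect_size = 1, seed = 1)
#' ind <- compute_indicators(census, reg)
#' @export
compute_indicators <- function(census, registry) {
  if (!"area_id" %in% names(census)) {
    stop("census table must contain an `area_id` column", call. = FALSE)
  }
  if (nrow(census) == 0L) stop("census table has no areas", call. = FALSE)
  if (anyDuplicated(census$area_id)) {
    stop("duplicate area_id in census table: ",
         paste(unique(census$area_id[duplicated(census$area_id)]),
               collapse = ", "), call. = FALSE)
  }
  all_m <- rbind(registry$metrics, registry$separate_metrics)
  need <- unique(c(all_m$numerator_field, all_m$denominator_field))
  missing_cols <- setdiff(need, names(census))
  if (length(missing_cols)) {
    stop("census table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(area_id = as.character(census$area_id),
                    stringsAsFactors = FALSE)
  tol <- 1e-9
  for (i in seq_len(nrow(all_m))) {
    num <- as.numeric(census[[all_m$numerator_field[i]]])
    den <- as.numeric(census[[all_m$denominator_field[i]]])
    v <- ifelse(is.na(den) | den == 0, NA_real_, num / den)
    if (!all_m$is_rate[i]) {
      bad <- !is.na(v) & (v > 1 + tol | v < -tol)
      if (any(bad)) {
        stop(sprintf(
          "metric '%s': numerator exceeds denominator in area(s) %s",
          all_m$metric_id[i],
          paste(out$area_id[bad], collapse = ", ")), call. = FALSE)
      }
      v <- pmin(1, pmax(0, v))
    }
    out[[all_m$metric_id[i]]] <- v
  }
  out
}

#' Summarise missingness of an indicator table
#'
#' @param indicators A [compute_indicators()] result.
#' @return List with `per_metric` and `per_area` missing fractions and the
#'   `overall` fraction.
#' @export
summarise_missingness <- function(indicators) {
  if (nrow(indicators) == 0L) {
    stop("indicator table has no areas", call. = FALSE)
  }
  m <- as.matrix(indicators[, setdiff(names(indicators), "area_id"),
                            drop = FALSE])
  miss <- is.na(m)
  list(per_metric = colMeans(miss),
       per_area = stats::setNames(rowMeans(miss), indicators$area_id),
       overall = mean(miss))
}
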