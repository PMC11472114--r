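#' Aggregate one sub-domain score from metric indicators
#'
#' The first level of the hierarchical index: each member metric is
#' rank-normalised across areas with its polarity, the normalised ranks are
#' combined as a weighted mean (weights renormalised over the metrics that
#' are non-missing for each area), and the combined values are rank-normalised
#' again and pushed through the exponential transform to a 0-100 score. An
#' area missing every member metric gets a missing score.
#'
#' @param indicators A [compute_indicators()] result.
#' @param registry A `vulnmap_registry`.
#' @param sub_domain_id Which sub-domain to aggregate.
#' @return Numeric vector of scores in `(0, 100]`, aligned with
#'   `indicators$area_id`.
#' @export
aggregate_subdomain <- function(indicators, registry, sub_domain_id) {
  mm <- registry$metrics[registry$metrics$sub_domain_id == sub_domain_id, ,
                         drop = FALSE]
  if (nrow(mm) == 0L) {
    stop(sprintf("sub-domain '%s' has no metrics", sub_domain_id),
         call. = FALSE)
  }
  missing_cols <- setdiff(mm$metric_id, names(indicators))
  if (length(missing_cols)) {
    stop(sprintf("indicator table lacks metric column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  ranks <- vapply(seq_len(nrow(mm)), function(i) {
    rank_normalise(indicators[[mm$metric_id[i]]], mm$polarity[i])
  }, numeric(nrow(indicators)))
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = nrow(indicators))
  combined <- weighted_mean_renorm(ranks, mm$weight)
  score <- rep(NA_real_, length(combined))
  ok <- !is.na(combined)
  if (!any(ok)) stop("all areas missing for sub-domain", call. = FALSE)
  score[ok] <- exponential_transform(rank_normalise(combined)[ok],
                                     registry$transform_scale)
  score
}

#' Aggregate sub-domain scores into a domain score
#'
#' Weighted mean of the member sub-domain scores on their 0-100 scale,
#' weights renormalised over non-missing members per area; a
#' single-sub-domain domain passes through unchanged.
#'
#' @param sub_scores Data frame (or matrix) of per-area sub-domain scores,
#'   columns named by `sub_domain_id`.
#' @param registry A `vulnmap_registry`.
#' @param domain_id Which domain to aggregate.
#' @return Numeric vector of per-area domain scores in `(0, 100]`.
#' @export
aggregate_domain <- function(sub_scores, registry, domain_id) {
  sds <- registry$sub_domains[registry$sub_domains$domain_id == domain_id, ,
                              drop = FALSE]
  if (nrow(sds) == 0L) {
    stop(sprintf("domain '%s' has no sub-domains", domain_id), call. = FALSE)
  }
  missing_cols <- setdiff(sds$sub_domain_id, colnames(sub_scores))
  if (length(missing_cols)) {
    stop(sprintf("sub-domain score column(s) missing: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(sub_scores)[, sds$sub_domain_id, drop = FALSE])
  weighted_mean_renorm(x, sds$weight)
}

#' Compose the overall vulnerability index from domain scores
#'
#' Each domain score is rank-normalised across areas and (by default)
#' exponential-transformed, then the transformed domain scores are combined
#' as a weighted sum with the registry's domain weights. Areas missing any
#' domain carry a missing index and no tercile. The overall rank uses the
#' convention rank 1 = most vulnerable.
#'
#' @param domain_scores Data frame/matrix of per-area domain scores, columns
#'   named by `domain_id`; rows aligned with `area_id`.
#' @param registry A `vulnmap_registry`.
#' @param area_id Character vector of area ids aligned with the rows.
#' @param second_transform Re-apply the exponential transform at this level
#'   (default `TRUE`, the convention of the deprivation-index methodology the
#'   hierarchy follows); if `FALSE` the raw domain scores are combined.
#' @return Data frame: `area_id`, one `domain_<id>` column per transformed
#'   domain score, `index` (0-100), `rank` (1 = most vulnerable) and
#'   `tercile` (3 = most vulnerable).
#' @export
compose_index <- function(domain_scores, registry, area_id,
                          second_transform = TRUE) {
  d <- registry$domains
  missing_cols <- setdiff(d$domain_id, colnames(domain_scores))
  if (length(missing_cols)) {
    stop(sprintf("domain score column(s) missing: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(domain_scores)[, d$domain_id, drop = FALSE])
  tx <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    if (!any(ok)) next
    r <- rank_normalise(x[, j])
    tx[, j] <- if (second_transform)
      exponential_transform(r, registry$transform_scale) else x[, j]
  }
  complete <- rowSums(is.na(tx)) == 0L
  index <- rep(NA_real_, nrow(tx))
  index[complete] <- as.vector(tx[complete, , drop = FALSE] %*% d$weight)
  rk <- rep(NA_integer_, length(index))
  rk[complete] <- as.integer(rank(-index[complete], ties.method = "min"))
  out <- data.frame(area_id = area_id, stringsAsFactors = FALSE)
  for (j in seq_along(d$domain_id)) {
    out[[paste0("domain_", d$domain_id[j])]] <- tx[, j]
  }
  out$index <- index
  out$rank <- rk
  out$tercile <- tercile_classify(index)
  out
}

#' Full hierarchical vulnerability index
#'
#' Runs the three aggregation levels in sequence — metric ranks to sub-domain
#' scores ([aggregate_subdomain()]), sub-domain to domain scores
#' ([aggregate_domain()]), domain scores to the overall 0-100 index
#' ([compose_index()]) — and returns one row per area with every
#' intermediate level attached.
#'
#' @param indicators A [compute_indicators()] result.
#' @param registry A `vulnmap_registry`.
#' @param second_transform See [compose_index()].
#' @return Data frame: `area_id`, `sub_<sub_domain_id>` scores,
#'   `domain_<domain_id>` transformed scores, `index`, `rank`, `tercile`.
#' @export
vulnerability_index <- function(indicators, registry, second_transform = TRUE) {
  sub_ids <- registry$sub_domains$sub_domain_id
  sub_scores <- vapply(sub_ids, function(id)
    aggregate_subdomain(indicators, registry, id),
    numeric(nrow(indicators)))
  if (!is.matrix(sub_scores)) {
    sub_scores <- matrix(sub_scores, nrow = nrow(indicators),
                         dimnames = list(NULL, sub_ids))
  }
  dom_ids <- registry$domains$domain_id
  dom_scores <- vapply(dom_ids, function(id)
    aggregate_domain(sub_scores, registry, id), numeric(nrow(indicators)))
  if (!is.matrix(dom_scores)) {
    dom_scores <- matrix(dom_scores, nrow = nrow(indicators),
                         dimnames = list(NULL, dom_ids))
  }
  res <- compose_index(dom_scores, registry, indicators$area_id,
                       second_transform = second_transform)
  subs <- as.data.frame(sub_scores)
  names(subs) <- paste0("sub_", sub_ids)
  cbind(res["area_id"], subs, res[, setdiff(names(res), "area_id")])
}
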