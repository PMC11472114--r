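#' Cross-classify vulnerability against hazard exposure on a 3x3 risk matrix
#'
#' Each area's vulnerability tercile (from the overall index) is crossed with
#' the tercile of a continuous hazard-exposure metric, giving a cell code
#' `(v - 1) * 3 + h` in 1..9 and a label `"V{v}-H{h}"`. Hazard terciles are
#' computed from the continuous metric itself (not by collapsing deciles,
#' which do not partition evenly into three) over the areas present on both
#' sides. Areas missing either side get missing cells and are counted in the
#' `n_unclassified` attribute.
#'
#' @param vulnerability A [vulnerability_index()] result (needs `area_id`,
#'   `index`, `tercile`).
#' @param hazard_values Data frame with `area_id` and `value` (continuous
#'   exposure metric).
#' @param hazard_name `"heat"` or `"flood"` (free label).
#' @param scenario Optional [flood_scenario()] metadata.
#' @return Data frame: `area_id`, `vulnerability_tercile`, `hazard_tercile`,
#'   `cell_code`, `cell_label`, `hazard_name` (+ scenario columns).
#' @export
build_risk_matrix <- function(vulnerability, hazard_values, hazard_name,
                              scenario = NULL) {
  stopifnot(all(c("area_id", "tercile") %in% names(vulnerability)),
            all(c("area_id", "value") %in% names(hazard_values)))
  common <- intersect(vulnerability$area_id, hazard_values$area_id)
  if (length(common) == 0L) {
    stop("vulnerability and hazard tables share no areas", call. = FALSE)
  }
  out <- data.frame(area_id = vulnerability$area_id,
                    vulnerability_tercile = vulnerability$tercile,
                    stringsAsFactors = FALSE)
  hv <- hazard_values$value[match(out$area_id, hazard_values$area_id)]
  out$hazard_tercile <- tercile_classify(hv)
  ok <- !is.na(out$vulnerability_tercile) & !is.na(out$hazard_tercile)
  out$cell_code <- ifelse(ok, (out$vulnerability_tercile - 1L) * 3L +
                            out$hazard_tercile, NA_integer_)
  out$cell_label <- ifelse(ok, sprintf("V%d-H%d", out$vulnerability_tercile,
                                       out$hazard_tercile), NA_character_)
  out$hazard_name <- hazard_name
  if (!is.null(scenario)) {
    out$return_period_years <- scenario$return_period_years
    out$climate_pathway <- scenario$climate_pathway
    out$horizon_year <- scenario$horizon_year
    out$scenario_role <- scenario$role
  }
  structure(out, n_unclassified = sum(!ok))
}

#' Summarise a risk-matrix table
#'
#' @param result A [build_risk_matrix()] result.
#' @return List with `counts` (3x3 matrix, vulnerability terciles as rows),
#'   `row_marginal`, `col_marginal` and `n_classified`.
#' @export
matrix_summary <- function(result) {
  ok <- !is.na(result$cell_code)
  if (!any(ok)) stop("no classified areas in the risk-matrix table",
                     call. = FALSE)
  counts <- table(factor(result$vulnerability_tercile[ok], levels = 1:3),
                  factor(result$hazard_tercile[ok], levels = 1:3))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(vulnerability = paste0("V", 1:3),
                                   hazard = paste0("H", 1:3)))
  list(counts = counts,
       row_marginal = rowSums(counts),
       col_marginal = colSums(counts),
       n_classified = sum(counts))
}
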