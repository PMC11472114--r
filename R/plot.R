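#' Static bivariate choropleth of a risk-matrix layer
#'
#' Draws the rectangular areas of a region coloured by their 3x3 risk-matrix
#' cell, with the conventional bivariate palette (vulnerability deepening
#' towards blue, hazard towards red, joint risk towards dark purple), and a
#' 3x3 legend. Intended for the synthetic lattice and any rectangular-area
#' dataset; unclassified areas are drawn grey.
#'
#' @param areas Data frame with `area_id`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @param risk A [build_risk_matrix()] result.
#' @param main Plot title.
#' @return Invisibly, the named palette used.
#' @export
plot_risk_map <- function(areas, risk, main = "") {
  pal <- c("V1-H1" = "#e8e8e8", "V1-H2" = "#e4acac", "V1-H3" = "#c85a5a",
           "V2-H1" = "#b0d5df", "V2-H2" = "#ad9ea5", "V2-H3" = "#985356",
           "V3-H1" = "#64acbe", "V3-H2" = "#627f8c", "V3-H3" = "#574249")
  lab <- risk$cell_label[match(areas$area_id, risk$area_id)]
  col <- pal[lab]
  col[is.na(col)] <- "#bbbbbb"
  graphics::plot(NA, xlim = c(min(areas$xmin), max(areas$xmax)),
                 ylim = c(min(areas$ymin), max(areas$ymax)),
                 asp = 1, xlab = "x (m)", ylab = "y (m)", main = main)
  graphics::rect(areas$xmin, areas$ymin, areas$xmax, areas$ymax,
                 col = col, border = "white", lwd = 0.3)
  invisible(pal)
}
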