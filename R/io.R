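#' Write area polygons (with attributes) to GeoJSON
#'
#' Emits a `FeatureCollection` of axis-aligned rectangle polygons built from
#' the areas' bounding boxes, one feature per area, with every non-geometry
#' column as feature properties. A legacy `crs` member records the projected
#' coordinate system name so readers can refuse geographic coordinates.
#'
#' @param areas Data frame with `area_id`, `xmin`, `ymin`, `xmax`, `ymax`;
#'   any further columns become properties.
#' @param path Output `.geojson` path.
#' @param crs_name Name recorded in the `crs` member (default a local planar
#'   metric system).
#' @return `path`, invisibly.
#' @export
write_geojson_areas <- function(areas, path,
                                crs_name = "urn:vulnmap:local-planar-metre") {
  prop_cols <- setdiff(names(areas), c("xmin", "ymin", "xmax", "ymax"))
  features <- lapply(seq_len(nrow(areas)), function(i) {
    ring <- list(
      c(areas$xmin[i], areas$ymin[i]), c(areas$xmax[i], areas$ymin[i]),
      c(areas$xmax[i], areas$ymax[i]), c(areas$xmin[i], areas$ymax[i]),
      c(areas$xmin[i], areas$ymin[i]))
    props <- as.list(areas[i, prop_cols, drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  doc <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = crs_name)),
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

geographic_crs_names <- c("urn:ogc:def:crs:OGC:1.3:CRS84",
                          "urn:ogc:def:crs:EPSG::4326", "EPSG:4326")

#' Read area polygons from GeoJSON
#'
#' Parses a polygon `FeatureCollection`, checks that area ids are present and
#' unique and that the coordinate system is projected (plain GeoJSON without
#' a `crs` member is WGS84 longitude/latitude by specification, which this
#' tool refuses: reproject to a metric planar system first). Ring
#' coordinates are kept, and the per-feature bounding box is extracted into
#' the columns the exposure modules use.
#'
#' @param path Path to a `.geojson` file.
#' @param id_property Property holding the area id (default `"area_id"`).
#' @return Data frame with `area_id`, bounding-box columns and any further
#'   properties; full ring coordinates in attribute `geometry` (named list
#'   of matrices).
#' @export
read_area_polygons <- function(path, id_property = "area_id") {
  doc <- jsonlite::read_json(path)
  crs <- doc$crs$properties$name
  if (is.null(crs) || crs %in% geographic_crs_names) {
    stop(paste0(
      "area polygons are in geographic coordinates (or carry no crs); ",
      "reproject to a projected metric system and record it in the ",
      "GeoJSON `crs` member"), call. = FALSE)
  }
  feats <- doc$features
  if (length(feats) == 0L) stop("no features in ", path, call. = FALSE)
  rows <- lapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature without '", id_property, "' property",
                          call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    props <- f$properties
    props <- props[!vapply(props, is.null, TRUE)]
    list(id = as.character(id), xy = xy, props = props)
  })
  ids <- vapply(rows, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate area id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(area_id = ids, stringsAsFactors = FALSE)
  out$xmin <- vapply(rows, function(r) min(r$xy[, 1]), 0)
  out$ymin <- vapply(rows, function(r) min(r$xy[, 2]), 0)
  out$xmax <- vapply(rows, function(r) max(r$xy[, 1]), 0)
  out$ymax <- vapply(rows, function(r) max(r$xy[, 2]), 0)
  extra <- setdiff(unique(unlist(lapply(rows, function(r) names(r$props)))),
                   id_property)
  for (nm in extra) {
    vals <- lapply(rows, function(r) r$props[[nm]])
    out[[nm]] <- unlist(ifelse(vapply(vals, is.null, TRUE), NA, vals))
  }
  geoms <- lapply(rows, `[[`, "xy")
  names(geoms) <- ids
  attr(out, "geometry") <- geoms
  out
}

#' Assign points to areas
#'
#' Returns the containing area id for each point, `NA` when outside all
#' areas. Axis-aligned rectangular areas (the synthetic lattice, and any
#' boundary file whose rings are rectangles) use a vectorised half-open
#' bounding-box test `[xmin, xmax) x [ymin, ymax)`; general polygons fall
#' back to even-odd ray casting against the stored rings.
#'
#' @param x,y Point coordinates (projected metres).
#' @param areas A data frame from [read_area_polygons()] or a region's
#'   `areas` table.
#' @return Character vector of area ids.
#' @export
assign_areas <- function(x, y, areas) {
  geoms <- attr(areas, "geometry")
  is_rect <- function(xy, i) {
    pts <- unique(xy)
    corners <- rbind(c(areas$xmin[i], areas$ymin[i]),
                     c(areas$xmax[i], areas$ymin[i]),
                     c(areas$xmax[i], areas$ymax[i]),
                     c(areas$xmin[i], areas$ymax[i]))
    nrow(pts) == 4L &&
      all(apply(corners, 1L, function(p)
        any(pts[, 1] == p[1] & pts[, 2] == p[2])))
  }
  rectangular <- if (is.null(geoms)) TRUE else
    all(vapply(seq_len(nrow(areas)),
               function(i) is_rect(geoms[[areas$area_id[i]]], i), TRUE))
  out <- rep(NA_character_, length(x))
  if (rectangular) {
    for (i in seq_len(nrow(areas))) {
      hit <- x >= areas$xmin[i] & x < areas$xmax[i] &
        y >= areas$ymin[i] & y < areas$ymax[i] & is.na(out)
      out[hit] <- areas$area_id[i]
    }
    return(out)
  }
  for (i in seq_len(nrow(areas))) {
    ring <- geoms[[areas$area_id[i]]]
    cand <- which(is.na(out) & x >= areas$xmin[i] & x <= areas$xmax[i] &
                    y >= areas$ymin[i] & y <= areas$ymax[i])
    if (!length(cand)) next
    inside <- point_in_ring(x[cand], y[cand], ring)
    out[cand[inside]] <- areas$area_id[i]
  }
  out
}

# Even-odd rule point-in-polygon for one ring.
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) n <- n - 1L
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp, precision = 15L)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline and write map-ready outputs
#'
#' Generates a synthetic study region, computes indicators, the hierarchical
#' vulnerability index, flood exposure under the typical and disaster
#' scenarios, heat exposure, and the heat and flood risk matrices, then
#' writes every table as CSV, the joined per-area dataset as GeoJSON, the
#' ground-truth record as JSON and a run manifest. Outputs are byte-identical
#' across reruns with the same configuration and seed (the manifest, which
#' carries a timestamp, is the only file allowed to differ).
#'
#' @param out_dir Output directory (created if needed).
#' @param n_side Areas per side of the synthetic region.
#' @param seed Master seed (overrides `config$rng_seed`).
#' @param config A [pipeline_config()].
#' @param registry A `vulnmap_registry`.
#' @param effect_size,uhi_strength Planted signal strengths (see
#'   [generate_census_counts()] and [generate_daily_temperatures()]).
#' @param flood_h0_typical,flood_h0_disaster Channel depths (m) of the two
#'   scenario grids.
#' @param flood_cell_size,temp_cell_size Grid resolutions in metres.
#' @param write_grids Also write the flood grids as ESRI ASCII rasters
#'   (default `FALSE`; they are large).
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, n_side = 20L, seed = NULL,
                         config = pipeline_config(),
                         registry = default_registry(),
                         effect_size = 1, uhi_strength = 3,
                         flood_h0_typical = 1.2, flood_h0_disaster = 2.0,
                         flood_cell_size = 50, temp_cell_size = 500,
                         write_grids = FALSE) {
  seed <- if (is.null(seed)) config$rng_seed else as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  region <- generate_region(n_side, seed)
  census <- generate_census_counts(region, registry, effect_size, seed)
  indicators <- compute_indicators(census, registry)
  missing <- summarise_missingness(indicators)
  vuln <- vulnerability_index(indicators, registry,
                              second_transform = config$second_transform)

  grid_typical <- generate_flood_depths(
    region, flood_cell_size, seed, h0 = flood_h0_typical,
    scenario = config$scenario_typical)
  grid_disaster <- generate_flood_depths(
    region, flood_cell_size, seed, h0 = flood_h0_disaster,
    scenario = config$scenario_disaster)
  flood_typ <- flood_exposure(grid_typical, region$buildings,
                              region$areas$area_id, config)
  flood_dis <- flood_exposure(grid_disaster, region$buildings,
                              region$areas$area_id, config)

  temps <- generate_daily_temperatures(region, config, uhi_strength, seed,
                                       cell_size = temp_cell_size)
  heat <- heat_exposure_table(temps$tmax, temps$tmean, region$buildings,
                              region$areas, config)

  heat_metric_col <- if (config$heat_metric == "mean_tmax")
    "mean_summer_tmax" else "exceedance_fraction"
  risk_heat <- build_risk_matrix(
    vuln, data.frame(area_id = heat$area_id, value = heat[[heat_metric_col]]),
    hazard_name = "heat")
  risk_flood_typ <- build_risk_matrix(
    vuln, data.frame(area_id = flood_typ$area_id,
                     value = flood_typ$proportion_flooded),
    hazard_name = "flood", scenario = config$scenario_typical)
  risk_flood_dis <- build_risk_matrix(
    vuln, data.frame(area_id = flood_dis$area_id,
                     value = flood_dis$proportion_flooded),
    hazard_name = "flood", scenario = config$scenario_disaster)

  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  tables <- list(census = census, indicators = indicators,
                 vulnerability = vuln, flood_typical = flood_typ,
                 flood_disaster = flood_dis, heat = heat,
                 risk_heat = risk_heat, risk_flood_typical = risk_flood_typ,
                 risk_flood_disaster = risk_flood_dis)
  paths <- mapply(wcsv, tables, paste0(names(tables), ".csv"))

  joined <- region$areas[, c("area_id", "xmin", "ymin", "xmax", "ymax",
                             "population", "households", "area_km2")]
  joined <- merge(joined, vuln, by = "area_id", sort = FALSE)
  joined$flood_decile_typical <- flood_typ$decile[
    match(joined$area_id, flood_typ$area_id)]
  joined$flood_decile_disaster <- flood_dis$decile[
    match(joined$area_id, flood_dis$area_id)]
  m <- match(joined$area_id, heat$area_id)
  joined$heat_decile_tmax <- heat$decile_tmax[m]
  joined$heat_decile_exceed <- heat$decile_exceed[m]
  joined$risk_heat_cell <- risk_heat$cell_label[
    match(joined$area_id, risk_heat$area_id)]
  joined$risk_flood_cell <- risk_flood_typ$cell_label[
    match(joined$area_id, risk_flood_typ$area_id)]
  # separate metrics travel as standalone layers, outside the index
  ind_m <- match(joined$area_id, indicators$area_id)
  for (sm in registry$separate_metrics$metric_id) {
    joined[[paste0("separate_", sm)]] <- indicators[[sm]][ind_m]
  }
  geo_path <- file.path(out_dir, "joined.geojson")
  write_geojson_areas(joined, geo_path)
  wcsv(joined, "joined.csv")

  jsonlite::write_json(
    list(seed = seed, region = region$truth["seed" != names(region$truth)],
         latent = as.list(region$truth$latent),
         flood = grid_typical$metadata$truth,
         temperature = temps$truth[setdiff(names(temps$truth),
                                           "building_density")]),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  if (write_grids) {
    write_ascii_grid(grid_typical, file.path(out_dir, "flood_typical.asc"))
    write_ascii_grid(grid_disaster, file.path(out_dir, "flood_disaster.asc"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vulnmap")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = config_hash(config),
    n_areas = nrow(region$areas),
    n_buildings = nrow(region$buildings),
    row_counts = lapply(tables, nrow),
    missing_overall = missing$overall,
    n_unclassified_heat = attr(risk_heat, "n_unclassified"),
    n_unclassified_flood = attr(risk_flood_typ, "n_unclassified"),
    n_no_building_areas = attr(flood_typ, "n_no_building_areas"),
    output_checksums = as.list(tools::md5sum(
      c(unname(paths), geo_path))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
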