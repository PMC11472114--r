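#' @name synthetic_data
#' @title Synthetic study-region generation
#' @description Generators for a complete synthetic study region with known
#'   ground truth: a square lattice of small areas with populations in the
#'   1,000-3,000 range typical of UK Lower Layer Super Output Areas, a
#'   spatially smoothed latent vulnerability factor planted into
#'   binomially-drawn census counts, building point locations, a flood-depth
#'   grid decaying away from a synthetic channel, and daily summer
#'   temperature grids carrying an urban-heat-island signal proportional to
#'   building density. Every generator is deterministic for a fixed seed;
#'   independent components draw from independent sub-seeds derived from the
#'   master seed.
NULL

# Deterministic sub-seed derivation so independent components do not share
# RNG streams; stays within 32-bit integer range for any small master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# 3x3 binomial-kernel smoothing of a matrix, edge weights renormalised.
smooth3 <- function(m) {
  k <- outer(c(1, 2, 1), c(1, 2, 1))
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p); wt <- matrix(0, n, p)
  for (di in -1:1) for (dj in -1:1) {
    w <- k[di + 2, dj + 2]
    si <- max(1, 1 - di):min(n, n - di)
    sj <- max(1, 1 - dj):min(p, p - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * m[si, sj]
    wt[si + di, sj + dj] <- wt[si + di, sj + dj] + w
  }
  out / wt
}

#' Generate a synthetic study region
#'
#' Lays out `n_side` x `n_side` square areas (side `area_size` metres) on a
#' planar metric coordinate system, draws a per-area population uniformly in
#' 1,000-3,000, derives a household count (`population / 2.4`, the typical
#' mean household size), scatters one building point per household uniformly
#' inside its area, plants a spatially autocorrelated standard-normal latent
#' vulnerability factor `L` (iid Gaussian field smoothed with a 3x3 binomial
#' kernel, then re-standardised), and lays a straight channel across the
#' middle of the region from which flood depths later decay.
#'
#' @param n_side Number of areas per side, >= 2.
#' @param seed Integer master seed; output is fully deterministic given it.
#' @param area_size Area edge length in metres (default 1000, so each area
#'   is 1 km^2).
#' @return A `vulnmap_region`: list with `areas` (data frame of id, bounding
#'   box, population, households, area_km2, latent factor, building count),
#'   `buildings` (point data frame with area ids), `channel` (polyline
#'   matrix), and `truth` (all generator parameters and planted values).
#' @examples
#' r <- generate_region(4, seed = 1)
#' nrow(r$areas)     # 16
#' @export
generate_region <- function(n_side, seed, area_size = 1000) {
  if (n_side < 2) stop("`n_side` must be >= 2", call. = FALSE)
  n_side <- as.integer(n_side)
  n <- n_side * n_side
  ix <- rep(seq_len(n_side), times = n_side)   # column (x) index
  iy <- rep(seq_len(n_side), each = n_side)    # row (y) index
  areas <- data.frame(
    area_id = sprintf("A%04d", seq_len(n)),
    xmin = (ix - 1) * area_size, ymin = (iy - 1) * area_size,
    xmax = ix * area_size, ymax = iy * area_size,
    stringsAsFactors = FALSE)
  areas$area_km2 <- (area_size / 1000)^2

  latent <- with_seed(derive_seed(seed, 1L), {
    m <- matrix(stats::rnorm(n), n_side, n_side)  # [y, x]
    s <- smooth3(m)
    (s - mean(s)) / stats::sd(s)
  })
  areas$latent <- latent[cbind(iy, ix)]

  areas$population <- with_seed(derive_seed(seed, 2L),
                                sample(1000:3000, n, replace = TRUE))
  areas$households <- pmax(1L, as.integer(round(areas$population / 2.4)))
  areas$building_count <- areas$households

  buildings <- with_seed(derive_seed(seed, 3L), {
    nb <- areas$building_count
    data.frame(
      building_id = seq_len(sum(nb)),
      x = rep(areas$xmin, nb) + stats::runif(sum(nb)) * area_size,
      y = rep(areas$ymin, nb) + stats::runif(sum(nb)) * area_size,
      area_id = rep(areas$area_id, nb),
      stringsAsFactors = FALSE)
  })

  extent <- n_side * area_size
  channel <- matrix(c(0, extent / 2, extent, extent / 2), 2, 2, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y")))

  structure(list(
    areas = areas, buildings = buildings, channel = channel,
    n_side = n_side, area_size = area_size,
    truth = list(seed = seed, n_side = n_side, area_size = area_size,
                 latent = stats::setNames(areas$latent, areas$area_id),
                 population = stats::setNames(areas$population, areas$area_id),
                 building_count = stats::setNames(areas$building_count,
                                                  areas$area_id))),
    class = "vulnmap_region")
}

#' @export
print.vulnmap_region <- function(x, ...) {
  cat(sprintf("<vulnmap_region> %d areas (%d x %d of %g m), %d buildings\n",
              nrow(x$areas), x$n_side, x$n_side, x$area_size,
              nrow(x$buildings)))
  invisible(x)
}

#' Generate census-style counts with a planted vulnerability signal
#'
#' For every metric in the registry a per-area numerator is drawn as
#' `Binomial(denominator, p)` with
#' `logit(p) = logit(p0) + effect_size * polarity * L(area)`, where `p0` is a
#' metric-specific baseline prevalence drawn once (deterministically from the
#' seed) in `[0.02, 0.4]` and `L` is the region's latent vulnerability
#' factor. Denominators follow the registry's base for each metric
#' (population or households). The separate `% female` metric is drawn at a
#' fixed 0.51 with no latent effect; population density needs no draw (it is
#' the population count over the area in km^2).
#'
#' @param region A [generate_region()] result.
#' @param registry A [default_registry()]-shaped registry.
#' @param effect_size Strength of the planted signal, >= 0; 0 gives pure
#'   noise.
#' @param seed Integer seed.
#' @return Data frame with `area_id`, base columns (`population`,
#'   `households`, `area_km2`) and one numerator column per metric; baseline
#'   prevalences attached as attribute `truth`.
#' @export
generate_census_counts <- function(region, registry, effect_size = 1, seed) {
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  a <- region$areas
  out <- data.frame(area_id = a$area_id, population = a$population,
                    households = a$households, area_km2 = a$area_km2,
                    stringsAsFactors = FALSE)
  all_m <- rbind(registry$metrics, registry$separate_metrics)
  draw <- !(all_m$numerator_field %in% names(out)) & !all_m$is_rate
  mdraw <- all_m[draw, , drop = FALSE]
  bad_den <- setdiff(mdraw$denominator_field, names(out))
  if (length(bad_den)) {
    stop("unknown denominator field(s): ", paste(bad_den, collapse = ", "),
         call. = FALSE)
  }
  p0 <- with_seed(derive_seed(seed, 11L),
                  stats::runif(nrow(mdraw), 0.02, 0.40))
  # separate metrics carry no planted signal; % female is a fixed 0.51 split
  p0[is.na(mdraw$sub_domain_id) & mdraw$metric_id == "female"] <- 0.51
  eff <- ifelse(is.na(mdraw$sub_domain_id), 0, effect_size * mdraw$polarity)
  with_seed(derive_seed(seed, 12L), {
    for (i in seq_len(nrow(mdraw))) {
      den <- out[[mdraw$denominator_field[i]]]
      p <- stats::plogis(stats::qlogis(p0[i]) + eff[i] * a$latent)
      out[[mdraw$numerator_field[i]]] <- stats::rbinom(nrow(a), den, p)
    }
  })
  attr(out, "truth") <- list(effect_size = effect_size, seed = seed,
                             baseline_prevalence = stats::setNames(p0, mdraw$metric_id))
  out
}

# Minimum distance from points to a polyline (matrix of vertices).
dist_to_polyline <- function(x, y, line) {
  d <- rep(Inf, length(x))
  for (s in seq_len(nrow(line) - 1L)) {
    ax <- line[s, 1]; ay <- line[s, 2]
    bx <- line[s + 1L, 1]; by <- line[s + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    d <- pmin(d, sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2))
  }
  d
}

#' Generate a flood-depth grid decaying from the region's channel
#'
#' Cell depth is `max(0, H0 - decay * distance_to_channel) + noise`, with
#' zero-mean Gaussian noise applied only where the deterministic component is
#' positive (and the sum floored at zero), so cells beyond the flood reach
#' `H0 / decay` are exactly dry. The noise field depends on the seed and grid
#' only, not on `h0`, so a "disaster" grid generated with a larger `h0` at
#' the same seed dominates the "typical" grid cell by cell.
#'
#' @param region A [generate_region()] result.
#' @param cell_size Grid resolution in metres.
#' @param seed Integer seed.
#' @param h0 Depth at the channel in metres (default 1.2; a disaster
#'   scenario conventionally uses a larger value such as 2.0).
#' @param decay Depth lost per metre of distance from the channel
#'   (default 2e-4, i.e. a 6 km reach at `h0 = 1.2`).
#' @param noise_sd Noise standard deviation in metres.
#' @param scenario Optional [flood_scenario()] metadata attached to the grid.
#' @return A [hazard_grid()] of depths in metres.
#' @export
generate_flood_depths <- function(region, cell_size = 50, seed,
                                  h0 = 1.2, decay = 2e-4, noise_sd = 0.15,
                                  scenario = flood_scenario(role = "typical")) {
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  extent <- region$n_side * region$area_size
  nc <- nr <- as.integer(ceiling(extent / cell_size))
  cx <- (seq_len(nc) - 0.5) * cell_size
  cy <- (seq_len(nr) - 0.5) * cell_size
  dist <- outer(cy, cx, function(Y, X) dist_to_polyline(X, Y, region$channel))
  base <- pmax(h0 - decay * dist, 0)
  noise <- with_seed(derive_seed(seed, 21L),
                     matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc))
  depth <- pmax(base + noise * (base > 0), 0)
  hazard_grid(depth, origin = c(0, 0), cell_size = cell_size,
              metadata = list(scenario = scenario,
                              truth = list(seed = seed, h0 = h0, decay = decay,
                                           noise_sd = noise_sd)))
}

season_dates <- function(config) {
  if (length(config$years) == 0L) return(as.Date(character(0)))
  dates <- do.call(c, lapply(config$years, function(y) {
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), 1)
  }))
  dates[as.integer(format(dates, "%m")) %in% config$season_months]
}

#' Generate daily summer temperature grids with an urban-heat-island signal
#'
#' One layer per day of the configured season months and years. The daily
#' mean field is `base_mean_c + uhi_strength * d(cell) + day_offset +
#' cell_noise`, where `d(cell)` is the cell's building density normalised to
#' `[0, 1]`, the day offset is shared across cells (synoptic variability) and
#' the cell noise is small and independent. The daily maximum adds a
#' non-negative diurnal gap, so `tmax >= tmean` for every cell-day.
#'
#' @param region A [generate_region()] result.
#' @param config A [pipeline_config()] (season months and years are taken
#'   from it).
#' @param uhi_strength Urban-heat-island amplitude in degrees C (>= 0); the
#'   densest-built cell runs this much warmer than an empty cell on average.
#' @param seed Integer seed.
#' @param cell_size Grid resolution in metres (default 500).
#' @param base_mean_c Seasonal baseline daily-mean temperature.
#' @param diurnal_range_c Average excess of the daily maximum over the mean.
#' @param day_sd_c Standard deviation of the shared day-to-day offset.
#' @param cell_sd_c Standard deviation of independent per-cell-day noise.
#' @return List with `tmax` and `tmean`, both [grid_stack()]s on the same
#'   date axis, plus a `truth` record.
#' @export
generate_daily_temperatures <- function(region, config, uhi_strength = 3,
                                        seed, cell_size = 500,
                                        base_mean_c = 16, diurnal_range_c = 6,
                                        day_sd_c = 2, cell_sd_c = 0.3) {
  if (uhi_strength < 0) stop("`uhi_strength` must be >= 0", call. = FALSE)
  dates <- season_dates(config)
  if (length(dates) == 0L) {
    stop("configured season/years contain no days", call. = FALSE)
  }
  extent <- region$n_side * region$area_size
  nc <- nr <- as.integer(ceiling(extent / cell_size))
  template <- hazard_grid(matrix(0, nr, nc), cell_size = cell_size)
  idx <- point_cell_index(template, region$buildings$x, region$buildings$y)
  counts <- tabulate(idx, nbins = nr * nc)
  dens <- matrix(counts / max(counts, 1L), nr, nc)
  nd <- length(dates)
  out <- with_seed(derive_seed(seed, 31L), {
    day_off <- stats::rnorm(nd, 0, day_sd_c)
    eps <- array(stats::rnorm(nr * nc * nd, 0, cell_sd_c), c(nr, nc, nd))
    gap <- pmax(0, diurnal_range_c +
                  array(stats::rnorm(nr * nc * nd, 0, 1.5), c(nr, nc, nd)))
    tmean <- array(base_mean_c + uhi_strength * as.vector(dens),
                   c(nr, nc, nd)) +
      rep(day_off, each = nr * nc) + eps
    list(tmean = tmean, tmax = tmean + gap)
  })
  list(
    tmax = grid_stack(out$tmax, dates, cell_size = cell_size),
    tmean = grid_stack(out$tmean, dates, cell_size = cell_size),
    truth = list(seed = seed, uhi_strength = uhi_strength,
                 cell_size = cell_size, base_mean_c = base_mean_c,
                 diurnal_range_c = diurnal_range_c, day_sd_c = day_sd_c,
                 cell_sd_c = cell_sd_c, building_density = dens))
}
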