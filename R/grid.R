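#' Georeferenced scalar grid
#'
#' Minimal raster container used for flood-depth and temperature fields: a
#' numeric matrix indexed `[row, col]` with row 1 at the southern (minimum-y)
#' edge, an origin at the lower-left corner, a square cell size in metres,
#' and an optional no-data marker. Coordinates are assumed to be in a
#' projected planar system with metre units.
#'
#' @param values Numeric matrix, `[row, col]`, row 1 = south.
#' @param origin Numeric `c(x, y)` of the lower-left corner.
#' @param cell_size Cell edge length in metres, > 0.
#' @param nodata Value standing for no-data (converted to `NA` internally),
#'   or `NULL`.
#' @param metadata Optional list (e.g. a [flood_scenario()]).
#' @return A `vulnmap_grid`.
#' @export
hazard_grid <- function(values, origin = c(0, 0), cell_size,
                        nodata = NULL, metadata = list()) {
  stopifnot(is.matrix(values), is.numeric(values), length(origin) == 2L)
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  if (!is.null(nodata)) values[values == nodata] <- NA_real_
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size), metadata = metadata),
            class = "vulnmap_grid")
}

#' @export
print.vulnmap_grid <- function(x, ...) {
  cat(sprintf("<vulnmap_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  invisible(x)
}

# Half-open cell ownership: a point at (x, y) belongs to the single cell
# [x0, x0 + cs) x [y0, y0 + cs). Returns a data.frame with row/col (NA when
# the point falls outside the grid extent).
point_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1
  row <- floor((y - grid$origin[2]) / cs) + 1
  out <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Linear (column-major) cell index for fast tabulation; NA outside.
point_cell_index <- function(grid, x, y) {
  rc <- point_cell(grid, x, y)
  (rc$col - 1L) * nrow(grid$values) + rc$row
}

#' Write / read a grid as an ESRI ASCII raster
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south); readable
#' by standard GIS software.
#'
#' @param grid A `vulnmap_grid`.
#' @param path File path (`.asc`).
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `vulnmap_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- -9999
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           "NODATA_value -9999")
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  hazard_grid(v, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
              cell_size = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}

#' Daily grid stack
#'
#' A time-stacked [hazard_grid()]: a 3-D array `[row, col, day]` sharing one
#' georeference, with a `Date` axis. Used for daily maximum and daily mean
#' temperature fields.
#'
#' @param values 3-D numeric array `[row, col, day]`.
#' @param dates `Date` vector, one per layer.
#' @param origin,cell_size As in [hazard_grid()].
#' @return A `vulnmap_grid_stack`.
#' @export
grid_stack <- function(values, dates, origin = c(0, 0), cell_size) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == length(dates))
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  structure(list(values = values, dates = as.Date(dates),
                 origin = as.numeric(origin), cell_size = as.numeric(cell_size)),
            class = "vulnmap_grid_stack")
}

#' @export
print.vulnmap_grid_stack <- function(x, ...) {
  cat(sprintf("<vulnmap_grid_stack> %d x %d cells x %d days (%s to %s)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$dates), max(x$dates)))
  invisible(x)
}

# Extract one layer of a stack as a plain grid (used when reducing per cell).
stack_layer_grid <- function(stack, layer = matrix(0, dim(stack$values)[1],
                                                   dim(stack$values)[2])) {
  hazard_grid(layer, origin = stack$origin, cell_size = stack$cell_size)
}

# Logical mask over the date axis for the configured season months and years.
season_mask <- function(dates, config) {
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  m %in% config$season_months & y %in% config$years
}
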