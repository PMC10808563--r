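#' Zero out sub-measurable precipitation values
#'
#' Kriging output can contain small negative values and vanishingly small
#' positive values (e.g. 2.252e-10 in) that do not correspond to measurable
#' rain.  Following the U.S. National Weather Service convention that
#' precipitation below 0.01 inches is not measurable, every value below the
#' threshold -- including all negatives -- is set to exactly zero.  The
#' operation is idempotent and order-preserving.
#'
#' @param x numeric vector of precipitation values, inches/day.
#' @param threshold measurability threshold in inches (default 0.01).
#' @return numeric vector with no values in \code{(-Inf, threshold)} other
#'   than 0.
#' @examples
#' clean_precip(c(-0.003, 2.252e-10, 0.005, 0.02))
#' @export
clean_precip <- function(x, threshold = 0.01) {
  if (!is.numeric(x)) stop("precipitation values must be numeric")
  if (any(!is.finite(x))) stop("non-finite precipitation values")
  x[x < threshold] <- 0
  x
}

#' Convert precipitation from inches to millimeters
#' @param x inches
#' @return millimeters
#' @export
in_to_mm <- function(x) x * 25.4

#' Regular lon/lat analysis grid
#'
#' Defines a cell-center registered grid tiling a bounding box.  Cells are
#' half-open (closed on their left/bottom edges) so every interior point
#' belongs to exactly one cell.  Matrix row 1 corresponds to the northern
#' (lat_max) edge, following raster convention.
#'
#' @param bbox numeric \code{c(lon_min, lat_min, lon_max, lat_max)}, degrees.
#' @param n_rows,n_cols grid dimensions.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(bbox, n_rows, n_cols) {
  stopifnot(length(bbox) == 4, is.numeric(bbox),
            bbox[3] > bbox[1], bbox[4] > bbox[2],
            n_rows >= 1, n_cols >= 1)
  structure(list(
    lon_min = bbox[1], lat_min = bbox[2],
    lon_max = bbox[3], lat_max = bbox[4],
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    dx = (bbox[3] - bbox[1]) / n_cols,
    dy = (bbox[4] - bbox[2]) / n_rows
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells over [%g, %g] x [%g, %g] (dx=%g, dy=%g deg)\n",
              x$n_rows, x$n_cols, x$lon_min, x$lon_max, x$lat_min, x$lat_max,
              x$dx, x$dy))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a \code{grid_spec}.
#' @return data.frame with columns \code{row}, \code{col}, \code{lon},
#'   \code{lat}, in row-major order (row 1 = northern edge).
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    row = rows, col = cols,
    lon = grid$lon_min + (cols - 0.5) * grid$dx,
    lat = grid$lat_max - (rows - 0.5) * grid$dy
  )
}

#' Locate the grid cell containing each point
#'
#' Half-open cells: a point on a cell's left or bottom edge belongs to that
#' cell; points on the grid's top or right outer edge are outside.
#'
#' @param grid a \code{grid_spec}.
#' @param lon,lat point coordinates, degrees.
#' @return data.frame with integer columns \code{row}, \code{col}.
#' @export
grid_cell <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  inside <- lon >= grid$lon_min & lon < grid$lon_max &
            lat >= grid$lat_min & lat < grid$lat_max
  if (any(!inside))
    stop(sprintf("%d point(s) fall outside the grid bounding box", sum(!inside)))
  col <- floor((lon - grid$lon_min) / grid$dx) + 1L
  row_from_bottom <- floor((lat - grid$lat_min) / grid$dy) + 1L
  data.frame(row = grid$n_rows - row_from_bottom + 1L, col = pmin(col, grid$n_cols))
}

#' Daily precipitation surface
#'
#' One calendar date's interpolated precipitation over an analysis grid,
#' optionally with the kriging variance.
#'
#' @param grid a \code{grid_spec}.
#' @param date a \code{Date} (length 1).
#' @param values numeric matrix \code{n_rows x n_cols}, inches/day.
#' @param variance optional matrix of kriging variances, (inches)^2.
#' @return object of class \code{precip_surface}.
#' @export
precip_surface <- function(grid, date, values, variance = NULL) {
  stopifnot(inherits(grid, "grid_spec"), inherits(date, "Date"),
            is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (!is.null(variance))
    stopifnot(is.matrix(variance), dim(variance) == dim(values))
  structure(list(grid = grid, date = date, values = values,
                 variance = variance),
            class = "precip_surface")
}

#' @export
print.precip_surface <- function(x, ...) {
  cat(sprintf("precip_surface %s: %d x %d cells, mean %.4f in%s\n",
              format(x$date), x$grid$n_rows, x$grid$n_cols,
              mean(x$values, na.rm = TRUE),
              if (is.null(x$variance)) "" else " (+variance layer)"))
  invisible(x)
}

#' Surface value at point locations
#'
#' Point-in-cell extraction (no smoothing across cells).
#'
#' @param surface a \code{precip_surface}.
#' @param lon,lat coordinates.
#' @return numeric vector of cell values.
#' @export
surface_at <- function(surface, lon, lat) {
  idx <- grid_cell(surface$grid, lon, lat)
  surface$values[cbind(idx$row, idx$col)]
}

## ---- station / trap readers -------------------------------------------------

station_columns <- c("station_id", "lon", "lat", "elevation_m", "date", "precip_in")
trap_columns <- c("trap_id", "lon", "lat", "trap_type", "collection_date",
                  "female_count", "male_count")

check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
}

# Report rows whose parsed field is NA although the raw field was non-missing.
bad_rows <- function(raw, parsed) which(!is.na(raw) & raw != "" & is.na(parsed))

#' Read daily station precipitation observations
#'
#' Expects a UTF-8 CSV with header columns \code{station_id, lon, lat,
#' elevation_m, date, precip_in} (dates ISO-8601, precipitation in inches).
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of station-day records with parsed types.
#' @export
read_stations <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  check_schema(raw, station_columns, path)
  if (nrow(raw) == 0) {
    warning(sprintf("'%s' contains a header but no records", path))
    return(data.frame(station_id = character(), lon = numeric(),
                      lat = numeric(), elevation_m = numeric(),
                      date = as.Date(character()), precip_in = numeric()))
  }
  out <- data.frame(
    station_id = raw$station_id,
    lon = suppressWarnings(as.numeric(raw$lon)),
    lat = suppressWarnings(as.numeric(raw$lat)),
    elevation_m = suppressWarnings(as.numeric(raw$elevation_m)),
    date = as.Date(raw$date, format = "%Y-%m-%d"),
    precip_in = suppressWarnings(as.numeric(raw$precip_in))
  )
  for (fld in c("lon", "lat", "elevation_m", "date", "precip_in")) {
    bad <- bad_rows(raw[[fld]], out[[fld]])
    if (length(bad))
      stop(sprintf("unparseable '%s' in '%s' at data row(s): %s",
                   fld, path, paste(head(bad, 10), collapse = ", ")))
  }
  if (any(!is.finite(out$precip_in)))
    stop(sprintf("missing/non-finite precip_in in '%s'", path))
  out
}

#' Read trap-collection events
#'
#' Expects a UTF-8 CSV with header columns \code{trap_id, lon, lat, trap_type,
#' collection_date, female_count, male_count}.  Trap types must be
#' \code{"CO2"} or \code{"BG"}; BG-Sentinel events are read but are normally
#' excluded from analyses downstream (see \code{\link{filter_co2}}).  Counts
#' must be non-negative integers.  A logical \code{presence} column (at least
#' one female) is added.
#'
#' @param path CSV file path.
#' @return data.frame of trap events.
#' @export
read_traps <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = TRUE)
  check_schema(raw, trap_columns, path)
  out <- data.frame(
    trap_id = raw$trap_id,
    lon = suppressWarnings(as.numeric(raw$lon)),
    lat = suppressWarnings(as.numeric(raw$lat)),
    trap_type = raw$trap_type,
    collection_date = as.Date(raw$collection_date, format = "%Y-%m-%d"),
    female_count = suppressWarnings(as.integer(raw$female_count)),
    male_count = suppressWarnings(as.integer(raw$male_count))
  )
  for (fld in c("lon", "lat", "collection_date", "female_count", "male_count")) {
    bad <- bad_rows(raw[[fld]], out[[fld]])
    if (length(bad))
      stop(sprintf("unparseable '%s' in '%s' at data row(s): %s",
                   fld, path, paste(head(bad, 10), collapse = ", ")))
  }
  unknown <- !out$trap_type %in% c("CO2", "BG")
  if (any(unknown))
    stop(sprintf("unknown trap_type in '%s' at data row(s): %s",
                 path, paste(head(which(unknown), 10), collapse = ", ")))
  neg <- out$female_count < 0 | out$male_count < 0
  if (any(neg, na.rm = TRUE))
    stop(sprintf("negative count in '%s' at data row(s): %s",
                 path, paste(head(which(neg), 10), collapse = ", ")))
  out$presence <- out$female_count >= 1
  out
}

#' Keep only CO2-baited trap events
#'
#' BG-Sentinel traps were deployed briefly and are excluded from all
#' analyses by default; this filter makes the exclusion explicit and logs it.
#'
#' @param events trap-event data.frame from \code{\link{read_traps}}.
#' @param exclude_bg drop BG events (default TRUE).
#' @return filtered data.frame.
#' @export
filter_co2 <- function(events, exclude_bg = TRUE) {
  if (!exclude_bg) return(events)
  n_bg <- sum(events$trap_type == "BG")
  if (n_bg > 0)
    message(sprintf("excluding %d BG-Sentinel trapping event(s)", n_bg))
  events[events$trap_type != "BG", , drop = FALSE]
}

## ---- surface serialization --------------------------------------------------

# Plain-text grid format: '#' metadata lines (format tag, date, bbox, dims,
# layer markers), then comma-separated matrix rows, row 1 = northern edge.

#' Write a precipitation surface to a plain-text grid file
#'
#' @param surface a \code{precip_surface}.
#' @param path output path (conventionally \code{precip_YYYY-MM-DD.csv}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_surface}}
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "precip_surface"))
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#kriglag_surface,1",
    sprintf("#date,%s", format(surface$date)),
    sprintf("#bbox,%.10g,%.10g,%.10g,%.10g",
            g$lon_min, g$lat_min, g$lon_max, g$lat_max),
    sprintf("#dims,%d,%d", g$n_rows, g$n_cols),
    "#layer,values"), con)
  write.table(format(surface$values, digits = 12, trim = TRUE, scientific = TRUE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  if (!is.null(surface$variance)) {
    writeLines("#layer,variance", con)
    write.table(format(surface$variance, digits = 12, trim = TRUE,
                       scientific = TRUE),
                con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' Read a precipitation surface written by \code{write_surface}
#'
#' @param path file path.
#' @return a \code{precip_surface}; values and variance round-trip to within
#'   storage precision.
#' @export
read_surface <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "#kriglag_surface,1")
    stop(sprintf("'%s' is not a kriglag surface file", path))
  meta <- grep("^#", lines)
  get_meta <- function(key) {
    hit <- grep(paste0("^#", key, ","), lines, value = TRUE)
    if (length(hit) != 1) stop(sprintf("surface file '%s': missing #%s", path, key))
    strsplit(sub(paste0("^#", key, ","), "", hit), ",")[[1]]
  }
  date <- as.Date(get_meta("date"))
  bbox <- as.numeric(get_meta("bbox"))
  dims <- as.integer(get_meta("dims"))
  grid <- grid_spec(bbox, dims[1], dims[2])
  layer_lines <- grep("^#layer,", lines)
  layer_names <- sub("^#layer,", "", lines[layer_lines])
  if (!identical(layer_names, "values") &&
      !identical(layer_names, c("values", "variance")))
    stop(sprintf("surface file '%s': unexpected layer set (%s)",
                 path, paste(layer_names, collapse = ", ")))
  read_block <- function(from, to) {
    block <- lines[from:to]
    block <- block[!grepl("^#", block)]
    if (length(block) != dims[1])
      stop(sprintf("surface file '%s': layer has %d rows, grid declares %d",
                   path, length(block), dims[1]))
    m <- t(vapply(strsplit(block, ","),
                  function(p) as.numeric(p), numeric(dims[2])))
    if (ncol(m) != dims[2])
      stop(sprintf("surface file '%s': column count mismatch", path))
    m
  }
  bounds <- c(layer_lines, length(lines) + 1L)
  values <- read_block(bounds[1] + 1L, bounds[2] - 1L)
  variance <- if (length(layer_lines) == 2)
    read_block(bounds[2] + 1L, bounds[3] - 1L) else NULL
  precip_surface(grid, date, values, variance)
}
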