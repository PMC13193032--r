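# Regular lon-lat raster time series: the container for hourly reanalysis
# fields and daily column-water-vapor products, with nearest-cell lookup and
# a plain-text serialization.

#' Construct a regular lon-lat gridded field
#'
#' @param lon,lat Strictly monotone cell-center axes, degrees.
#' @param time Time axis: `Date` vector for daily fields, POSIXct for hourly.
#' @param values Numeric array `length(lon) x length(lat) x length(time)`;
#'   `NA` marks missing cells.
#' @param qa Optional integer bitmask array of the same shape (daily
#'   water-vapor fields only).
#' @param units Value units, e.g. `"K"` or `"cm"`.
#' @return Object of class `grid_field`.
#' @export
grid_field <- function(lon, lat, time, values, qa = NULL, units = "K") {
  stopifnot(length(lon) >= 1, length(lat) >= 1)
  if (is.unsorted(lon, strictly = TRUE) && is.unsorted(rev(lon), strictly = TRUE))
    stop("lon axis must be strictly monotone")
  if (is.unsorted(lat, strictly = TRUE) && is.unsorted(rev(lat), strictly = TRUE))
    stop("lat axis must be strictly monotone")
  values <- array(values, dim = c(length(lon), length(lat), length(time)))
  if (!is.null(qa)) {
    qa <- array(as.integer(qa), dim = dim(values))
  }
  structure(list(lon = lon, lat = lat, time = time, values = values,
                 qa = qa, units = units),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d cells, %d time steps [%s]%s\n",
              length(x$lon), length(x$lat), length(x$time), x$units,
              if (is.null(x$qa)) "" else ", with QA"))
  cat(sprintf("  lon [%g, %g]  lat [%g, %g]  missing %.1f%%\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              100 * mean(is.na(x$values))))
  invisible(x)
}

# index of the time slice matching `when` (Date or POSIXct); NA if absent
.time_index <- function(field, when) {
  if (inherits(field$time, "Date")) when <- as.Date(when)
  i <- match(as.numeric(when), as.numeric(field$time))
  i
}

# nearest cell-center index on one axis, tie toward lower index
.nearest_axis_index <- function(axis, x) {
  vapply(x, function(p) which.min(abs(axis - p)), 0L)
}

#' Nearest-cell-center lookup in a gridded field
#'
#' Returns the value of the cell whose center is nearest to the query point
#' (deterministic tie-break toward the lower index). Points outside the grid
#' bounding box (cell centers padded by half a cell) or times absent from the
#' axis yield `NA`.
#'
#' @param field A [grid_field()].
#' @param lon,lat Query coordinates (vectors of equal length), degrees.
#' @param when Query time (`Date` or POSIXct matching the field's axis);
#'   recycled to the query length.
#' @return Numeric vector of values (`NA` = missing).
#' @export
sample_grid <- function(field, lon, lat, when) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  when <- rep_len(when, n)
  res_lon <- if (length(field$lon) > 1) abs(diff(field$lon[1:2])) else Inf
  res_lat <- if (length(field$lat) > 1) abs(diff(field$lat[1:2])) else Inf
  inside <- lon >= min(field$lon) - res_lon / 2 & lon <= max(field$lon) + res_lon / 2 &
    lat >= min(field$lat) - res_lat / 2 & lat <= max(field$lat) + res_lat / 2
  ti <- .time_index(field, when)
  out <- rep(NA_real_, n)
  ok <- inside & !is.na(ti)
  if (any(ok)) {
    ii <- .nearest_axis_index(field$lon, lon[ok])
    jj <- .nearest_axis_index(field$lat, lat[ok])
    out[ok] <- field$values[cbind(ii, jj, ti[ok])]
  }
  out
}

#' Write / read a gridded field as long-format CSV
#'
#' Plain-text serialization: columns `lon,lat,time,value[,qa]`, one row per
#' cell-time (missing cells written with empty value). Time is ISO 8601.
#'
#' @param field A [grid_field()].
#' @param path CSV path.
#' @export
write_grid_field <- function(field, path) {
  tvals <- if (inherits(field$time, "Date")) format(field$time) else
    format(field$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  g <- expand.grid(lon = field$lon, lat = field$lat, time = tvals,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$value <- as.vector(field$values)
  if (!is.null(field$qa)) g$qa <- as.vector(field$qa)
  g$units <- field$units
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE, na = "")
}

#' @rdname write_grid_field
#' @return `read_grid_field()` returns a [grid_field()].
#' @export
read_grid_field <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- sort(unique(g$lon)); lat <- sort(unique(g$lat))
  tchr <- unique(g$time)
  daily <- all(nchar(tchr) == 10)
  time <- if (daily) as.Date(sort(tchr)) else sort(parse_rfc3339(tchr))
  tkey <- if (daily) as.character(g$time) else
    format(parse_rfc3339(g$time), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tlev <- if (daily) format(time) else format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  idx <- cbind(match(g$lon, lon), match(g$lat, lat), match(tkey, tlev))
  vals <- array(NA_real_, dim = c(length(lon), length(lat), length(time)))
  vals[idx] <- g$value
  qa <- NULL
  if ("qa" %in% names(g)) {
    qa <- array(NA_integer_, dim = dim(vals))
    qa[idx] <- g$qa
  }
  grid_field(lon, lat, time, vals, qa = qa,
             units = if ("units" %in% names(g)) g$units[1] else "K")
}
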