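# Predictor construction: DV-analogous daily aggregation of hourly gridded
# fields, coarse-grid fallback for fine-grid gaps, QA filtering of column
# water vapor, and assembly of the per-station-day feature vector.

#' Aggregate hourly humidity/temperature grids to a daily DV-analogous field
#'
#' Per cell: for `dv_kind = "mean"`, the simple average of the day's hourly
#' values; for `"min"`/`"max"`, the humidity at the hour at which the cell's
#' temperature attains its extremum (earliest hour on ties). Temperature is
#' aggregated the same way so the temperature predictor matches the DV
#' definition.
#'
#' @param humidity_hourly,temperature_hourly Hourly [grid_field()]s sharing
#'   axes, covering one study day.
#' @param dv_kind `"min"`, `"mean"` or `"max"`.
#' @param day `Date` to stamp on the output fields.
#' @return List with daily [grid_field()]s `humidity` and `temperature`.
#' @export
aggregate_hourly_to_dv <- function(humidity_hourly, temperature_hourly,
                                   dv_kind = c("mean", "min", "max"),
                                   day = assign_day(humidity_hourly$time[1])) {
  dv_kind <- match.arg(dv_kind)
  if (!identical(humidity_hourly$lon, temperature_hourly$lon) ||
      !identical(humidity_hourly$lat, temperature_hourly$lat) ||
      !identical(as.numeric(humidity_hourly$time),
                 as.numeric(temperature_hourly$time)))
    stop("humidity and temperature grids must share lon/lat/time axes")
  nl <- length(humidity_hourly$lon); nb <- length(humidity_hourly$lat)
  nt <- length(humidity_hourly$time)
  hm <- matrix(humidity_hourly$values, nl * nb, nt)
  tm <- matrix(temperature_hourly$values, nl * nb, nt)
  if (dv_kind == "mean") {
    hv <- rowMeans(hm)      # NA if any hour missing: a gap day falls back
    tv <- rowMeans(tm)      # to the coarse grid rather than a partial mean
  } else {
    pick <- function(row_t, row_h) {
      if (all(is.na(row_t))) return(c(NA_real_, NA_real_))
      i <- if (dv_kind == "min") which.min(row_t) else which.max(row_t)
      c(row_h[i], row_t[i])
    }
    sel <- vapply(seq_len(nrow(tm)), function(r) pick(tm[r, ], hm[r, ]),
                  numeric(2))
    hv <- sel[1, ]; tv <- sel[2, ]
  }
  list(
    humidity = grid_field(humidity_hourly$lon, humidity_hourly$lat,
                          day, hv, units = humidity_hourly$units),
    temperature = grid_field(temperature_hourly$lon, temperature_hourly$lat,
                             day, tv, units = temperature_hourly$units)
  )
}

#' Fill fine-grid gaps from a coarse grid
#'
#' Output equals the fine field wherever it is present; missing fine cells
#' take the value of the nearest coarse cell center. Cells missing in both
#' stay missing. A provenance mask records the source per cell.
#'
#' @param fine,coarse [grid_field()]s for the same day(s) and variable;
#'   coarse resolution >= fine resolution.
#' @return A [grid_field()] with attribute `provenance`: character array
#'   (`"fine"`, `"coarse"`, or `NA`).
#' @export
fill_from_coarse <- function(fine, coarse) {
  out <- fine$values
  prov <- array(ifelse(is.na(out), NA_character_, "fine"), dim = dim(out))
  ic <- .nearest_axis_index(coarse$lon, fine$lon)
  jc <- .nearest_axis_index(coarse$lat, fine$lat)
  for (t in seq_along(fine$time)) {
    tc <- .time_index(coarse, fine$time[t])
    if (is.na(tc)) next
    miss <- which(is.na(out[, , t]), arr.ind = TRUE)
    if (!nrow(miss)) next
    vals <- coarse$values[cbind(ic[miss[, 1]], jc[miss[, 2]], tc)]
    out[cbind(miss, t)] <- vals
    prov[cbind(miss, t)] <- ifelse(is.na(vals), NA_character_, "coarse")
  }
  res <- grid_field(fine$lon, fine$lat, fine$time, out, units = fine$units)
  attr(res, "provenance") <- prov
  res
}

#' Drop cloudy column-water-vapor cells by QA bitmask
#'
#' A value is kept iff it is present and its QA low three bits differ from
#' 0b011 (decimal 3), the cloudy-pixel code; only bits 0-2 are tested.
#' Idempotent, and never increases the count of present cells.
#'
#' @param field A [grid_field()] with a `qa` bitmask.
#' @return The field with cloudy cells set to missing (`qa` retained).
#' @export
filter_cwv <- function(field) {
  if (is.null(field$qa)) stop("filter_cwv requires a QA bitmask")
  cloudy <- !is.na(field$qa) & bitwAnd(field$qa, 7L) == 3L
  field$values[cloudy | is.na(field$qa)] <- NA_real_
  field
}

#' Default static-feature registry
#'
#' The 13 static (per-station) predictors carried alongside the gridded
#' predictors and the IDW feature. `lon`, `lat` come from station
#' coordinates and `doy_sin`/`doy_cos` are day-of-year harmonics computed
#' from the date; the rest must be supplied in the statics table.
#'
#' @return Character vector of feature names.
#' @export
default_feature_registry <- function() {
  c("lon", "lat", "elevation_m", "dist_water_km", "pop_density",
    "isolation_km", "doy_sin", "doy_cos", "impervious_frac", "canopy_frac",
    "nightlights", "urban_dist_km", "slope_deg")
}

# registry features computed from the station-day row itself
.derived_registry_features <- c("lon", "lat", "doy_sin", "doy_cos")

#' Assemble the per-station-day predictor table
#'
#' Builds one predictor vector per station-day: the leave-self-out IDW
#' feature, the DV-matched daily reanalysis humidity and temperature, the two
#' satellite column-water-vapor values (QA-filtered; Terra and Aqua kept as
#' separate features), and the static registry block. Missing IDW and CWV are
#' passed through as `NA` (the tree learner handles them natively).
#'
#' @param days Station-day table from [derive_station_days()].
#' @param grids List with daily [grid_field()]s `era5_humid`, `era5_temp`
#'   (already DV-aggregated and coarse-filled, time axis = dates) and
#'   `cwv_terra`, `cwv_aqua` (QA applied here if a `qa` mask is present).
#' @param statics Wide data.frame: `station_id` plus one column per
#'   non-derived registry feature.
#' @param dv_kind `"min"`, `"mean"` or `"max"`; selects the observed DV column.
#' @param idw_cfg An [idw_config()].
#' @param registry Static-feature names; defaults to
#'   [default_feature_registry()].
#' @return data.frame with identifier columns (`station_id`, `day`, `y`,
#'   `temp_max`) and the feature columns named in
#'   `attr(, "feature_cols")`; attributes `dv_kind` and `registry`.
#' @export
assemble_features <- function(days, grids, statics,
                              dv_kind = c("mean", "min", "max"),
                              idw_cfg = idw_config(),
                              registry = default_feature_registry()) {
  dv_kind <- match.arg(dv_kind)
  dv_col <- paste0("humid_", dv_kind)
  static_needed <- setdiff(registry, .derived_registry_features)
  miss_cols <- setdiff(static_needed, names(statics))
  if (length(miss_cols))
    stop("statics table lacks registry features: ",
         paste(miss_cols, collapse = ", "))
  si <- match(days$station_id, statics$station_id)
  if (anyNA(si))
    stop("statics missing for stations: ",
         paste(unique(days$station_id[is.na(si)]), collapse = ", "))
  for (f in static_needed) {
    if (anyNA(statics[[f]][si]))
      stop("static feature '", f, "' absent for stations: ",
           paste(unique(days$station_id[is.na(statics[[f]])[si]]),
                 collapse = ", "))
  }

  cwv_t <- grids$cwv_terra; cwv_a <- grids$cwv_aqua
  if (!is.null(cwv_t) && !is.null(cwv_t$qa)) cwv_t <- filter_cwv(cwv_t)
  if (!is.null(cwv_a) && !is.null(cwv_a$qa)) cwv_a <- filter_cwv(cwv_a)

  doy <- as.integer(strftime(days$day, "%j"))
  out <- data.frame(
    station_id = days$station_id,
    day = days$day,
    y = days[[dv_col]],
    temp_max = days$temp_max,
    idw = idw_features_all(days, dv_col, idw_cfg),
    era5_humid = sample_grid(grids$era5_humid, days$lon, days$lat, days$day),
    era5_temp = sample_grid(grids$era5_temp, days$lon, days$lat, days$day),
    cwv_terra = if (is.null(cwv_t)) NA_real_ else
      sample_grid(cwv_t, days$lon, days$lat, days$day),
    cwv_aqua = if (is.null(cwv_a)) NA_real_ else
      sample_grid(cwv_a, days$lon, days$lat, days$day),
    stringsAsFactors = FALSE
  )
  for (f in registry) {
    out[[f]] <- switch(f,
      lon = days$lon,
      lat = days$lat,
      doy_sin = sin(2 * pi * doy / 365.25),
      doy_cos = cos(2 * pi * doy / 365.25),
      statics[[f]][si])
  }
  feature_cols <- c("idw", "era5_humid", "era5_temp", "cwv_terra", "cwv_aqua",
                    registry)
  structure(out, feature_cols = feature_cols, dv_kind = dv_kind,
            registry = registry, idw_cfg = idw_cfg)
}

#' Build DV-matched daily predictor grids from hourly fields
#'
#' For each study day present in the hourly axes: aggregate the fine hourly
#' humidity/temperature pair to the DV-analogous daily value, do the same for
#' the coarse pair, and fill fine-grid gaps from the coarse aggregate.
#'
#' @param fine_humid,fine_temp,coarse_humid,coarse_temp Hourly
#'   [grid_field()]s (POSIXct time axis).
#' @param dv_kind `"min"`, `"mean"` or `"max"`.
#' @return List of daily [grid_field()]s `era5_humid`, `era5_temp` with the
#'   union of study days on the time axis.
#' @export
build_daily_predictor_grids <- function(fine_humid, fine_temp,
                                        coarse_humid, coarse_temp,
                                        dv_kind = c("mean", "min", "max")) {
  dv_kind <- match.arg(dv_kind)
  days <- sort(unique(assign_day(fine_humid$time)))
  nl <- length(fine_humid$lon); nb <- length(fine_humid$lat)
  hv <- array(NA_real_, c(nl, nb, length(days)))
  tv <- hv
  fdays <- assign_day(fine_humid$time)
  cdays <- assign_day(coarse_humid$time)
  sub <- function(g, keep) grid_field(g$lon, g$lat, g$time[keep],
                                      g$values[, , keep, drop = FALSE],
                                      units = g$units)
  for (i in seq_along(days)) {
    fk <- fdays == days[i]; ck <- cdays == days[i]
    fine_day <- aggregate_hourly_to_dv(sub(fine_humid, fk), sub(fine_temp, fk),
                                       dv_kind, day = days[i])
    coarse_day <- aggregate_hourly_to_dv(sub(coarse_humid, ck),
                                         sub(coarse_temp, ck),
                                         dv_kind, day = days[i])
    hv[, , i] <- fill_from_coarse(fine_day$humidity, coarse_day$humidity)$values
    tv[, , i] <- fill_from_coarse(fine_day$temperature,
                                  coarse_day$temperature)$values
  }
  list(era5_humid = grid_field(fine_humid$lon, fine_humid$lat, days, hv,
                               units = fine_humid$units),
       era5_temp = grid_field(fine_temp$lon, fine_temp$lat, days, tv,
                              units = fine_temp$units))
}
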