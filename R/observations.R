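# Sub-daily station observations: RFC 3339 parsing, study-day assignment,
# cleaning against record bounds, and reduction to the three daily dependent
# variables (T-min humidity, mean humidity, T-max humidity).

# The study day is a fixed UTC-6 offset (Central Standard Time, no daylight
# saving ever applied).
.study_utc_offset_hours <- -6

#' Parse an RFC 3339 timestamp with a mandatory UTC offset
#'
#' Accepts `YYYY-MM-DDTHH:MM[:SS[.fff]](Z|+hh:mm|-hh:mm)`. Timestamps without
#' an explicit offset are rejected: the study-day definition depends on the
#' absolute instant, so a naive local time would be ambiguous.
#'
#' @param x Character vector of timestamps.
#' @return POSIXct vector in UTC. Unparseable entries are `NA` with a warning
#'   when `strict = FALSE`, an error when `strict = TRUE`.
#' @param strict Reject on any unparseable entry instead of returning NA.
#' @export
parse_rfc3339 <- function(x, strict = TRUE) {
  re <- paste0(
    "^(\\d{4})-(\\d{2})-(\\d{2})[Tt ]",
    "(\\d{2}):(\\d{2})(?::(\\d{2})(?:\\.(\\d+))?)?",
    "(Z|z|[+-]\\d{2}:?\\d{2})$"
  )
  m <- regmatches(x, regexec(re, x))
  bad <- lengths(m) == 0
  if (any(bad)) {
    msg <- sprintf("timestamp without parseable RFC 3339 form or UTC offset: %s",
                   paste(utils::head(x[bad], 3), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  out <- rep(as.POSIXct(NA), length(x))
  ok <- which(!bad)
  if (length(ok)) {
    part <- function(i) vapply(m[ok], `[`, "", i + 1)
    sec <- part(6); sec[sec == ""] <- "0"
    frac <- part(7); frac[frac == ""] <- "0"
    off <- part(8)
    off_min <- numeric(length(off))
    numeric_off <- toupper(off) != "Z"
    if (any(numeric_off)) {
      o <- off[numeric_off]
      off_min[numeric_off] <- (as.integer(substr(o, 2, 3)) * 60 +
                                 as.integer(substr(o, nchar(o) - 1, nchar(o)))) *
        ifelse(substr(o, 1, 1) == "-", -1, 1)
    }
    utc <- ISOdatetime(as.integer(part(1)), as.integer(part(2)),
                       as.integer(part(3)), as.integer(part(4)),
                       as.integer(part(5)), as.numeric(sec) +
                         as.numeric(paste0("0.", frac)),
                       tz = "UTC") - off_min * 60
    out[ok] <- utc
  }
  attr(out, "tzone") <- "UTC"
  out
}

#' Assign an instant to a study day
#'
#' The study day runs midnight to midnight in a fixed UTC-6 offset (Central
#' Standard Time); daylight saving is never applied.
#'
#' @param timestamp POSIXct vector (any tz attribute; the instant is what
#'   matters) or RFC 3339 character vector with explicit offsets.
#' @return `Date` vector of study days.
#' @examples
#' assign_day("2010-07-28T05:59:00Z")  # 2010-07-27
#' assign_day("2010-07-28T06:00:00Z")  # 2010-07-28
#' @export
assign_day <- function(timestamp) {
  if (is.character(timestamp)) timestamp <- parse_rfc3339(timestamp)
  if (!inherits(timestamp, "POSIXct"))
    stop("timestamp must be POSIXct or RFC 3339 character with explicit offset")
  as.Date(timestamp + .study_utc_offset_hours * 3600, tz = "UTC")
}

#' Cleaning configuration for station observations
#'
#' @param bound_lo,bound_hi Record-based dew-point bounds, kelvin. Defaults
#'   suit synthetic work; supply domain-appropriate record bounds for real
#'   data.
#' @param min_obs Minimum observations for a valid station-day.
#' @param min_span_hours Minimum hours between a day's first and last
#'   observation.
#' @param boundary_cap_hours Cap on the day-boundary weight extension used in
#'   the time-weighted daily mean (see [derive_station_day()]).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(bound_lo = 210, bound_hi = 310,
                            min_obs = 4, min_span_hours = 18,
                            boundary_cap_hours = 1) {
  stopifnot(bound_lo < bound_hi, min_obs >= 1,
            min_span_hours >= 0, min_span_hours <= 24,
            boundary_cap_hours >= 0)
  structure(list(bound_lo = bound_lo, bound_hi = bound_hi,
                 min_obs = min_obs, min_span_hours = min_span_hours,
                 boundary_cap_hours = boundary_cap_hours),
            class = "cleaning_config")
}

#' Clean sub-daily observations
#'
#' Keeps a dew-point observation only when temperature is present and finite
#' in the same record, and drops dew points beyond the configured record
#' bounds. Input order is preserved; each dropped record gets a reason code.
#' Supersaturated records (dew point above temperature) are counted in a
#' diagnostic attribute but never dropped.
#'
#' @param obs data.frame with columns `station_id, lon, lat, time,
#'   temperature_k, dew_point_k` (`time` POSIXct or RFC 3339 character).
#' @param cfg A [cleaning_config()].
#' @return List with `kept` (cleaned data.frame), `rejections` (data.frame
#'   `row, station_id, reason`), and `n_supersaturated`.
#' @export
clean_observations <- function(obs, cfg = cleaning_config()) {
  stopifnot(inherits(cfg, "cleaning_config"))
  need <- c("station_id", "lon", "lat", "time", "temperature_k", "dew_point_k")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols))
    stop("observations lack columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(obs) == 0) {
    return(list(kept = obs,
                rejections = data.frame(row = integer(), station_id = character(),
                                        reason = character()),
                n_supersaturated = 0L))
  }
  if (any(obs$lon < -180 | obs$lon > 180, na.rm = TRUE) ||
      any(obs$lat < -90 | obs$lat > 90, na.rm = TRUE))
    stop("longitude/latitude out of range")

  reason <- rep(NA_character_, nrow(obs))
  has_t <- is.finite(obs$temperature_k)
  has_td <- is.finite(obs$dew_point_k)
  reason[!has_td] <- "no_dew_point"
  reason[has_td & !has_t] <- "no_paired_temperature"
  oob <- has_td & has_t &
    (obs$dew_point_k < cfg$bound_lo | obs$dew_point_k > cfg$bound_hi)
  reason[oob] <- "beyond_record_bounds"

  keep <- is.na(reason)
  kept <- obs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  rejections <- data.frame(row = which(!keep),
                           station_id = obs$station_id[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  list(kept = kept, rejections = rejections,
       n_supersaturated = sum(kept$dew_point_k > kept$temperature_k))
}

# Interval time weights: half the gap to each temporal neighbor, plus a
# capped extension to the day boundaries for the first/last observation.
.interval_weights_hours <- function(hours_in_day, cap) {
  n <- length(hours_in_day)
  if (n == 1) return(1)
  gaps <- diff(hours_in_day)
  w <- c(gaps[1] / 2, (gaps[-length(gaps)] + gaps[-1]) / 2, gaps[length(gaps)] / 2)
  w[1] <- w[1] + min(hours_in_day[1], cap)
  w[n] <- w[n] + min(24 - hours_in_day[n], cap)
  w
}

#' Reduce one station-day of cleaned observations to daily dependent variables
#'
#' Computes the three daily targets: `humid_mean` is the time-weighted mean
#' dew point (trapezoidal-interval weights: each observation carries half the
#' gap to its temporal neighbors, and the first/last observation additionally
#' carries the gap to the day boundary, capped at
#' `cfg$boundary_cap_hours`); `humid_min` is the dew point of the observation
#' at which temperature attains its daily minimum (earliest on ties), and
#' `humid_max` analogously for the maximum. Temperature extrema and the
#' time-weighted temperature mean are carried along. Returns `NULL` when the
#' day fails the completeness rule (`min_obs`, `min_span_hours`).
#'
#' @param obs Cleaned observations for one station and one assigned study day,
#'   sorted by time.
#' @param cfg A [cleaning_config()].
#' @return One-row data.frame (a StationDay) or `NULL`.
#' @export
derive_station_day <- function(obs, cfg = cleaning_config()) {
  stopifnot(nrow(obs) >= 1)
  tt <- if (is.character(obs$time)) parse_rfc3339(obs$time) else obs$time
  if (length(unique(obs$station_id)) != 1)
    stop("observations span multiple stations")
  day <- assign_day(tt)
  if (length(unique(day)) != 1) stop("observations span multiple study days")
  if (is.unsorted(as.numeric(tt), strictly = FALSE))
    stop("observations must be sorted by time")

  n <- nrow(obs)
  span <- as.numeric(difftime(tt[n], tt[1], units = "hours"))
  if (n < cfg$min_obs || span < cfg$min_span_hours) return(NULL)

  # hours since the study-day start
  day_start <- as.POSIXct(paste0(format(day[1]), " 00:00:00"), tz = "UTC") -
    .study_utc_offset_hours * 3600
  hrs <- as.numeric(difftime(tt, day_start, units = "hours"))
  w <- .interval_weights_hours(hrs, cfg$boundary_cap_hours)

  i_min <- which.min(obs$temperature_k)   # earliest on ties
  i_max <- which.max(obs$temperature_k)
  data.frame(
    station_id = obs$station_id[1],
    day = day[1],
    lon = obs$lon[1], lat = obs$lat[1],
    humid_min = obs$dew_point_k[i_min],
    humid_mean = sum(w * obs$dew_point_k) / sum(w),
    humid_max = obs$dew_point_k[i_max],
    temp_min = obs$temperature_k[i_min],
    temp_mean = sum(w * obs$temperature_k) / sum(w),
    temp_max = obs$temperature_k[i_max],
    n_obs = n,
    span_hours = span,
    stringsAsFactors = FALSE
  )
}

#' Reduce a cleaned observation table to station-days
#'
#' Groups by station and assigned study day, sorts each group by time, and
#' applies [derive_station_day()].
#'
#' @param obs Cleaned observation data.frame.
#' @param cfg A [cleaning_config()].
#' @return data.frame of StationDay rows (possibly zero rows).
#' @export
derive_station_days <- function(obs, cfg = cleaning_config()) {
  empty <- derive_station_day(
    data.frame(station_id = "x", lon = 0, lat = 0,
               time = "2010-01-01T12:00:00-06:00",
               temperature_k = 280, dew_point_k = 270),
    cleaning_config(min_obs = 1, min_span_hours = 0))[0, ]
  if (nrow(obs) == 0) return(empty)
  tt <- if (is.character(obs$time)) parse_rfc3339(obs$time) else obs$time
  obs$time <- tt
  obs$.day <- assign_day(tt)
  key <- interaction(obs$station_id, obs$.day, drop = TRUE)
  parts <- split(seq_len(nrow(obs)), key)
  rows <- lapply(parts, function(idx) {
    g <- obs[idx[order(as.numeric(obs$time[idx]))], , drop = FALSE]
    g$.day <- NULL
    derive_station_day(g, cfg)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$day, out$station_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read sub-daily observations from CSV
#'
#' Expects header `station_id,lon,lat,time,temperature_k,dew_point_k` with
#' `time` in RFC 3339. Malformed rows (unparseable timestamp or non-numeric
#' coordinates) are logged and skipped rather than aborting.
#'
#' @param path CSV file path.
#' @return List with `obs` (data.frame, `time` as POSIXct UTC) and
#'   `rejections` (data.frame `row, reason`).
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("station_id", "lon", "lat", "time", "temperature_k", "dew_point_k")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("observation file lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    return(list(obs = data.frame(station_id = character(), lon = numeric(),
                                 lat = numeric(),
                                 time = as.POSIXct(character(), tz = "UTC"),
                                 temperature_k = numeric(),
                                 dew_point_k = numeric()),
                rejections = data.frame(row = integer(), reason = character())))
  }
  tm <- suppressWarnings(parse_rfc3339(raw$time, strict = FALSE))
  num <- function(x) suppressWarnings(as.numeric(x))
  lon <- num(raw$lon); lat <- num(raw$lat)
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(tm)] <- "bad_timestamp"
  reason[is.na(reason) & (!is.finite(lon) | !is.finite(lat))] <- "bad_coordinates"
  keep <- is.na(reason)
  obs <- data.frame(station_id = raw$station_id[keep],
                    lon = lon[keep], lat = lat[keep],
                    time = tm[keep],
                    temperature_k = num(raw$temperature_k[keep]),
                    dew_point_k = num(raw$dew_point_k[keep]),
                    stringsAsFactors = FALSE)
  list(obs = obs,
       rejections = data.frame(row = which(!keep), reason = reason[!keep]))
}

#' Write observations / station-days to CSV
#'
#' @param path Output path.
#' @param x data.frame (observations with POSIXct `time` are serialized as
#'   RFC 3339 UTC; station-day tables are written as-is).
#' @export
write_observations <- function(path, x) {
  if (inherits(x$time, "POSIXct"))
    x$time <- format(x$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_observations
#' @export
write_station_days <- function(path, x) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' Read a station-day table written by [write_station_days()]
#' @param path CSV path.
#' @return data.frame with `day` as `Date`.
#' @export
read_station_days <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$day <- as.Date(x$day)
  x
}
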