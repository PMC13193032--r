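# Inverse-distance weighting on the sphere: the baseline estimator whose
# residuals the boosted model corrects, plus the leave-self-out training
# feature.

.earth_radius_km <- 6371.0

#' Great-circle distance (haversine), kilometers
#'
#' Spherical earth, radius 6371 km. Vectorized over either argument.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90) ||
      any(abs(lon1) > 180) || any(abs(lon2) > 180))
    stop("coordinates out of range")
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * .earth_radius_km * asin(pmin(1, sqrt(a)))
}

#' IDW configuration
#'
#' @param power Inverse-distance exponent (> 0).
#' @param k_neighbors Number of nearest neighbors used (0 = all).
#' @param max_radius_km Neighbor search radius (0 = unlimited).
#' @param exact_hit_epsilon_km Distances at or below this are treated as
#'   coincident: the mean of coincident stations' values is returned.
#' @return List of class `idw_config`.
#' @export
idw_config <- function(power = 2, k_neighbors = 8, max_radius_km = 0,
                       exact_hit_epsilon_km = 0.001) {
  stopifnot(power > 0, k_neighbors >= 0, max_radius_km >= 0,
            exact_hit_epsilon_km >= 0)
  structure(list(power = power, k_neighbors = k_neighbors,
                 max_radius_km = max_radius_km,
                 exact_hit_epsilon_km = exact_hit_epsilon_km),
            class = "idw_config")
}

#' Inverse-distance-weighted estimate at a query point
#'
#' Weights the k nearest in-radius neighbors by distance^(-power). If any
#' neighbor sits within `exact_hit_epsilon_km` of the query, the mean value of
#' those coincident neighbors is returned instead. The estimate always lies
#' within the range of the neighbor values used.
#'
#' @param distances_km Great-circle distances to neighbors (km, >= 0).
#' @param values Neighbor DV values (kelvin).
#' @param cfg An [idw_config()].
#' @return Estimate in kelvin, or `NA` (with attribute `reason =
#'   "no_neighbors"`) when the radius/k truncation empties the neighbor set.
#' @export
idw_estimate <- function(distances_km, values, cfg = idw_config()) {
  stopifnot(length(distances_km) == length(values))
  ok <- is.finite(distances_km) & is.finite(values) & distances_km >= 0
  distances_km <- distances_km[ok]; values <- values[ok]
  if (cfg$max_radius_km > 0) {
    in_r <- distances_km <= cfg$max_radius_km
    distances_km <- distances_km[in_r]; values <- values[in_r]
  }
  if (length(values) == 0)
    return(structure(NA_real_, reason = "no_neighbors"))
  if (cfg$k_neighbors > 0 && length(values) > cfg$k_neighbors) {
    nearest <- order(distances_km)[seq_len(cfg$k_neighbors)]
    distances_km <- distances_km[nearest]; values <- values[nearest]
  }
  hit <- distances_km <= cfg$exact_hit_epsilon_km
  if (any(hit)) return(mean(values[hit]))
  w <- distances_km^(-cfg$power)
  sum(w * values) / sum(w)
}

#' Leave-self-out IDW feature for a training station-day
#'
#' Estimates the DV at a target station from the same day's other stations,
#' with the target's own station excluded. Returns `NA` when no neighbor
#' exists (e.g. a single-station day).
#'
#' @param target One StationDay row (needs `station_id`, `day`, `lon`, `lat`).
#' @param all_days Station-day table for the same DV.
#' @param dv Column of `all_days` holding the DV value.
#' @param cfg An [idw_config()].
#' @return Kelvin estimate or `NA`.
#' @export
idw_training_feature <- function(target, all_days, dv = "humid_mean",
                                 cfg = idw_config()) {
  same_day <- all_days[all_days$day == target$day &
                         all_days$station_id != target$station_id, ,
                       drop = FALSE]
  if (nrow(same_day) == 0)
    return(structure(NA_real_, reason = "no_neighbors"))
  d <- haversine_km(target$lon, target$lat, same_day$lon, same_day$lat)
  idw_estimate(d, same_day[[dv]], cfg)
}

# Vectorized leave-self-out IDW over a whole station-day table (or IDW from a
# separate donor pool): the workhorse behind feature assembly and per-fold
# recomputation in cross-validation. `donors` defaults to `rows` itself, and
# a donor with the same station_id as a query row is always excluded for that
# row.
idw_features_all <- function(rows, dv, cfg = idw_config(), donors = rows) {
  out <- rep(NA_real_, nrow(rows))
  for (day in unique(rows$day)) {
    qi <- which(rows$day == day)
    di <- which(donors$day == day)
    if (!length(di)) next
    dsub <- donors[di, , drop = FALSE]
    for (j in qi) {
      use <- dsub$station_id != rows$station_id[j]
      if (!any(use)) next
      d <- haversine_km(rows$lon[j], rows$lat[j],
                        dsub$lon[use], dsub$lat[use])
      out[j] <- idw_estimate(d, dsub[[dv]][use], cfg)
    }
  }
  out
}
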