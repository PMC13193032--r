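# Synthetic study generator: a smooth spatiotemporal dew-point/temperature
# truth with station noise, gridded predictor versions of the field with
# bias and gaps, cloud-masked column water vapor, static covariates with
# known effects, and a regional partition -- everything the pipeline ingests,
# with ground truth retained for oracles.

#' Configuration for the synthetic study
#'
#' Defaults define the package's standard desk-scale scenario: 150 stations
#' over an 8 x 6 degree domain, 30 days, 8 observations per day, 1 K
#' observation noise, a smooth field with a ~500 km length scale, moderate
#' linear covariate effects, and biased/masked gridded predictors. The truth
#' field is a sum of low-frequency sinusoidal spatial basis functions (O(1)
#' evaluation at arbitrary points), a slow temporal component, a diurnal
#' harmonic, and local land-use effects; local effects appear at stations but
#' not in the gridded fields, which emulates reanalysis products that do not
#' resolve local land-use signals.
#'
#' @param n_stations Stations in the network.
#' @param bbox Named numeric: `lon_min, lon_max, lat_min, lat_max`.
#' @param n_days Study days.
#' @param start_day First study day (`Date`).
#' @param obs_hours Sub-daily sampling schedule, hours into the study day.
#' @param noise_sd Station observation noise, kelvin.
#' @param spatial_sd,length_scale_km Smooth spatial component: SD (K) and
#'   correlation length (km).
#' @param temporal_sd,temporal_scale_days Slow temporal component: SD (K) and
#'   period scale (days).
#' @param elev_scale_km Length scale of the synthetic terrain; kept well below
#'   the moisture field's scale, since terrain varies faster than synoptic
#'   moisture.
#' @param diurnal_amp_td,diurnal_amp_t Diurnal harmonic amplitudes (K) for dew
#'   point and temperature.
#' @param effect_elevation_k_per_m,effect_dist_water_k_per_km Linear local
#'   covariate effects on dew point.
#' @param nonlinear_step_k Amplitude (K) of a step effect of elevation above
#'   its domain median; 0 in the default scenario, positive in the nonlinear
#'   scenario used for model-ordering checks.
#' @param fine_res_deg Fine grid resolution (coarse is 2x, so coarse cells
#'   are exact block means of fine cells).
#' @param grid_bias_sd SD (K) of the smooth spatial bias added to gridded
#'   fields (the signal the residual learner corrects).
#' @param coast_band_deg Width of the western band where the fine grid is
#'   missing (exercises the coarse fallback).
#' @param cloud_fraction Fraction of CWV cells flagged cloudy in QA.
#' @param cwv_noise_sd Noise SD (cm) on the CWV transform.
#' @param missing_dew_fraction Fraction of observations with dew point
#'   removed (exercises cleaning).
#' @param cluster_fraction Fraction of stations placed in tight clusters
#'   (exercises density weighting).
#' @param region_grid Regions as an `c(nx, ny)` spatial partition of the box.
#' @param seed Integer seed; all generators are reproducible given
#'   (config, seed).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_stations = 150,
    bbox = c(lon_min = -100, lon_max = -92, lat_min = 36, lat_max = 42),
    n_days = 30,
    start_day = as.Date("2010-06-01"),
    obs_hours = seq(1.5, 22.5, by = 3),
    noise_sd = 1.0,
    spatial_sd = 4, length_scale_km = 500,
    temporal_sd = 2, temporal_scale_days = 10,
    elev_scale_km = 120,
    diurnal_amp_td = 1.5, diurnal_amp_t = 5,
    effect_elevation_k_per_m = -0.003,
    effect_dist_water_k_per_km = -0.008,
    nonlinear_step_k = 0,
    fine_res_deg = 0.2,
    grid_bias_sd = 0.7,
    coast_band_deg = 0.4,
    cloud_fraction = 0.3,
    cwv_noise_sd = 0.1,
    missing_dew_fraction = 0.02,
    cluster_fraction = 0,
    region_grid = c(3, 3),
    seed = 1L) {
  stopifnot(noise_sd >= 0, fine_res_deg > 0,
            cloud_fraction >= 0, cloud_fraction <= 1,
            missing_dew_fraction >= 0, missing_dew_fraction <= 1,
            bbox["lon_min"] < bbox["lon_max"], bbox["lat_min"] < bbox["lat_max"])
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

# km coordinates relative to the box's southwest corner (local equirectangular)
.to_km <- function(cfg, lon, lat) {
  lat_mid <- (cfg$bbox[["lat_min"]] + cfg$bbox[["lat_max"]]) / 2
  list(x = (lon - cfg$bbox[["lon_min"]]) * 111.32 * cos(lat_mid * pi / 180),
       y = (lat - cfg$bbox[["lat_min"]]) * 111.32)
}

#' Generate the continuous ground-truth field
#'
#' Returns closures evaluating true dew point and temperature at arbitrary
#' (lon, lat, hour) where `hour` counts hours since the first study day's
#' midnight. `smooth_td`/`smooth_t` are the large-scale components (what the
#' gridded predictors see); `td`/`t` add the local covariate effects and are
#' what stations observe (before noise). Temperature stays at least 2 K above
#' dew point by construction.
#'
#' @param cfg A [synthetic_config()].
#' @return List of class `synthetic_truth` with functions `td`, `t`,
#'   `smooth_td`, `smooth_t`, `elevation_m`, `dist_water_km`, `local_effect`.
#' @export
generate_truth <- function(cfg) {
  set.seed(cfg$seed)
  # Random-direction sinusoids have correlation J0(2 pi d / L), which falls
  # to 1/2 at d = 0.242 L; the 4.13 multiplier makes `length_scale_km` the
  # distance at which the field's spatial correlation drops to 1/2.
  n_basis <- 24
  theta <- stats::runif(n_basis, 0, pi)
  wavelength <- cfg$length_scale_km * 4.13 * stats::runif(n_basis, 0.85, 1.15)
  phase <- stats::runif(n_basis, 0, 2 * pi)
  amp <- abs(stats::rnorm(n_basis))
  amp <- amp / sqrt(sum(amp^2) / 2) * cfg$spatial_sd  # sum of sin^2 -> sd

  n_tb <- 4
  t_period <- cfg$temporal_scale_days * 24 * stats::runif(n_tb, 0.8, 2.5)
  t_phase <- stats::runif(n_tb, 0, 2 * pi)
  t_amp <- abs(stats::rnorm(n_tb))
  t_amp <- t_amp / sqrt(sum(t_amp^2) / 2) * cfg$temporal_sd

  # independent smooth fields for elevation and the grid bias
  e_theta <- stats::runif(4, 0, pi)
  e_wl <- cfg$elev_scale_km * stats::runif(4, 0.7, 1.5)
  e_phase <- stats::runif(4, 0, 2 * pi)

  spatial <- function(lon, lat) {
    p <- .to_km(cfg, lon, lat)
    out <- 0
    for (m in seq_len(n_basis))
      out <- out + amp[m] *
        sin(2 * pi * (p$x * cos(theta[m]) + p$y * sin(theta[m])) /
              wavelength[m] + phase[m])
    out
  }
  temporal <- function(hour) {
    out <- 0
    for (m in seq_len(n_tb))
      out <- out + t_amp[m] * sin(2 * pi * hour / t_period[m] + t_phase[m])
    out
  }
  elevation_m <- function(lon, lat) {
    p <- .to_km(cfg, lon, lat)
    out <- 0
    for (m in 1:4)
      out <- out + sin(2 * pi * (p$x * cos(e_theta[m]) + p$y * sin(e_theta[m])) /
                         e_wl[m] + e_phase[m])
    400 + 180 * out + 0.25 * p$x   # ~ [-320, 1300] m, eastward ramp
  }
  dist_water_km <- function(lon, lat) {
    # "coast" = a wavy north-south line near the western box edge
    p <- .to_km(cfg, lon, lat)
    span_y <- (cfg$bbox[["lat_max"]] - cfg$bbox[["lat_min"]]) * 111.32
    coast_x <- 30 + 25 * sin(2 * pi * p$y / span_y)
    pmax(0, p$x - coast_x)
  }
  # piecewise-constant effect on a mid-elevation band: nearly orthogonal to
  # the linear elevation term, so a linear model cannot absorb it
  step_band <- c(300, 520)
  local_effect <- function(lon, lat) {
    ev <- elevation_m(lon, lat)
    cfg$effect_elevation_k_per_m * (ev - 400) +
      cfg$effect_dist_water_k_per_km * dist_water_km(lon, lat) +
      cfg$nonlinear_step_k * (ev > step_band[1] & ev < step_band[2])
  }
  smooth_td <- function(lon, lat, hour) {
    285 + spatial(lon, lat) + temporal(hour) +
      cfg$diurnal_amp_td * sin(2 * pi * (hour %% 24 - 4) / 24)
  }
  smooth_t <- function(lon, lat, hour) {
    smooth_td(lon, lat, hour) + 2 +
      cfg$diurnal_amp_t * (1 + sin(2 * pi * (hour %% 24 - 8) / 24))
  }
  structure(list(
    td = function(lon, lat, hour) smooth_td(lon, lat, hour) +
      local_effect(lon, lat),
    t = function(lon, lat, hour) smooth_t(lon, lat, hour) +
      pmax(0, local_effect(lon, lat)),
    smooth_td = smooth_td, smooth_t = smooth_t,
    elevation_m = elevation_m, dist_water_km = dist_water_km,
    local_effect = local_effect), class = "synthetic_truth")
}

# UTC instant at `hour` hours after the first study day's midnight (UTC-6)
.study_instant <- function(cfg, hour) {
  as.POSIXct(paste(format(cfg$start_day), "00:00:00"), tz = "UTC") +
    6 * 3600 + hour * 3600
}

#' Place the station network
#'
#' Uniform placement in the box, with an optional fraction of stations drawn
#' in tight clusters around random centers (to give density weighting and
#' isolation subsets something to detect).
#'
#' @param cfg A [synthetic_config()].
#' @return data.frame `station_id, lon, lat`.
#' @export
generate_stations <- function(cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_stations
  b <- cfg$bbox
  lon <- stats::runif(n, b[["lon_min"]], b[["lon_max"]])
  lat <- stats::runif(n, b[["lat_min"]], b[["lat_max"]])
  n_cl <- round(cfg$cluster_fraction * n)
  if (n_cl > 0) {
    k <- max(1, round(n_cl / 10))
    cx <- stats::runif(k, b[["lon_min"]], b[["lon_max"]])
    cy <- stats::runif(k, b[["lat_min"]], b[["lat_max"]])
    pick <- sample(k, n_cl, replace = TRUE)
    idx <- seq_len(n_cl)
    lon[idx] <- pmin(pmax(cx[pick] + stats::rnorm(n_cl, 0, 0.05), b[["lon_min"]]),
                     b[["lon_max"]])
    lat[idx] <- pmin(pmax(cy[pick] + stats::rnorm(n_cl, 0, 0.05), b[["lat_min"]]),
                     b[["lat_max"]])
  }
  data.frame(station_id = sprintf("S%03d", seq_len(n)), lon = lon, lat = lat,
             stringsAsFactors = FALSE)
}

#' Generate sub-daily station observations from the truth
#'
#' Each station-day is sampled at the configured schedule; observed values
#' are truth plus independent Gaussian noise, and a configured fraction of
#' records lose their dew point (to exercise cleaning).
#'
#' @param cfg A [synthetic_config()].
#' @param truth From [generate_truth()].
#' @param stations From [generate_stations()]; regenerated if omitted.
#' @return data.frame in the observation schema (`time` POSIXct UTC).
#' @export
generate_observations <- function(cfg, truth, stations = generate_stations(cfg)) {
  set.seed(cfg$seed + 2L)
  grid <- expand.grid(si = seq_len(nrow(stations)),
                      day = seq_len(cfg$n_days) - 1L,
                      h = cfg$obs_hours, KEEP.OUT.ATTRS = FALSE)
  hour_abs <- grid$day * 24 + grid$h
  lon <- stations$lon[grid$si]; lat <- stations$lat[grid$si]
  n <- nrow(grid)
  obs <- data.frame(
    station_id = stations$station_id[grid$si],
    lon = lon, lat = lat,
    time = .study_instant(cfg, hour_abs),
    temperature_k = truth$t(lon, lat, hour_abs) + stats::rnorm(n, 0, cfg$noise_sd),
    dew_point_k = truth$td(lon, lat, hour_abs) + stats::rnorm(n, 0, cfg$noise_sd),
    stringsAsFactors = FALSE)
  drop <- stats::runif(n) < cfg$missing_dew_fraction
  obs$dew_point_k[drop] <- NA_real_
  obs <- obs[order(obs$station_id, obs$time), ]
  rownames(obs) <- NULL
  obs
}

# regular cell-center axis covering [lo, hi] at resolution res
.axis <- function(lo, hi, res) seq(lo + res / 2, hi - res / 2 + 1e-9, by = res)

#' Generate gridded predictor fields from the truth
#'
#' Fine hourly humidity/temperature grids are the truth's smooth component at
#' cell centers plus a smooth spatial bias field (so the residual learner has
#' signal to correct); coarse grids are exact 2x2 block means of the
#' unmasked fine grids; fine cells in a western coastal band are then set
#' missing. Daily column water vapor is a monotone transform of daytime
#' dew point plus noise, with QA low bits set to the cloudy code (3) on a
#' random mask.
#'
#' @param cfg A [synthetic_config()].
#' @param truth From [generate_truth()].
#' @return List: hourly [grid_field()]s `fine_humid`, `fine_temp`,
#'   `coarse_humid`, `coarse_temp`; daily `cwv_terra`, `cwv_aqua` with QA.
#' @export
generate_grids <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  b <- cfg$bbox
  lon_f <- .axis(b[["lon_min"]], b[["lon_max"]], cfg$fine_res_deg)
  lat_f <- .axis(b[["lat_min"]], b[["lat_max"]], cfg$fine_res_deg)
  stopifnot(length(lon_f) %% 2 == 0, length(lat_f) %% 2 == 0)
  hours <- seq_len(cfg$n_days * 24) - 1L
  times <- .study_instant(cfg, hours)

  # smooth spatial bias, one realization per variable
  bias_field <- function() {
    th <- stats::runif(3, 0, pi); wl <- cfg$length_scale_km * stats::runif(3, 0.3, 0.8)
    ph <- stats::runif(3, 0, 2 * pi)
    a <- abs(stats::rnorm(3)); a <- a / sqrt(sum(a^2) / 2) * cfg$grid_bias_sd
    function(lon, lat) {
      p <- .to_km(cfg, lon, lat)
      out <- 0
      for (m in 1:3)
        out <- out + a[m] * sin(2 * pi * (p$x * cos(th[m]) + p$y * sin(th[m])) /
                                  wl[m] + ph[m])
      out
    }
  }
  bias_h <- bias_field(); bias_t <- bias_field()

  cells <- expand.grid(lon = lon_f, lat = lat_f, KEEP.OUT.ATTRS = FALSE)
  nl <- length(lon_f); nb <- length(lat_f); nt <- length(times)
  fh <- array(NA_real_, c(nl, nb, nt)); ft <- fh
  bh <- bias_h(cells$lon, cells$lat); bt <- bias_t(cells$lon, cells$lat)
  for (k in seq_len(nt)) {
    fh[, , k] <- truth$smooth_td(cells$lon, cells$lat, hours[k]) + bh
    ft[, , k] <- truth$smooth_t(cells$lon, cells$lat, hours[k]) + bt
  }

  # coarse = 2x2 block means of the unmasked fine values
  block_mean <- function(a) {
    m <- array(NA_real_, c(nl / 2, nb / 2, nt))
    for (i in seq_len(nl / 2)) for (j in seq_len(nb / 2))
      m[i, j, ] <- (a[2 * i - 1, 2 * j - 1, ] + a[2 * i, 2 * j - 1, ] +
                      a[2 * i - 1, 2 * j, ] + a[2 * i, 2 * j, ]) / 4
    m
  }
  lon_c <- (lon_f[seq(1, nl, 2)] + lon_f[seq(2, nl, 2)]) / 2
  lat_c <- (lat_f[seq(1, nb, 2)] + lat_f[seq(2, nb, 2)]) / 2
  ch <- block_mean(fh); ct <- block_mean(ft)

  # coastal gap in the fine grid
  gap <- lon_f < b[["lon_min"]] + cfg$coast_band_deg
  fh[gap, , ] <- NA_real_; ft[gap, , ] <- NA_real_

  # daily CWV: monotone transform of late-morning / early-afternoon dew point
  days <- cfg$start_day + seq_len(cfg$n_days) - 1L
  make_cwv <- function(local_hour, seed_shift) {
    set.seed(cfg$seed + seed_shift)
    vals <- array(NA_real_, c(nl, nb, cfg$n_days))
    qa <- array(0L, dim = dim(vals))
    for (d in seq_len(cfg$n_days)) {
      h <- (d - 1) * 24 + local_hour
      td <- truth$smooth_td(cells$lon, cells$lat, h)
      vals[, , d] <- exp((td - 273.15) / 20) +
        stats::rnorm(nl * nb, 0, cfg$cwv_noise_sd)
      cloudy <- stats::runif(nl * nb) < cfg$cloud_fraction
      q <- ifelse(cloudy, 3L, sample(c(0L, 1L, 2L, 4L, 5L), nl * nb,
                                     replace = TRUE))
      q <- q + 8L * sample(0:7, nl * nb, replace = TRUE)  # arbitrary high bits
      qa[, , d] <- q
    }
    grid_field(lon_f, lat_f, days, vals, qa = qa, units = "cm")
  }

  list(fine_humid = grid_field(lon_f, lat_f, times, fh),
       fine_temp = grid_field(lon_f, lat_f, times, ft),
       coarse_humid = grid_field(lon_c, lat_c, times, ch),
       coarse_temp = grid_field(lon_c, lat_c, times, ct),
       cwv_terra = make_cwv(10.5, 4L),
       cwv_aqua = make_cwv(13.5, 5L))
}

#' Generate static covariates and the regional partition
#'
#' Elevation and distance-from-water come from the truth's covariate fields
#' (so their configured effects are recoverable); population density is
#' log-normal and spatially clustered; isolation is each station's true
#' nearest-neighbor distance; the remaining registry features are plausible
#' correlates with no effect on truth. Regions are a `region_grid` spatial
#' partition of the box.
#'
#' @param cfg A [synthetic_config()].
#' @param truth From [generate_truth()].
#' @param stations From [generate_stations()].
#' @return List: `statics` (wide data.frame) and `regions`
#'   (data.frame `station_id, region`).
#' @export
generate_statics_and_regions <- function(cfg, truth,
                                         stations = generate_stations(cfg)) {
  set.seed(cfg$seed + 6L)
  n <- nrow(stations)
  iso <- vapply(seq_len(n), function(i)
    if (n == 1) Inf else min(haversine_km(stations$lon[i], stations$lat[i],
                                          stations$lon[-i], stations$lat[-i])),
    0)
  pop <- stats::rlnorm(n, meanlog = 4, sdlog = 1.5)
  statics <- data.frame(
    station_id = stations$station_id,
    elevation_m = truth$elevation_m(stations$lon, stations$lat),
    dist_water_km = truth$dist_water_km(stations$lon, stations$lat),
    pop_density = pop,
    isolation_km = iso,
    impervious_frac = stats::plogis(log(pop) - 5 + stats::rnorm(n, 0, 0.5)),
    canopy_frac = stats::runif(n),
    nightlights = log1p(pop) + stats::rnorm(n, 0, 0.3),
    urban_dist_km = stats::rexp(n, 1 / 30),
    slope_deg = abs(stats::rnorm(n, 0, 3)),
    stringsAsFactors = FALSE)
  b <- cfg$bbox
  gx <- pmin(cfg$region_grid[1], pmax(1, ceiling(
    (stations$lon - b[["lon_min"]]) / (b[["lon_max"]] - b[["lon_min"]]) *
      cfg$region_grid[1])))
  gy <- pmin(cfg$region_grid[2], pmax(1, ceiling(
    (stations$lat - b[["lat_min"]]) / (b[["lat_max"]] - b[["lat_min"]]) *
      cfg$region_grid[2])))
  regions <- data.frame(station_id = stations$station_id,
                        region = sprintf("R%d%d", gx, gy),
                        stringsAsFactors = FALSE)
  list(statics = statics, regions = regions)
}

#' Generate the complete synthetic input bundle
#'
#' Runs every generator and the observation-processing front end, returning
#' the pieces the modeling modules consume plus the retained truth.
#'
#' @param cfg A [synthetic_config()].
#' @param cleaning A [cleaning_config()] for the reduction to station-days.
#' @return List of class `synthetic_bundle`: `config`, `truth`, `stations`,
#'   `observations`, `station_days`, `grids`, `statics`, `regions`.
#' @export
generate_dataset <- function(cfg = synthetic_config(),
                             cleaning = cleaning_config()) {
  truth <- generate_truth(cfg)
  stations <- generate_stations(cfg)
  obs <- generate_observations(cfg, truth, stations)
  cleaned <- clean_observations(obs, cleaning)
  station_days <- derive_station_days(cleaned$kept, cleaning)
  grids <- generate_grids(cfg, truth)
  sr <- generate_statics_and_regions(cfg, truth, stations)
  structure(list(config = cfg, truth = truth, stations = stations,
                 observations = obs, station_days = station_days,
                 grids = grids, statics = sr$statics, regions = sr$regions),
            class = "synthetic_bundle")
}

#' Assemble the feature table for a synthetic bundle
#'
#' Convenience wrapper: builds the DV-matched daily predictor grids from the
#' bundle's hourly fields and assembles the feature table.
#'
#' @param bundle From [generate_dataset()].
#' @param dv_kind `"min"`, `"mean"` or `"max"`.
#' @param idw_cfg An [idw_config()].
#' @return Feature table (see [assemble_features()]).
#' @export
synthetic_features <- function(bundle, dv_kind = "mean",
                               idw_cfg = idw_config()) {
  daily <- build_daily_predictor_grids(bundle$grids$fine_humid,
                                       bundle$grids$fine_temp,
                                       bundle$grids$coarse_humid,
                                       bundle$grids$coarse_temp, dv_kind)
  assemble_features(bundle$station_days,
                    c(daily, list(cwv_terra = bundle$grids$cwv_terra,
                                  cwv_aqua = bundle$grids$cwv_aqua)),
                    bundle$statics, dv_kind, idw_cfg)
}

#' Write a synthetic bundle to disk in the package's text formats
#'
#' Observations, station-days, statics and regions as CSV; gridded fields as
#' long-format CSV via [write_grid_field()].
#'
#' @param bundle From [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_observations(file.path(dir, "observations.csv"), bundle$observations)
  write_station_days(file.path(dir, "station_days.csv"), bundle$station_days)
  utils::write.csv(bundle$statics, file.path(dir, "statics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$grids))
    write_grid_field(bundle$grids[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Named study scenarios
#'
#' `synthetic_config_nonlinear()` is the model-ordering scenario: a strong
#' piecewise-constant (mid-elevation band) covariate effect of 5 K that a
#' linear model cannot absorb, doubled linear effects, and a slightly smaller
#' network (100 stations, 20 days) so replicated comparisons stay cheap.
#' [desk_scale_hyperparameters()] are boosting settings sized for these
#' desk-scale row counts (a few thousand rows), where the heavy regularization
#' tuned for national-scale archives would underfit.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
synthetic_config_nonlinear <- function(seed = 1L) {
  synthetic_config(n_stations = 100, n_days = 20, nonlinear_step_k = 5,
                   effect_elevation_k_per_m = -0.006,
                   effect_dist_water_k_per_km = -0.016, seed = seed)
}

#' @rdname synthetic_config_nonlinear
#' @return An [hyperparameters()] object.
#' @export
desk_scale_hyperparameters <- function() {
  hyperparameters(600, 4, 0.1, 0, 1, 0)
}
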