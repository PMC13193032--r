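# Gridded-field handling and predictor assembly: nearest-cell lookup,
# DV-analogous daily aggregation, coarse fallback, QA filtering, and the
# assembled feature table.

make_hourly_pair <- function(nl = 6, nb = 5, day = as.Date("2010-06-01"),
                             f_h = function(i, j, h) 280 + i + j + 0.1 * h,
                             f_t = function(i, j, h) 290 - 0.1 * (h - 14)^2) {
  lon <- seq(-100 + 0.1, by = 0.2, length.out = nl)
  lat <- seq(36 + 0.1, by = 0.2, length.out = nb)
  times <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + 6 * 3600 +
    (0:23) * 3600
  hv <- array(0, c(nl, nb, 24)); tv <- hv
  for (i in 1:nl) for (j in 1:nb) for (h in 0:23) {
    hv[i, j, h + 1] <- f_h(i, j, h)
    tv[i, j, h + 1] <- f_t(i, j, h)
  }
  list(h = grid_field(lon, lat, times, hv),
       t = grid_field(lon, lat, times, tv))
}

test_that("nearest-cell lookup matches exhaustive search", {
  b <- small_bundle()
  g <- b$grids$cwv_terra
  day <- g$time[2]
  # exact cell center
  expect_equal(sample_grid(g, g$lon[3], g$lat[4], day), g$values[3, 4, 2])
  # outside the bounding box
  expect_true(is.na(sample_grid(g, min(g$lon) - 1, g$lat[1], day)))
  expect_true(is.na(sample_grid(g, g$lon[1], max(g$lat) + 0.5, day)))
  # 50 random points against brute force
  set.seed(11)
  lon <- runif(50, min(g$lon), max(g$lon))
  lat <- runif(50, min(g$lat), max(g$lat))
  got <- sample_grid(g, lon, lat, day)
  for (k in 1:50) {
    i <- which.min(abs(g$lon - lon[k])); j <- which.min(abs(g$lat - lat[k]))
    expect_identical(got[k], g$values[i, j, 2])
  }
})

test_that("daily aggregation follows the DV definitions", {
  pair <- make_hourly_pair()
  # constant humidity -> constant daily field for every dv kind
  const <- make_hourly_pair(f_h = function(i, j, h) 283)
  for (dv in c("min", "mean", "max")) {
    agg <- aggregate_hourly_to_dv(const$h, const$t, dv)
    expect_true(all(agg$humidity$values == 283))
  }
  # temperature peaks at hour 14 -> max-analog humidity is hour-14 humidity
  agg_max <- aggregate_hourly_to_dv(pair$h, pair$t, "max")
  expect_equal(agg_max$humidity$values[2, 3, 1], 280 + 2 + 3 + 0.1 * 14)
  expect_equal(agg_max$temperature$values[2, 3, 1], 290)
  # mean-analog equals the brute-force hourly average
  agg_mean <- aggregate_hourly_to_dv(pair$h, pair$t, "mean")
  expect_equal(agg_mean$humidity$values[4, 2, 1],
               mean(280 + 4 + 2 + 0.1 * (0:23)), tolerance = 1e-9)
  # ties in temperature go to the earliest hour
  flat <- make_hourly_pair(f_t = function(i, j, h) 290)
  agg_tie <- aggregate_hourly_to_dv(flat$h, flat$t, "max")
  expect_equal(agg_tie$humidity$values[1, 1, 1], 280 + 1 + 1 + 0)
  # adding a constant to humidity commutes with aggregation
  shifted <- make_hourly_pair(f_h = function(i, j, h) 280 + i + j + 0.1 * h + 2.5)
  for (dv in c("min", "mean", "max")) {
    a <- aggregate_hourly_to_dv(pair$h, pair$t, dv)$humidity$values
    s <- aggregate_hourly_to_dv(shifted$h, pair$t, dv)$humidity$values
    expect_equal(s, a + 2.5, tolerance = 1e-9)
  }
  # mismatched axes are rejected
  off <- grid_field(pair$h$lon + 1, pair$h$lat, pair$h$time, pair$h$values)
  expect_error(aggregate_hourly_to_dv(off, pair$t, "mean"), "axes")
})

test_that("coarse fallback fills exactly the missing fine cells", {
  lon_f <- seq(0.05, 0.95, by = 0.1); lat_f <- seq(0.05, 0.55, by = 0.1)
  day <- as.Date("2010-06-01")
  vf <- array(seq_len(length(lon_f) * length(lat_f)),
              c(length(lon_f), length(lat_f), 1))
  lon_c <- seq(0.1, 0.9, by = 0.2); lat_c <- seq(0.1, 0.5, by = 0.2)
  vc <- array(1000 + seq_len(length(lon_c) * length(lat_c)),
              c(length(lon_c), length(lat_c), 1))
  fine <- grid_field(lon_f, lat_f, day, vf)
  coarse <- grid_field(lon_c, lat_c, day, vc)
  # fully present fine: no-op
  full <- fill_from_coarse(fine, coarse)
  expect_equal(full$values, fine$values)
  expect_true(all(attr(full, "provenance") == "fine"))
  # fully missing fine: nearest-coarse resample everywhere
  empty <- fine; empty$values[] <- NA
  filled <- fill_from_coarse(empty, coarse)
  expect_true(all(attr(filled, "provenance") == "coarse"))
  for (i in seq_along(lon_f)) for (j in seq_along(lat_f)) {
    ic <- which.min(abs(lon_c - lon_f[i])); jc <- which.min(abs(lat_c - lat_f[j]))
    expect_equal(filled$values[i, j, 1], vc[ic, jc, 1])
  }
  # checkerboard: present fine values untouched, gaps from nearest coarse
  cb <- fine
  mask <- outer(seq_along(lon_f), seq_along(lat_f), function(i, j) (i + j) %% 2 == 0)
  cb$values[, , 1][mask] <- NA
  out <- fill_from_coarse(cb, coarse)
  expect_equal(out$values[, , 1][!mask], fine$values[, , 1][!mask])
  prov <- attr(out, "provenance")[, , 1]
  expect_true(all(prov[mask] == "coarse"))
  expect_true(all(prov[!mask] == "fine"))
})

test_that("the QA filter keeps exactly the non-cloudy cells", {
  qa <- 0:255
  g <- grid_field(seq(0.5, 255.5) / 100, 1, as.Date("2010-06-01"),
                  array(runif(256), c(256, 1, 1)),
                  qa = array(qa, c(256, 1, 1)))
  f <- filter_cwv(g)
  kept <- !is.na(f$values[, 1, 1])
  expect_identical(kept, bitwAnd(qa, 7L) != 3L)
  # the specific documented cases
  expect_false(kept[3 + 1])    # 0b011: cloudy
  expect_true(kept[2 + 1])     # 0b010
  expect_false(kept[11 + 1])   # 0b1011: only bits 0-2 tested
  # idempotent, and never resurrects cells
  f2 <- filter_cwv(f)
  expect_identical(f2$values, f$values)
  expect_lte(sum(!is.na(f$values)), sum(!is.na(g$values)))
  expect_error(filter_cwv(grid_field(1, 1, as.Date("2010-06-01"),
                                     array(1, c(1, 1, 1)))),
               "QA")
})

test_that("grid fields round-trip through long-format CSV", {
  b <- small_bundle()
  g <- b$grids$cwv_aqua
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_field(g, path)
  rt <- read_grid_field(path)
  expect_equal(rt$lon, g$lon)
  expect_equal(rt$values, g$values)
  expect_equal(rt$qa, g$qa)
  expect_equal(rt$time, g$time)
  # hourly fields too (subset for speed)
  gh <- b$grids$coarse_humid
  gh <- grid_field(gh$lon, gh$lat, gh$time[1:5], gh$values[, , 1:5])
  write_grid_field(gh, path)
  rt2 <- read_grid_field(path)
  expect_equal(as.numeric(rt2$time), as.numeric(gh$time[1:5]))
  expect_equal(rt2$values, gh$values, tolerance = 1e-12)
})

test_that("assembled features match independent per-row recomputation", {
  b <- small_bundle()
  ft <- small_features("mean")
  expect_equal(nrow(ft), nrow(b$station_days))
  expect_setequal(attr(ft, "feature_cols"),
                  c("idw", "era5_humid", "era5_temp", "cwv_terra", "cwv_aqua",
                    default_feature_registry()))
  expect_length(attr(ft, "feature_cols"), 18)
  daily <- build_daily_predictor_grids(b$grids$fine_humid, b$grids$fine_temp,
                                       b$grids$coarse_humid,
                                       b$grids$coarse_temp, "mean")
  terra <- filter_cwv(b$grids$cwv_terra)
  set.seed(12)
  for (r in sample(nrow(ft), 10)) {
    row <- b$station_days[r, ]
    expect_equal(ft$y[r], row$humid_mean)
    expect_equal(ft$era5_humid[r],
                 sample_grid(daily$era5_humid, row$lon, row$lat, row$day))
    expect_equal(ft$cwv_terra[r],
                 sample_grid(terra, row$lon, row$lat, row$day))
    expect_equal(ft$idw[r],
                 idw_training_feature(row, b$station_days, "humid_mean",
                                      idw_config()),
                 tolerance = 1e-12)
    expect_equal(ft$elevation_m[r],
                 b$statics$elevation_m[b$statics$station_id == row$station_id])
  }
})

test_that("feature assembly is deterministic under row shuffling", {
  b <- small_bundle()
  ft <- small_features("mean")
  set.seed(13)
  days2 <- b$station_days[sample(nrow(b$station_days)), ]
  grids <- c(build_daily_predictor_grids(b$grids$fine_humid, b$grids$fine_temp,
                                         b$grids$coarse_humid,
                                         b$grids$coarse_temp, "mean"),
             list(cwv_terra = b$grids$cwv_terra, cwv_aqua = b$grids$cwv_aqua))
  ft2 <- assemble_features(days2, grids, b$statics, "mean")
  ord <- order(ft2$day, ft2$station_id)
  ft2 <- ft2[ord, ]
  rownames(ft2) <- NULL
  ft1 <- as.data.frame(ft)[order(ft$day, ft$station_id), ]
  rownames(ft1) <- NULL
  expect_equal(ft2, ft1, ignore_attr = TRUE)
})

test_that("a single-station day keeps its row with a missing IDW feature", {
  b <- small_bundle()
  days <- b$station_days[b$station_days$day == b$station_days$day[1], ]
  lone <- days[1, ]
  lone$day <- lone$day + 400
  both <- rbind(days, lone)
  grids <- c(build_daily_predictor_grids(b$grids$fine_humid, b$grids$fine_temp,
                                         b$grids$coarse_humid,
                                         b$grids$coarse_temp, "mean"),
             list(cwv_terra = NULL, cwv_aqua = NULL))
  ft <- assemble_features(both, grids, b$statics, "mean")
  lone_row <- ft[ft$day == lone$day, ]
  expect_equal(nrow(lone_row), 1)
  expect_true(is.na(lone_row$idw))
})

test_that("missing registry statics are rejected with the station named", {
  b <- small_bundle()
  grids <- c(build_daily_predictor_grids(b$grids$fine_humid, b$grids$fine_temp,
                                         b$grids$coarse_humid,
                                         b$grids$coarse_temp, "mean"),
             list(cwv_terra = NULL, cwv_aqua = NULL))
  statics_bad <- b$statics[, setdiff(names(b$statics), "pop_density")]
  expect_error(assemble_features(b$station_days, grids, statics_bad, "mean"),
               "pop_density")
  statics_na <- b$statics
  statics_na$elevation_m[2] <- NA
  expect_error(assemble_features(b$station_days, grids, statics_na, "mean"),
               statics_na$station_id[2])
})
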