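# Station-level cross-validation, weighted metrics, evaluation subsets,
# baseline comparison, and attribution summaries.

test_that("folds partition stations into near-equal groups, reproducibly", {
  f <- make_folds(sprintf("s%02d", 1:10), 5, seed = 2)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  f23 <- make_folds(sprintf("s%02d", 1:23), 5, seed = 2)
  expect_setequal(as.integer(table(f23$fold)), c(5L, 5L, 5L, 4L, 4L))
  expect_identical(make_folds(sprintf("s%02d", 1:23), 5, seed = 7),
                   make_folds(sprintf("s%02d", 1:23), 5, seed = 7))
  expect_error(make_folds(c("a", "b"), 5), "fewer stations")
})

test_that("weighted metrics reduce to the closed forms", {
  m <- weighted_metrics(c(286, 284), c(285, 285))
  expect_equal(m$rmse, 1); expect_equal(m$bias, 0)
  m1 <- weighted_metrics(283, 285)
  expect_equal(m1$sd, 0); expect_equal(m1$rmse, 2)
  set.seed(15)
  pred <- rnorm(40, 285); obs <- rnorm(40, 285); w <- rexp(40) + 0.1
  m <- weighted_metrics(pred, obs, w)
  e <- pred - obs
  expect_equal(m$rmse, sqrt(sum(w * e^2) / sum(w)), tolerance = 1e-12)
  expect_equal(m$bias, sum(w * e) / sum(w), tolerance = 1e-12)
  mu <- sum(w * obs) / sum(w)
  expect_equal(m$sd, sqrt(sum(w * (obs - mu)^2) / sum(w)), tolerance = 1e-12)
  expect_gte(m$rmse, abs(m$bias))
  # unit weights equal the unweighted formulas
  mu_u <- weighted_metrics(pred, obs)
  expect_equal(mu_u$rmse, sqrt(mean(e^2)), tolerance = 1e-12)
  expect_error(weighted_metrics(1, 1, 0), "positive")
})

test_that("inverse-density weights favor isolated stations", {
  st <- data.frame(station_id = c("iso", sprintf("c%d", 1:9)),
                   lon = c(-95, rep(-98, 9) + runif(9, 0, 0.05)),
                   lat = c(38, rep(40, 9) + runif(9, 0, 0.05)))
  w <- station_weights(st, "inverse_density", radius_km = 50)
  expect_gt(w$weight[w$station_id == "iso"],
            max(w$weight[w$station_id != "iso"]))
  expect_equal(mean(w$weight), 1)
  expect_true(all(station_weights(st, "uniform")$weight == 1))
  # brute-force neighbor counting oracle
  set.seed(16)
  st2 <- data.frame(station_id = sprintf("r%02d", 1:20),
                    lon = runif(20, -100, -98), lat = runif(20, 36, 38))
  w2 <- station_weights(st2, "inverse_density", radius_km = 50)
  raw <- sapply(1:20, function(i) {
    cnt <- 0
    for (j in setdiff(1:20, i))
      if (haversine_km(st2$lon[i], st2$lat[i], st2$lon[j], st2$lat[j]) <= 50)
        cnt <- cnt + 1
    1 / (1 + cnt)
  })
  expect_equal(w2$weight, raw / mean(raw), tolerance = 1e-12)
})

test_that("isolation and hot-day subsets agree with brute-force scans", {
  # threshold boundaries: 12 km
  close_pair <- data.frame(station_id = c("a", "b"), lon = c(0, 0),
                           lat = c(0, 11.9 / 111.195))
  expect_length(isolated_subset(close_pair, 12), 0)
  far_pair <- data.frame(station_id = c("a", "b"), lon = c(0, 0),
                         lat = c(0, 12.1 / 111.195))
  expect_setequal(isolated_subset(far_pair, 12), c("a", "b"))
  # random layout vs exhaustive nearest-neighbor scan
  set.seed(17)
  st <- data.frame(station_id = sprintf("s%02d", 1:30),
                   lon = runif(30, -100, -99), lat = runif(30, 36, 37))
  got <- isolated_subset(st, 12)
  want <- st$station_id[sapply(1:30, function(i)
    min(haversine_km(st$lon[i], st$lat[i], st$lon[-i], st$lat[-i])) >= 12)]
  expect_setequal(got, want)

  # hot subset: strict 92 F threshold
  thr <- fahrenheit_to_kelvin(92)
  sd_tab <- data.frame(temp_max = c(thr - 1e-6, thr, 306.49, 300))
  hot <- hot_subset(sd_tab)
  expect_equal(hot$temp_max, c(thr, 306.49))
  set.seed(18)
  sd_rand <- data.frame(temp_max = runif(200, 300, 312))
  expect_equal(nrow(hot_subset(sd_rand)),
               sum(sd_rand$temp_max >= fahrenheit_to_kelvin(92)))
})

test_that("every row gets exactly one out-of-fold prediction", {
  ft <- small_features("mean")
  folds <- make_folds(unique(ft$station_id), 5, seed = 1)
  hp <- hyperparameters(40, 3, 0.2, 0, 1, 0)
  cv <- cross_validate(ft, hp, folds, seed = 1,
                       region_map = small_bundle()$regions)
  expect_false(anyNA(cv$predictions$prediction))
  expect_equal(nrow(cv$predictions), nrow(ft))
  expect_setequal(unique(cv$predictions$fold), 0:4)
  # regional scopes partition the rows
  expect_equal(sum(cv$by_region$n_obs), cv$overall$n_obs)
  expect_gte(cv$overall$rmse, abs(cv$overall$bias))
})

test_that("poisoning a station's observations leaves its fold's predictions unchanged", {
  ft <- small_features("mean")
  folds <- make_folds(unique(ft$station_id), 5, seed = 1)
  hp <- hyperparameters(40, 3, 0.2, 0, 1, 0)
  cv <- cross_validate(ft, hp, folds, seed = 1)
  victim <- folds$station_id[1]
  vf <- folds$fold[1]
  poisoned <- ft
  poisoned$y[poisoned$station_id == victim] <- 999
  for (a in c("feature_cols", "registry", "dv_kind", "idw_cfg"))
    attr(poisoned, a) <- attr(ft, a)
  cv2 <- cross_validate(poisoned, hp, folds, seed = 1)
  in_fold <- cv$predictions$fold == vf
  expect_identical(cv2$predictions$prediction[in_fold],
                   cv$predictions$prediction[in_fold])
  # sanity: the poison did change other folds' models
  expect_false(isTRUE(all.equal(cv2$predictions$prediction[!in_fold],
                                cv$predictions$prediction[!in_fold])))
})

test_that("out-of-fold predictions are invariant to row order", {
  ft <- small_features("mean")
  folds <- make_folds(unique(ft$station_id), 5, seed = 1)
  hp <- hyperparameters(30, 3, 0.2, 0, 1, 0)
  cv1 <- cross_validate(ft, hp, folds, seed = 1)
  set.seed(19)
  perm <- sample(nrow(ft))
  cv2 <- cross_validate(subset_features(ft, perm), hp, folds, seed = 1)
  a <- cv1$predictions[order(cv1$predictions$station_id, cv1$predictions$day), ]
  b <- cv2$predictions[order(cv2$predictions$station_id, cv2$predictions$day), ]
  expect_equal(a$prediction, b$prediction, tolerance = 1e-9)
})

test_that("OLS recovers a noise-free linear truth almost exactly", {
  set.seed(20)
  n <- 400
  ft <- data.frame(
    station_id = sprintf("S%02d", rep(1:40, each = 10)),
    day = rep(as.Date("2010-06-01") + 0:9, times = 40),
    lon = rep(runif(40, -100, -95), each = 10),
    lat = rep(runif(40, 36, 40), each = 10),
    x1 = runif(n), x2 = rnorm(n))
  ft$y <- 280 + 2 * ft$x1 - 0.5 * ft$x2 + 0.1 * (ft$lon + 97)
  ft$idw <- 280  # uninformative constant baseline column
  attr(ft, "feature_cols") <- c("idw", "lon", "lat", "x1", "x2")
  folds <- make_folds(unique(ft$station_id), 5, seed = 3)
  cmp <- compare_baselines(ft, hyperparameters(10, 2, 0.3, 0, 1, 0), folds,
                           seed = 3, weights_scheme = "uniform",
                           idw_cfg = idw_config())
  expect_lt(cmp$summary$rmse[cmp$summary$model == "ols"], 0.05)
})

test_that("XIS stays close to IDW when predictors are pure noise", {
  b <- small_bundle()
  ft <- small_features("mean")
  # strip all predictor signal: replace features (except idw) with noise
  set.seed(21)
  noisy <- ft
  for (col in setdiff(attr(ft, "feature_cols"), "idw"))
    noisy[[col]] <- rnorm(nrow(ft))
  for (a in c("feature_cols", "registry", "dv_kind", "idw_cfg"))
    attr(noisy, a) <- attr(ft, a)
  folds <- make_folds(unique(ft$station_id), 5, seed = 2)
  cmp <- compare_baselines(noisy, default_hyperparameters("mean"), folds,
                           seed = 2)
  rmse <- setNames(cmp$summary$rmse, cmp$summary$model)
  expect_lt(abs(rmse["xis"] - rmse["idw_only"]), 0.1)
})

test_that("XIS is never much worse than its own IDW baseline under CV", {
  ft <- small_features("mean")
  folds <- make_folds(unique(ft$station_id), 5, seed = 4)
  cmp <- compare_baselines(ft, desk_scale_hyperparameters(), folds, seed = 4)
  rmse <- setNames(cmp$summary$rmse, cmp$summary$model)
  expect_lte(rmse["xis"], rmse["idw_only"] + 0.05)
})

test_that("attributions are additive and concentrate on real signal", {
  ft <- small_features("mean")
  m <- xis_fit(ft, hyperparameters(60, 4, 0.2, 0, 1, 0), seed = 5)
  att <- attribution_summary(m, ft, region_map = small_bundle()$regions)
  # additivity is asserted inside attribution_summary at 1e-4 K; confirm here
  resid_pred <- predict(m, ft) - ifelse(is.na(ft$idw), m$idw_fallback, ft$idw)
  sums <- rowSums(att$attributions) + att$base_value
  expect_equal(sums, resid_pred, tolerance = 1e-4)
  expect_setequal(att$overall$feature, m$feature_cols)
  expect_true(all(att$by_region$mean_abs_attribution >= 0))
  # a zero-round model attributes nothing
  m0 <- xis_fit(ft, hyperparameters(0, 1, 0.1, 0, 1, 0), seed = 5)
  att0 <- attribution_summary(m0, ft)
  expect_true(all(att0$overall$mean_abs_attribution == 0))
})

test_that("a single-feature model attributes everything to that feature", {
  ft <- toy_features()
  attr(ft, "feature_cols") <- "x1"
  ft$y <- ft$idw + 3 * ft$x1
  m <- xis_fit(ft, hyperparameters(60, 2, 0.3, 0, 0, 0), seed = 6)
  att <- attribution_summary(m, ft)
  resid_pred <- predict(m, ft) - ft$idw
  expect_equal(att$attributions[, "x1"] + att$base_value, resid_pred,
               tolerance = 1e-4)
})
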