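# Station-level cross-validation, weighted error metrics with regional and
# subset breakdowns, baseline comparators, and SHAP attribution summaries.

#' Partition stations into cross-validation folds
#'
#' Uniform random partition at the station level (all of a station's rows
#' share its fold) with fold sizes differing by at most one; deterministic
#' given the seed.
#'
#' @param stations Character vector of station ids (uniqueness enforced).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return data.frame `station_id, fold` with folds in `0:(k-1)`.
#' @export
make_folds <- function(stations, k = 5, seed = 1L) {
  stations <- unique(as.character(stations))
  if (length(stations) < k)
    stop("fewer stations (", length(stations), ") than folds (", k, ")")
  set.seed(seed)
  shuffled <- sample(stations)
  fold <- rep(seq_len(k) - 1L, length.out = length(stations))
  data.frame(station_id = shuffled, fold = fold, stringsAsFactors = FALSE)
}

#' Weighted SD / RMSE / bias
#'
#' RMSE = sqrt(sum(w e^2) / sum(w)) with e = prediction - observation;
#' bias = sum(w e) / sum(w); SD is the weighted standard deviation of the
#' observations about their weighted mean. With unit weights these reduce to
#' the unweighted formulas.
#'
#' @param prediction,observation Numeric vectors.
#' @param weight Positive weights (default unit).
#' @return List `sd, rmse, bias, n_obs`.
#' @export
weighted_metrics <- function(prediction, observation,
                             weight = rep(1, length(observation))) {
  stopifnot(length(prediction) == length(observation),
            length(weight) == length(observation))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weights must be positive and finite")
  e <- prediction - observation
  sw <- sum(weight)
  wmean <- sum(weight * observation) / sw
  list(sd = sqrt(sum(weight * (observation - wmean)^2) / sw),
       rmse = sqrt(sum(weight * e^2) / sw),
       bias = sum(weight * e) / sw,
       n_obs = length(observation))
}

#' Per-station evaluation weights
#'
#' `uniform` gives every station-day weight 1. `inverse_density` weights a
#' station proportionally to 1 / (1 + number of other stations within
#' `radius_km`), normalized to mean 1 across stations, so dense networks do
#' not dominate domain-wide error summaries.
#'
#' @param stations data.frame `station_id, lon, lat` (one row per station).
#' @param scheme `"uniform"` or `"inverse_density"`.
#' @param radius_km Neighborhood radius for the density count.
#' @return data.frame `station_id, weight`.
#' @export
station_weights <- function(stations, scheme = c("inverse_density", "uniform"),
                            radius_km = 50) {
  scheme <- match.arg(scheme)
  stations <- stations[!duplicated(stations$station_id), , drop = FALSE]
  n <- nrow(stations)
  if (scheme == "uniform") {
    w <- rep(1, n)
  } else {
    counts <- vapply(seq_len(n), function(i) {
      d <- haversine_km(stations$lon[i], stations$lat[i],
                        stations$lon[-i], stations$lat[-i])
      sum(d <= radius_km)
    }, 0L)
    w <- 1 / (1 + counts)
    w <- w / mean(w)
  }
  data.frame(station_id = stations$station_id, weight = w,
             stringsAsFactors = FALSE)
}

#' Stations isolated from the rest of the network
#'
#' A station is isolated when its nearest neighbor among the supplied
#' stations is at least `threshold_km` away.
#'
#' @param stations data.frame `station_id, lon, lat`.
#' @param threshold_km Isolation threshold (default 12 km).
#' @return Character vector of isolated station ids.
#' @export
isolated_subset <- function(stations, threshold_km = 12) {
  stations <- stations[!duplicated(stations$station_id), , drop = FALSE]
  n <- nrow(stations)
  if (n <= 1) return(stations$station_id)
  iso <- vapply(seq_len(n), function(i) {
    d <- haversine_km(stations$lon[i], stations$lat[i],
                      stations$lon[-i], stations$lat[-i])
    min(d) >= threshold_km
  }, TRUE)
  stations$station_id[iso]
}

#' Hot station-days
#'
#' Station-days whose maximum temperature reaches 92 F (306.483 K) or more;
#' this subset is conventionally evaluated unweighted.
#'
#' @param station_days data.frame with a `temp_max` column (kelvin).
#' @param threshold_f Threshold in Fahrenheit.
#' @return The subset data.frame.
#' @export
hot_subset <- function(station_days, threshold_f = 92) {
  station_days[station_days$temp_max >= fahrenheit_to_kelvin(threshold_f), ,
               drop = FALSE]
}

# station table (one row per station) from a feature/station-day table
.station_table <- function(rows) {
  s <- rows[!duplicated(rows$station_id), c("station_id", "lon", "lat")]
  rownames(s) <- NULL
  s
}

# per-row weights for a feature table under a scheme
.row_weights <- function(rows, weights_scheme, radius_km = 50) {
  w <- station_weights(.station_table(rows), weights_scheme, radius_km)
  w$weight[match(rows$station_id, w$station_id)]
}

.scope_metrics <- function(rows, scope_name) {
  m <- weighted_metrics(rows$prediction, rows$y, rows$weight)
  data.frame(scope = scope_name, n_obs = m$n_obs,
             n_sites = length(unique(rows$station_id)),
             sd = m$sd, rmse = m$rmse, bias = m$bias,
             stringsAsFactors = FALSE)
}

#' Station-level k-fold cross-validation of an XIS model
#'
#' For each fold, a model is trained on the rows of stations outside the fold
#' and predicts the rows of stations inside it, so no station is ever
#' evaluated by a model that saw it. The IDW feature is recomputed per fold:
#' validation rows take their IDW estimate from training-fold stations only,
#' and training rows take leave-self-out estimates within the training fold,
#' preventing leakage through the baseline.
#'
#' @param features Feature table from [assemble_features()].
#' @param hp An [hyperparameters()] object.
#' @param folds Fold assignment from [make_folds()].
#' @param seed Integer seed (per-fold fits derive from it).
#' @param region_map Optional data.frame `station_id, region` for the
#'   regional breakdown.
#' @param weights_scheme,weights_radius_km Passed to [station_weights()].
#' @param idw_cfg IDW settings; defaults to the snapshot stored on `features`.
#' @return List of class `xis_cv`: `predictions` (per-row out-of-fold
#'   prediction with fold and weight), `overall` and `by_region` metric
#'   tables, and the weighting metadata.
#' @export
cross_validate <- function(features, hp, folds, seed = 1L, region_map = NULL,
                           weights_scheme = "inverse_density",
                           weights_radius_km = 50,
                           idw_cfg = attr(features, "idw_cfg") %||% idw_config()) {
  fold_of <- folds$fold[match(features$station_id, folds$station_id)]
  if (anyNA(fold_of))
    stop("folds do not cover stations: ",
         paste(unique(features$station_id[is.na(fold_of)]), collapse = ", "))
  pred <- rep(NA_real_, nrow(features))
  for (f in sort(unique(folds$fold))) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    if (!length(va)) next
    train <- features[tr, , drop = FALSE]
    valid <- features[va, , drop = FALSE]
    train$idw <- idw_features_all(train, "y", idw_cfg)
    valid$idw <- idw_features_all(valid, "y", idw_cfg, donors = train)
    for (a in c("feature_cols", "registry", "dv_kind"))
      attr(train, a) <- attr(features, a)
    fit <- xis_fit(train, hp, seed = seed + f)
    pred[va] <- predict(fit, valid)
  }
  out <- data.frame(station_id = features$station_id, day = features$day,
                    y = features$y, prediction = pred, fold = fold_of,
                    weight = .row_weights(features, weights_scheme,
                                          weights_radius_km),
                    stringsAsFactors = FALSE)
  out$lon <- features$lon; out$lat <- features$lat
  overall <- .scope_metrics(out, "overall")
  by_region <- NULL
  if (!is.null(region_map)) {
    reg <- region_map$region[match(out$station_id, region_map$station_id)]
    if (anyNA(reg))
      stop("region map does not cover stations: ",
           paste(unique(out$station_id[is.na(reg)]), collapse = ", "))
    by_region <- do.call(rbind, lapply(sort(unique(reg)), function(r) {
      m <- .scope_metrics(out[reg == r, , drop = FALSE], r)
      names(m)[1] <- "region"
      m
    }))
  }
  structure(list(predictions = out, overall = overall, by_region = by_region,
                 weights_scheme = weights_scheme,
                 weights_radius_km = weights_radius_km),
            class = "xis_cv")
}

#' @export
print.xis_cv <- function(x, ...) {
  cat(sprintf("<xis_cv> %d out-of-fold predictions, %d stations (weights: %s)\n",
              nrow(x$predictions), length(unique(x$predictions$station_id)),
              x$weights_scheme))
  print(x$overall, row.names = FALSE)
  invisible(x)
}

# OLS with per-feature training-median imputation; falls back to a small
# ridge when the design is singular.
.ols_fit <- function(train_x, train_y) {
  med <- apply(train_x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  impute <- function(x) {
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
    x
  }
  X <- cbind(`(Intercept)` = 1, impute(train_x))
  fit <- stats::lm.fit(X, train_y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("singular OLS design; using ridge fallback")
    lam <- 1e-6 * mean(diag(crossprod(X)))
    beta <- solve(crossprod(X) + lam * diag(ncol(X)), crossprod(X, train_y))[, 1]
  }
  list(beta = beta, impute = impute)
}

.ols_predict <- function(model, x) {
  as.vector(cbind(1, model$impute(x)) %*% model$beta)
}

#' Compare XIS against IDW-only and OLS baselines under identical folds
#'
#' `idw_only` predicts the (per-fold recomputed) IDW feature directly, `ols`
#' is ordinary least squares on the full predictor vector (training-fold
#' median imputation of missing values, intercept included), and `xis` is the
#' boosted model. All three receive identical fold assignments and weighted
#' metrics.
#'
#' @inheritParams cross_validate
#' @return List: `summary` (data.frame `model, rmse, bias`), `metrics`
#'   (per-model full metric lists), and `predictions` (per-row out-of-fold
#'   predictions per model).
#' @export
compare_baselines <- function(features, hp, folds, seed = 1L,
                              weights_scheme = "inverse_density",
                              weights_radius_km = 50,
                              idw_cfg = attr(features, "idw_cfg") %||% idw_config()) {
  fold_of <- folds$fold[match(features$station_id, folds$station_id)]
  if (anyNA(fold_of)) stop("folds do not cover all stations")
  feature_cols <- attr(features, "feature_cols")
  n <- nrow(features)
  pred <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("idw_only", "ols", "xis")))
  for (f in sort(unique(folds$fold))) {
    tr <- which(fold_of != f); va <- which(fold_of == f)
    if (!length(va)) next
    train <- features[tr, , drop = FALSE]
    valid <- features[va, , drop = FALSE]
    train$idw <- idw_features_all(train, "y", idw_cfg)
    valid$idw <- idw_features_all(valid, "y", idw_cfg, donors = train)
    fallback <- mean(train$y)
    pred[va, "idw_only"] <- ifelse(is.na(valid$idw), fallback, valid$idw)
    ols <- .ols_fit(as.matrix(train[, feature_cols]), train$y)
    pred[va, "ols"] <- .ols_predict(ols, as.matrix(valid[, feature_cols]))
    for (a in c("feature_cols", "registry", "dv_kind"))
      attr(train, a) <- attr(features, a)
    fit <- xis_fit(train, hp, seed = seed + f)
    pred[va, "xis"] <- predict(fit, valid)
  }
  w <- .row_weights(features, weights_scheme, weights_radius_km)
  metrics <- lapply(colnames(pred), function(m)
    weighted_metrics(pred[, m], features$y, w))
  names(metrics) <- colnames(pred)
  summary <- data.frame(
    model = colnames(pred),
    rmse = vapply(metrics, `[[`, 0, "rmse"),
    bias = vapply(metrics, `[[`, 0, "bias"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, metrics = metrics,
       predictions = data.frame(station_id = features$station_id,
                                day = features$day, y = features$y,
                                pred, weight = w, check.names = FALSE))
}

#' Mean absolute SHAP attribution per feature
#'
#' Computes exact tree-additive (SHAP) attributions of the ensemble's
#' residual prediction for every row, verifies that per-row attributions plus
#' the base value reproduce the residual prediction, and summarizes the mean
#' absolute attribution per feature, overall and (optionally) per region.
#'
#' @param model An [xis_fit()] model.
#' @param features Feature table.
#' @param region_map Optional data.frame `station_id, region`.
#' @param tol Additivity tolerance, kelvin.
#' @return List: `overall` (data.frame `feature, mean_abs_attribution`),
#'   `by_region` (or NULL), `base_value`, and the per-row `attributions`
#'   matrix.
#' @export
attribution_summary <- function(model, features, region_map = NULL,
                                tol = 1e-4) {
  fc <- model$feature_cols
  if (is.null(model$booster)) {
    contrib <- matrix(0, nrow(features), length(fc) + 1,
                      dimnames = list(NULL, c(fc, "BIAS")))
  } else {
    mm <- .feature_matrix(features, fc)
    contrib <- predict(model$booster, xgboost::xgb.DMatrix(mm),
                       predcontrib = TRUE)
    colnames(contrib) <- c(fc, "BIAS")
    resid_pred <- .xis_residual_prediction(model, features)
    gap <- max(abs(rowSums(contrib) - resid_pred))
    if (gap > tol)
      stop(sprintf("attribution additivity violated: max gap %.2e K", gap))
  }
  atts <- contrib[, fc, drop = FALSE]
  overall <- data.frame(feature = fc,
                        mean_abs_attribution = colMeans(abs(atts)),
                        row.names = NULL, stringsAsFactors = FALSE)
  by_region <- NULL
  if (!is.null(region_map)) {
    reg <- region_map$region[match(features$station_id, region_map$station_id)]
    by_region <- do.call(rbind, lapply(sort(unique(reg)), function(r) {
      data.frame(region = r, feature = fc,
                 mean_abs_attribution =
                   colMeans(abs(atts[reg == r, , drop = FALSE])),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  list(overall = overall[order(-overall$mean_abs_attribution), ],
       by_region = by_region,
       base_value = mean(contrib[, "BIAS"]),
       attributions = atts)
}
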