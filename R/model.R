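# The XIS estimator: gradient-boosted trees fit to the observation-minus-IDW
# residual, plus hyperparameter search (maximin Latin hypercube) and the
# RMSEZ tuning criterion.

#' Gradient-boosting hyperparameters
#'
#' @param nrounds Boosting rounds (>= 0; 0 yields the pure-IDW identity).
#' @param max_depth Tree depth (>= 1).
#' @param eta Learning rate in (0, 1].
#' @param gamma Minimum split-loss reduction (>= 0).
#' @param lambda L2 weight penalty (>= 0).
#' @param alpha L1 weight penalty (>= 0).
#' @return List of class `xis_hyperparameters`.
#' @export
hyperparameters <- function(nrounds, max_depth, eta, gamma, lambda, alpha) {
  stopifnot(nrounds >= 0, max_depth >= 1, eta > 0, eta <= 1,
            gamma >= 0, lambda >= 0, alpha >= 0)
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth),
                 eta = eta, gamma = gamma, lambda = lambda, alpha = alpha),
            class = "xis_hyperparameters")
}

#' Tuned default hyperparameters per dependent variable
#'
#' The selected values from the national-scale tuning: T-min and mean
#' humidity share one vector, T-max humidity has its own.
#'
#' @param dv_kind `"min"`, `"mean"` or `"max"`.
#' @return An [hyperparameters()] object.
#' @export
default_hyperparameters <- function(dv_kind = c("mean", "min", "max")) {
  dv_kind <- match.arg(dv_kind)
  switch(dv_kind,
    min  = hyperparameters(500, 9, 0.078, 0.38, 360, 0.57),
    mean = hyperparameters(500, 9, 0.078, 0.38, 360, 0.57),
    max  = hyperparameters(500, 9, 0.051, 0.37, 120, 0.28))
}

# feature matrix (xgboost order) from an assembled feature table
.feature_matrix <- function(features, feature_cols) {
  as.matrix(features[, feature_cols, drop = FALSE])
}

#' Fit an XIS model
#'
#' The boosted ensemble is trained on the residual r = y - idw with a
#' squared-error objective, subsampling fixed at 1, and deterministic
#' behavior given the seed. Rows whose IDW feature is missing (single-station
#' days) use the training-set mean DV as the IDW fallback; the missingness
#' itself stays visible to the trees through the missing IDW feature.
#'
#' @param features Feature table from [assemble_features()] (needs `y` and
#'   the columns in `attr(features, "feature_cols")`).
#' @param hp An [hyperparameters()] object.
#' @param seed Integer seed.
#' @return Object of class `xis_model` with the booster, the feature-registry
#'   snapshot, the IDW-fallback value and training metadata.
#' @export
xis_fit <- function(features, hp = default_hyperparameters(
                      attr(features, "dv_kind") %||% "mean"),
                    seed = 1L) {
  if (nrow(features) == 0) stop("empty feature table")
  if (anyNA(features$y)) stop("every training row needs an observed DV")
  feature_cols <- attr(features, "feature_cols")
  if (is.null(feature_cols))
    stop("features must come from assemble_features() (no feature_cols attribute)")
  idw_fallback <- mean(features$y)
  idw_eff <- ifelse(is.na(features$idw), idw_fallback, features$idw)
  residual <- features$y - idw_eff
  booster <- NULL
  if (hp$nrounds > 0) {
    set.seed(seed)
    dtrain <- xgboost::xgb.DMatrix(.feature_matrix(features, feature_cols),
                                   label = residual)
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = hp$max_depth,
                    eta = hp$eta, gamma = hp$gamma, lambda = hp$lambda,
                    alpha = hp$alpha, subsample = 1, colsample_bytree = 1,
                    base_score = 0, nthread = 1, seed = seed),
      data = dtrain, nrounds = hp$nrounds, verbose = 0)
  }
  structure(list(booster = booster, hp = hp,
                 feature_cols = feature_cols,
                 registry = attr(features, "registry"),
                 dv_kind = attr(features, "dv_kind"),
                 idw_fallback = idw_fallback,
                 seed = seed, n_train = nrow(features)),
            class = "xis_model")
}

#' @export
print.xis_model <- function(x, ...) {
  cat(sprintf(
    "<xis_model> dv=%s, %d training rows, %d features, nrounds=%d depth=%d eta=%g\n",
    x$dv_kind %||% "?", x$n_train, length(x$feature_cols),
    x$hp$nrounds, x$hp$max_depth, x$hp$eta))
  invisible(x)
}

# residual-scale ensemble output (0 when nrounds = 0)
.xis_residual_prediction <- function(model, features) {
  if (is.null(model$booster)) return(rep(0, nrow(features)))
  mm <- .feature_matrix(features, model$feature_cols)
  predict(model$booster, xgboost::xgb.DMatrix(mm))
}

#' Predict from an XIS model
#'
#' prediction = IDW feature + ensemble residual; rows with a missing IDW
#' feature use the model's training-mean fallback, as in fitting.
#'
#' @param object An [xis_fit()] model.
#' @param features Feature table whose columns match the model's registry
#'   snapshot.
#' @param ... Unused.
#' @return Numeric predictions, kelvin.
#' @export
predict.xis_model <- function(object, features, ...) {
  missing_cols <- setdiff(object$feature_cols, names(features))
  if (length(missing_cols))
    stop("feature table lacks model features: ",
         paste(missing_cols, collapse = ", "))
  fc <- attr(features, "feature_cols")
  if (!is.null(fc)) {
    extra <- setdiff(fc, object$feature_cols)
    if (length(extra))
      stop("feature table has features unknown to the model: ",
           paste(extra, collapse = ", "))
  }
  idw_eff <- ifelse(is.na(features$idw), object$idw_fallback, features$idw)
  idw_eff + .xis_residual_prediction(object, features)
}

#' Maximin Latin-hypercube hyperparameter candidates
#'
#' Draws `n_designs` random Latin hypercube designs of `n` points in the unit
#' cube (one stratum per point and parameter) and keeps the design whose
#' minimum pairwise Euclidean distance is largest, then maps it onto the
#' supplied parameter bounds. Deterministic given `seed`.
#'
#' @param n Number of candidate vectors (>= 2).
#' @param bounds Named list: each element `c(lo, hi)`; names must be
#'   hyperparameter fields. Integer fields (`nrounds`, `max_depth`) are
#'   rounded.
#' @param seed Integer seed.
#' @param n_designs Random designs scanned for the maximin selection.
#' @return List of [hyperparameters()] with attribute `design` (the unit-cube
#'   matrix) and `min_distance`.
#' @export
sample_candidates <- function(n, bounds = default_tuning_bounds(), seed = 1L,
                              n_designs = 100L) {
  stopifnot(n >= 2, n_designs >= 1)
  k <- length(bounds)
  set.seed(seed)
  best <- NULL; best_d <- -Inf
  for (i in seq_len(n_designs)) {
    cand <- lhs::randomLHS(n, k)
    d <- min(stats::dist(cand))
    if (d > best_d) { best <- cand; best_d <- d }
  }
  colnames(best) <- names(bounds)
  scaled <- best
  for (j in seq_len(k)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    stopifnot(is.finite(lo), is.finite(hi), lo < hi)
    scaled[, j] <- lo + best[, j] * (hi - lo)
  }
  out <- lapply(seq_len(n), function(i) {
    v <- as.list(scaled[i, ])
    full <- list(nrounds = 100, max_depth = 6, eta = 0.1, gamma = 0,
                 lambda = 1, alpha = 0)
    full[names(v)] <- v
    full$nrounds <- round(full$nrounds)
    full$max_depth <- round(full$max_depth)
    do.call(hyperparameters, full)
  })
  attr(out, "design") <- best
  attr(out, "min_distance") <- best_d
  out
}

#' Default hyperparameter search bounds
#' @return Named list of `c(lo, hi)` ranges.
#' @export
default_tuning_bounds <- function() {
  list(nrounds = c(50, 600), max_depth = c(2, 10), eta = c(0.01, 0.3),
       gamma = c(0, 1), lambda = c(0, 500), alpha = c(0, 1))
}

#' RMSEZ: standardized cross-candidate tuning criterion
#'
#' Each region-year column of the candidate-by-column weighted-RMSE matrix is
#' standardized to z-scores across candidates (sample SD, n-1); a candidate's
#' `rmsez_mean` is the mean of its z-scores over columns and `rmsez_max` their
#' maximum. Lower is better. Columns with zero variance across candidates
#' yield z = 0 with a warning.
#'
#' @param scores Numeric matrix, candidates x region-year columns, no missing
#'   cells.
#' @return data.frame `candidate, rmsez_mean, rmsez_max`.
#' @export
rmsez <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("RMSEZ requires a complete candidate x column matrix")
  z <- apply(scores, 2, function(col) {
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance column in RMSEZ; z-scores set to 0")
      rep(0, length(col))
    } else (col - mean(col)) / s
  })
  z <- matrix(z, nrow = nrow(scores))
  data.frame(candidate = seq_len(nrow(scores)),
             rmsez_mean = rowMeans(z),
             rmsez_max = apply(z, 1, max))
}

#' Rank hyperparameter candidates by cross-validated regional RMSE
#'
#' Cross-validates each candidate on the supplied feature table(s) (one per
#' year), collects per-region weighted RMSEs, and summarizes them with
#' [rmsez()]. Final selection is left to the analyst: the ranked table
#' reports fit time alongside both RMSEZ summaries.
#'
#' @param feature_tables Named list (by year) of feature tables.
#' @param candidates List of [hyperparameters()] from [sample_candidates()].
#' @param region_map data.frame `station_id, region`.
#' @param folds_k Folds for station-level CV.
#' @param seed Integer seed.
#' @param weights_scheme Passed to [cross_validate()].
#' @return data.frame: candidate id, hyperparameters, fit seconds,
#'   `rmsez_mean`, `rmsez_max`, sorted by `rmsez_mean`.
#' @export
tune_candidates <- function(feature_tables, candidates, region_map,
                            folds_k = 5, seed = 1L,
                            weights_scheme = "inverse_density") {
  if (is.null(names(feature_tables)))
    names(feature_tables) <- paste0("year", seq_along(feature_tables))
  cols <- list(); times <- numeric(length(candidates))
  score_rows <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    t0 <- proc.time()[["elapsed"]]
    row <- c()
    for (yr in names(feature_tables)) {
      ft <- feature_tables[[yr]]
      cv <- cross_validate(ft, candidates[[ci]],
                           folds = make_folds(unique(ft$station_id), folds_k,
                                              seed = seed),
                           seed = seed, region_map = region_map,
                           weights_scheme = weights_scheme)
      reg <- cv$by_region
      row <- c(row, stats::setNames(reg$rmse, paste(yr, reg$region, sep = ":")))
    }
    score_rows[[ci]] <- row
    times[ci] <- proc.time()[["elapsed"]] - t0
  }
  scores <- do.call(rbind, score_rows)
  zz <- rmsez(scores)
  hp_df <- do.call(rbind, lapply(candidates, function(h)
    as.data.frame(unclass(h))))
  out <- cbind(candidate = zz$candidate, hp_df, fit_seconds = times,
               rmsez_mean = zz$rmsez_mean, rmsez_max = zz$rmsez_max)
  out[order(out$rmsez_mean), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
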