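# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# compact synthetic study: 30 stations, 6 days
small_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- generate_dataset(
      synthetic_config(n_stations = 30, n_days = 6, seed = 42))
  .fixture_env$bundle
}

small_features <- function(dv = "mean") {
  key <- paste0("feat_", dv)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- synthetic_features(small_bundle(), dv)
  .fixture_env[[key]]
}

# subsetting a feature table drops its attributes; re-attach them
subset_features <- function(ft, idx) {
  out <- ft[idx, , drop = FALSE]
  for (a in c("feature_cols", "registry", "dv_kind", "idw_cfg"))
    attr(out, a) <- attr(ft, a)
  out
}

# minimal hand-built feature table (for model-level tests that don't need
# the full synthetic pipeline)
toy_features <- function(n = 200, seed = 7, feature_cols = c("idw", "x1", "x2")) {
  set.seed(seed)
  ft <- data.frame(
    station_id = sprintf("S%02d", rep(seq_len(20), length.out = n)),
    day = as.Date("2010-06-01") + rep(seq_len(ceiling(n / 20)),
                                      each = 20)[seq_len(n)],
    idw = 280 + rnorm(n),
    x1 = runif(n), x2 = rnorm(n),
    stringsAsFactors = FALSE)
  ft$y <- ft$idw + 0.5 * ft$x1
  structure(ft, feature_cols = feature_cols, dv_kind = "mean")
}

rfc <- function(day, hour, offset = "-06:00") {
  sprintf("%sT%02d:%02d:00%s", day, hour %/% 1, round((hour %% 1) * 60), offset)
}

# the standard desk-scale scenario (memoized; used by the acceptance checks)
default_bundle <- function() {
  if (is.null(.fixture_env$default_bundle))
    .fixture_env$default_bundle <- generate_dataset(synthetic_config(seed = 1))
  .fixture_env$default_bundle
}

default_features <- function(dv = "max") {
  key <- paste0("default_feat_", dv)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- synthetic_features(default_bundle(), dv)
  .fixture_env[[key]]
}

# independent implementation of the NWS algorithm, written from the published
# Rothfusz regression and adjustment terms
nws_heat_index_oracle_f <- function(t_f, rh) {
  if (t_f < 80) return(0.5 * (t_f + 61 + (t_f - 68) * 1.2 + 0.094 * rh))
  hi <- (-42.379 + 2.04901523 * t_f + 10.14333127 * rh
         - 0.22475541 * t_f * rh - 0.00683783 * t_f * t_f
         - 0.05481717 * rh * rh + 0.00122874 * t_f * t_f * rh
         + 0.00085282 * t_f * rh * rh - 0.00000199 * t_f * t_f * rh * rh)
  if (rh < 13 && t_f <= 112)
    hi <- hi - ((13 - rh) / 4) * sqrt((17 - abs(t_f - 95)) / 17)
  if (rh > 85 && t_f <= 87)
    hi <- hi + ((rh - 85) / 10) * ((87 - t_f) / 5)
  hi
}

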