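#' Permutation variable importance of environmental drivers
#'
#' Ranks environmental factors by their importance for predicting
#' respiration using a bagged regression-tree ensemble (CART trees on
#' bootstrap samples with per-node random feature subsetting). Importance
#' of a variable is the mean increase in out-of-bag squared error when that
#' variable's values are permuted. Significance comes from a
#' response-permutation null with family-wise control: the response is
#' permuted `n_permutations` times, the ensemble refitted, and a variable
#' is significant when its observed importance exceeds the null
#' distribution of the *maximum* importance across variables — so with a
#' pure-noise response the chance of any false positive at level alpha is
#' about alpha, not alpha per variable. This significance scheme is this
#' package's choice.
#'
#' Feature columns are canonicalised (alphabetical) before fitting, so
#' importance and ranks do not depend on the column order of `features`.
#'
#' @param features data frame of numeric environmental factor columns
#'   (>= 8 rows); conventional names are ph, som, soc, tn, tp, an, ap,
#'   prcp, temp, rh.
#' @param response numeric response vector (e.g. seasonal mean respiration
#'   rates), same length as `nrow(features)`.
#' @param n_trees trees per ensemble (default 500).
#' @param n_permutations response permutations for the null (default 500).
#' @param mtry features tried per split; default `max(1, floor(p / 3))`.
#' @param min_node minimum node size (default 5).
#' @param seed integer seed or `NULL`.
#' @return data frame (one row per variable, ordered by rank): variable,
#'   importance, rank, p_value, star, plus attributes `oob_mse` and
#'   `n_permutations`.
#' @export
rank_variable_importance <- function(features, response, n_trees = 500L,
                                     n_permutations = 500L, mtry = NULL,
                                     min_node = 5L, seed = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) < 8)
    abort_fs("need >= 8 rows for the importance analysis", "fs_argument_error")
  if (length(response) != nrow(features))
    abort_fs("response length must match nrow(features)", "fs_argument_error")
  if (!all(vapply(features, is.numeric, TRUE)))
    abort_fs("all feature columns must be numeric", "fs_argument_error")
  keep <- is.finite(response) & stats::complete.cases(features)
  features <- features[keep, , drop = FALSE]
  response <- response[keep]
  if (nrow(features) < 8)
    abort_fs("fewer than 8 complete rows", "fs_argument_error")

  canon <- order(names(features))             # column-order invariance
  X <- as.matrix(features[, canon, drop = FALSE])
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))

  with_seed(seed, {
    obs <- rf_importance_cpp(X, response, as.integer(n_trees),
                             as.integer(mtry), as.integer(min_node))
    null_max <- vapply(seq_len(n_permutations), function(k) {
      imp <- rf_importance_cpp(X, sample(response), as.integer(n_trees),
                               as.integer(mtry),
                               as.integer(min_node))$importance
      max(imp)
    }, 0)
    imp <- obs$importance
    p_val <- vapply(imp, function(v) (1 + sum(null_max >= v)) /
                      (n_permutations + 1), 0)
    ord <- order(-imp, colnames(X))           # ties broken alphabetically
    out <- data.frame(variable = colnames(X)[ord],
                      importance = imp[ord],
                      rank = seq_len(p),
                      p_value = p_val[ord],
                      star = significance_star(p_val[ord]),
                      row.names = NULL)
    attr(out, "oob_mse") <- obs$oob_mse
    attr(out, "n_permutations") <- n_permutations
    out
  })
}

# Build stand x month rows joining monthly respiration means with monthly
# climate and seasonal chemistry, the aggregate table on which the
# correlation screen and importance ranking operate by default.
#' Assemble the environmental-driver table for one season
#'
#' Rows are stand x month within the requested season: monthly mean
#' respiration (`rs`), monthly climate aggregates (`temp` = mean air
#' temperature, `prcp` = total precipitation, `rh` = mean relative
#' humidity) and the stand's seasonal soil chemistry.
#'
#' @param measurements,climate,chemistry the three core tables.
#' @param season `"dry"` or `"wet"`.
#' @return data frame with columns stand_id, month, rs and the ten
#'   environmental factors.
#' @export
driver_table <- function(measurements, climate, chemistry,
                         season = c("dry", "wet")) {
  season <- match.arg(season)
  measurements <- validate_measurements(measurements)
  climate <- validate_climate(climate)
  chemistry <- validate_chemistry(chemistry)

  rs <- monthly_mean(measurements, "rs")
  rs <- rs[assign_season(paste0(rs$month, "-15")) == season, ]

  ym <- format(climate$date, "%Y-%m")
  key <- paste(climate$stand_id, ym, sep = "\t")
  clim <- data.frame(
    key = names(split(climate$air_temp, key)),
    temp = vapply(split(climate$air_temp, key), mean, 0),
    prcp = vapply(split(climate$precip, key), sum, 0),
    rh = vapply(split(climate$rh, key), mean, 0), row.names = NULL)

  rs$key <- paste(rs$stand_id, rs$month, sep = "\t")
  merged <- merge(rs[c("key", "stand_id", "month", "mean")], clim, by = "key")
  names(merged)[names(merged) == "mean"] <- "rs"
  chem <- chemistry[chemistry$season == season,
                    c("stand_id", CHEM_VARS)]
  merged <- merge(merged, chem, by = "stand_id")
  merged[order(merged$stand_id, merged$month),
         c("stand_id", "month", "rs", ENV_VARS)]
}
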