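#' Encode hydrographic predictors as network features
#'
#' Maps each sample to the fixed 11-feature vector
#' `latitude, longitude, depth, temperature, salinity, phosphate, nitrate,
#' silicate, year, week_sin, week_cos` (in this order). Week-of-year is
#' periodic, so it enters as `sin(2*pi*week/52)` and `cos(2*pi*week/52)`;
#' all other predictors pass through unchanged.
#'
#' @param table a hydrographic table (see [as_hydro_table()]).
#' @return numeric matrix, one row per sample, 11 named columns.
#' @export
encode_features <- function(table) {
  src <- c(latitude = "latitude", longitude = "longitude", depth = "depth_m",
           temperature = "temperature_c", salinity = "salinity",
           phosphate = "phosphate_umol_kg", nitrate = "nitrate_umol_kg",
           silicate = "silicate_umol_kg", year = "year_decimal",
           week = "week")
  for (nm in names(src)) {
    v <- table[[src[[nm]]]]
    if (is.null(v)) stop("missing predictor column: ", src[[nm]], call. = FALSE)
    if (any(!is.finite(v))) {
      stop(sprintf("predictor '%s' is missing or non-finite at row %d",
                   nm, which(!is.finite(v))[1]), call. = FALSE)
    }
  }
  week <- pmin(as.numeric(table$week), 52)
  ang <- 2 * pi * week / 52
  x <- cbind(latitude = table$latitude, longitude = table$longitude,
             depth = table$depth_m, temperature = table$temperature_c,
             salinity = table$salinity, phosphate = table$phosphate_umol_kg,
             nitrate = table$nitrate_umol_kg,
             silicate = table$silicate_umol_kg, year = table$year_decimal,
             week_sin = sin(ang), week_cos = cos(ang))
  x
}

#' Random train/test split
#'
#' Disjoint, exhaustive partition with `round(fraction_test * N)` test rows,
#' rounding halves away from zero (so 575.5 becomes 576). The same seed
#' always yields the same partition.
#'
#' @param n number of rows, or a data.frame whose rows are split.
#' @param fraction_test held-out fraction (default 0.10).
#' @param seed integer seed for the permutation.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(n, fraction_test = 0.10, seed) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 10) stop("need at least 10 labelled rows to split", call. = FALSE)
  n_test <- round_half_away(fraction_test * n)
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq.int(n_test + 1L, n)]),
       test = sort(idx[seq_len(n_test)]))
}

round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Regression metrics on a held-out set
#'
#' Mean absolute error, mean squared error, its square root, and the
#' coefficient of determination `r2 = 1 - SS_res / SS_tot` (total sum of
#' squares about the observation mean). With zero variance in the
#' observations `r2` is undefined and returned as `NA`.
#'
#' @param predictions,observations equal-length finite numeric vectors
#'   (length >= 2), in target units.
#' @return named list `mae`, `mse`, `rmse`, `r2`, `n`.
#' @export
evaluate <- function(predictions, observations) {
  if (length(predictions) != length(observations)) {
    stop("predictions and observations differ in length", call. = FALSE)
  }
  if (length(observations) < 2) stop("need at least 2 points", call. = FALSE)
  stopifnot(all(is.finite(predictions)), all(is.finite(observations)))
  e <- observations - predictions
  ss_tot <- sum((observations - mean(observations))^2)
  list(mae = mean(abs(e)),
       mse = mean(e^2),
       rmse = sqrt(mean(e^2)),
       r2 = if (ss_tot > 0) 1 - sum(e^2) / ss_tot else NA_real_,
       n = length(e))
}
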