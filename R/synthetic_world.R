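#' Specification of a synthetic coastal-hydrography world
#'
#' Defines every planted truth of the generator: station geometry, depth
#' bins, seasonal cycles of the predictors, the acidification trend field,
#' the linear alkalinity-salinity relationship, and per-variable observation
#' noise. A `world_spec` plus its seed fully determines the generated tables,
#' so recovery of any quantity can be judged against the spec itself.
#'
#' The pH field is
#' `ph(lat, depth, t) = ph_baseline + ph_lat_coef*(lat - lat0) +
#'  ph_depth_coef*depth + ph_seasonal_amplitude*sin(2*pi*t + ph_phase) +
#'  trend(lat, depth)*(t - t_ref)`,
#' with `t_ref = years[1]` and the trend a linear field in latitude and
#' depth. Nutrients load on the same seasonal driver with opposite sign
#' (nutrient-rich upwelled water is low-pH water), temperature and salinity
#' carry their own annual cycles, and total alkalinity is linear in the
#' *observed* salinity: `ta = ta_intercept + ta_salinity_slope*S +
#' ta_trend_per_year*(t - t_ref)`.
#'
#' @param seed integer; fully determines the generated tables.
#' @param n_stations number of monitoring stations (default 6).
#' @param depth_bins two-column matrix of (lo, hi) depth bins in metres,
#'   ascending and non-overlapping; default 0-5, 5-10, 10-15 m. Binned data
#'   are represented by the bin midpoint.
#' @param years numeric length-2, calendar span of the weekly prediction
#'   series (default 1995-2020).
#' @param train_years numeric length-2, span of the irregular training
#'   cruises (default 1976-2018).
#' @param n_train_ph,n_train_ta number of training records carrying a pH /
#'   alkalinity label (defaults 5755 and 3850; overlap allowed).
#' @param ph_baseline surface pH at the reference latitude and `t_ref`.
#' @param ph_seasonal_amplitude amplitude of the annual pH cycle (pH units).
#' @param ph_phase phase of the annual cycle (radians).
#' @param ph_lat_coef,ph_depth_coef spatial pH gradients (per degree N,
#'   per metre).
#' @param ph_trend_per_year acidification trend. Either a scalar (uniform
#'   field), `NULL` (default linear field whose values at the station/depth
#'   strata span about -0.0042 to -0.0025 pH yr^-1, strongest at the surface
#'   and at the inner stations), or an `n_stations x nrow(depth_bins)` matrix
#'   of per-stratum targets to which a linear field in (latitude, depth) is
#'   fitted; the achieved per-stratum values are reported in the truth.
#' @param ta_salinity_slope slope of TA on salinity (umol kg^-1 per salinity
#'   unit; default 46.7).
#' @param ta_intercept TA at salinity 0 (umol kg^-1).
#' @param ta_trend_per_year planted TA trend (umol kg^-1 yr^-1).
#' @param temp_mean,temp_amplitude,temp_phase,temp_depth_coef temperature
#'   cycle (deg C).
#' @param sal_mean,sal_amplitude,sal_phase,sal_depth_coef salinity cycle.
#' @param phosphate_mean,nitrate_mean,silicate_mean nutrient means
#'   (umol kg^-1).
#' @param phosphate_loading,nitrate_loading,silicate_loading loadings on the
#'   (anti-pH) seasonal upwelling driver.
#' @param noise_sd named numeric vector of additive zero-mean Gaussian
#'   observation noise SDs; names `temperature`, `salinity`, `phosphate`,
#'   `nitrate`, `silicate`, `ph`, `ta`.
#' @param gap_fraction fraction of weekly rows randomly dropped per stratum
#'   (default 0: complete coverage).
#' @param sampling_bias seasonal bias of cruise sampling times (0 = uniform;
#'   b > 0 weights times by `1 + b*sin(2*pi*t + ph_phase)`).
#' @return an object of class `world_spec`.
#' @export
world_spec <- function(seed,
                       n_stations = 6L,
                       depth_bins = rbind(c(0, 5), c(5, 10), c(10, 15)),
                       years = c(1995, 2020),
                       train_years = c(1976, 2018),
                       n_train_ph = 5755L,
                       n_train_ta = 3850L,
                       ph_baseline = 8.15,
                       ph_seasonal_amplitude = 0.05,
                       ph_phase = 0.5,
                       ph_lat_coef = 0.05,
                       ph_depth_coef = -0.004,
                       ph_trend_per_year = NULL,
                       ta_salinity_slope = 46.7,
                       ta_intercept = 700,
                       ta_trend_per_year = 0.8,
                       temp_mean = 14.5,
                       temp_amplitude = 3,
                       temp_phase = -2.4,
                       temp_depth_coef = -0.06,
                       sal_mean = 35.1,
                       sal_amplitude = 0.4,
                       sal_phase = -2.1,
                       sal_depth_coef = 0.012,
                       phosphate_mean = 0.4,
                       nitrate_mean = 5,
                       silicate_mean = 4,
                       phosphate_loading = 0.25,
                       nitrate_loading = 3,
                       silicate_loading = 2.5,
                       noise_sd = c(temperature = 0.3, salinity = 0.15,
                                    phosphate = 0.05, nitrate = 0.5,
                                    silicate = 0.5, ph = 0.02, ta = 10),
                       gap_fraction = 0,
                       sampling_bias = 0) {
  spec <- list(
    seed = as.integer(seed), n_stations = as.integer(n_stations),
    depth_bins = as.matrix(depth_bins), years = as.numeric(years),
    train_years = as.numeric(train_years),
    n_train_ph = as.integer(n_train_ph), n_train_ta = as.integer(n_train_ta),
    ph_baseline = ph_baseline,
    ph_seasonal_amplitude = ph_seasonal_amplitude, ph_phase = ph_phase,
    ph_lat_coef = ph_lat_coef, ph_depth_coef = ph_depth_coef,
    ph_trend_per_year = ph_trend_per_year,
    ta_salinity_slope = ta_salinity_slope, ta_intercept = ta_intercept,
    ta_trend_per_year = ta_trend_per_year,
    temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    temp_phase = temp_phase, temp_depth_coef = temp_depth_coef,
    sal_mean = sal_mean, sal_amplitude = sal_amplitude,
    sal_phase = sal_phase, sal_depth_coef = sal_depth_coef,
    phosphate_mean = phosphate_mean, nitrate_mean = nitrate_mean,
    silicate_mean = silicate_mean,
    phosphate_loading = phosphate_loading,
    nitrate_loading = nitrate_loading, silicate_loading = silicate_loading,
    noise_sd = noise_sd, gap_fraction = gap_fraction,
    sampling_bias = sampling_bias,
    # study-region geometry: latitudes 42-42.35 N, longitudes 8.6-9.11 W,
    # training samples in the upper 50 m
    region = list(lat = c(42.0, 42.35), lon = c(-9.11, -8.6),
                  depth = c(0, 50)),
    lat0 = 42.0, t_ref = as.numeric(years[1])
  )
  class(spec) <- "world_spec"
  validate_world_spec(spec)
  spec
}

validate_world_spec <- function(spec) {
  fail <- function(field, msg) {
    stop(sprintf("invalid world_spec field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.finite(spec$seed)) fail("seed", "must be a finite integer")
  if (spec$n_stations < 1) fail("n_stations", "must be >= 1")
  db <- spec$depth_bins
  if (ncol(db) != 2 || any(db[, 2] <= db[, 1])) {
    fail("depth_bins", "each bin needs hi > lo")
  }
  if (nrow(db) > 1 && any(db[-1, 1] < db[-nrow(db), 2])) {
    fail("depth_bins", "bins must be ascending and non-overlapping")
  }
  if (any(db < 0)) fail("depth_bins", "depths must be >= 0")
  if (diff(spec$years) <= 0) fail("years", "end must exceed start")
  if (diff(spec$train_years) <= 0) fail("train_years", "end must exceed start")
  if (spec$n_train_ph < 0 || spec$n_train_ta < 0) {
    fail("n_train_ph", "label counts must be >= 0")
  }
  need <- c("temperature", "salinity", "phosphate", "nitrate", "silicate",
            "ph", "ta")
  if (!all(need %in% names(spec$noise_sd))) {
    fail("noise_sd", paste("needs named entries:", paste(need, collapse = ", ")))
  }
  if (any(spec$noise_sd < 0)) fail("noise_sd", "noise SDs must be >= 0")
  if (spec$gap_fraction < 0 || spec$gap_fraction >= 1) {
    fail("gap_fraction", "must be in [0, 1)")
  }
  tr <- spec$ph_trend_per_year
  if (!is.null(tr) && !(length(tr) == 1L ||
      (is.matrix(tr) && all(dim(tr) == c(spec$n_stations, nrow(db)))))) {
    fail("ph_trend_per_year",
         "must be NULL, a scalar, or an n_stations x n_bins matrix")
  }
  invisible(spec)
}

# Station geometry: stations laid out along the embayment axis from the
# mouth (SW) to the inner reaches (NE), inside the study region.
world_stations <- function(spec) {
  n <- spec$n_stations
  r <- spec$region
  f <- if (n == 1) 0.5 else seq(0.08, 0.92, length.out = n)
  data.frame(
    station_id = sprintf("V%d", seq_len(n)),
    latitude = r$lat[1] + f * diff(r$lat) * 0.9,
    longitude = r$lon[1] + f * diff(r$lon) * 0.9,
    stringsAsFactors = FALSE
  )
}

# Linear acidification-trend field in (latitude, depth). Resolves the
# ph_trend_per_year option to coefficients c(intercept, lat, depth), where
# latitude is measured from spec$lat0.
trend_field_coefs <- function(spec) {
  tr <- spec$ph_trend_per_year
  if (is.null(tr)) {
    # default: strongest acidification at the surface of the inner (high
    # latitude) stations, weakening with depth; stratum values span about
    # [-0.0042, -0.0025] pH yr^-1
    return(c(intercept = -0.0038, lat = -0.0016, depth = 0.00009))
  }
  if (length(tr) == 1L) {
    return(c(intercept = as.numeric(tr), lat = 0, depth = 0))
  }
  st <- world_stations(spec)
  mid <- rowMeans(spec$depth_bins)
  g <- expand.grid(station = seq_len(spec$n_stations),
                   bin = seq_len(nrow(spec$depth_bins)))
  X <- cbind(1, st$latitude[g$station] - spec$lat0, mid[g$bin])
  y <- tr[cbind(g$station, g$bin)]
  co <- qr.coef(qr(X), y)
  co[is.na(co)] <- 0
  c(intercept = co[1], lat = co[2], depth = co[3])
}

eval_trend_field <- function(coefs, lat, depth, lat0) {
  coefs[["intercept"]] + coefs[["lat"]] * (lat - lat0) +
    coefs[["depth"]] * depth
}

# Noiseless generative fields ------------------------------------------------

true_ph_field <- function(spec, lat, depth, t, trend_coefs) {
  spec$ph_baseline +
    spec$ph_lat_coef * (lat - spec$lat0) +
    spec$ph_depth_coef * depth +
    spec$ph_seasonal_amplitude * sin(2 * pi * t + spec$ph_phase) +
    eval_trend_field(trend_coefs, lat, depth, spec$lat0) * (t - spec$t_ref)
}

true_temperature <- function(spec, depth, t) {
  spec$temp_mean + spec$temp_depth_coef * depth +
    spec$temp_amplitude * sin(2 * pi * t + spec$temp_phase)
}

true_salinity <- function(spec, depth, t) {
  spec$sal_mean + spec$sal_depth_coef * depth +
    spec$sal_amplitude * sin(2 * pi * t + spec$sal_phase)
}

# nutrients ride the upwelling driver in anti-phase with pH
true_nutrient <- function(mean, loading, spec, t) {
  mean - loading * sin(2 * pi * t + spec$ph_phase)
}

true_ta_field <- function(spec, salinity, t) {
  spec$ta_intercept + spec$ta_salinity_slope * salinity +
    spec$ta_trend_per_year * (t - spec$t_ref)
}

#' Noiseless planted labels for a hydrographic table
#'
#' Re-evaluates the generative formulas of a synthetic world at the rows of
#' a hydrographic table: the planted pH from position, depth and time, and
#' the planted alkalinity from the table's (observed) salinity and time.
#' Used to judge recovery, and to verify that generated labels decompose
#' exactly into their generator terms when all noise SDs are zero.
#'
#' @param truth the `truth` element returned by [generate_world()].
#' @param table a hydrographic table (data.frame) with columns `latitude`,
#'   `depth_m`, `year_decimal`, `salinity`.
#' @return data.frame with columns `ph` and `ta`.
#' @export
true_labels <- function(truth, table) {
  spec <- truth$spec
  data.frame(
    ph = true_ph_field(spec, table$latitude, table$depth_m,
                       table$year_decimal, truth$trend_coefs),
    ta = true_ta_field(spec, table$salinity, table$year_decimal)
  )
}

#' Generate a synthetic world: training cruises, weekly station series, truth
#'
#' Produces (a) an irregular training table of discrete hydrographic samples
#' carrying pH and/or alkalinity labels, emulating four decades of
#' oceanographic cruises over the study region, and (b) a complete weekly
#' prediction table at every station and depth bin over the study years,
#' with predictors observed (noisy) and labels absent. All planted truths
#' are returned so downstream recovery can be scored.
#'
#' @param spec a [world_spec()].
#' @return a list of class `synthetic_world` with elements
#'   \describe{
#'     \item{training}{data.frame of labelled discrete samples}
#'     \item{prediction}{data.frame of weekly unlabelled station rows}
#'     \item{truth}{list: the spec, the station table, the resolved trend
#'       field coefficients, and a per-stratum table of planted pH, TA and
#'       normalized-TA trends}
#'   }
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  validate_world_spec(spec)
  trend_coefs <- trend_field_coefs(spec)
  stations <- world_stations(spec)
  truth <- list(spec = spec, stations = stations, trend_coefs = trend_coefs,
                trend_table = stratum_truth_table(spec, stations, trend_coefs))

  training <- with_seed(derive_seed(spec$seed, "world-training"),
                        generate_training(spec, trend_coefs))
  prediction <- with_seed(derive_seed(spec$seed, "world-prediction"),
                          generate_prediction(spec, stations, trend_coefs))
  structure(list(training = training, prediction = prediction, truth = truth),
            class = "synthetic_world")
}

stratum_truth_table <- function(spec, stations, trend_coefs) {
  mid <- rowMeans(spec$depth_bins)
  bins <- sprintf("%g-%g", spec$depth_bins[, 1], spec$depth_bins[, 2])
  g <- expand.grid(station = seq_len(spec$n_stations),
                   bin = seq_len(nrow(spec$depth_bins)))
  data.frame(
    station_id = stations$station_id[g$station],
    depth_bin = bins[g$bin],
    latitude = stations$latitude[g$station],
    depth_m = mid[g$bin],
    ph_trend = eval_trend_field(trend_coefs, stations$latitude[g$station],
                                mid[g$bin], spec$lat0),
    ta_trend = spec$ta_trend_per_year,
    nta_trend = spec$ta_trend_per_year,
    stringsAsFactors = FALSE
  )
}

observe_predictors <- function(spec, lat, lon, depth, t) {
  n <- length(t)
  sd <- spec$noise_sd
  noise <- function(nm) if (sd[[nm]] > 0) stats::rnorm(n, 0, sd[[nm]]) else 0
  sal <- true_salinity(spec, depth, t) + noise("salinity")
  data.frame(
    latitude = lat, longitude = lon, depth_m = depth,
    date = decimal_year_to_date(t), year_decimal = t,
    week = iso_week(decimal_year_to_date(t)),
    temperature_c = true_temperature(spec, depth, t) + noise("temperature"),
    salinity = sal,
    phosphate_umol_kg = pmax(0, true_nutrient(spec$phosphate_mean,
      spec$phosphate_loading, spec, t) + noise("phosphate")),
    nitrate_umol_kg = pmax(0, true_nutrient(spec$nitrate_mean,
      spec$nitrate_loading, spec, t) + noise("nitrate")),
    silicate_umol_kg = pmax(0, true_nutrient(spec$silicate_mean,
      spec$silicate_loading, spec, t) + noise("silicate"))
  )
}

generate_training <- function(spec, trend_coefs) {
  n <- max(spec$n_train_ph, spec$n_train_ta)
  r <- spec$region
  # cruise times: uniform over the training span, optionally re-weighted by
  # a seasonal sampling bias (rejection sampling)
  t <- stats::runif(n, spec$train_years[1], spec$train_years[2])
  if (spec$sampling_bias > 0) {
    b <- spec$sampling_bias
    repeat {
      w <- (1 + b * sin(2 * pi * t + spec$ph_phase)) / (1 + b)
      bad <- stats::runif(n) > w
      if (!any(bad)) break
      t[bad] <- stats::runif(sum(bad), spec$train_years[1],
                             spec$train_years[2])
    }
  }
  lat <- stats::runif(n, r$lat[1], r$lat[2])
  lon <- stats::runif(n, r$lon[1], r$lon[2])
  depth <- stats::runif(n, r$depth[1], r$depth[2])
  tab <- observe_predictors(spec, lat, lon, depth, t)
  sd <- spec$noise_sd
  ph <- true_ph_field(spec, lat, depth, t, trend_coefs) +
    (if (sd[["ph"]] > 0) stats::rnorm(n, 0, sd[["ph"]]) else 0)
  ta <- true_ta_field(spec, tab$salinity, t) +
    (if (sd[["ta"]] > 0) stats::rnorm(n, 0, sd[["ta"]]) else 0)
  keep_ph <- sort(sample.int(n, spec$n_train_ph))
  keep_ta <- sort(sample.int(n, spec$n_train_ta))
  tab$ph <- replace(rep(NA_real_, n), keep_ph, ph[keep_ph])
  tab$ta_umol_kg <- replace(rep(NA_real_, n), keep_ta, ta[keep_ta])
  tab <- cbind(station_id = sprintf("C%05d", seq_len(n)), tab,
               stringsAsFactors = FALSE)
  as_hydro_table(tab)
}

generate_prediction <- function(spec, stations, trend_coefs) {
  dates <- weekly_dates(spec$years)
  t <- decimal_year(dates)
  mid <- rowMeans(spec$depth_bins)
  rows <- vector("list", spec$n_stations * length(mid))
  k <- 0
  for (s in seq_len(spec$n_stations)) {
    for (b in seq_along(mid)) {
      k <- k + 1
      tab <- observe_predictors(spec, stations$latitude[s],
                                stations$longitude[s], mid[b], t)
      tab <- cbind(station_id = stations$station_id[s], tab,
                   stringsAsFactors = FALSE)
      if (spec$gap_fraction > 0) {
        drop <- stats::runif(nrow(tab)) < spec$gap_fraction
        tab <- tab[!drop, , drop = FALSE]
      }
      rows[[k]] <- tab
    }
  }
  tab <- do.call(rbind, rows)
  tab$ph <- NA_real_
  tab$ta_umol_kg <- NA_real_
  rownames(tab) <- NULL
  as_hydro_table(tab)
}

#' Weekly sampling dates over a calendar span
#'
#' One sample every 7 days starting 4 January of the first year (inside the
#' first ISO week) and ending no later than 31 December of the last year.
#'
#' @param years numeric length-2 (start, end) calendar years.
#' @return a `Date` vector.
#' @export
weekly_dates <- function(years) {
  start <- as.Date(sprintf("%d-01-04", as.integer(years[1])))
  end <- as.Date(sprintf("%d-12-31", as.integer(years[2])))
  seq(start, end, by = 7)
}
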