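#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the data source (a synthetic
#' [world_spec()] or paths to real training/prediction tables in the same
#' delimited format), network settings, the alkalinity normalization method,
#' trend-fit settings, the output directory and the master seed. The master
#' seed fans out deterministically (see [derive_seed()]) to world
#' generation, the train/test splits and every member initialization, so a
#' config reruns bit-identically.
#'
#' @param world a [world_spec()], or `NULL` when real tables are given.
#' @param training_path,prediction_path CSV paths for real-data mode
#'   (exactly one of `world` / the path pair must be set).
#' @param seed master seed. Defaults to the world seed when a world is
#'   given.
#' @param nn list: `ph_layers`, `ta_layers` (hidden widths), `n_members`,
#'   `fraction_test`, `max_iter`, `tol`.
#' @param normalization list: `method` (`"empirical-global"`,
#'   `"empirical-stratum"` or `"reference"`) and `s_min`.
#' @param trends list: `confidence`, `z_max`.
#' @param output_dir directory for artifacts (created if needed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(world = NULL, training_path = NULL,
                            prediction_path = NULL, seed = NULL,
                            nn = list(), normalization = list(),
                            trends = list(), output_dir = tempfile("riacarb-")) {
  synthetic <- !is.null(world)
  real <- !is.null(training_path) || !is.null(prediction_path)
  if (synthetic == real) {
    stop("set exactly one data source: a world spec, or both table paths",
         call. = FALSE)
  }
  if (real && (is.null(training_path) || is.null(prediction_path))) {
    stop("real-data mode needs both training_path and prediction_path",
         call. = FALSE)
  }
  if (is.null(seed)) {
    if (!synthetic) stop("real-data mode needs an explicit seed", call. = FALSE)
    seed <- world$seed
  }
  nn <- utils::modifyList(list(ph_layers = c(28L, 10L), ta_layers = 40L,
                               n_members = 10L, fraction_test = 0.10,
                               max_iter = 200,
                               tol = c(gradient = 1e-6, gamma = 1e-3,
                                       f_rel = 1e-9)), nn)
  normalization <- utils::modifyList(list(method = "empirical-global",
                                          s_min = 5), normalization)
  if (!normalization$method %in%
      c("empirical-global", "empirical-stratum", "reference")) {
    stop("unknown normalization method: ", normalization$method,
         call. = FALSE)
  }
  trends <- utils::modifyList(list(confidence = 0.95, z_max = 3), trends)
  structure(list(world = world, training_path = training_path,
                 prediction_path = prediction_path, seed = as.integer(seed),
                 nn = nn, normalization = normalization, trends = trends,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full reconstruction pipeline
#'
#' Stages, in order: (1) generate or load the training and weekly prediction
#' tables; (2) train the pH and alkalinity ensembles; (3) predict weekly pH
#' and alkalinity at every station and depth bin; (4) transform pH to
#' hydrogen-ion concentration and normalize alkalinity to salinity 35;
#' (5) filter outliers and fit the seasonal-trend model per stratum and
#' variable. Artifacts written under `config$output_dir`: the input tables,
#' both serialized models, the predicted weekly series
#' (`predicted_series.csv`), the alkalinity-salinity slope table
#' (`alpha.csv`), the trend table (`trends.csv`) and a JSON run manifest
#' with config, per-stage wall times, artifact checksums and test metrics.
#' A stage failure aborts with the stage name after persisting the partial
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the run manifest, invisibly a list (also written as
#'   `manifest.json`); its `paths` element locates every artifact.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    training = file.path(config$output_dir, "training.csv"),
    prediction = file.path(config$output_dir, "prediction.csv"),
    model_ph = file.path(config$output_dir, "model_ph.json"),
    model_ta = file.path(config$output_dir, "model_ta.json"),
    predicted = file.path(config$output_dir, "predicted_series.csv"),
    alpha = file.path(config$output_dir, "alpha.csv"),
    trends = file.path(config$output_dir, "trends.csv"),
    metrics = file.path(config$output_dir, "metrics.csv"),
    manifest = file.path(config$output_dir, "manifest.json")
  )
  manifest <- list(package_version = as.character(utils::packageVersion("riacarb")),
                   seed = config$seed, stages = list(), paths = paths)
  say <- function(...) if (!quiet) message(sprintf(...))
  persist <- function() {
    jsonlite::write_json(manifest_serializable(manifest, config),
                         paths$manifest, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(err) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(err))
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(err)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  # stage 1: data
  dat <- stage("data", {
    if (!is.null(config$world)) {
      w <- generate_world(config$world)
      write_hydro_table(w$training, paths$training)
      write_hydro_table(w$prediction, paths$prediction)
      say("stage data: synthetic world seed %d (%d training, %d prediction rows)",
          config$world$seed, nrow(w$training), nrow(w$prediction))
      list(training = w$training, prediction = w$prediction, truth = w$truth)
    } else {
      tr <- read_hydro_table(config$training_path, training = TRUE)
      pr <- read_hydro_table(config$prediction_path)
      file.copy(config$training_path, paths$training, overwrite = TRUE)
      file.copy(config$prediction_path, paths$prediction, overwrite = TRUE)
      say("stage data: loaded %d training and %d prediction rows",
          nrow(tr), nrow(pr))
      list(training = tr, prediction = pr, truth = NULL)
    }
  })

  # stage 2: ensembles
  models <- stage("train", {
    m_ph <- train_ensemble(dat$training, "ph",
                           layer_sizes = config$nn$ph_layers,
                           n_members = config$nn$n_members,
                           fraction_test = config$nn$fraction_test,
                           seed = derive_seed(config$seed, "ensemble-ph"),
                           max_iter = config$nn$max_iter, tol = config$nn$tol)
    m_ta <- train_ensemble(dat$training, "ta",
                           layer_sizes = config$nn$ta_layers,
                           n_members = config$nn$n_members,
                           fraction_test = config$nn$fraction_test,
                           seed = derive_seed(config$seed, "ensemble-ta"),
                           max_iter = config$nn$max_iter, tol = config$nn$tol)
    write_ensemble(m_ph, paths$model_ph)
    write_ensemble(m_ta, paths$model_ta)
    say("stage train: pH test RMSE %.4g | TA test RMSE %.4g",
        m_ph$ensemble_metrics$rmse, m_ta$ensemble_metrics$rmse)
    list(ph = m_ph, ta = m_ta)
  })
  metrics <- summarize_table1(models$ph, models$ta)
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  manifest$test_metrics <- metrics[metrics$member == "ensemble", ]

  # stage 3: weekly projections
  pred <- stage("predict", {
    p <- dat$prediction
    p$ph <- predict(models$ph, p)
    p$ta_umol_kg <- predict(models$ta, p)
    say("stage predict: %d weekly rows projected", nrow(p))
    p
  })

  # stage 4: transforms and normalization. The alkalinity-salinity slopes
  # are fitted on the projected weekly series: station/depth strata only
  # exist there, and the projections are the alkalinity actually normalized.
  pred <- stage("transform", {
    alpha_tab <- alpha_table(pred)
    utils::write.csv(alpha_tab, paths$alpha, row.names = FALSE)
    pred$h_nmol_kg <- ph_to_h(pred$ph)
    pred$nta_umol_kg <- normalize_ta(pred, alpha_tab, config$normalization)
    utils::write.csv(as.data.frame(pred), paths$predicted, row.names = FALSE)
    g <- alpha_tab[alpha_tab$stratum == "global", ]
    say("stage transform: global alpha %.2f (r2 %.2f), method %s",
        g$alpha, g$r2, config$normalization$method)
    manifest$alpha_global <- list(alpha = g$alpha, r2 = g$r2, n = g$n)
    pred
  })

  # stage 5: trends
  trends <- stage("trends", {
    tt <- trends_from_predictions(pred,
                                  confidence = config$trends$confidence,
                                  z_max = config$trends$z_max)
    utils::write.csv(tt, paths$trends, row.names = FALSE)
    say("stage trends: %d series fitted (%d flagged)",
        nrow(tt), sum(tt$flag == "!"))
    tt
  })

  checked <- file.exists(unlist(paths[names(paths) != "manifest"]))
  manifest$checksums <- as.list(tools::md5sum(
    unlist(paths[names(paths) != "manifest"])[checked]))
  manifest$truth <- if (!is.null(dat$truth)) dat$truth$trend_table
  persist()
  manifest$models <- models
  manifest$trends <- trends
  manifest$predicted <- pred
  manifest$config <- config
  invisible(manifest)
}

# strip non-serializable pieces before writing the manifest
manifest_serializable <- function(manifest, config) {
  cfg <- unclass(config)
  if (!is.null(cfg$world)) cfg$world <- unclass(cfg$world)
  manifest$config <- cfg
  manifest
}

normalize_ta <- function(pred, alpha_tab, normalization) {
  method <- normalization$method
  if (method == "reference") {
    return(nta_reference(pred$ta_umol_kg, pred$salinity,
                         s_min = normalization$s_min))
  }
  global <- alpha_tab$alpha[alpha_tab$stratum == "global"]
  if (method == "empirical-global") {
    return(nta_empirical(pred$ta_umol_kg, pred$salinity, global))
  }
  # per-stratum slope where a stratum fit exists, global fallback
  key <- paste(pred$station_id, pred$depth_m, sep = " @ ")
  alpha <- alpha_tab$alpha[match(key, alpha_tab$stratum)]
  alpha[is.na(alpha)] <- global
  pred$ta_umol_kg + alpha * (35 - pred$salinity)
}

#' Seasonal-trend table from a projected weekly series table
#'
#' Stage 5 of the pipeline in isolation: takes the predicted weekly series
#' (a table or the `predicted_series.csv` written by [run_pipeline()]),
#' builds one series per station x depth bin for each of pH, hydrogen-ion
#' concentration, alkalinity and normalized alkalinity, applies the outlier
#' filter and fits the seasonal-trend model. Ordering is station-major,
#' depth-minor, with variables in the order ph, h, ta, nta.
#'
#' @param pred data.frame or CSV path with the predicted series columns
#'   (`ph`, `h_nmol_kg`, `ta_umol_kg`, `nta_umol_kg`).
#' @param confidence,z_max see [trend_table()].
#' @return the [trend_table()] data.frame.
#' @export
trends_from_predictions <- function(pred, confidence = 0.95, z_max = 3) {
  if (is.character(pred)) {
    pred <- utils::read.csv(pred, stringsAsFactors = FALSE)
  }
  cols <- c(ph = "ph", h = "h_nmol_kg", ta = "ta_umol_kg",
            nta = "nta_umol_kg")
  missing_cols <- setdiff(unname(cols), names(pred))
  if (length(missing_cols)) {
    stop("predicted series table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stations <- unique(pred$station_id)
  series <- list()
  for (st in stations) {
    for (d in sort(unique(pred$depth_m[pred$station_id == st]))) {
      sub <- pred[pred$station_id == st & pred$depth_m == d, , drop = FALSE]
      sub <- sub[order(sub$year_decimal), , drop = FALSE]
      for (v in names(cols)) {
        series[[length(series) + 1L]] <-
          hydro_series(sub$year_decimal, sub[[cols[[v]]]],
                       stratum = paste(st, d, sep = " @ "), variable = v)
      }
    }
  }
  trend_table(series, confidence = confidence, z_max = z_max)
}

#' Test-set metrics table for both ensembles
#'
#' One row per member plus an ensemble row, for pH and alkalinity, with
#' MAE/MSE/RMSE/r2 on the shared held-out test set; plus an ensemble row for
#' hydrogen-ion concentration obtained by transforming the stored pH test
#' predictions and observations before scoring.
#'
#' @param model_ph,model_ta trained [train_ensemble()] models.
#' @return data.frame with columns `target`, `member`, `mae`, `mse`,
#'   `rmse`, `r2`.
#' @export
summarize_table1 <- function(model_ph, model_ta) {
  one <- function(model, target) {
    rows <- lapply(seq_along(model$members), function(i) {
      m <- model$member_metrics[[i]]
      data.frame(target = target, member = as.character(i), mae = m$mae,
                 mse = m$mse, rmse = m$rmse, r2 = m$r2,
                 stringsAsFactors = FALSE)
    })
    e <- model$ensemble_metrics
    rows[[length(rows) + 1L]] <- data.frame(
      target = target, member = "ensemble", mae = e$mae, mse = e$mse,
      rmse = e$rmse, r2 = e$r2, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }
  h <- evaluate(ph_to_h(model_ph$test_predictions),
                ph_to_h(model_ph$test_observations))
  out <- rbind(
    one(model_ph, "ph"),
    data.frame(target = "h", member = "ensemble", mae = h$mae, mse = h$mse,
               rmse = h$rmse, r2 = h$r2, stringsAsFactors = FALSE),
    one(model_ta, "ta"))
  rownames(out) <- NULL
  out
}
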