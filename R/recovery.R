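#' Planted long-term trends for every stratum and variable
#'
#' The planted pH and (normalized) alkalinity trends are generator
#' parameters. The hydrogen-ion concentration is a nonlinear transform of
#' pH, so its planted *linear* trend is derived by evaluating the noiseless
#' pH series weekly over the study years, transforming it, and fitting the
#' same seasonal-trend model the pipeline uses.
#'
#' @param truth the `truth` element of [generate_world()].
#' @return data.frame: `stratum`, `variable` (ph/h/ta/nta), `planted`.
#' @export
planted_trends <- function(truth) {
  spec <- truth$spec
  tt <- truth$trend_table
  t <- decimal_year(weekly_dates(spec$years))
  rows <- lapply(seq_len(nrow(tt)), function(i) {
    ph0 <- true_ph_field(spec, tt$latitude[i], tt$depth_m[i], t,
                         truth$trend_coefs)
    h_fit <- fit_seasonal_trend(hydro_series(t, ph_to_h(ph0)))
    data.frame(
      stratum = paste(tt$station_id[i], tt$depth_m[i], sep = " @ "),
      variable = c("ph", "h", "ta", "nta"),
      planted = c(tt$ph_trend[i], h_fit$B, tt$ta_trend[i], tt$nta_trend[i]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' End-to-end parameter-recovery experiment
#'
#' Runs the full pipeline on a sequence of independently seeded synthetic
#' worlds and scores every recovered long-term trend against its planted
#' value: the sign, the error, and whether the planted value falls inside
#' the reported confidence interval. This is the package's primary
#' validation: the generator defines the truth, the pipeline never sees it.
#'
#' @param seeds integer vector of world seeds (one world per seed).
#' @param world_args named list of [world_spec()] overrides applied to every
#'   world (e.g. reduced training sizes).
#' @param nn named list of network settings for [pipeline_config()]
#'   (e.g. reduced hidden-layer widths).
#' @param quiet suppress per-stage messages (default TRUE).
#' @return data.frame with one row per seed x stratum x variable: `seed`,
#'   `stratum`, `variable`, `B`, `ci_lo`, `ci_hi`, `planted`, `covered`,
#'   `sign_correct`.
#' @export
recovery_experiment <- function(seeds,
                                world_args = list(n_train_ph = 1500L,
                                                  n_train_ta = 1000L),
                                nn = list(ph_layers = c(14L, 5L),
                                          ta_layers = 20L,
                                          max_iter = 100),
                                quiet = TRUE) {
  out <- lapply(seeds, function(sd) {
    spec <- do.call(world_spec, c(list(seed = as.integer(sd)), world_args))
    dir <- tempfile("recovery-")
    on.exit(unlink(dir, recursive = TRUE), add = TRUE)
    man <- run_pipeline(pipeline_config(world = spec, nn = nn,
                                        output_dir = dir), quiet = quiet)
    coefs <- trend_field_coefs(spec)
    planted <- planted_trends(list(
      spec = spec, trend_coefs = coefs,
      trend_table = stratum_truth_table(spec, world_stations(spec), coefs)))
    tt <- merge(man$trends[, c("stratum", "variable", "B", "ci_lo", "ci_hi")],
                planted, by = c("stratum", "variable"), sort = FALSE)
    tt$seed <- sd
    tt$covered <- tt$planted >= tt$ci_lo & tt$planted <= tt$ci_hi
    tt$sign_correct <- sign(tt$B) == sign(tt$planted)
    tt
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("seed", "stratum", "variable", "B", "ci_lo", "ci_hi", "planted",
          "covered", "sign_correct")]
}
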