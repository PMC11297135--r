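#' Construct a time series for trend analysis
#'
#' @param t decimal years, strictly increasing (gaps allowed).
#' @param y values in the variable's units.
#' @param stratum label, conventionally "station @ depth bin".
#' @param variable one of `"ph"`, `"h"`, `"ta"`, `"nta"` (free-form labels
#'   are accepted for other uses).
#' @return object of class `hydro_series`.
#' @export
hydro_series <- function(t, y, stratum = "series", variable = "y") {
  stopifnot(length(t) == length(y))
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]
  y <- y[keep]
  if (is.unsorted(t, strictly = TRUE)) {
    o <- order(t)
    t <- t[o]
    y <- y[o]
    if (anyDuplicated(t)) stop("time axis has duplicated points", call. = FALSE)
  }
  structure(list(stratum = stratum, variable = variable, t = t, y = y),
            class = "hydro_series")
}

#' Remove gross outliers by a z-score rule
#'
#' Single pass (no re-iteration): points whose absolute deviation from the
#' series mean exceeds `z_max` standard deviations are dropped. A constant
#' series (zero SD) is returned unchanged.
#'
#' @param series a [hydro_series()].
#' @param z_max z-score threshold (default 3).
#' @return list with the `filtered` series and `n_removed`.
#' @export
remove_outliers <- function(series, z_max = 3) {
  stopifnot(inherits(series, "hydro_series"), z_max > 0)
  s <- stats::sd(series$y)
  if (!is.finite(s) || s == 0) {
    return(list(filtered = series, n_removed = 0L))
  }
  z <- abs(series$y - mean(series$y)) / s
  keep <- z <= z_max
  filtered <- hydro_series(series$t[keep], series$y[keep],
                           series$stratum, series$variable)
  list(filtered = filtered, n_removed = sum(!keep))
}

#' Fit the seasonal-plus-trend model and extract the long-term trend
#'
#' Fits the oscillatory model
#' \deqn{y(t) = A \sin(\omega t + \phi) + B t + C}
#' with the angular frequency fixed at the annual cycle
#' (\eqn{\omega = 2\pi} rad yr^-1), by rewriting the seasonal term as
#' `a*sin(2*pi*t) + b*cos(2*pi*t)` and solving the linear least-squares
#' problem; then `A = sqrt(a^2 + b^2)` and `phi = atan2(b, a)` normalized to
#' `[0, 2*pi)`. The fitted seasonal component is subtracted and an ordinary
#' linear regression of the deseasonalized series on time yields the
#' reported trend `B`, its confidence interval (t distribution, n - 2 df),
#' `r2` and the two-sided p-value of the slope; `significant` flags
#' `p <= 0.01`. Optionally the frequency is refined by a 1-D grid search
#' around the annual cycle.
#'
#' @param series a [hydro_series()] with at least 8 points spanning at least
#'   2 years.
#' @param confidence confidence level for the trend interval (default 0.95).
#' @param refine_omega if `TRUE`, pick omega on a grid of
#'   `omega_grid_points` values within +/-10% of the annual frequency by
#'   residual sum of squares before extracting the trend.
#' @param omega_grid_points grid size for the refinement (default 41).
#' @return object of class `seasonal_trend_fit` with fields `A`, `omega`,
#'   `phi`, `B`, `C`, `ci_B`, `se_B`, `r2`, `p_value`, `n_used`,
#'   `significant`, `confidence`, plus `stratum` and `variable` labels.
#' @export
fit_seasonal_trend <- function(series, confidence = 0.95,
                               refine_omega = FALSE, omega_grid_points = 41L) {
  stopifnot(inherits(series, "hydro_series"))
  t <- series$t
  y <- series$y
  if (length(t) < 8) {
    stop("need at least 8 points to fit the seasonal-trend model",
         call. = FALSE)
  }
  if (diff(range(t)) < 2) {
    stop("series must span at least 2 years", call. = FALSE)
  }
  omega <- 2 * pi
  if (refine_omega) {
    grid <- 2 * pi * seq(0.9, 1.1, length.out = omega_grid_points)
    rss <- vapply(grid, function(w) {
      fit <- stats::lm.fit(cbind(1, sin(w * t), cos(w * t), t), y)
      sum(fit$residuals^2)
    }, numeric(1))
    omega <- grid[which.min(rss)]
  }
  X <- cbind(`(Intercept)` = 1, s = sin(omega * t), c = cos(omega * t), t = t)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate fit: seasonal-trend design is rank deficient ",
         "(e.g. all samples at the same phase)", call. = FALSE)
  }
  co <- stats::lm.fit(X, y)$coefficients
  a <- co[["s"]]
  b <- co[["c"]]
  A <- sqrt(a^2 + b^2)
  phi <- atan2(b, a) %% (2 * pi)

  # subtract the seasonal component, then a standard linear regression of
  # the deseasonalized series on time gives the reported trend statistics;
  # the slope se, CI (t distribution, n - 2 df), r2 and two-sided p-value
  # are computed directly so that zero-residual (noiseless) series yield
  # exact values rather than summary.lm warnings
  y_deseason <- y - (a * sin(omega * t) + b * cos(omega * t))
  lin <- stats::lm(y_deseason ~ t)
  B <- unname(stats::coef(lin)[2])
  res <- stats::residuals(lin)
  n <- length(y)
  df <- n - 2L
  sxx <- sum((t - mean(t))^2)
  se_B <- sqrt(sum(res^2) / df / sxx)
  tq <- stats::qt(1 - (1 - confidence) / 2, df)
  ci <- c(B - tq * se_B, B + tq * se_B)
  tstat <- if (se_B > 0) B / se_B else if (B == 0) 0 else sign(B) * Inf
  p <- 2 * stats::pt(-abs(tstat), df)
  ss_tot <- sum((y_deseason - mean(y_deseason))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0

  structure(list(stratum = series$stratum, variable = series$variable,
                 A = A, omega = omega, phi = phi, B = B,
                 C = unname(stats::coef(lin)[1]),
                 ci_B = ci, se_B = se_B,
                 r2 = r2, p_value = p, n_used = length(y),
                 significant = p <= 0.01, confidence = confidence),
            class = "seasonal_trend_fit")
}

#' @export
print.seasonal_trend_fit <- function(x, ...) {
  cat(sprintf(
    "seasonal-trend fit [%s, %s]: B = %.5g %s/yr (%g%% CI %.5g..%.5g), A = %.4g, r2 = %.3f, p = %.3g%s\n",
    x$stratum, x$variable, x$B, x$variable, 100 * x$confidence,
    x$ci_B[1], x$ci_B[2], x$A, x$r2, x$p_value,
    if (x$significant) "" else " *"))
  invisible(x)
}

#' Long-term trend table over a collection of series
#'
#' One row per series (stratum x variable): trend, half-width of its
#' confidence interval, r2, p-value and the significance flag (trends with
#' p > 0.01 are marked with an asterisk in `flag`, mirroring the
#' conventional table layout). Series whose fit fails are kept as flagged
#' rows with `NA` statistics rather than aborting the table. Rows are
#' ordered station-major, depth-minor as supplied.
#'
#' @param series_list list of [hydro_series()] objects.
#' @param confidence confidence level (default 0.95).
#' @param z_max outlier threshold applied to each raw series before fitting
#'   (default 3; `Inf` disables).
#' @return data.frame with columns `stratum`, `variable`, `B`, `ci_half`,
#'   `ci_lo`, `ci_hi`, `se_B`, `r2`, `p_value`, `significant`, `flag`,
#'   `n_used`, `n_removed`, `error`.
#' @export
trend_table <- function(series_list, confidence = 0.95, z_max = 3) {
  rows <- lapply(series_list, function(s) {
    res <- tryCatch({
      filt <- remove_outliers(s, z_max)
      fit <- fit_seasonal_trend(filt$filtered, confidence)
      data.frame(stratum = s$stratum, variable = s$variable,
                 B = fit$B, ci_half = diff(fit$ci_B) / 2,
                 ci_lo = fit$ci_B[1], ci_hi = fit$ci_B[2], se_B = fit$se_B,
                 r2 = fit$r2, p_value = fit$p_value,
                 significant = fit$significant,
                 flag = if (fit$significant) "" else "*",
                 n_used = fit$n_used, n_removed = filt$n_removed,
                 error = "", stringsAsFactors = FALSE)
    }, error = function(err) {
      data.frame(stratum = s$stratum, variable = s$variable,
                 B = NA_real_, ci_half = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, se_B = NA_real_, r2 = NA_real_,
                 p_value = NA_real_, significant = NA, flag = "!",
                 n_used = NA_integer_, n_removed = NA_integer_,
                 error = conditionMessage(err), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a series with its fitted seasonal-trend model
#'
#' Weekly values as points, the full fitted oscillatory model as a thin
#' curve, and the extracted linear trend as a heavy line, in the style of
#' station time-series panels.
#'
#' @param series a [hydro_series()].
#' @param fit the matching [fit_seasonal_trend()] result (refitted when
#'   omitted).
#' @param path optional PNG path; when given the plot is written there
#'   instead of the active device.
#' @param ... passed to [plot()].
#' @return `fit`, invisibly.
#' @export
plot_series_trend <- function(series, fit = NULL, path = NULL, ...) {
  stopifnot(inherits(series, "hydro_series"))
  if (is.null(fit)) fit <- fit_seasonal_trend(series)
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 500, res = 130)
    on.exit(grDevices::dev.off())
  }
  plot(series$t, series$y, pch = 16, cex = 0.35, col = "steelblue",
       xlab = "year", ylab = series$variable,
       main = sprintf("%s  (B = %.4g %s/yr, p = %.2g%s)", series$stratum,
                      fit$B, series$variable, fit$p_value,
                      if (fit$significant) "" else " *"), ...)
  tt <- seq(min(series$t), max(series$t), length.out = 2000)
  a <- fit$A * cos(fit$phi)
  b <- fit$A * sin(fit$phi)
  graphics::lines(tt, a * sin(fit$omega * tt) + b * cos(fit$omega * tt) +
                    fit$B * tt + fit$C, col = "grey55", lwd = 0.6)
  graphics::abline(fit$C, fit$B, col = "firebrick", lwd = 2)
  invisible(fit)
}
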