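#' Hydrogen-ion concentration from pH
#'
#' Converts total-scale pH to total hydrogen-ion concentration in
#' nmol kg^-1: `h = 10^(9 - ph)`. The transform is strictly decreasing, and
#' expressing acidification in [H+] avoids the non-linearity of the
#' logarithmic pH scale.
#'
#' @param ph numeric pH values.
#' @param range sanity bounds on pH; values outside signal unit confusion
#'   and raise an error.
#' @return [H+] in nmol kg^-1.
#' @export
ph_to_h <- function(ph, range = c(0, 14)) {
  if (any(!is.finite(ph))) stop("non-finite pH", call. = FALSE)
  if (any(ph <= range[1] | ph >= range[2])) {
    stop(sprintf("pH outside (%g, %g): check units", range[1], range[2]),
         call. = FALSE)
  }
  10^(9 - ph)
}

#' Salinity normalization of total alkalinity
#'
#' Two normalizations to the reference salinity 35. The traditional ratio
#' method, `nta = ta * 35 / s`, divides out dilution/evaporation but is
#' known to over-correct where the alkalinity-salinity slope is shallower
#' than `ta / s` (it fails near river mouths, and is guarded by a hard
#' salinity floor). The empirical method, `nta = ta + alpha * (35 - s)`,
#' removes the fitted linear salinity dependence (see [fit_alpha()]). Both
#' are the identity at salinity 35.
#'
#' @param ta total alkalinity, umol kg^-1.
#' @param s practical salinity.
#' @param s_min hard salinity floor for the ratio method (default 5).
#' @return normalized alkalinity, umol kg^-1.
#' @export
nta_reference <- function(ta, s, s_min = 5) {
  stopifnot(all(is.finite(ta)), all(is.finite(s)))
  if (any(s <= s_min)) {
    stop(sprintf(paste(
      "salinity <= %g: the reference-salinity normalization is unreliable",
      "in nearly fresh water (near river mouths); use the empirical method"),
      s_min), call. = FALSE)
  }
  ta * 35 / s
}

#' @rdname nta_reference
#' @param alpha an [fit_alpha()] result, or a bare numeric slope
#'   (umol kg^-1 per salinity unit).
#' @export
nta_empirical <- function(ta, s, alpha) {
  if (inherits(alpha, "alpha_fit")) alpha <- alpha$alpha
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  stopifnot(all(is.finite(ta)), all(is.finite(s)))
  ta + alpha * (35 - s)
}

#' Empirical alkalinity-salinity slope
#'
#' Ordinary least-squares regression of alkalinity on salinity; the slope
#' `alpha` feeds the empirical normalization. Fitted per stratum
#' (station x depth bin) or pooled over all data as a single global
#' constant.
#'
#' @param ta alkalinity values, umol kg^-1.
#' @param s paired salinities.
#' @param stratum label for the fitted subset (default `"global"`).
#' @return object of class `alpha_fit`: `alpha`, `intercept`, `r2`,
#'   `alpha_se`, `n`, `stratum`.
#' @export
fit_alpha <- function(ta, s, stratum = "global") {
  keep <- is.finite(ta) & is.finite(s)
  ta <- ta[keep]
  s <- s[keep]
  if (length(ta) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(s) == 0) {
    stop("degenerate fit: salinity has zero variance", call. = FALSE)
  }
  fit <- stats::lm(ta ~ s)
  res <- stats::residuals(fit)
  ss_tot <- sum((ta - mean(ta))^2)
  # guard degenerate cases explicitly instead of trusting summary.lm on a
  # zero-residual fit: constant TA has no explainable variance (r2 = 0)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  sigma2 <- sum(res^2) / (length(ta) - 2)
  se <- sqrt(sigma2 / sum((s - mean(s))^2))
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 alpha_se = se,
                 n = length(ta), stratum = stratum),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("TA~S slope [%s]: alpha = %.3f +/- %.3f umol kg^-1, r2 = %.3f, n = %d\n",
              x$stratum, x$alpha, x$alpha_se, x$r2, x$n))
  invisible(x)
}

#' Alkalinity-salinity slopes per stratum and pooled
#'
#' Fits [fit_alpha()] within every station x depth-bin stratum of a table
#' and once on all rows pooled (`"global"`).
#'
#' @param table hydrographic table with `ta_umol_kg` labels.
#' @return data.frame with one row per stratum plus a global row:
#'   `stratum`, `alpha`, `intercept`, `r2`, `n`.
#' @export
alpha_table <- function(table) {
  table <- as_hydro_table(table)
  keep <- !is.na(table$ta_umol_kg)
  table <- table[keep, , drop = FALSE]
  strata <- split(table, interaction(table$station_id, table$depth_m,
                                     drop = TRUE, sep = " @ "))
  fits <- lapply(names(strata), function(nm) {
    tryCatch(fit_alpha(strata[[nm]]$ta_umol_kg, strata[[nm]]$salinity, nm),
             error = function(err) NULL)
  })
  fits <- c(fits, list(fit_alpha(table$ta_umol_kg, table$salinity, "global")))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  do.call(rbind, lapply(fits, function(f) {
    data.frame(stratum = f$stratum, alpha = f$alpha, intercept = f$intercept,
               r2 = f$r2, n = f$n, stringsAsFactors = FALSE)
  }))
}
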