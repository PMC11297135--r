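weekly_t <- function(years = c(1995, 2020)) decimal_year(weekly_dates(years))

test_that("outlier filter: constant series untouched, infinite threshold is the identity", {
  s <- hydro_series(2000 + (0:99) / 52, rep(8.1, 100))
  res <- remove_outliers(s)
  expect_identical(res$n_removed, 0L)
  expect_identical(res$filtered$y, s$y)

  set.seed(41)
  s2 <- hydro_series(2000 + (0:199) / 52, rnorm(200))
  res2 <- remove_outliers(s2, z_max = Inf)
  expect_identical(res2$n_removed, 0L)
  expect_identical(res2$filtered$y, s2$y)
})

test_that("a gross outlier among standard normals is removed, verified by brute-force z-scores", {
  set.seed(42)
  y <- rnorm(200)
  y[77] <- 50
  s <- hydro_series(2000 + (0:199) / 52, y)
  res <- remove_outliers(s, z_max = 3)
  z <- abs(y - mean(y)) / sd(y) # brute-force, single pass
  expect_identical(res$n_removed, sum(z > 3))
  expect_identical(res$filtered$y, y[z <= 3])
  expect_false(50 %in% res$filtered$y)
})

test_that("the number of removed points is non-increasing in the threshold", {
  set.seed(43)
  s <- hydro_series(2000 + (0:499) / 52, rt(500, df = 3))
  removed <- vapply(c(1, 1.5, 2, 2.5, 3, 4, 6, Inf),
                    function(z) remove_outliers(s, z)$n_removed, integer(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("noiseless seasonal-plus-trend data is recovered to solver precision", {
  t <- weekly_t()
  y <- 0.05 * sin(2 * pi * t + 0.3) - 0.003 * t + 8.1
  fit <- fit_seasonal_trend(hydro_series(t, y))
  expect_equal(fit$B, -0.003, tolerance = 1e-9)
  expect_equal(fit$A, 0.05, tolerance = 1e-9)
  expect_equal(fit$phi, 0.3, tolerance = 1e-7)
  expect_equal(fit$C, 8.1, tolerance = 1e-6)
  expect_true(fit$ci_B[1] <= fit$B && fit$B <= fit$ci_B[2])
  expect_true(fit$significant)

  # independent normal-equations oracle for the joint linear fit
  X <- cbind(1, sin(2 * pi * t), cos(2 * pi * t), t)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$B, beta[4], tolerance = 1e-9)
  expect_equal(fit$A, sqrt(beta[2]^2 + beta[3]^2), tolerance = 1e-9)
})

test_that("with no seasonal component the trend equals the plain OLS slope", {
  t <- weekly_t(c(2000, 2010))
  y <- -0.0031 * t + 14
  fit <- fit_seasonal_trend(hydro_series(t, y))
  ols <- unname(coef(lm(y ~ t))[2])
  expect_equal(fit$B, ols, tolerance = 1e-12)
})

test_that("shifting the series moves only the intercept; tilting moves only the trend", {
  set.seed(44)
  t <- weekly_t(c(1995, 2005))
  y <- 0.04 * sin(2 * pi * t + 1.1) - 0.002 * t + 8 + rnorm(length(t), 0, 0.01)
  f0 <- fit_seasonal_trend(hydro_series(t, y))
  f_shift <- fit_seasonal_trend(hydro_series(t, y + 5))
  expect_equal(f_shift$C, f0$C + 5, tolerance = 1e-9)
  expect_equal(f_shift$B, f0$B, tolerance = 1e-12)
  expect_equal(f_shift$A, f0$A, tolerance = 1e-9)
  expect_equal(f_shift$phi, f0$phi, tolerance = 1e-9)
  f_tilt <- fit_seasonal_trend(hydro_series(t, y + 0.01 * t))
  expect_equal(f_tilt$B, f0$B + 0.01, tolerance = 1e-12)
  expect_equal(f_tilt$A, f0$A, tolerance = 1e-9)
})

test_that("confidence intervals are calibrated near their nominal level", {
  t <- weekly_t(c(1995, 2020))
  b_true <- -0.003
  signal <- 0.05 * sin(2 * pi * t + 0.3) + b_true * t + 8.1
  set.seed(45)
  covered <- vapply(1:200, function(i) {
    fit <- fit_seasonal_trend(hydro_series(t, signal + rnorm(length(t), 0, 0.02)))
    fit$ci_B[1] <= b_true && b_true <= fit$ci_B[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("the trend estimator is unbiased at scale", {
  t <- weekly_t(c(1995, 2020))
  b_true <- -0.003
  signal <- 0.05 * sin(2 * pi * t + 0.3) + b_true * t + 8.1
  set.seed(46)
  ests <- replicate(200, {
    fit_seasonal_trend(hydro_series(t, signal + rnorm(length(t), 0, 0.02)))$B
  })
  se_hat <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - b_true), 3 * se_hat)
  expect_lt(abs(mean(ests) - b_true), 0.1 * sd(ests))
})

test_that("degenerate designs and short series are refused", {
  expect_error(fit_seasonal_trend(hydro_series(2000 + (0:5) / 52,
                                               rnorm(6))), "8")
  expect_error(fit_seasonal_trend(hydro_series(2000 + (0:9) / 52,
                                               rnorm(10))), "2 years")
  # annual sampling: every point at the same seasonal phase
  t_annual <- 2000:2012
  expect_error(fit_seasonal_trend(hydro_series(t_annual, rnorm(13))),
               "rank|degenerate")
})

test_that("hydrogen-ion and pH trends are consistent for small trends", {
  t <- weekly_t()
  ph <- 0.04 * sin(2 * pi * t + 0.8) - 0.0035 * (t - 1995) + 8.1
  h <- ph_to_h(ph)
  fit_ph <- fit_seasonal_trend(hydro_series(t, ph))
  fit_h <- fit_seasonal_trend(hydro_series(t, h))
  predicted_h_trend <- -log(10) * mean(h) * fit_ph$B
  expect_lt(abs(fit_h$B - predicted_h_trend) / abs(predicted_h_trend), 0.1)
  expect_gt(fit_h$B, 0)
})

test_that("the trend table maps every stratum-variable series to one ordered row", {
  w <- generate_world(tiny_world_spec(seed = 47, ph_trend_per_year = -0.003))
  pred <- w$prediction
  tl <- true_labels(w$truth, pred)
  pred$ph <- tl$ph
  pred$ta_umol_kg <- tl$ta
  pred$h_nmol_kg <- ph_to_h(pred$ph)
  pred$nta_umol_kg <- nta_empirical(pred$ta_umol_kg, pred$salinity, 46.7)
  tt <- trends_from_predictions(pred)
  expect_identical(nrow(tt), 6L * 3L * 4L)
  expect_identical(unique(tt$variable), c("ph", "h", "ta", "nta"))
  # deterministic station-major, depth-minor ordering
  expect_identical(tt$stratum[1:8],
                   rep(c("V1 @ 2.5", "V1 @ 7.5"), each = 4))
  # planted trends recovered from the noiseless series
  ph_rows <- tt[tt$variable == "ph", ]
  expect_equal(ph_rows$B, rep(-0.003, 18), tolerance = 1e-6)
})

test_that("a degenerate series yields a flagged row, not an abort", {
  t <- weekly_t(c(2000, 2010))
  good <- hydro_series(t, 0.02 * sin(2 * pi * t) + 8, "s1", "ph")
  bad <- hydro_series(t[1:4], rep(8, 4), "s2", "ph")
  tt <- trend_table(list(good, bad))
  expect_identical(nrow(tt), 2L)
  expect_identical(tt$flag[2], "!")
  expect_true(is.na(tt$B[2]))
  expect_false(is.na(tt$B[1]))
  expect_match(tt$error[2], "8")
})

test_that("the series plot renders to a PNG file", {
  t <- weekly_t(c(2000, 2010))
  set.seed(48)
  s <- hydro_series(t, 0.05 * sin(2 * pi * t) - 0.003 * t + 8.1 +
                      rnorm(length(t), 0, 0.02), "V1 @ 2.5", "ph")
  path <- tempfile(fileext = ".png")
  fit <- plot_series_trend(s, path = path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
  expect_s3_class(fit, "seasonal_trend_fit")
})
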