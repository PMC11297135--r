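# ---- single members --------------------------------------------------------

test_that("a tiny network drives a noiseless linear relationship below 1e-3 RMSE", {
  set.seed(1)
  x <- cbind(a = runif(300), b = runif(300))
  y <- 3 * x[, 1] + 1
  m <- train_member(x[1:250, ], y[1:250], layer_sizes = 1L, seed = 42,
                    max_iter = 400)
  rmse <- sqrt(mean((predict(m, x[251:300, ]) - y[251:300])^2))
  expect_lt(rmse, 1e-3)
})

test_that("sum-of-squares error at a zero output layer equals the squared scaled labels", {
  dims <- riacarb:::layer_dims(3L, 2L)
  w <- riacarb:::init_weights(dims, seed = 1)
  # zero the output-layer block: the network output is identically zero
  nw_out <- prod(dims[[length(dims)]])
  w[(length(w) - nw_out + 1):length(w)] <- 0
  x <- matrix(rnorm(30), 10, 3)
  out <- riacarb:::mlp_forward(w, dims, x)$out
  expect_identical(sum((rep(0, 10) - out)^2), 0) # all-zero labels: E_D = 0
})

test_that("evidence updates reach the ridge parameter that maximizes the exact log-evidence", {
  set.seed(7)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3)
  y <- drop(x %*% c(1.5, -0.7, 0.2)) + rnorm(n, 0, 0.5)
  m <- train_member(x, y, layer_sizes = integer(0), seed = 3, max_iter = 500)
  lambda_hat <- m$alpha / m$beta

  # oracle: for a linear model the Laplace evidence is exact; profile out
  # beta analytically and maximize over a fine 1-D grid of the ridge
  # parameter lambda = alpha/beta
  xs <- scale(x)
  ys <- drop(scale(y))
  Xb <- cbind(xs, 1)
  nw <- ncol(Xb)
  xtx <- crossprod(Xb)
  xty <- drop(crossprod(Xb, ys))
  log_ev <- function(lambda) {
    w <- solve(xtx + diag(lambda, nw), xty)
    ed <- sum((ys - Xb %*% w)^2)
    ew <- sum(w^2)
    beta <- n / (2 * (ed + lambda * ew))
    (n / 2) * log(beta) + (nw / 2) * log(lambda) -
      0.5 * determinant(xtx + diag(lambda, nw))$modulus
  }
  grid <- 10^seq(-6, 2, length.out = 2000)
  lambda_star <- grid[which.max(vapply(grid, log_ev, numeric(1)))]
  # agreement to 2 significant figures
  expect_equal(signif(lambda_hat, 2), signif(lambda_star, 2),
               tolerance = 0.051)
})

test_that("the trained member is a fixed point of the evidence equations and gamma stabilizes", {
  set.seed(8)
  n <- 150
  x <- matrix(rnorm(n * 2), n, 2)
  y <- drop(x %*% c(1, 2)) + rnorm(n, 0, 0.3)
  m <- train_member(x, y, layer_sizes = integer(0), seed = 5, max_iter = 500)
  expect_true(m$converged)
  expect_gte(m$gamma, 0)
  expect_lte(m$gamma, m$n_weights)
  # self-consistency: recompute gamma, alpha, beta from the stored weights
  xs <- scale(x)
  ys <- drop(scale(y))
  Xb <- cbind(xs, 1)
  ed <- sum((ys - drop(Xb %*% m$weights))^2)
  ew <- sum(m$weights^2)
  H <- 2 * m$beta * crossprod(Xb) + diag(2 * m$alpha, m$n_weights)
  gamma <- m$n_weights - 2 * m$alpha * sum(diag(solve(H)))
  expect_equal(m$gamma, gamma, tolerance = 1e-2)
  expect_equal(m$alpha, gamma / (2 * ew), tolerance = 1e-2)
  expect_equal(m$beta, (n - gamma) / (2 * ed), tolerance = 1e-2)
})

test_that("standardization absorbs affine rescaling of a feature", {
  set.seed(9)
  x <- matrix(runif(200 * 3), 200, 3)
  y <- sin(2 * x[, 1]) + 0.5 * x[, 2] + rnorm(200, 0, 0.05)
  m1 <- train_member(x, y, layer_sizes = 3L, seed = 11, max_iter = 50)
  x2 <- x
  x2[, 1] <- 1000 * x2[, 1] - 273.15
  m2 <- train_member(x2, y, layer_sizes = 3L, seed = 11, max_iter = 50)
  p1 <- predict(m1, x)
  p2 <- predict(m2, x2)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("non-finite training data is rejected", {
  x <- matrix(1:10, 5, 2)
  expect_error(train_member(x, c(1, 2, NA, 4, 5), 2L, seed = 1),
               "non-finite")
  expect_error(train_member(x, 1:5, c(3L, 0L), seed = 1), "widths")
})

# ---- ensembles --------------------------------------------------------------

test_that("an ensemble of linear members nails a noiseless linear world", {
  spec <- silent_world_spec(seed = 21)
  w <- generate_world(spec)
  ens <- train_ensemble(w$training, "ph", layer_sizes = integer(0),
                        n_members = 3L, seed = 17, max_iter = 200)
  expect_lt(ens$ensemble_metrics$rmse, 1e-3)
})

test_that("ensemble training is deterministic and member-averaged", {
  spec <- tiny_world_spec(seed = 22)
  w <- generate_world(spec)
  e1 <- train_ensemble(w$training, "ph", layer_sizes = c(4L, 2L),
                       n_members = 3L, seed = 5, max_iter = 25)
  e2 <- train_ensemble(w$training, "ph", layer_sizes = c(4L, 2L),
                       n_members = 3L, seed = 5, max_iter = 25)
  expect_identical(e1$ensemble_metrics, e2$ensemble_metrics)
  expect_identical(predict(e1, w$prediction[1:50, ]),
                   predict(e2, w$prediction[1:50, ]))
  # all members share one split
  expect_identical(e1$split, split_train_test(
    sum(!is.na(w$training$ph)), 0.10, derive_seed(5, "split-ph")))
  # prediction is the arithmetic mean of the members
  x <- w$prediction[1:20, ]
  by_member <- sapply(e1$members, function(m) predict(m, encode_features(x)))
  expect_equal(predict(e1, x), rowMeans(by_member), tolerance = 1e-12)
})

test_that("ensemble MSE never exceeds the members' average MSE", {
  spec <- tiny_world_spec(seed = 23)
  w <- generate_world(spec)
  ens <- train_ensemble(w$training, "ta", layer_sizes = 4L, n_members = 4L,
                        seed = 2, max_iter = 25)
  member_mse <- vapply(ens$member_metrics, `[[`, numeric(1), "mse")
  expect_lte(ens$ensemble_metrics$mse, mean(member_mse))
})

test_that("stub members averaging constants 7.9 and 8.1 predict 8.0", {
  w <- generate_world(tiny_world_spec(seed = 24))
  ens <- list(target = "ph", layer_sizes = integer(0),
              members = list(constant_member(7.9, 11),
                             constant_member(8.1, 11)))
  class(ens) <- "brnn_ensemble"
  p <- predict(ens, w$prediction[1:5, ])
  expect_equal(p, rep(8.0, 5), tolerance = 1e-12)
})

test_that("with pH observation noise of 0.02 the test RMSE approaches the noise floor", {
  spec <- world_spec(seed = 25, n_train_ph = 800L, n_train_ta = 300L)
  w <- generate_world(spec)
  ens <- train_ensemble(w$training, "ph", layer_sizes = c(10L, 4L),
                        n_members = 10L, seed = 4, max_iter = 60)
  noise <- spec$noise_sd[["ph"]]
  expect_gte(ens$ensemble_metrics$rmse, 0.5 * noise)
  expect_lte(ens$ensemble_metrics$rmse, 2 * noise)
})

test_that("a serialized ensemble restores to identical predictions and metrics", {
  spec <- tiny_world_spec(seed = 26)
  w <- generate_world(spec)
  ens <- train_ensemble(w$training, "ta", layer_sizes = 3L, n_members = 2L,
                        seed = 6, max_iter = 20)
  path <- tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  x <- w$prediction[1:40, ]
  expect_equal(predict(back, x), predict(ens, x), tolerance = 1e-12)
  expect_equal(back$ensemble_metrics, ens$ensemble_metrics, tolerance = 1e-12)
  expect_identical(back$split, ens$split)
})

test_that("the training trace logs the regularization trajectory", {
  set.seed(10)
  x <- matrix(rnorm(200), 100, 2)
  y <- drop(x %*% c(1, -1)) + rnorm(100, 0, 0.2)
  m <- train_member(x, y, layer_sizes = 2L, seed = 7, max_iter = 80,
                    trace = TRUE)
  h <- m$history
  expect_true(all(c("epoch", "f", "e_d", "e_w", "gamma", "alpha", "beta")
                  %in% names(h)))
  expect_identical(nrow(h), m$n_iter)
  expect_true(all(h$gamma >= 0 & h$gamma <= m$n_weights))
  # gamma settles: last changes are small relative to early ones
  if (nrow(h) > 10) {
    expect_lt(max(abs(diff(tail(h$gamma, 5)))),
              max(abs(diff(h$gamma[1:5]))) + 1e-8)
  }
})
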