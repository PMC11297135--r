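#' @name brnn_member
#' @title Bayesian-regularized network members
#'
#' @description
#' Each ensemble member is a feed-forward perceptron with tanh hidden layers
#' and a linear output, trained by Levenberg-Marquardt minimization of the
#' regularized objective
#' \deqn{F = \beta E_D + \alpha E_W,}
#' where \eqn{E_D} is the sum of squared errors on the (standardized)
#' training data and \eqn{E_W} the sum of squared weights and biases. The
#' hyperparameters are re-estimated each epoch by MacKay's evidence
#' framework in the Foresee-Hagan form used by the classic `trainbr`
#' algorithm:
#' \deqn{\gamma = N_w - 2\alpha\,\mathrm{tr}(H^{-1}), \quad
#'       \alpha = \gamma / (2 E_W), \quad \beta = (N - \gamma) / (2 E_D),}
#' with \eqn{H = 2\beta J^\top J + 2\alpha I} the Gauss-Newton approximation
#' to the Hessian of \eqn{F}, \eqn{N_w} the number of weights, and
#' \eqn{\gamma} the effective number of parameters. Hyperparameters start at
#' \eqn{\alpha = 0, \beta = 1}. Inputs and the target are standardized to
#' zero mean and unit SD on the training split; the stored scalers are
#' applied at prediction time. `layer_sizes = integer(0)` gives a plain
#' linear model (used to validate the evidence updates against ridge
#' regression).
NULL

# weight packing --------------------------------------------------------------

layer_dims <- function(n_in, layer_sizes) {
  sizes <- c(n_in, layer_sizes, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    c(sizes[l] + 1L, sizes[l + 1L]) # +1: bias row
  })
}

unpack_weights <- function(w, dims) {
  out <- vector("list", length(dims))
  pos <- 0L
  for (l in seq_along(dims)) {
    k <- prod(dims[[l]])
    out[[l]] <- matrix(w[pos + seq_len(k)], dims[[l]][1], dims[[l]][2])
    pos <- pos + k
  }
  out
}

n_weights <- function(dims) sum(vapply(dims, prod, numeric(1)))

# Nguyen-Widrow-style scaled uniform initialization, seeded per member
init_weights <- function(dims, seed) {
  with_seed(seed, {
    unlist(lapply(dims, function(d) {
      fan_in <- d[1] - 1L
      scale <- 0.7 * d[2]^(1 / max(fan_in, 1)) / max(sqrt(fan_in), 1)
      stats::runif(prod(d), -scale, scale)
    }))
  })
}

# forward pass on standardized inputs; returns output vector and, if
# jacobian = TRUE, the N x Nw Jacobian of the output w.r.t. the weights
mlp_forward <- function(w, dims, x, jacobian = FALSE) {
  W <- unpack_weights(w, dims)
  L <- length(W)
  acts <- vector("list", L + 1L)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    z <- cbind(acts[[l]], 1) %*% W[[l]]
    acts[[l + 1L]] <- if (l < L) tanh(z) else z
  }
  out <- drop(acts[[L + 1L]])
  if (!jacobian) return(list(out = out))

  n <- nrow(x)
  J <- matrix(0, n, n_weights(dims))
  # backprop the derivative of the single linear output unit
  delta <- matrix(1, n, 1)
  pos_end <- n_weights(dims)
  for (l in rev(seq_len(L))) {
    ain <- cbind(acts[[l]], 1) # n x (fan_in + 1)
    k <- prod(dims[[l]])
    cols <- (pos_end - k + 1L):pos_end
    # d out / d W_l[i, j] = ain[, i] * delta[, j], column-major over (i, j)
    blk <- matrix(0, n, k)
    nin <- dims[[l]][1]
    for (j in seq_len(dims[[l]][2])) {
      blk[, (j - 1L) * nin + seq_len(nin)] <- ain * delta[, j]
    }
    J[, cols] <- blk
    pos_end <- pos_end - k
    if (l > 1L) {
      Wl <- W[[l]][seq_len(nin - 1L), , drop = FALSE] # drop bias row
      delta <- (delta %*% t(Wl)) * (1 - acts[[l]]^2)
    }
  }
  list(out = out, J = J)
}

standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(x, s) {
  sweep(sweep(x, 2, s$center, "-"), 2, s$scale, "/")
}

#' Train one Bayesian-regularized network member
#'
#' @param x numeric feature matrix (samples x features), unscaled.
#' @param y numeric target vector, unscaled.
#' @param layer_sizes integer vector of hidden-layer widths; `integer(0)`
#'   for a linear model.
#' @param seed integer seed for the weight initialization.
#' @param max_iter maximum number of Levenberg-Marquardt epochs.
#' @param tol list or vector of convergence tolerances: `gradient`
#'   (infinity-norm of the gradient of F), `gamma` (absolute change in the
#'   effective number of parameters), `f_rel` (relative change in F).
#' @param trace if `TRUE`, keep a per-epoch log of `F`, `E_D`, `E_W`,
#'   `gamma`, `alpha`, `beta` in the returned member's `history`.
#' @return an object of class `brnn_member`: weights, layer sizes, input and
#'   output scalers, final `alpha`, `beta`, `gamma`, epoch count and
#'   convergence flag.
#' @export
train_member <- function(x, y, layer_sizes, seed,
                         max_iter = 200,
                         tol = c(gradient = 1e-6, gamma = 1e-3,
                                 f_rel = 1e-9),
                         trace = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite training data", call. = FALSE)
  }
  layer_sizes <- as.integer(layer_sizes)
  if (any(layer_sizes <= 0)) stop("hidden-layer widths must be > 0",
                                  call. = FALSE)
  xs <- standardizer(x)
  ys <- standardizer(matrix(y, ncol = 1))
  xsc <- apply_standardizer(x, xs)
  ysc <- (y - ys$center) / ys$scale

  dims <- layer_dims(ncol(x), layer_sizes)
  nw <- n_weights(dims)
  n <- length(y)
  w <- init_weights(dims, seed)

  alpha <- 0
  beta <- 1
  mu <- 0.005
  fw <- mlp_forward(w, dims, xsc, jacobian = TRUE)
  e <- ysc - fw$out
  ed <- sum(e^2)
  ew <- sum(w^2)
  f <- beta * ed + alpha * ew
  gamma <- nw
  converged <- FALSE
  iter <- 0L
  history <- if (trace) vector("list", max_iter)

  while (iter < max_iter) {
    iter <- iter + 1L
    if (trace) {
      history[[iter]] <- data.frame(epoch = iter, f = f, e_d = ed, e_w = ew,
                                    gamma = gamma, alpha = alpha, beta = beta)
    }
    J <- fw$J
    jtj <- crossprod(J)
    g <- -2 * beta * drop(crossprod(J, e)) + 2 * alpha * w # gradient of F
    if (max(abs(g)) < tol[["gradient"]]) { converged <- TRUE; break }

    # LM step on F with adaptive damping
    accepted <- FALSE
    for (try in 1:30) {
      A <- beta * jtj + diag(alpha + mu, nw)
      step <- tryCatch({
        R <- chol(A)
        backsolve(R, forwardsolve(t(R), beta * drop(crossprod(J, e)) -
                                     alpha * w))
      }, error = function(err) NULL)
      if (!is.null(step)) {
        w_new <- w + step
        out_new <- mlp_forward(w_new, dims, xsc)$out
        if (all(is.finite(out_new))) {
          e_new <- ysc - out_new
          f_new <- beta * sum(e_new^2) + alpha * sum(w_new^2)
          if (is.finite(f_new) && f_new < f) {
            w <- w_new
            accepted <- TRUE
            mu <- max(mu * 0.1, 1e-12)
            break
          }
        }
      }
      mu <- mu * 10
      if (mu > 1e10) break
    }
    if (!accepted) { converged <- TRUE; break } # damping exhausted: at a minimum

    fw <- mlp_forward(w, dims, xsc, jacobian = TRUE)
    if (any(!is.finite(fw$out))) {
      stop("non-finite network output at epoch ", iter, call. = FALSE)
    }
    e <- ysc - fw$out
    ed <- sum(e^2)
    ew <- sum(w^2)

    # evidence update of the hyperparameters
    gamma_old <- gamma
    if (alpha > 0) {
      H <- 2 * beta * crossprod(fw$J) + diag(2 * alpha, nw)
      tr_hinv <- tryCatch(sum(diag(chol2inv(chol(H)))), error = function(err) {
        ev <- eigen(crossprod(fw$J), symmetric = TRUE, only.values = TRUE)$values
        sum(1 / (2 * beta * pmax(ev, 0) + 2 * alpha))
      })
      gamma <- nw - 2 * alpha * tr_hinv
    } else {
      gamma <- nw
    }
    gamma <- min(max(gamma, 0), nw)
    alpha_old <- alpha
    beta_old <- beta
    alpha <- if (ew > 0) gamma / (2 * ew) else alpha
    beta <- if (ed > .Machine$double.eps * n) (n - gamma) / (2 * ed) else 1e10
    beta <- min(max(beta, .Machine$double.xmin), 1e10)
    f_old <- f
    f <- beta * ed + alpha * ew
    hyper_stable <-
      abs(alpha - alpha_old) < 1e-3 * max(alpha_old, 1e-12) &&
      abs(beta - beta_old) < 1e-3 * max(beta_old, 1e-12)
    if (abs(gamma - gamma_old) < tol[["gamma"]] && hyper_stable &&
        abs(f - f_old) < tol[["f_rel"]] * max(abs(f_old), 1)) {
      converged <- TRUE
      break
    }
  }

  structure(list(layer_sizes = layer_sizes, dims = dims, weights = w,
                 x_center = xs$center, x_scale = xs$scale,
                 y_center = ys$center[1], y_scale = ys$scale[1],
                 alpha = alpha, beta = beta, gamma = gamma,
                 n_weights = nw, n_train = n, seed = seed,
                 n_iter = iter, converged = converged,
                 history = if (trace) do.call(rbind, history[seq_len(iter)])),
            class = "brnn_member")
}

#' Predict with a single trained member
#'
#' @param object a `brnn_member`.
#' @param x unscaled feature matrix.
#' @param ... unused.
#' @return numeric predictions in target units.
#' @export
predict.brnn_member <- function(object, x, ...) {
  xsc <- apply_standardizer(x, list(center = object$x_center,
                                    scale = object$x_scale))
  out <- mlp_forward(object$weights, object$dims, xsc)$out
  out * object$y_scale + object$y_center
}
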