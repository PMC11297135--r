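#' Train an ensemble of Bayesian-regularized networks
#'
#' Ten members share one random train/test split and differ only in their
#' weight initialization; the ensemble prediction is the arithmetic mean of
#' the members' outputs, which can never have larger mean squared error than
#' the members' average. Default architectures: two hidden layers of 28 and
#' 10 neurons for pH, one hidden layer of 40 neurons for alkalinity.
#'
#' @param table a labelled hydrographic table.
#' @param target `"ph"` or `"ta"`.
#' @param layer_sizes hidden-layer widths; `NULL` picks the default for the
#'   target.
#' @param n_members ensemble size (default 10).
#' @param fraction_test held-out fraction (default 0.10).
#' @param seed master seed; the split and each member's initialization are
#'   derived from it.
#' @param max_iter,tol passed to [train_member()].
#' @return object of class `brnn_ensemble`: members, split indices, target,
#'   per-member and ensemble test metrics, and the stored test-set
#'   predictions and observations.
#' @export
train_ensemble <- function(table, target = c("ph", "ta"), layer_sizes = NULL,
                           n_members = 10L, fraction_test = 0.10, seed,
                           max_iter = 200,
                           tol = c(gradient = 1e-6, gamma = 1e-3,
                                   f_rel = 1e-9)) {
  target <- match.arg(target)
  if (is.null(layer_sizes)) {
    layer_sizes <- if (target == "ph") c(28L, 10L) else 40L
  }
  label_col <- if (target == "ph") "ph" else "ta_umol_kg"
  table <- as_hydro_table(table)
  table <- table[!is.na(table[[label_col]]), , drop = FALSE]
  if (nrow(table) < 10) {
    stop("too few labelled rows for target ", target, call. = FALSE)
  }
  x <- encode_features(table)
  y <- table[[label_col]]
  split_seed <- derive_seed(seed, paste0("split-", target))
  split <- split_train_test(nrow(x), fraction_test, split_seed)

  members <- vector("list", n_members)
  member_metrics <- vector("list", n_members)
  pred_test <- matrix(NA_real_, length(split$test), n_members)
  for (i in seq_len(n_members)) {
    m <- tryCatch(
      train_member(x[split$train, , drop = FALSE], y[split$train],
                   layer_sizes = layer_sizes,
                   seed = derive_seed(seed, sprintf("member-%s-%d", target, i)),
                   max_iter = max_iter, tol = tol),
      error = function(err) {
        stop(sprintf("training of ensemble member %d failed: %s", i,
                     conditionMessage(err)), call. = FALSE)
      })
    members[[i]] <- m
    pred_test[, i] <- predict(m, x[split$test, , drop = FALSE])
    member_metrics[[i]] <- evaluate(pred_test[, i], y[split$test])
  }
  ens_pred <- rowMeans(pred_test)
  structure(list(
    target = target, layer_sizes = layer_sizes, members = members,
    seed = seed, split_seed = split_seed, split = split,
    member_metrics = member_metrics,
    ensemble_metrics = evaluate(ens_pred, y[split$test]),
    test_predictions = ens_pred, test_observations = y[split$test]
  ), class = "brnn_ensemble")
}

#' Predict with an ensemble
#'
#' Arithmetic mean of the members' (de-scaled) outputs, row order preserved.
#'
#' @param object a `brnn_ensemble`.
#' @param table a hydrographic table of prediction rows.
#' @param ... unused.
#' @return numeric predictions in target units.
#' @export
predict.brnn_ensemble <- function(object, table, ...) {
  x <- encode_features(table)
  p <- vapply(object$members, function(m) predict(m, x),
              numeric(nrow(x)))
  if (nrow(x) == 1L) p <- matrix(p, nrow = 1L)
  rowMeans(p)
}

#' @export
print.brnn_ensemble <- function(x, ...) {
  m <- x$ensemble_metrics
  cat(sprintf(
    "Bayesian-regularized network ensemble for %s: %d members [%s]\n",
    x$target, length(x$members), paste(x$layer_sizes, collapse = ", ")))
  cat(sprintf("test set n = %d | MAE %.4g | MSE %.4g | RMSE %.4g | r2 %.3g\n",
              m$n, m$mae, m$mse, m$rmse, m$r2))
  invisible(x)
}

#' Serialize / restore an ensemble as self-describing JSON
#'
#' Stores layer sizes, flattened weights, scalers, hyperparameters, seeds
#' and metrics, so a saved model predicts identically after reload.
#'
#' @param model a `brnn_ensemble`.
#' @param path file path (JSON).
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns the restored `brnn_ensemble`.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "brnn_ensemble"))
  payload <- list(
    format = "riacarb-brnn-ensemble", version = 1L,
    target = model$target, layer_sizes = model$layer_sizes,
    seed = model$seed, split_seed = model$split_seed, split = model$split,
    member_metrics = model$member_metrics,
    ensemble_metrics = model$ensemble_metrics,
    test_predictions = model$test_predictions,
    test_observations = model$test_observations,
    members = lapply(model$members, function(m) {
      m$dims <- NULL # reconstructed from layer sizes and feature count
      unclass(m)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "riacarb-brnn-ensemble")) {
    stop("not a serialized ensemble: ", path, call. = FALSE)
  }
  members <- lapply(seq_len(nrow_or_len(p$members)), function(i) {
    m <- member_record(p$members, i)
    m$layer_sizes <- as.integer(m$layer_sizes)
    m$dims <- layer_dims(length(m$x_center), m$layer_sizes)
    class(m) <- "brnn_member"
    m
  })
  structure(list(
    target = p$target, layer_sizes = as.integer(p$layer_sizes),
    members = members, seed = p$seed, split_seed = p$split_seed,
    split = lapply(p$split, as.integer),
    member_metrics = metric_rows(p$member_metrics),
    ensemble_metrics = as.list(p$ensemble_metrics),
    test_predictions = p$test_predictions,
    test_observations = p$test_observations
  ), class = "brnn_ensemble")
}

# jsonlite simplification may return either a list of records or a
# data.frame-like structure; normalize both
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

member_record <- function(x, i) {
  if (is.data.frame(x)) lapply(as.list(x[i, , drop = FALSE]), unlist_keep,
                               use_names = FALSE)
  else x[[i]]
}

unlist_keep <- function(v, use_names) {
  if (is.list(v)) unlist(v, use.names = use_names) else v
}

metric_rows <- function(x) {
  if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  else lapply(x, as.list)
}
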