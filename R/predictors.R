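# Component regressors (CNN / elastic net / random forest), ensemble
# rules, permutation feature importance, and model-bundle serialization.

#' Subsample training pairs
#'
#' Pairs the feature tensor rows with their observed normalized
#' expression and draws a uniform, seeded subsample without replacement
#' (all eligible pairs, in original gene-major order, when there are
#' fewer than `n`). Pairs whose gene or cell is absent from the
#' expression matrix are excluded.
#'
#' @param tensor a `feature_tensor`.
#' @param targets normalized genes x cells expression matrix.
#' @param n maximum number of pairs (default 100000).
#' @param seed RNG seed.
#' @return List with `X` (pairs x features), `y`, `pairs` (data.table),
#'   `idx` (row indices into the tensor).
#' @export
subsample_training_pairs <- function(tensor, targets, n = 100000L,
                                     seed = 1L) {
  gi <- match(tensor$pairs$gene_id, rownames(targets))
  ci <- match(tensor$pairs$cell_id, colnames(targets))
  eligible <- which(!is.na(gi) & !is.na(ci))
  if (!length(eligible)) abort_validation("no gene-cell pairs with expression")
  idx <- if (length(eligible) > n)
    with_seed(seed, sort(sample(eligible, n)))
  else eligible
  X <- as.matrix(tensor)[idx, , drop = FALSE]
  y <- targets[cbind(gi[idx], ci[idx])]
  list(X = X, y = y, pairs = tensor$pairs[idx], idx = idx)
}

new_trained_model <- function(kind, fit, feature_order,
                              training_max_log_expr = NA_real_) {
  structure(list(kind = kind, fit = fit, feature_order = feature_order,
                 training_max_log_expr = training_max_log_expr),
            class = "trained_model")
}

#' @exportS3Method base::print
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s over %d features\n",
              x$kind, length(x$feature_order)))
  invisible(x)
}

check_layout <- function(model, X) {
  if (ncol(X) != length(model$feature_order))
    abort_validation("feature layout mismatch: model has %d features, X has %d",
                     length(model$feature_order), ncol(X))
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_order))
    abort_validation("feature column order differs from the trained layout")
}

#' Train a regression random forest
#'
#' 500 trees by default; each tree is grown on a random subsample of 80%
#' of the training rows drawn *without* replacement, with `mtry`
#' candidate features per split (p/3 by default, the regression-forest
#' convention) and variance-reduction splits down to `min_node` samples.
#'
#' @param X pairs x features matrix.
#' @param y numeric targets.
#' @param n_trees number of trees (default 500).
#' @param sample_frac per-tree subsampling fraction (default 0.8).
#' @param mtry features tried per split (default `max(1, floor(p/3))`).
#' @param min_node minimal node size for splitting (default 5).
#' @param max_bins histogram resolution for candidate thresholds.
#' @param seed RNG seed (bit-reproducible).
#' @return A `trained_model` of kind `"random_forest"`.
#' @export
train_random_forest <- function(X, y, n_trees = 500L, sample_frac = 0.8,
                                mtry = NULL, min_node = 5L, max_bins = 256L,
                                seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    warning("constant training targets; forest will predict the constant")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  fit <- .rf_train_cpp(X, as.numeric(y), as.integer(n_trees), sample_frac,
                       as.integer(mtry), as.integer(min_node),
                       as.integer(max_bins), as.integer(seed))
  fit$hyper <- list(n_trees = n_trees, sample_frac = sample_frac,
                    mtry = mtry, min_node = min_node, seed = seed)
  new_trained_model("random_forest", fit,
                    colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

#' Train an elastic net
#'
#' `glmnet` with mixing parameter `alpha = 0.5`; the penalty `lambda` is
#' chosen by seeded 10-fold cross-validation as the value minimizing CV
#' MSE (`lambda.min`) over glmnet's log-spaced path. Features are
#' standardized internally by glmnet and coefficients returned on the
#' original scale.
#'
#' @param X,y training data.
#' @param alpha_mix elastic-net mixing parameter (default 0.5).
#' @param n_cv_folds folds for the lambda search (default 10).
#' @param seed RNG seed (controls fold assignment).
#' @return A `trained_model` of kind `"elastic_net"`.
#' @export
train_elastic_net <- function(X, y, alpha_mix = 0.5, n_cv_folds = 10L,
                              seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < n_cv_folds)
    abort_validation("fewer samples (%d) than CV folds (%d)",
                     nrow(X), n_cv_folds)
  foldid <- with_seed(seed,
                      sample(rep_len(seq_len(n_cv_folds), nrow(X))))
  fit <- glmnet::cv.glmnet(X, as.numeric(y), alpha = alpha_mix,
                           foldid = foldid, family = "gaussian")
  new_trained_model("elastic_net",
                    list(cvfit = fit, lambda = fit$lambda.min,
                         alpha = alpha_mix),
                    colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

#' Train the 1-D convolutional network
#'
#' The flat feature vector is reshaped as `n_bins` promoter positions
#' with two channels (CpG frequency, pooled methylation rate), so the
#' convolution slides along the promoter. Architecture: `n_filters`
#' ReLU filters of width `kernel`, max-pooling of size `pool`, dropout,
#' one dense ReLU layer, linear scalar output; MSE loss, Adam, early
#' stopping with the given `patience` on a 10% validation split.
#'
#' @param X,y training data (`ncol(X)` must be `2 * n_bins`).
#' @param n_filters,kernel,pool,dropout,patience network hyperparameters
#'   (defaults 50, 5, 4, 0.2, 10).
#' @param dense width of the dense hidden layer (default 64).
#' @param max_epochs,lr,batch_size optimizer settings.
#' @param seed RNG seed.
#' @return A `trained_model` of kind `"cnn"`.
#' @export
train_cnn <- function(X, y, n_filters = 50L, kernel = 5L, pool = 4L,
                      dropout = 0.2, patience = 10L, dense = 64L,
                      max_epochs = 150L, lr = 5e-3, batch_size = 128L,
                      seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) %% 2L != 0L)
    abort_validation("CNN expects an even number of columns (2 channels)")
  fit <- cnn_fit(X, as.numeric(y), n_bins = ncol(X) %/% 2L,
                 n_filters = n_filters, kernel = kernel, pool = pool,
                 dropout = dropout, patience = patience, dense = dense,
                 max_epochs = max_epochs, lr = lr, batch_size = batch_size,
                 seed = seed)
  new_trained_model("cnn", fit,
                    colnames(X) %||% paste0("f", seq_len(ncol(X))))
}

#' @export
predict.trained_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  check_layout(object, X)
  out <- switch(object$kind,
    random_forest = .rf_predict_cpp(object$fit, X),
    elastic_net = drop(predict(object$fit$cvfit, newx = X,
                               s = object$fit$lambda)),
    cnn = cnn_predict_fit(object$fit, X),
    abort_validation("unknown model kind '%s'", object$kind))
  unname(out)
}

#' Train the component ensemble
#'
#' Trains the requested components on the full training set and combines
#' them under one of four rules. `unweighted` (the default, chosen for
#' its simplicity and stability) is the arithmetic mean of component
#' outputs. The weighted rules derive per-component weights from seeded
#' internal cross-validation on the training set: the median per-fold
#' Spearman correlation (`weighted_correlation`) or median per-fold
#' accuracy `1 - MSE` (`weighted_accuracy`), clipped at zero and
#' renormalized to sum to one. `stacking` fits a second-layer elastic
#' net on out-of-fold component predictions.
#'
#' @param X,y training data.
#' @param rule ensemble rule.
#' @param components subset of
#'   `c("cnn", "elastic_net", "random_forest")`.
#' @param seed RNG seed, fanned out to the components.
#' @param cv_folds internal folds for weight estimation (default 5).
#' @param control named list of hyperparameter overrides per component,
#'   e.g. `list(random_forest = list(n_trees = 100))`.
#' @return An `ensemble_model`.
#' @export
train_ensemble <- function(X, y,
                           rule = c("unweighted", "weighted_correlation",
                                    "weighted_accuracy", "stacking"),
                           components = c("cnn", "elastic_net",
                                          "random_forest"),
                           seed = 1L, cv_folds = 5L, control = list()) {
  rule <- match.arg(rule)
  components <- match.arg(components, several.ok = TRUE)
  X <- as.matrix(X)
  train_one <- function(kind, Xt, yt, seed_off) {
    args <- control[[kind]] %||% list()
    fun <- switch(kind, cnn = train_cnn, elastic_net = train_elastic_net,
                  random_forest = train_random_forest)
    do.call(fun, c(list(X = Xt, y = yt,
                        seed = derive_seed(seed, seed_off)), args))
  }
  fitted <- lapply(seq_along(components), function(i)
    train_one(components[i], X, y, i))
  names(fitted) <- components

  weights <- rep(1 / length(components), length(components))
  stacker <- NULL
  if (rule != "unweighted") {
    foldid <- with_seed(derive_seed(seed, 97L),
                        sample(rep_len(seq_len(cv_folds), nrow(X))))
    oof <- matrix(NA_real_, nrow(X), length(components),
                  dimnames = list(NULL, components))
    stat <- matrix(NA_real_, cv_folds, length(components))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      for (i in seq_along(components)) {
        m <- train_one(components[i], X[tr, , drop = FALSE], y[tr],
                       100L * f + i)
        p <- predict(m, X[!tr, , drop = FALSE])
        oof[!tr, i] <- p
        stat[f, i] <- if (rule == "weighted_accuracy")
          1 - mean((p - y[!tr])^2)
        else suppressWarnings(cor(p, y[!tr], method = "spearman"))
      }
    }
    if (rule == "stacking") {
      stacker <- train_elastic_net(oof, y, seed = derive_seed(seed, 98L))
    } else {
      w <- apply(stat, 2L, median, na.rm = TRUE)
      w[!is.finite(w) | w < 0] <- 0
      weights <- if (sum(w) > 0) w / sum(w)
      else rep(1 / length(components), length(components))
    }
  }
  structure(list(components = fitted, rule = rule, weights = weights,
                 stacker = stacker,
                 feature_order = fitted[[1L]]$feature_order),
            class = "ensemble_model")
}

#' @exportS3Method base::print
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s over {%s}\n", x$rule,
              paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  preds <- vapply(object$components, predict, numeric(nrow(X)), newdata = X)
  if (nrow(X) == 1L) preds <- matrix(preds, nrow = 1L)
  switch(object$rule,
    unweighted = rowMeans(preds),
    weighted_correlation = ,
    weighted_accuracy = drop(preds %*% object$weights),
    stacking = {
      colnames(preds) <- names(object$components)
      predict(object$stacker, preds)
    })
}

#' Permutation feature importance
#'
#' Importance of feature `f` is the mean, over seeded repeats, of the
#' increase in MSE when column `f` is randomly permuted:
#' `MSE(permuted f) - MSE(baseline)`. Constant columns score exactly 0;
#' irrelevant features score near 0 and may go slightly negative.
#'
#' @param model a `trained_model` or `ensemble_model`.
#' @param X,y evaluation data (held-out or training, per caller).
#' @param n_repeats permutations per feature (default 5).
#' @param seed RNG seed.
#' @return `data.frame` with `feature`, `class` (`"cpg"`/`"mr"`/other),
#'   `bin` and `importance`, in feature order.
#' @export
feature_importance <- function(model, X, y, n_repeats = 5L, seed = 1L) {
  X <- as.matrix(X)
  base_mse <- mean((predict(model, X) - y)^2)
  p <- ncol(X)
  scores <- matrix(NA_real_, n_repeats, p)
  perms <- with_seed(seed, replicate(n_repeats, sample.int(nrow(X)),
                                     simplify = FALSE))
  for (r in seq_len(n_repeats)) {
    for (f in seq_len(p)) {
      if (length(unique(X[, f])) < 2L) { scores[r, f] <- 0; next }
      Xp <- X
      Xp[, f] <- X[perms[[r]], f]
      scores[r, f] <- mean((predict(model, Xp) - y)^2) - base_mse
    }
  }
  nm <- colnames(X) %||% paste0("f", seq_len(p))
  cls <- sub("_.*$", "", nm)
  bin <- suppressWarnings(as.integer(sub("^[a-z]+_", "", nm)))
  data.frame(feature = nm, class = cls, bin = bin,
             importance = colMeans(scores), stringsAsFactors = FALSE)
}

# One master seed fans out to per-stage seeds deterministically; stays
# below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + 7919 * as.numeric(offset)) %%
               2147483647)
}

#' Save / load a trained model bundle
#'
#' A bundle is a directory with `metadata.json` (kind, rule,
#' hyperparameters, feature order, normalization constant, seed) and one
#' serialized parameter file per component.
#'
#' @param model an `ensemble_model` or `trained_model`.
#' @param dir bundle directory (created if needed).
#' @param max_log_expr training normalization constant to store.
#' @param config optional run configuration to record.
#' @return `dir` (save) or the model (load).
#' @export
save_model_bundle <- function(model, dir, max_log_expr = NA_real_,
                              config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  is_ens <- inherits(model, "ensemble_model")
  meta <- list(
    type = if (is_ens) "ensemble" else "single",
    rule = if (is_ens) model$rule else model$kind,
    components = if (is_ens) names(model$components) else model$kind,
    feature_order = model$feature_order,
    max_log_expr = max_log_expr,
    weights = if (is_ens) model$weights else NULL,
    config = config)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  rds_path <- file.path(dir, "model.rds")
  if (!file.exists(meta_path) || !file.exists(rds_path))
    abort_validation("not a model bundle: %s", dir)
  model <- readRDS(rds_path)
  meta <- jsonlite::read_json(meta_path)
  attr(model, "max_log_expr") <-
    if (is.null(meta$max_log_expr)) NA_real_ else as.numeric(meta$max_log_expr)
  attr(model, "config") <- meta$config
  model
}
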