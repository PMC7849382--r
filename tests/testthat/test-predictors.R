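fake_tensor <- function(n_genes = 5L, n_cells = 4L, n_bins = 20L,
                        seed = 30L) {
  set.seed(seed)
  n <- n_genes * n_cells
  structure(list(
    pairs = data.table::data.table(
      gene_id = rep(paste0("g", seq_len(n_genes)), each = n_cells),
      cell_id = rep(paste0("c", seq_len(n_cells)), times = n_genes)),
    cpg_ratio = matrix(runif(n * n_bins), n, n_bins),
    meth_rate = matrix(runif(n * n_bins), n, n_bins),
    meth_mask = matrix(FALSE, n, n_bins),
    n_bins = n_bins), class = "feature_tensor")
}

test_that("subsample_training_pairs clamps, seeds and filters", {
  tensor <- fake_tensor()
  expr <- matrix(runif(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  all_pairs <- subsample_training_pairs(tensor, expr, n = 1e5, seed = 1)
  expect_identical(nrow(all_pairs$X), 20L)
  expect_identical(all_pairs$idx, seq_len(20L))      # original pair order
  expect_equal(all_pairs$y[1], expr["g1", "c1"])
  s1 <- subsample_training_pairs(tensor, expr, n = 7, seed = 5)
  s2 <- subsample_training_pairs(tensor, expr, n = 7, seed = 5)
  expect_identical(s1$idx, s2$idx)
  expect_identical(nrow(s1$X), 7L)
  s3 <- subsample_training_pairs(tensor, expr, n = 7, seed = 6)
  expect_false(identical(s1$idx, s3$idx))
  # genes missing from expression are excluded
  expr2 <- expr[1:3, ]
  s4 <- subsample_training_pairs(tensor, expr2, n = 1e5, seed = 1)
  expect_identical(nrow(s4$X), 12L)
  expect_error(subsample_training_pairs(tensor, expr[0, ], n = 5, seed = 1),
               "no gene-cell pairs")
})

test_that("random forest learns a planted feature and is reproducible", {
  set.seed(31)
  n <- 600
  X <- matrix(runif(n * 10), n, 10)
  colnames(X) <- paste0("f", 1:10)
  y <- X[, 3]
  rf <- train_random_forest(X, y, n_trees = 100, seed = 2)
  p <- predict(rf, X)
  expect_gt(1 - mean((p - y)^2) / var(y), 0.95)      # training R^2
  rf2 <- train_random_forest(X, y, n_trees = 100, seed = 2)
  expect_identical(predict(rf2, X), p)               # bit-exact rerun
  rf3 <- train_random_forest(X, y, n_trees = 100, seed = 3)
  expect_false(identical(predict(rf3, X), p))
  expect_warning(cf <- train_random_forest(X, rep(0.4, n), n_trees = 5,
                                           seed = 1),
                 "constant")
  expect_equal(predict(cf, X), rep(0.4, n))
})

test_that("elastic net recovers a noiseless linear signal", {
  set.seed(32)
  n <- 300
  X <- matrix(runif(n * 8), n, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- 2 * X[, 1]
  en <- train_elastic_net(X, y, seed = 4)
  Xnew <- matrix(runif(40 * 8), 40, 8, dimnames = list(NULL, colnames(X)))
  p <- predict(en, Xnew)
  slope <- coef(lm(p ~ Xnew[, 1]))[2]
  expect_lt(abs(slope - 2) / 2, 0.05)
  expect_lt(max(abs(p - 2 * Xnew[, 1])), 0.15)
  expect_error(train_elastic_net(X[1:5, ], y[1:5], n_cv_folds = 10),
               "fewer samples")
  # same seed, same fit
  en2 <- train_elastic_net(X, y, seed = 4)
  expect_identical(predict(en2, Xnew), p)
})

test_that("CNN learns a planted positional signal", {
  set.seed(33)
  n <- 4000
  X <- matrix(runif(n * 40), n, 40)
  colnames(X) <- c(sprintf("cpg_%02d", 1:20), sprintf("mr_%02d", 1:20))
  y <- (X[, 31] + X[, 32]) / 2           # mean of meth-rate bins 11-12
  cnn <- train_cnn(X, y, max_epochs = 60, seed = 5)
  Xte <- matrix(runif(1000 * 40), 1000, 40,
                dimnames = list(NULL, colnames(X)))
  yte <- (Xte[, 31] + Xte[, 32]) / 2
  p <- predict(cnn, Xte)
  expect_gt(cor(p, yte, method = "spearman"), 0.9)
  # constant target converges to the constant
  cnn0 <- train_cnn(X[1:500, ], rep(0.3, 500), max_epochs = 20, seed = 6)
  expect_lt(mean((predict(cnn0, Xte) - 0.3)^2), 0.01)
})

test_that("predict validates the feature layout", {
  set.seed(34)
  X <- matrix(runif(200), 20, 10)
  colnames(X) <- paste0("f", 1:10)
  rf <- train_random_forest(X, runif(20), n_trees = 5, seed = 1)
  bad <- X[, c(2:10, 1)]
  expect_error(predict(rf, bad), "order")
  expect_error(predict(rf, X[, 1:5]), "layout mismatch")
})

test_that("ensemble rules satisfy their algebraic identities", {
  set.seed(35)
  n <- 120
  X <- matrix(runif(n * 40), n, 40)
  colnames(X) <- c(sprintf("cpg_%02d", 1:20), sprintf("mr_%02d", 1:20))
  y <- X[, 25] + 0.1 * rnorm(n)
  ens <- train_ensemble(X, y, rule = "unweighted",
                        seed = 7,
                        control = list(random_forest = list(n_trees = 20),
                                       cnn = list(max_epochs = 3)))
  comp_preds <- vapply(ens$components, predict, numeric(n), newdata = X)
  p <- predict(ens, X)
  expect_equal(p, rowMeans(comp_preds))               # mean identity
  expect_true(all(p >= apply(comp_preds, 1, min) - 1e-12))
  expect_true(all(p <= apply(comp_preds, 1, max) + 1e-12))
  expect_equal(ens$weights, rep(1 / 3, 3))
  # identical components pass through unchanged under unweighted
  ens_same <- ens
  ens_same$components <- ens$components[c(2, 2, 2)]
  expect_equal(predict(ens_same, X),
               unname(predict(ens$components[[2]], X)))
  # weighted rule reproduces a hand-computed dot product
  ens_w <- ens
  ens_w$rule <- "weighted_correlation"
  ens_w$weights <- c(0.5, 0.3, 0.2)
  expect_equal(predict(ens_w, X),
               drop(comp_preds %*% c(0.5, 0.3, 0.2)))
})

test_that("weighted and stacking ensembles train end to end", {
  set.seed(36)
  n <- 200
  X <- matrix(runif(n * 40), n, 40)
  colnames(X) <- c(sprintf("cpg_%02d", 1:20), sprintf("mr_%02d", 1:20))
  y <- 0.8 * X[, 30] + 0.1 * rnorm(n)
  ctl <- list(random_forest = list(n_trees = 15),
              cnn = list(max_epochs = 3),
              elastic_net = list(n_cv_folds = 5))
  ew <- train_ensemble(X, y, rule = "weighted_correlation", seed = 8,
                       cv_folds = 3, control = ctl)
  expect_equal(sum(ew$weights), 1)
  expect_true(all(ew$weights >= 0))
  es <- train_ensemble(X, y, rule = "stacking", seed = 8, cv_folds = 3,
                       control = ctl)
  expect_s3_class(es$stacker, "trained_model")
  expect_true(all(is.finite(predict(es, X))))
})

test_that("permutation importance recovers a planted feature", {
  set.seed(37)
  n <- 500
  X <- matrix(runif(n * 12), n, 12)
  X[, 7] <- 0.5                                       # constant column
  colnames(X) <- paste0("f", 1:12)
  y <- X[, 5]
  rf <- train_random_forest(X, y, n_trees = 100, seed = 9)
  imp <- feature_importance(rf, X, y, n_repeats = 5, seed = 10)
  expect_identical(nrow(imp), 12L)
  expect_identical(which.max(imp$importance), 5L)
  expect_gt(imp$importance[5], max(imp$importance[-5]) * 5)
  expect_equal(imp$importance[7], 0)                  # permutation no-op
  expect_lt(max(abs(imp$importance[-c(5, 7)])), 0.02) # noise features ~ 0
  # seeded repeats are reproducible
  imp2 <- feature_importance(rf, X, y, n_repeats = 5, seed = 10)
  expect_identical(imp$importance, imp2$importance)
})

test_that("model bundles round-trip through disk", {
  set.seed(38)
  X <- matrix(runif(80 * 40), 80, 40)
  colnames(X) <- c(sprintf("cpg_%02d", 1:20), sprintf("mr_%02d", 1:20))
  y <- runif(80)
  ens <- train_ensemble(X, y, components = c("elastic_net", "random_forest"),
                        seed = 11,
                        control = list(random_forest = list(n_trees = 10)))
  dir <- withr::local_tempdir()
  save_model_bundle(ens, dir, max_log_expr = 12.3)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- load_model_bundle(dir)
  expect_equal(predict(back, X), predict(ens, X))
  expect_equal(attr(back, "max_log_expr"), 12.3)
  expect_error(load_model_bundle(withr::local_tempdir()), "bundle")
})
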