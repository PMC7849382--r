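# End-to-end glue: default run configuration, feature pipeline, training
# and prediction entry points used by both the CLI and the CV harness.

#' Default run configuration
#'
#' All tunables with their standard defaults: promoter +/- 5 kb split
#' into 20 bins of 500 bp, top 5000 variable promoters, 10 principal
#' components, k = 20 neighbours, 100000 training pairs, RF with 500
#' trees on 80% subsamples, elastic net alpha 0.5 with 10-fold lambda
#' CV, CNN with 50 filters / kernel 5 / pool 4 / dropout 0.2 / patience
#' 10, unweighted ensemble.
#'
#' @param ... overrides of any default, e.g. `run_config(knn_k = 10)`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    flank = 5000L, bin_size = 500L,
    n_variable_promoters = 5000L, pca_d = 10L, knn_k = 20L,
    include_self = TRUE,
    subsample_n = 100000L,
    rf_trees = 500L, rf_frac = 0.8,
    en_alpha = 0.5, en_folds = 10L,
    cnn_filters = 50L, cnn_kernel = 5L, cnn_pool = 4L,
    cnn_dropout = 0.2, cnn_patience = 10L, cnn_dense = 64L,
    cnn_max_epochs = 150L,
    ensemble_rule = "unweighted",
    components = c("cnn", "elastic_net", "random_forest"),
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      abort_validation("unknown config field(s): %s",
                       paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "run_config")
}

config_control <- function(cfg) {
  list(random_forest = list(n_trees = cfg$rf_trees,
                            sample_frac = cfg$rf_frac),
       elastic_net = list(alpha_mix = cfg$en_alpha,
                          n_cv_folds = cfg$en_folds),
       cnn = list(n_filters = cfg$cnn_filters, kernel = cfg$cnn_kernel,
                  pool = cfg$cnn_pool, dropout = cfg$cnn_dropout,
                  patience = cfg$cnn_patience, dense = cfg$cnn_dense,
                  max_epochs = cfg$cnn_max_epochs))
}

#' Run the feature pipeline: promoter matrix, meta-cells, feature tensor
#'
#' @param calls named list of [methylation_calls].
#' @param tss TSS annotation.
#' @param genome [Biostrings::DNAStringSet].
#' @param config a [run_config()].
#' @return List with `tensor`, `metacells`, `embedding`, `pmm`.
#' @export
build_features <- function(calls, tss, genome, config = run_config()) {
  cfg <- config
  pmm <- compute_promoter_methylation_matrix(calls, tss, flank = cfg$flank)
  vp <- select_variable_promoters(pmm, n_top = cfg$n_variable_promoters)
  d <- min(cfg$pca_d, length(vp), ncol(pmm$values))
  emb <- compute_pca_embedding(pmm, vp, d = d)
  mc <- build_metacells(emb, k = cfg$knn_k, include_self = cfg$include_self)
  tensor <- assemble_features(tss, mc, calls, genome,
                              flank = cfg$flank, bin_size = cfg$bin_size)
  list(tensor = tensor, metacells = mc, embedding = emb, pmm = pmm)
}

#' Train a gene-activity predictor from matched multi-omics data
#'
#' @param calls named list of [methylation_calls] (cells must match the
#'   expression columns; unmatched cells are an error).
#' @param counts raw genes x cells expression counts.
#' @param tss,genome annotation and sequence.
#' @param config a [run_config()].
#' @return List with the trained `model` (an `ensemble_model`),
#'   `max_log_expr`, and the training `features`.
#' @export
train_gene_activity <- function(calls, counts, tss, genome,
                                config = run_config()) {
  cfg <- config
  shared <- intersect(names(calls), colnames(counts))
  unmatched <- union(setdiff(names(calls), shared),
                     setdiff(colnames(counts), shared))
  if (!length(shared))
    abort_validation("no cells shared between methylome and expression")
  if (length(unmatched))
    warning(sprintf("dropping %d cell(s) without both modalities: %s",
                    length(unmatched),
                    paste(head(unmatched, 5), collapse = ", ")))
  calls <- calls[shared]
  counts <- counts[, shared, drop = FALSE]
  expr <- normalize_expression(counts)
  feats <- build_features(calls, tss, genome, cfg)
  sub <- subsample_training_pairs(feats$tensor, expr, n = cfg$subsample_n,
                                  seed = derive_seed(cfg$seed, 5L))
  model <- train_ensemble(sub$X, sub$y, rule = cfg$ensemble_rule,
                          components = cfg$components,
                          seed = derive_seed(cfg$seed, 6L),
                          control = config_control(cfg))
  list(model = model, max_log_expr = attr(expr, "max_log_expr"),
       features = feats, config = cfg)
}

#' Predict gene activity for methylation-only cells
#'
#' @param model an `ensemble_model` or `trained_model`.
#' @param calls named list of [methylation_calls].
#' @param tss,genome annotation and sequence.
#' @param config a [run_config()] (geometry must match training).
#' @return genes x cells matrix of predicted activity scores.
#' @export
predict_gene_activity <- function(model, calls, tss, genome,
                                  config = run_config()) {
  feats <- build_features(calls, tss, genome, config)
  pred <- predict(model, as.matrix(feats$tensor))
  pairs_to_matrix(feats$tensor$pairs, pred)
}
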