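# Evaluation: Spearman metrics, median squared error, internal 5-fold and
# external cross-dataset validation, CpG-context stratification.

#' Global Spearman correlation over all gene-cell pairs
#'
#' Rank correlation with average ranks for ties, pooling every pair.
#' Constant input is undefined and returns `NA` with a warning.
#'
#' @param pred,obs equal-length numeric vectors.
#' @return Scalar in `[-1, 1]`, or `NA`.
#' @export
global_spearman <- function(pred, obs) {
  if (length(pred) != length(obs)) abort_validation("length mismatch")
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 2L || sd(pred[ok]) == 0 || sd(obs[ok]) == 0) {
    warning("Spearman undefined for constant or too-short input")
    return(NA_real_)
  }
  cor(pred[ok], obs[ok], method = "spearman")
}

#' Per-cell Spearman correlation across genes
#'
#' @param pred,obs genes x cells matrices with matching dimensions.
#' @return Named vector, one value per cell; `NA` for constant cells.
#' @export
per_cell_spearman <- function(pred, obs) {
  if (!all(dim(pred) == dim(obs))) abort_validation("shape mismatch")
  out <- vapply(seq_len(ncol(pred)), function(j)
    suppressWarnings(global_spearman(pred[, j], obs[, j])), 0)
  names(out) <- colnames(pred)
  out
}

#' Median squared error
#'
#' @param pred,obs equal-length numeric vectors.
#' @return `median((pred - obs)^2)`.
#' @export
median_squared_error <- function(pred, obs) {
  if (length(pred) != length(obs)) abort_validation("length mismatch")
  median((pred - obs)^2, na.rm = TRUE)
}

#' Classify a promoter by CpG-island context
#'
#' Precedence island > shore > shelf: a promoter overlapping an
#' annotated island is `island`; else within 2 kb of one, `shore`; else
#' within 4 kb, `shelf`; else `open_sea` (the standard 2 kb shore / 2 kb
#' shelf widths).
#'
#' @param gene one annotation row (`chrom`, `tss`), or a full annotation
#'   `data.frame` (vectorized).
#' @param islands `data.frame` of island intervals (`chrom`, `start`,
#'   `end`, 1-based inclusive), e.g. read from BED via [read_islands_bed()].
#' @param flank promoter half-width (default 5000).
#' @return Character vector of context labels.
#' @export
classify_cpg_context <- function(gene, islands, flank = 5000L) {
  n <- nrow(gene)
  out <- rep("open_sea", n)
  if (!nrow(islands)) return(if (n == 1L) out[1L] else out)
  p_start <- gene$tss - flank
  p_end <- gene$tss + flank
  for (i in seq_len(n)) {
    isl <- islands[islands$chrom == gene$chrom[i], , drop = FALSE]
    if (!nrow(isl)) next
    ov <- function(pad)
      any(isl$start - pad <= p_end[i] & isl$end + pad >= p_start[i])
    out[i] <- if (ov(0L)) "island"
    else if (ov(2000L)) "shore"
    else if (ov(4000L)) "shelf"
    else "open_sea"
  }
  out
}

#' Read CpG islands from BED
#'
#' @param path BED file (0-based half-open); converted to 1-based
#'   inclusive intervals.
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
read_islands_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  data.frame(chrom = as.character(dt[[1L]]), start = dt[[2L]] + 1L,
             end = dt[[3L]], stringsAsFactors = FALSE)
}

#' Evaluation report for a prediction
#'
#' @param pred,obs genes x cells matrices over matching labels.
#' @param tss optional annotation for context stratification.
#' @param islands optional island intervals (see [classify_cpg_context()]).
#' @param flank promoter half-width for the context call.
#' @return An `evaluation_report`: list with `global_spearman`,
#'   `per_cell_spearman`, `median_squared_error` and, when `islands` is
#'   given, `stratified` per-context global Spearman / MSE.
#' @export
evaluate_predictions <- function(pred, obs, tss = NULL, islands = NULL,
                                 flank = 5000L) {
  genes <- intersect(rownames(pred), rownames(obs))
  cells <- intersect(colnames(pred), colnames(obs))
  if (!length(genes) || !length(cells))
    abort_validation("no overlapping gene/cell labels between pred and obs")
  p <- pred[genes, cells, drop = FALSE]
  o <- obs[genes, cells, drop = FALSE]
  rep_out <- list(
    global_spearman = suppressWarnings(global_spearman(as.vector(p),
                                                       as.vector(o))),
    per_cell_spearman = per_cell_spearman(p, o),
    median_squared_error = median_squared_error(as.vector(p), as.vector(o)),
    n_genes = length(genes), n_cells = length(cells))
  if (!is.null(islands) && !is.null(tss)) {
    ann <- tss[match(genes, tss$gene_id), , drop = FALSE]
    ctx <- classify_cpg_context(ann, islands, flank = flank)
    rep_out$stratified <- lapply(
      split(seq_along(genes), factor(ctx, levels = c("island", "shore",
                                                     "shelf", "open_sea"))),
      function(ix) {
        if (!length(ix)) return(list(global_spearman = NA_real_,
                                     median_squared_error = NA_real_,
                                     n_genes = 0L))
        list(global_spearman = suppressWarnings(
               global_spearman(as.vector(p[ix, , drop = FALSE]),
                               as.vector(o[ix, , drop = FALSE]))),
             median_squared_error = median_squared_error(
               as.vector(p[ix, , drop = FALSE]),
               as.vector(o[ix, , drop = FALSE])),
             n_genes = length(ix))
      })
  }
  structure(rep_out, class = "evaluation_report")
}

#' @exportS3Method base::print
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> %d genes x %d cells: global ",
                     "Spearman %.3f, median per-cell Spearman %.3f, ",
                     "median squared error %.4g\n"),
              x$n_genes, x$n_cells, x$global_spearman,
              median(x$per_cell_spearman, na.rm = TRUE),
              x$median_squared_error))
  invisible(x)
}

#' Cross-validation harness
#'
#' Internal mode: the (gene, cell) pairs of a single dataset are split
#' into `n_folds` seeded folds; for each fold the ensemble is trained on
#' the remaining pairs and evaluated on the fold. External mode: for
#' every ordered pair of distinct datasets, train on one and evaluate on
#' the other (4 datasets give the 12 off-diagonal train/test reports).
#' Test metrics always use the test dataset's own expression
#' normalization.
#'
#' Each dataset is a list with elements `tensor` (a `feature_tensor`)
#' and `expression` (normalized genes x cells matrix); optional `name`.
#'
#' @param datasets list of datasets as above.
#' @param mode `"internal_5fold"` or `"external"`.
#' @param rule ensemble rule (see [train_ensemble()]).
#' @param components component subset, passed to [train_ensemble()].
#' @param seed RNG seed.
#' @param n_folds folds for internal mode (default 5).
#' @param subsample_n training pairs drawn per fit (default 100000).
#' @param control hyperparameter overrides, passed to [train_ensemble()].
#' @return For internal mode, a list of per-fold `evaluation_report`s
#'   (attribute `folds` holds the pair assignment); for external mode a
#'   train x test matrix-shaped list of reports (diagonal `NULL`).
#' @export
cross_validate <- function(datasets, mode = c("internal_5fold", "external"),
                           rule = "unweighted",
                           components = c("cnn", "elastic_net",
                                          "random_forest"),
                           seed = 1L, n_folds = 5L, subsample_n = 100000L,
                           control = list()) {
  mode <- match.arg(mode)
  if (mode == "internal_5fold") {
    if (length(datasets) < 1L) abort_validation("internal CV needs a dataset")
    ds <- datasets[[1L]]
    sub <- subsample_training_pairs(ds$tensor, ds$expression,
                                    n = subsample_n,
                                    seed = derive_seed(seed, 11L))
    n <- nrow(sub$X)
    folds <- with_seed(derive_seed(seed, 12L),
                       sample(rep_len(seq_len(n_folds), n)))
    reports <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      model <- train_ensemble(sub$X[tr, , drop = FALSE], sub$y[tr],
                              rule = rule, components = components,
                              seed = derive_seed(seed, 20L + f),
                              control = control)
      p <- predict(model, sub$X[!tr, , drop = FALSE])
      reports[[f]] <- list(
        global_spearman = suppressWarnings(global_spearman(p, sub$y[!tr])),
        median_squared_error = median_squared_error(p, sub$y[!tr]),
        n_pairs = sum(!tr))
    }
    attr(reports, "folds") <- folds
    return(reports)
  }
  if (length(datasets) < 2L) abort_validation("external CV needs >= 2 datasets")
  nd <- length(datasets)
  nms <- vapply(seq_len(nd), function(i)
    datasets[[i]]$name %||% paste0("dataset", i), "")
  grid <- matrix(vector("list", nd * nd), nd, nd,
                 dimnames = list(train = nms, test = nms))
  for (i in seq_len(nd)) {
    sub <- subsample_training_pairs(datasets[[i]]$tensor,
                                    datasets[[i]]$expression,
                                    n = subsample_n,
                                    seed = derive_seed(seed, 30L + i))
    model <- train_ensemble(sub$X, sub$y, rule = rule,
                            components = components,
                            seed = derive_seed(seed, 40L + i),
                            control = control)
    for (j in seq_len(nd)) {
      if (j == i) next
      te <- datasets[[j]]
      pred_vec <- predict(model, as.matrix(te$tensor))
      pm <- pairs_to_matrix(te$tensor$pairs, pred_vec)
      grid[[i, j]] <- evaluate_predictions(pm, te$expression)
    }
  }
  grid
}

# Reshape a per-pair prediction vector into a genes x cells matrix.
pairs_to_matrix <- function(pairs, values) {
  genes <- unique(pairs$gene_id)
  cells <- unique(pairs$cell_id)
  m <- matrix(NA_real_, length(genes), length(cells),
              dimnames = list(genes, cells))
  m[cbind(match(pairs$gene_id, genes), match(pairs$cell_id, cells))] <- values
  m
}

#' Export an external-CV Spearman grid as TSV
#'
#' @param grid result of [cross_validate()] in external mode.
#' @param path output TSV (train rows, test columns).
#' @export
write_spearman_grid <- function(grid, path) {
  m <- apply(grid, c(1, 2), function(cell) {
    r <- cell[[1L]]
    if (is.null(r)) NA_real_ else r$global_spearman
  })
  dt <- data.table(train = rownames(m))
  fwrite(cbind(dt, as.data.table(m)), path, sep = "\t")
  invisible(path)
}
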