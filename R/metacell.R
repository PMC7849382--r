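# Meta-cell construction: promoter methylation matrix -> variable-promoter
# selection -> PCA -> exact k-NN neighbourhoods.

# Pooled methylated / total call counts per (promoter window, cell).
promoter_call_counts <- function(calls, tss, flank) {
  cells <- names(calls) %||% vapply(calls, cell_id_of, "")
  win <- data.table(gene = seq_len(nrow(tss)), chrom = tss$chrom,
                    start = pmax(1L, tss$tss - as.integer(flank)),
                    end = tss$tss + as.integer(flank))
  setkey(win, chrom, start, end)
  meth <- tot <- matrix(0, nrow(tss), length(calls),
                        dimnames = list(tss$gene_id, cells))
  for (j in seq_along(calls)) {
    cc <- as.data.table(calls[[j]])
    if (!nrow(cc)) next
    cc[, `:=`(start = pos, end = pos)]
    hits <- foverlaps(cc, win, type = "within", nomatch = NULL)
    if (!nrow(hits)) next
    agg <- hits[, .(m = sum(n_meth), t = sum(n_meth + n_unmeth)), by = gene]
    meth[agg$gene, j] <- agg$m
    tot[agg$gene, j] <- agg$t
  }
  list(meth = meth, tot = tot)
}

#' Promoter-level methylation matrix across cells
#'
#' For each gene the promoter is the +/- `flank` bp window around the TSS
#' (positions `tss - flank` .. `tss + flank`, 1-based inclusive). The
#' entry for (gene, cell) is the pooled ratio of methylated to total CpG
#' calls inside the window. Promoters with zero calls in a cell are
#' imputed with that cell's mean methylation over its covered promoters;
#' the pre-imputation pattern is kept in `missing_mask`.
#'
#' @param calls named list of [methylation_calls], one per cell.
#' @param tss annotation `data.frame` from [read_tss_annotation()].
#' @param flank promoter half-width in bp (default 5000).
#' @return A `promoter_meth_matrix`: list with `values` (genes x cells in
#'   `[0,1]`), `missing_mask` (logical, pre-imputation missingness) and
#'   `flank`.
#' @export
compute_promoter_methylation_matrix <- function(calls, tss, flank = 5000L) {
  if (length(calls) < 2L) abort_validation("need at least 2 cells")
  if (nrow(tss) < 1L) abort_validation("need at least 1 gene")
  cells <- names(calls) %||% vapply(calls, cell_id_of, "")
  if (is.null(names(calls))) names(calls) <- cells
  cnt <- promoter_call_counts(calls, tss, flank)
  meth <- cnt$meth
  tot <- cnt$tot
  missing_mask <- tot == 0
  values <- ifelse(missing_mask, NA_real_, meth / pmax(tot, 1))
  cell_means <- colMeans(values, na.rm = TRUE)
  empty <- which(is.nan(cell_means))
  if (length(empty))
    abort_validation("cell '%s' has no CpG calls in any promoter",
                     cells[empty[1L]])
  for (j in seq_along(calls))
    values[missing_mask[, j], j] <- cell_means[j]
  structure(list(values = values, missing_mask = missing_mask,
                 flank = as.integer(flank)),
            class = "promoter_meth_matrix")
}

#' @exportS3Method base::print
print.promoter_meth_matrix <- function(x, ...) {
  cat(sprintf("<promoter_meth_matrix> %d promoters x %d cells (%.1f%% observed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(!x$missing_mask)))
  invisible(x)
}

#' Select the most variably methylated promoters
#'
#' Ranks genes by population (divide-by-n) variance of promoter
#' methylation across cells, descending; ties break by ascending gene
#' index so the selection is deterministic.
#'
#' @param pmm a `promoter_meth_matrix` or a plain genes x cells matrix.
#' @param n_top number of promoters to keep (default 5000; clamped).
#' @return Integer vector of gene row indices, most variable first.
#' @export
select_variable_promoters <- function(pmm, n_top = 5000L) {
  if (n_top < 1L) abort_validation("n_top must be >= 1")
  m <- if (inherits(pmm, "promoter_meth_matrix")) pmm$values else as.matrix(pmm)
  n <- ncol(m)
  v <- rowMeans(m^2) - rowMeans(m)^2    # population variance
  ord <- order(-v, seq_along(v))
  ord[seq_len(min(n_top, nrow(m)))]
}

#' PCA embedding of cells from promoter methylation
#'
#' Cells are embedded by projecting the per-gene mean-centred (not
#' scaled: all promoters share the `[0,1]` methylation scale) cells x
#' genes matrix onto its top `d` right singular directions. Component
#' signs are fixed so that each component's largest-magnitude gene
#' loading is positive.
#'
#' @param pmm a `promoter_meth_matrix` or plain matrix.
#' @param gene_subset row indices, e.g. from [select_variable_promoters()].
#' @param d number of components (default 10).
#' @return cells x d numeric matrix with cell rownames.
#' @export
compute_pca_embedding <- function(pmm, gene_subset = NULL, d = 10L) {
  m <- if (inherits(pmm, "promoter_meth_matrix")) pmm$values else as.matrix(pmm)
  if (!is.null(gene_subset)) m <- m[gene_subset, , drop = FALSE]
  x <- t(m)                                # cells x genes
  if (d > min(dim(x)))
    abort_validation("d = %d exceeds min(n_cells, n_genes) = %d",
                     d, min(dim(x)))
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = 0, nv = d)
  v <- sv$v[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  emb <- xc %*% v
  rownames(emb) <- colnames(m)
  colnames(emb) <- paste0("PC", seq_len(d))
  emb
}

#' Build meta-cells by exact k-nearest-neighbour search
#'
#' Each cell's meta-cell is itself plus its `k` nearest cells by
#' Euclidean distance in the embedding (exact all-pairs search; distance
#' ties break by ascending cell index). With `include_self = FALSE` the
#' anchor cell is excluded and the meta-cell has `k` members.
#'
#' @param embedding cells x d matrix from [compute_pca_embedding()].
#' @param k neighbourhood size (default 20).
#' @param include_self include the anchor cell in its own meta-cell.
#' @return A `metacell_map`: list with `members` (list of sorted integer
#'   vectors), `k`, `cell_ids`.
#' @export
build_metacells <- function(embedding, k = 20L, include_self = TRUE) {
  n <- nrow(embedding)
  if (n <= k)
    abort_validation("n_cells = %d <= k = %d; use a smaller k", n, k)
  dd <- as.matrix(stats::dist(embedding))
  members <- vector("list", n)
  for (i in seq_len(n)) {
    o <- order(dd[i, ], seq_len(n))      # ties by ascending index
    o <- o[o != i]
    nb <- o[seq_len(k)]
    members[[i]] <- sort(if (include_self) c(i, nb) else nb)
  }
  structure(list(members = members, k = as.integer(k),
                 include_self = include_self,
                 cell_ids = rownames(embedding) %||% as.character(seq_len(n))),
            class = "metacell_map")
}

#' @exportS3Method base::print
print.metacell_map <- function(x, ...) {
  cat(sprintf("<metacell_map> %d meta-cells, k = %d%s\n",
              length(x$members), x$k,
              if (x$include_self) " (self included)" else ""))
  invisible(x)
}

#' Fraction of changed k-NN edges between two meta-cell maps
#'
#' Both maps are read as directed edge sets `{(i, j): j in members(i),
#' j != i}`. Under the default `"replacements"` convention one swapped
#' neighbour counts as one change and the denominator is the number of
#' edges of `map_a` (`n_cells * k`); `"symmetric"` counts both the lost
#' and the gained edge, i.e. `|A xor B| / |A|`.
#'
#' @param map_a,map_b `metacell_map`s over the same cells with equal `k`.
#' @param convention `"replacements"` (default) or `"symmetric"`.
#' @return Fraction of changed edges.
#' @export
adjacency_difference <- function(map_a, map_b,
                                 convention = c("replacements", "symmetric")) {
  convention <- match.arg(convention)
  if (length(map_a$members) != length(map_b$members) ||
      !identical(map_a$cell_ids, map_b$cell_ids))
    abort_validation("meta-cell maps are over different cell sets")
  if (map_a$k != map_b$k) abort_validation("meta-cell maps have different k")
  n <- length(map_a$members)
  lost <- 0L
  total <- 0L
  for (i in seq_len(n)) {
    ea <- setdiff(map_a$members[[i]], i)
    eb <- setdiff(map_b$members[[i]], i)
    lost <- lost + length(setdiff(ea, eb))
    total <- total + length(ea)
  }
  if (convention == "replacements") lost / total
  else min(1, 2 * lost / total)
}

#' Serialize a meta-cell map to TSV
#'
#' Two columns: `cell_id` and comma-joined member cell ids.
#'
#' @param map a `metacell_map`.
#' @param path output TSV.
#' @export
write_metacell_map <- function(map, path) {
  dt <- data.table(
    cell_id = map$cell_ids,
    members = vapply(map$members,
                     function(m) paste(map$cell_ids[m], collapse = ","), ""))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
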