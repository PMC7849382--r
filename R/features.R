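# Per (gene, meta-cell) features: binned promoter CpG-dinucleotide
# frequency (gene-dependent, cell-independent) and binned pooled CpG
# methylation rate (gene- and cell-dependent); plus the MPD baseline.

#' Binned promoter model for a gene
#'
#' Tiles the +/- `flank` promoter window with `2 * flank / bin_size`
#' half-open genomic bins and orders them 5' to 3' relative to the gene's
#' strand, so bin 1 is always the farthest-upstream bin and bin
#' `n_bins/2 + 1` is the first bin downstream of the TSS. Strand-aware
#' ordering is what lets a learner express asymmetric importance around
#' the TSS. Bins extending past the chromosome start are clipped and
#' flagged.
#'
#' @param gene one row of a TSS annotation (`gene_id`, `chrom`, `tss`,
#'   `strand`).
#' @param flank promoter half-width in bp (default 5000).
#' @param bin_size bin width in bp (default 500; must divide `2 * flank`).
#' @return A `promoter_model`: list with `gene_id`, `chrom`, `strand`,
#'   `bins` (data.frame `start0`, `end0`, 0-based half-open, in
#'   upstream-to-downstream order), `clipped` flags, `flank`, `bin_size`.
#' @export
build_promoter_model <- function(gene, flank = 5000L, bin_size = 500L) {
  flank <- as.integer(flank); bin_size <- as.integer(bin_size)
  if ((2L * flank) %% bin_size != 0L)
    abort_validation("bin_size must divide 2 * flank")
  n_bins <- (2L * flank) %/% bin_size
  t0 <- as.integer(gene$tss) - 1L               # 0-based TSS
  starts <- t0 - flank + bin_size * (seq_len(n_bins) - 1L)
  ends <- starts + bin_size
  clipped <- starts < 0L
  starts <- pmax(starts, 0L)
  ends <- pmax(ends, 0L)
  ord <- if (gene$strand == "-") rev(seq_len(n_bins)) else seq_len(n_bins)
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand,
                 bins = data.frame(start0 = starts[ord], end0 = ends[ord]),
                 clipped = clipped[ord],
                 flank = flank, bin_size = bin_size, n_bins = n_bins),
            class = "promoter_model")
}

# Start positions (1-based, position of the C) of all CG dinucleotides,
# per sequence. Case-insensitive; N never matches.
genome_cg_positions <- function(genome) {
  lapply(seq_along(genome), function(i)
    Biostrings::start(Biostrings::matchPattern("CG", genome[[i]],
                                               fixed = TRUE))) |>
    stats::setNames(names(genome))
}

#' Binned CpG-dinucleotide frequency of a promoter
#'
#' Counts forward-strand `CG` occurrences per bin and reports
#' `2 * count / width`: `CG` is its own reverse complement, so each
#' occurrence contributes one methylatable cytosine per strand. A `CG`
#' straddling a bin boundary is assigned to the bin containing its C.
#' Zero-width (fully clipped) bins report 0.
#'
#' @param model a `promoter_model`.
#' @param genome a [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param cg_pos optional precomputed CG positions from an internal cache;
#'   computed from `genome` when `NULL`.
#' @return Numeric vector of length `n_bins` in `[0, 1]`.
#' @export
cpg_frequency <- function(model, genome, cg_pos = NULL) {
  if (is.null(cg_pos)) {
    if (!model$chrom %in% names(genome))
      abort_validation("chromosome '%s' absent from genome", model$chrom)
    cg <- Biostrings::start(
      Biostrings::matchPattern("CG", genome[[model$chrom]], fixed = TRUE))
  } else {
    if (!model$chrom %in% names(cg_pos))
      abort_validation("chromosome '%s' absent from genome", model$chrom)
    cg <- cg_pos[[model$chrom]]
  }
  vapply(seq_len(model$n_bins), function(b) {
    s0 <- model$bins$start0[b]; e0 <- model$bins$end0[b]
    w <- e0 - s0
    if (w <= 0L) return(0)
    # a CG belongs to the bin containing its C (1-based position p is in
    # the 0-based half-open bin when s0 < p <= e0); a CG straddling a bin
    # boundary is therefore assigned to the upstream-of-boundary bin
    2 * sum(cg > s0 & cg <= e0) / w
  }, 0)
}

#' Pooled per-bin methylation rate for one gene and one meta-cell
#'
#' Pools the raw methylated / unmethylated counts of every member cell
#' within each promoter bin and returns the count-pooled rate
#' `sum(n_meth) / sum(n_meth + n_unmeth)` (not a mean of per-cell
#' ratios). Bins with no calls across the whole meta-cell are `NA` with
#' `mask = TRUE`; empty bins are a data condition, not an error.
#'
#' @param model a `promoter_model`.
#' @param members integer indices (into `calls`) of the meta-cell members.
#' @param calls list of [methylation_calls] for all cells.
#' @return List with `rate` (length `n_bins`, `NA` where masked) and
#'   `mask` (logical).
#' @export
metacell_methylation_rate <- function(model, members, calls) {
  if (!length(members)) abort_validation("empty meta-cell")
  nm <- nu <- numeric(model$n_bins)
  for (j in members) {
    cc <- calls[[j]]
    on <- which(cc$chrom == model$chrom)
    if (!length(on)) next
    p0 <- cc$pos[on] - 1L
    for (b in seq_len(model$n_bins)) {
      inb <- p0 >= model$bins$start0[b] & p0 < model$bins$end0[b]
      nm[b] <- nm[b] + sum(cc$n_meth[on][inb])
      nu[b] <- nu[b] + sum(cc$n_unmeth[on][inb])
    }
  }
  tot <- nm + nu
  mask <- tot == 0
  rate <- ifelse(mask, NA_real_, nm / pmax(tot, 1))
  list(rate = rate, mask = mask)
}

#' Mean promoter demethylation (MPD) baseline
#'
#' The fraction of unmethylated CpG calls among all CpG calls in the
#' +/- `flank` promoter window of a *single* cell (no meta-cell
#' pooling). The classical unsupervised gene-activity proxy; on genes
#' whose expression correlates positively with promoter methylation it
#' points the wrong way.
#'
#' @param gene one annotation row (`chrom`, `tss`).
#' @param calls a [methylation_calls] object for one cell.
#' @param flank promoter half-width (default 5000).
#' @return Scalar in `[0, 1]`, or `NA` when the window has no calls.
#' @export
mpd <- function(gene, calls, flank = 5000L) {
  w <- calls$chrom == gene$chrom &
    calls$pos >= gene$tss - flank & calls$pos <= gene$tss + flank
  tot <- sum(calls$n_meth[w] + calls$n_unmeth[w])
  if (tot == 0) return(NA_real_)
  sum(calls$n_unmeth[w]) / tot
}

#' MPD gene-activity matrix over all genes and cells
#'
#' Per-cell promoter demethylation ratios; promoters without calls in a
#' cell are imputed with that cell's mean MPD across covered promoters.
#'
#' @param calls named list of [methylation_calls].
#' @param tss TSS annotation `data.frame`.
#' @param flank promoter half-width (default 5000).
#' @return genes x cells matrix in `[0, 1]`.
#' @export
mpd_matrix <- function(calls, tss, flank = 5000L) {
  cnt <- promoter_call_counts(calls, tss, flank)
  vals <- ifelse(cnt$tot == 0, NA_real_,
                 (cnt$tot - cnt$meth) / pmax(cnt$tot, 1))
  means <- colMeans(vals, na.rm = TRUE)
  for (j in seq_len(ncol(vals)))
    vals[is.na(vals[, j]), j] <- means[j]
  vals
}

feature_names <- function(n_bins = 20L) {
  c(sprintf("cpg_%02d", seq_len(n_bins)), sprintf("mr_%02d", seq_len(n_bins)))
}

#' Assemble the feature tensor over gene/meta-cell pairs
#'
#' One row per (gene, cell) pair, ordered gene-major; 2 * `n_bins`
#' columns in fixed order: CpG-frequency bins 1..n then methylation-rate
#' bins 1..n, both upstream-to-downstream. Methylation rates are pooled
#' over the cell's meta-cell members. Masked (zero-call) rate bins are
#' imputed with the meta-cell's mean rate over that gene's covered bins,
#' falling back to the meta-cell's mean over all genes, then the dataset
#' mean.
#'
#' @param tss TSS annotation `data.frame`.
#' @param metacells a `metacell_map` over the cells of `calls`.
#' @param calls named list of [methylation_calls].
#' @param genome [Biostrings::DNAStringSet].
#' @param gene_subset,cell_subset optional character id vectors.
#' @param flank,bin_size promoter geometry (defaults 5000 / 500).
#' @return A `feature_tensor`: list with `pairs` (data.table `gene_id`,
#'   `cell_id`), `cpg_ratio`, `meth_rate` (pairs x n_bins matrices),
#'   `meth_mask` (pre-imputation missingness), `n_bins`.
#' @export
assemble_features <- function(tss, metacells, calls, genome,
                              gene_subset = NULL, cell_subset = NULL,
                              flank = 5000L, bin_size = 500L) {
  cells_all <- names(calls)
  if (is.null(gene_subset)) gene_subset <- tss$gene_id
  if (is.null(cell_subset)) cell_subset <- metacells$cell_ids
  if (!all(gene_subset %in% tss$gene_id))
    abort_validation("unknown gene id(s): %s",
                     paste(head(setdiff(gene_subset, tss$gene_id), 3),
                           collapse = ", "))
  if (!all(cell_subset %in% metacells$cell_ids) ||
      !all(metacells$cell_ids %in% cells_all))
    abort_validation("cell ids of meta-cell map and calls do not match")

  tss <- tss[match(gene_subset, tss$gene_id), , drop = FALSE]
  n_genes <- nrow(tss)
  models <- lapply(seq_len(n_genes), function(i)
    build_promoter_model(tss[i, ], flank = flank, bin_size = bin_size))
  n_bins <- models[[1L]]$n_bins

  # --- CpG frequency (cell-independent), one row per gene -------------
  cg_pos <- genome_cg_positions(genome)
  cpg <- t(vapply(models, cpg_frequency, numeric(n_bins),
                  genome = genome, cg_pos = cg_pos))

  # --- binned call counts per (gene, genomic bin, cell) ---------------
  # bins in genomic-ascending order for the overlap join; re-oriented to
  # strand order afterwards.
  bin_tab <- rbindlist(lapply(seq_len(n_genes), function(i) {
    m <- models[[i]]
    g_ord <- order(m$bins$start0)      # genomic-ascending
    data.table(gene = i, bin = g_ord,  # bin = strand-oriented index
               chrom = m$chrom,
               start = m$bins$start0[g_ord] + 1L,  # 1-based inclusive
               end = m$bins$end0[g_ord])
  }))
  bin_tab <- bin_tab[bin_tab$end >= bin_tab$start, ]
  bin_tab[, row_id := (gene - 1L) * n_bins + bin]
  setkey(bin_tab, chrom, start, end)

  n_cells_all <- length(cells_all)
  meth <- tot <- matrix(0, n_genes * n_bins, n_cells_all)
  for (j in seq_len(n_cells_all)) {
    cc <- as.data.table(calls[[j]])
    if (!nrow(cc)) next
    cc[, `:=`(start = pos, end = pos)]
    hits <- foverlaps(cc, bin_tab, type = "within", nomatch = NULL)
    if (!nrow(hits)) next
    agg <- hits[, .(m = sum(n_meth), t = sum(n_meth + n_unmeth)), by = row_id]
    meth[agg$row_id, j] <- agg$m
    tot[agg$row_id, j] <- agg$t
  }

  # --- meta-cell pooling as a matrix product --------------------------
  S <- matrix(0, n_cells_all, n_cells_all)
  for (i in seq_along(metacells$members))
    S[metacells$members[[i]], i] <- 1
  pool_m <- meth %*% S
  pool_t <- tot %*% S
  mask_gb <- pool_t == 0
  rate_gb <- ifelse(mask_gb, NA_real_, pool_m / pmax(pool_t, 1))

  # --- lay out as pairs x n_bins, gene-major, with imputation ---------
  cell_idx <- match(cell_subset, cells_all)
  n_cells <- length(cell_idx)
  n_pairs <- n_genes * n_cells
  mr <- matrix(NA_real_, n_pairs, n_bins)
  mk <- matrix(TRUE, n_pairs, n_bins)
  cell_mean <- colMeans(rate_gb, na.rm = TRUE)   # meta-cell global mean
  cell_mean[is.nan(cell_mean)] <- mean(rate_gb, na.rm = TRUE)
  for (gi in seq_len(n_genes)) {
    rows_gb <- (gi - 1L) * n_bins + seq_len(n_bins)
    r <- rate_gb[rows_gb, cell_idx, drop = FALSE]
    m <- mask_gb[rows_gb, cell_idx, drop = FALSE]
    gene_mean <- colMeans(r, na.rm = TRUE)
    fill <- ifelse(is.nan(gene_mean), cell_mean[cell_idx], gene_mean)
    for (cj in seq_len(n_cells)) {
      v <- r[, cj]
      v[m[, cj]] <- fill[cj]
      mr[(gi - 1L) * n_cells + cj, ] <- v
      mk[(gi - 1L) * n_cells + cj, ] <- m[, cj]
    }
  }
  pairs <- data.table(gene_id = rep(gene_subset, each = n_cells),
                      cell_id = rep(cell_subset, times = n_genes))
  cpg_pairs <- cpg[rep(seq_len(n_genes), each = n_cells), , drop = FALSE]
  structure(list(pairs = pairs, cpg_ratio = cpg_pairs, meth_rate = mr,
                 meth_mask = mk, n_bins = n_bins,
                 flank = as.integer(flank), bin_size = as.integer(bin_size)),
            class = "feature_tensor")
}

#' @exportS3Method base::print
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %d gene-cell pairs x %d features (%.1f%% rate bins observed)\n",
              nrow(x$pairs), 2L * x$n_bins, 100 * mean(!x$meth_mask)))
  invisible(x)
}

#' Feature tensor as a modelling matrix
#'
#' @param x a `feature_tensor`.
#' @param ... unused.
#' @return pairs x (2 * n_bins) matrix, columns `cpg_01..cpg_n, mr_01..mr_n`.
#' @exportS3Method base::as.matrix
as.matrix.feature_tensor <- function(x, ...) {
  m <- cbind(x$cpg_ratio, x$meth_rate)
  colnames(m) <- feature_names(x$n_bins)
  m
}

#' Serialize a feature tensor to TSV
#'
#' @param x a `feature_tensor`.
#' @param path output TSV.
#' @param masks also write `mask_01..mask_n` columns.
#' @export
write_feature_tensor <- function(x, path, masks = FALSE) {
  dt <- cbind(x$pairs, as.data.table(as.matrix(x)))
  if (masks) {
    mk <- as.data.table(x$meth_mask)
    setnames(mk, sprintf("mask_%02d", seq_len(x$n_bins)))
    dt <- cbind(dt, mk)
  }
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
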