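# Shared fixtures, all built in code.

# A methylation_calls object from a compact record spec:
# list(c(pos, n_meth, n_unmeth), ...) on one chromosome.
mk_calls <- function(cell_id, recs, chrom = "chr1") {
  if (!length(recs))
    return(methylation_calls(cell_id))
  m <- do.call(rbind, recs)
  methylation_calls(cell_id, chrom = rep(chrom, nrow(m)), pos = m[, 1],
                    n_meth = m[, 2], n_unmeth = m[, 3])
}

mk_tss <- function(gene_id, chrom = "chr1", tss = 10001L, strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
             strand = strand, stringsAsFactors = FALSE)
}

# DNAStringSet from plain strings.
mk_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# Hand-built metacell_map.
mk_metacells <- function(members, cell_ids = NULL, k = NULL) {
  structure(list(members = members,
                 k = k %||% (length(members[[1]]) - 1L),
                 include_self = TRUE,
                 cell_ids = cell_ids %||%
                   as.character(seq_along(members))),
            class = "metacell_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small simulated dataset shared across test files (computed once per
# test run).
shared_sim_env <- new.env()
small_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    cfg <- sim_config(n_genes = 40L, n_cells = 50L, seed = 42L,
                      genes_per_chrom = 20L)
    shared_sim_env$sim <- simulate_dataset(cfg)
  }
  shared_sim_env$sim
}

# Feature pipeline over the shared sim (computed once).
small_features <- function() {
  if (is.null(shared_sim_env$feats)) {
    sim <- small_sim()
    shared_sim_env$feats <- build_features(
      sim$calls, sim$tss, sim$genome,
      run_config(knn_k = 8L, pca_d = 10L))
  }
  shared_sim_env$feats
}
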