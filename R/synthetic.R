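# Synthetic multi-omics generator: a small genome with CpG-structured
# promoters, sparse per-cell methylomes with cell-type structure and a
# planted methylation->expression coupling, and matched expression counts.
# The generator writes the truth (gene class, coupling sign/strength,
# context, signal bins, cell types) alongside the data so that every
# pipeline stage can be verified without external downloads.

#' Simulation configuration
#'
#' Defaults describe a desk-scale analogue of a joint single-cell
#' methylome+transcriptome experiment: ~5% of CpG sites observed per
#' cell at 1-3x depth, two cell subpopulations, and a mixture of
#' negative-coupled, positive-coupled and uncoupled genes across CpG
#' island / shore / shelf / open-sea promoter contexts. Coupling is
#' carried by the two bins immediately downstream of the TSS, and
#' positive-coupled genes are given a distinctively CpG-poor open-sea
#' promoter profile so the coupling sign is learnable from sequence.
#'
#' @param n_genes,n_cells,n_cell_types population sizes (300 / 300 / 2).
#' @param coverage_rate fraction of CpG sites observed per cell (0.05).
#' @param gene_classes proportions of negative / positive / uncoupled
#'   genes (must sum to 1).
#' @param cpg_context_mix proportions of island / shore / shelf /
#'   open-sea promoter profiles among non-positive genes.
#' @param coupling_strength log-scale effect sizes for the two coupled
#'   classes.
#' @param expression_noise negative-binomial size (smaller = noisier).
#' @param type_effect_sd SD of the per-type promoter methylation shift.
#' @param cell_signal_range half-range of the per-cell signal-bin shift.
#' @param flank,bin_size promoter geometry (5000 / 500).
#' @param genes_per_chrom,tss_spacing genome layout; spacing keeps
#'   promoters (and their flanking islands) from interfering.
#' @param seed master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 300L, n_cells = 300L, n_cell_types = 2L,
                       coverage_rate = 0.05,
                       gene_classes = c(negative = 0.4, positive = 0.3,
                                        uncoupled = 0.3),
                       cpg_context_mix = c(island = 0.25, shore = 0.15,
                                           shelf = 0.1, open_sea = 0.5),
                       coupling_strength = c(negative = 2, positive = 2),
                       expression_noise = 2,
                       type_effect_sd = 0.15, cell_signal_range = 0.35,
                       flank = 5000L, bin_size = 500L,
                       genes_per_chrom = 50L, tss_spacing = 20000L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_cell_types = as.integer(n_cell_types),
              coverage_rate = coverage_rate, gene_classes = gene_classes,
              cpg_context_mix = cpg_context_mix,
              coupling_strength = coupling_strength,
              expression_noise = expression_noise,
              type_effect_sd = type_effect_sd,
              cell_signal_range = cell_signal_range,
              flank = as.integer(flank), bin_size = as.integer(bin_size),
              genes_per_chrom = as.integer(genes_per_chrom),
              tss_spacing = as.integer(tss_spacing),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) abort_validation("n_genes must be >= 1")
  if (abs(sum(gene_classes) - 1) > 1e-8 ||
      abs(sum(cpg_context_mix) - 1) > 1e-8)
    abort_validation("class and context proportions must each sum to 1")
  if (coverage_rate <= 0 || coverage_rate > 1)
    abort_validation("coverage_rate must be in (0, 1]")
  structure(cfg, class = "sim_config")
}

# per-bin CG density (dinucleotides per bp) by context, in oriented bin
# order; positive-coupled genes get the sparse open-sea profile.
context_density_profile <- function(context, positive, n_bins) {
  prof <- rep(switch(context, island = 0.01, shore = 0.02, shelf = 0.015,
                     open_sea = if (positive) 0.004 else 0.012), n_bins)
  if (context == "island") {
    mid <- n_bins %/% 2L
    prof[(mid - 1L):(mid + 2L)] <- 0.06   # central +/- 1 kb
    prof[c(mid - 3L, mid - 2L, mid + 3L, mid + 4L)] <- 0.03
  }
  prof
}

context_strength_factor <- c(island = 0.3, shore = 0.6, shelf = 0.8,
                             open_sea = 1.0)

#' Simulate a genome with CpG-structured promoters
#'
#' Builds one chromosome per `genes_per_chrom` genes on a CG-free random
#' background and plants CG dinucleotides at context-specific densities
#' inside each promoter, so the set of CpG sites is known exactly.
#' Island-context genes get an annotated island covering TSS +/- 1 kb;
#' shore / shelf genes get an island planted 0.5 kb / 2.5 kb past the
#' promoter edge. TSS spacing guarantees promoters (and their islands,
#' padded by 4 kb) never interfere.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to a stream derived from the config
#'   seed).
#' @return List with `genome` ([Biostrings::DNAStringSet]), `tss`
#'   annotation, `islands` (1-based intervals), `gene_truth`
#'   (class/context/sign/strength/signal bins) and `sites` (per-gene CpG
#'   positions, 1-based position of the C).
#' @export
simulate_genome <- function(config, seed = derive_seed(config$seed, 1L)) {
  cfg <- config
  n_bins <- (2L * cfg$flank) %/% cfg$bin_size
  with_seed(seed, {
    classes <- sample(names(cfg$gene_classes), cfg$n_genes, replace = TRUE,
                      prob = cfg$gene_classes)
    contexts <- ifelse(
      classes == "positive", "open_sea",
      sample(names(cfg$cpg_context_mix), cfg$n_genes, replace = TRUE,
             prob = cfg$cpg_context_mix))
    strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

    n_chrom <- ceiling(cfg$n_genes / cfg$genes_per_chrom)
    chrom_of <- rep(seq_len(n_chrom), each = cfg$genes_per_chrom)[
      seq_len(cfg$n_genes)]
    idx_on <- stats::ave(seq_len(cfg$n_genes), chrom_of, FUN = seq_along)
    tss <- 6000L + (idx_on - 1L) * cfg$tss_spacing
    chrom_names <- paste0("chrS", seq_len(n_chrom))

    chrom_len <- vapply(seq_len(n_chrom), function(ch)
      max(tss[chrom_of == ch]) + cfg$flank + 5000L, 0L)

    seqs <- character(n_chrom)
    sites <- vector("list", cfg$n_genes)
    islands <- list()
    for (ch in seq_len(n_chrom)) {
      len <- chrom_len[ch]
      base <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                     prob = c(0.3, 0.2, 0.2, 0.3))
      s <- paste(base, collapse = "")
      s <- gsub("CG", "CA", s, fixed = TRUE)   # CG-free background
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      plant <- function(start0, end0, density) {
        n_cg <- round(density * (end0 - start0))
        if (n_cg < 1L) return(integer())
        cand <- seq(start0 + 1L, end0 - 1L, by = 2L)   # 1-based C positions
        p <- sort(sample(cand, min(n_cg, length(cand))))
        chars[p] <<- "C"
        chars[p + 1L] <<- "G"
        p
      }
      for (g in which(chrom_of == ch)) {
        model <- build_promoter_model(
          list(gene_id = g, chrom = chrom_names[ch], tss = tss[g],
               strand = strands[g]),
          flank = cfg$flank, bin_size = cfg$bin_size)
        prof <- context_density_profile(contexts[g],
                                        classes[g] == "positive", n_bins)
        gene_sites <- integer()
        for (b in seq_len(n_bins))
          gene_sites <- c(gene_sites,
                          plant(model$bins$start0[b], model$bins$end0[b],
                                prof[b]))
        sites[[g]] <- sort(gene_sites)
        if (contexts[g] == "island") {
          islands[[length(islands) + 1L]] <-
            data.frame(chrom = chrom_names[ch], start = tss[g] - 1000L,
                       end = tss[g] + 1000L)
        } else if (contexts[g] %in% c("shore", "shelf")) {
          off <- if (contexts[g] == "shore") 500L else 2500L
          i_start <- tss[g] + cfg$flank + off
          plant(i_start - 1L, i_start + 999L, 0.06)
          islands[[length(islands) + 1L]] <-
            data.frame(chrom = chrom_names[ch], start = i_start,
                       end = i_start + 1000L)
        }
      }
      seqs[ch] <- paste(chars, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chrom_names

    mid <- n_bins %/% 2L
    signal_bins <- c(mid + 1L, mid + 2L)   # immediately downstream of TSS
    sign <- ifelse(classes == "negative", -1L,
                   ifelse(classes == "positive", 1L, 0L))
    strength <- ifelse(
      classes == "uncoupled", 0,
      unname(cfg$coupling_strength[classes]) *
        unname(context_strength_factor[contexts]))
    gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
    list(
      genome = genome,
      tss = data.frame(gene_id = gene_ids, chrom = chrom_names[chrom_of],
                       tss = tss, strand = strands,
                       stringsAsFactors = FALSE),
      islands = if (length(islands)) do.call(rbind, islands)
                else data.frame(chrom = character(), start = integer(),
                                end = integer()),
      gene_truth = data.frame(
        gene_id = gene_ids, class = classes, context = contexts,
        sign = sign, strength = strength,
        signal_bins = paste(signal_bins, collapse = ","),
        n_sites = lengths(sites), stringsAsFactors = FALSE),
      sites = stats::setNames(sites, gene_ids),
      n_bins = n_bins, signal_bins = signal_bins)
  })
}

#' Simulate sparse per-cell methylomes
#'
#' Each cell type carries a latent per-gene, per-bin methylation
#' probability profile (gene baseline + per-bin jitter + type shift).
#' Cells additionally carry a continuous two-axis latent state,
#' expressed in the methylome through the two signal bins downstream of
#' the TSS (one axis per bin, gene-dependent amplitude and sign); the
#' mean signal-bin methylation later drives expression. Each CpG site
#' is
#' observed per cell with probability `coverage_rate` at a uniform
#' 1-3 read depth, with methylated counts binomial around the site's
#' latent probability.
#'
#' @param config a [sim_config()].
#' @param genome_art result of [simulate_genome()].
#' @param seed RNG seed.
#' @return List with `calls` (named list of [methylation_calls]),
#'   `cell_types`, `latent_bin` (genes x cells x bins array of latent
#'   probabilities) and `latent_driver` (genes x cells matrix: mean
#'   latent methylation of the signal bins).
#' @export
simulate_methylomes <- function(config, genome_art,
                                seed = derive_seed(config$seed, 2L)) {
  cfg <- config
  ga <- genome_art
  n_bins <- ga$n_bins
  n_g <- cfg$n_genes
  n_c <- cfg$n_cells
  with_seed(seed, {
    cell_types <- sample(rep_len(seq_len(cfg$n_cell_types), n_c))
    base_g <- runif(n_g, 0.25, 0.75)
    jit <- matrix(rnorm(n_g * n_bins, 0, 0.05), n_g, n_bins)
    delta <- matrix(rnorm(cfg$n_cell_types * n_g, 0, cfg$type_effect_sd),
                    cfg$n_cell_types, n_g)
    # The signal must be coherent across a cell's k-NN neighbourhood or
    # meta-cell pooling would (correctly) average it away: cells carry a
    # continuous 2-D latent state, expressed in the methylome by the two
    # downstream signal bins, one state axis per bin so the planted
    # signal is attributable bin by bin. Per-gene amplitudes and signs
    # make the response gene-dependent.
    state <- matrix(runif(2L * n_c, -1, 1), 2L, n_c)
    amp <- matrix(runif(n_g * 2L, 0.5, 1) *
                    sample(c(-1, 1), n_g * 2L, replace = TRUE),
                  n_g, 2L) * cfg$cell_signal_range
    u <- lapply(seq_along(ga$signal_bins), function(a)
      amp[, a] %o% state[a, ])
    names(u) <- as.character(ga$signal_bins)

    latent <- array(0, c(n_g, n_c, n_bins))
    for (b in seq_len(n_bins)) {
      m <- base_g + jit[, b] + t(delta)[, cell_types, drop = FALSE]
      if (b %in% ga$signal_bins) m <- m + u[[as.character(b)]]
      latent[, , b] <- pmin(pmax(m, 0.02), 0.98)
    }
    driver <- (latent[, , ga$signal_bins[1L]] +
                 latent[, , ga$signal_bins[2L]]) / 2

    cell_ids <- sprintf("cell%03d", seq_len(n_c))
    # oriented bin index of each site, per gene
    recs <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      pos <- ga$sites[[g]]
      if (!length(pos)) next
      model <- build_promoter_model(ga$tss[g, ], flank = cfg$flank,
                                    bin_size = cfg$bin_size)
      g_ord <- order(model$bins$start0)
      bin_of <- g_ord[findInterval(pos - 1L, model$bins$start0[g_ord])]
      n_s <- length(pos)
      obs <- matrix(runif(n_s * n_c) < cfg$coverage_rate, n_s, n_c)
      oi <- which(obs, arr.ind = TRUE)
      if (!nrow(oi)) next
      depth <- sample(3L, nrow(oi), replace = TRUE)
      pr <- latent[cbind(g, oi[, 2L], bin_of[oi[, 1L]])]
      nm <- rbinom(nrow(oi), depth, pr)
      recs[[g]] <- data.table(cell = oi[, 2L], chrom = ga$tss$chrom[g],
                              pos = pos[oi[, 1L]], n_meth = nm,
                              n_unmeth = depth - nm)
    }
    all_rec <- rbindlist(recs)
    calls <- lapply(seq_len(n_c), function(j) {
      cc <- all_rec[cell == j][order(chrom, pos)]
      methylation_calls(cell_ids[j], chrom = cc$chrom, pos = cc$pos,
                        n_meth = cc$n_meth, n_unmeth = cc$n_unmeth)
    })
    names(calls) <- cell_ids
    dimnames(latent) <- list(ga$tss$gene_id, cell_ids, NULL)
    dimnames(driver) <- list(ga$tss$gene_id, cell_ids)
    list(calls = calls,
         cell_types = stats::setNames(cell_types, cell_ids),
         latent_bin = latent, latent_driver = driver)
  })
}

#' Simulate expression counts coupled to latent methylation
#'
#' Gene g in cell c has latent log activity
#' `alpha_g + sign_g * strength_g * (M_gc - 0.5)` where `M_gc` is the
#' latent signal-bin methylation (not the sparse observed calls:
#' sparsity is observation noise, not signal); counts are negative
#' binomial around the exponentiated activity. Uncoupled genes ignore
#' methylation. Baselines `alpha_g` receive a mild context offset
#' (island promoters are more expressed), which is learnable from
#' sequence but invisible to the MPD baseline.
#'
#' @param config a [sim_config()].
#' @param genome_art result of [simulate_genome()].
#' @param methylomes result of [simulate_methylomes()].
#' @param seed RNG seed.
#' @return List with `counts` (genes x cells integer matrix) and
#'   `alpha` (per-gene baselines).
#' @export
simulate_expression <- function(config, genome_art, methylomes,
                                seed = derive_seed(config$seed, 3L)) {
  cfg <- config
  gt <- genome_art$gene_truth
  M <- methylomes$latent_driver
  with_seed(seed, {
    ctx_off <- c(island = 0.7, shore = 0.3, shelf = 0, open_sea = 0)
    alpha <- 1.5 + unname(ctx_off[gt$context]) + rnorm(nrow(gt), 0, 0.5)
    mu <- exp(alpha + gt$sign * gt$strength * (M - 0.5))
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = cfg$expression_noise),
                     nrow(mu), ncol(mu), dimnames = dimnames(M))
    list(counts = counts, alpha = alpha)
  })
}

#' Simulate a complete matched methylome+transcriptome dataset
#'
#' Runs [simulate_genome()], [simulate_methylomes()] and
#' [simulate_expression()] on seed streams derived from `seed`. Pass a
#' previous result's `genome_art` to generate an independent dataset
#' (new cells, new expression) over the same genome -- the external
#' cross-validation setting, where the trained model must transfer.
#'
#' @param config a [sim_config()].
#' @param genome_art optional pre-built genome artifacts to reuse.
#' @param seed master seed (defaults to `config$seed`).
#' @return List with `genome_art`, `methylomes`, `expression`, plus
#'   convenience handles `calls`, `counts`, `tss`, `islands`, `genome`.
#' @export
simulate_dataset <- function(config = sim_config(), genome_art = NULL,
                             seed = config$seed) {
  if (is.null(genome_art))
    genome_art <- simulate_genome(config, seed = derive_seed(seed, 1L))
  meth <- simulate_methylomes(config, genome_art,
                              seed = derive_seed(seed, 2L))
  expr <- simulate_expression(config, genome_art, meth,
                              seed = derive_seed(seed, 3L))
  list(genome_art = genome_art, methylomes = meth, expression = expr,
       calls = meth$calls, counts = expr$counts, tss = genome_art$tss,
       islands = genome_art$islands, genome = genome_art$genome,
       config = config, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.bed` (BED6), `islands.bed`, per-cell
#' gzipped COV files with a `manifest.tsv`, `counts.tsv`,
#' `gene_truth.tsv`, `cell_types.tsv` and `config.json`.
#'
#' @param sim result of [simulate_dataset()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  tss <- sim$tss
  bed <- data.table(tss$chrom,
                    ifelse(tss$strand == "+", tss$tss - 1L, tss$tss - 1L),
                    ifelse(tss$strand == "+", tss$tss, tss$tss),
                    tss$gene_id, 0L, tss$strand)
  fwrite(bed, file.path(outdir, "genes.bed"), sep = "\t",
         col.names = FALSE)
  isl <- sim$islands
  fwrite(data.table(isl$chrom, isl$start - 1L, isl$end),
         file.path(outdir, "islands.bed"), sep = "\t", col.names = FALSE)
  cov_dir <- file.path(outdir, "cov")
  dir.create(cov_dir, showWarnings = FALSE)
  man <- data.table(cell_id = names(sim$calls),
                    path = file.path("cov", paste0(names(sim$calls),
                                                   ".cov.gz")))
  for (cid in names(sim$calls))
    write_bismark_cov(sim$calls[[cid]],
                      file.path(cov_dir, paste0(cid, ".cov.gz")))
  fwrite(man, file.path(outdir, "manifest.tsv"), sep = "\t")
  cnt <- data.table(gene_id = rownames(sim$counts))
  fwrite(cbind(cnt, as.data.table(sim$counts)),
         file.path(outdir, "counts.tsv"), sep = "\t")
  fwrite(as.data.table(sim$genome_art$gene_truth),
         file.path(outdir, "gene_truth.tsv"), sep = "\t")
  fwrite(data.table(cell_id = names(sim$methylomes$cell_types),
                    cell_type = sim$methylomes$cell_types),
         file.path(outdir, "cell_types.tsv"), sep = "\t")
  jsonlite::write_json(unclass(sim$config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
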