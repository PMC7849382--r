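test_that("promoter model tiles the window and orients by strand", {
  g <- mk_tss("g1", tss = 10001L, strand = "+")
  m <- build_promoter_model(g[1, ])
  expect_identical(m$n_bins, 20L)
  expect_true(all(m$bins$end0 - m$bins$start0 == 500L))
  expect_equal(m$bins$start0[1], 5000)
  expect_equal(m$bins$end0[1], 5500)
  expect_equal(m$bins$end0[20], 15000)
  # bins tile the window exactly, no gaps
  ord <- order(m$bins$start0)
  expect_identical(m$bins$start0[ord][-1], m$bins$end0[ord][-20])
  gm <- mk_tss("g1", tss = 10001L, strand = "-")
  mm <- build_promoter_model(gm[1, ])
  expect_equal(mm$bins$start0[1], 14500)   # bin 1 = farthest upstream
  expect_equal(mm$bins$end0[1], 15000)
  # clipping at chromosome start
  gc <- mk_tss("g1", tss = 1001L, strand = "+")
  mc <- build_promoter_model(gc[1, ])
  expect_true(any(mc$clipped))
  expect_true(all(mc$bins$start0 >= 0))
  expect_error(build_promoter_model(g[1, ], flank = 5000, bin_size = 333),
               "divide")
})

test_that("cpg_frequency counts CG dinucleotides per bin", {
  # 2000 bp chromosome; gene at tss 1001 with flank 1000, bin 500
  allA <- paste(rep("A", 2000), collapse = "")
  cg_sat <- paste(rep("CG", 1000), collapse = "")
  g <- mk_tss("g1", chrom = "s1", tss = 1001L, strand = "+")
  m <- build_promoter_model(g[1, ], flank = 1000L, bin_size = 500L)
  expect_equal(cpg_frequency(m, mk_genome(s1 = allA)), rep(0, 4))
  expect_equal(cpg_frequency(m, mk_genome(s1 = cg_sat)), rep(1, 4))
  # random sequence vs a regex oracle on each bin's substring
  set.seed(20)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 2000, TRUE), collapse = "")
  freq <- cpg_frequency(m, mk_genome(s1 = seq))
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  oracle <- vapply(seq_len(4), function(b)
    2 * sum(hits > m$bins$start0[b] & hits <= m$bins$end0[b]) / 500, 0)
  expect_equal(freq, oracle)
  # case-insensitive
  expect_equal(cpg_frequency(m, mk_genome(s1 = tolower(cg_sat))), rep(1, 4))
  expect_error(cpg_frequency(m, mk_genome(other = allA)), "absent")
})

test_that("a CG straddling a bin boundary belongs to the C's bin", {
  # place a single CG with C at the last base of bin 1
  chars <- rep("A", 2000)
  g <- mk_tss("g1", chrom = "s1", tss = 1001L, strand = "+")
  m <- build_promoter_model(g[1, ], flank = 1000L, bin_size = 500L)
  boundary_c <- m$bins$end0[1]              # 1-based position of last base
  chars[boundary_c] <- "C"; chars[boundary_c + 1] <- "G"
  freq <- cpg_frequency(m, mk_genome(s1 = paste(chars, collapse = "")))
  expect_equal(freq, c(2 / 500, 0, 0, 0))
})

test_that("metacell_methylation_rate pools counts, not ratios", {
  g <- mk_tss("g1", tss = 10001L)
  m <- build_promoter_model(g[1, ])
  # one member, (2 meth, 2 unmeth) in one bin -> 0.5
  calls <- list(mk_calls("c1", list(c(5100, 2, 2))))
  r <- metacell_methylation_rate(m, 1L, calls)
  expect_equal(r$rate[1], 0.5)
  expect_true(all(r$mask[-1]))
  # pooled (3,0) + (1,3): 4/7, not the mean of ratios 0.625
  calls2 <- list(mk_calls("c1", list(c(5100, 3, 0))),
                 mk_calls("c2", list(c(5200, 1, 3))))
  r2 <- metacell_methylation_rate(m, c(1L, 2L), calls2)
  expect_equal(r2$rate[1], 4 / 7)
  # two members with (3,0) and (0,3) -> 0.5
  calls3 <- list(mk_calls("c1", list(c(5100, 3, 0))),
                 mk_calls("c2", list(c(5499, 0, 3))))
  expect_equal(metacell_methylation_rate(m, c(1L, 2L), calls3)$rate[1], 0.5)
  expect_error(metacell_methylation_rate(m, integer(), calls), "empty")
})

test_that("mpd complements promoter methylation on identical calls", {
  g <- mk_tss("g1", tss = 10001L)
  expect_equal(mpd(g[1, ], mk_calls("c", list(c(6000, 5, 0)))), 0)
  expect_equal(mpd(g[1, ], mk_calls("c", list(c(6000, 0, 4)))), 1)
  expect_equal(mpd(g[1, ], mk_calls("c", list(c(6000, 3, 1)))), 0.25)
  expect_true(is.na(mpd(g[1, ], mk_calls("c", list(c(99999, 3, 1))))))
  # complement identity on random call sets
  set.seed(21)
  for (rep in 1:5) {
    recs <- lapply(seq_len(10), function(i)
      c(5000 + i * 700, sample(0:3, 1), sample(1:3, 1)))
    cc <- mk_calls("c", recs)
    meth_level <- sum(cc$n_meth) / sum(cc$n_meth + cc$n_unmeth)
    expect_equal(mpd(g[1, ], cc), 1 - meth_level)
  }
})

test_that("mpd_matrix imputes missing promoters with the cell mean", {
  tss <- rbind(mk_tss("g1", tss = 10001L), mk_tss("g2", tss = 30001L))
  calls <- list(c1 = mk_calls("c1", list(c(6000, 3, 1), c(26000, 0, 2))),
                c2 = mk_calls("c2", list(c(7000, 1, 1))))
  m <- mpd_matrix(calls, tss)
  expect_equal(m["g1", "c1"], 0.25)
  expect_equal(m["g2", "c1"], 1)
  expect_equal(m["g2", "c2"], 0.5)   # imputed with c2's mean MPD
})

test_that("assemble_features yields the 40-column layout with fixed order", {
  feats <- small_features()
  sim <- small_sim()
  X <- as.matrix(feats$tensor)
  expect_identical(ncol(X), 40L)
  expect_identical(colnames(X)[c(1, 20, 21, 40)],
                   c("cpg_01", "cpg_20", "mr_01", "mr_20"))
  expect_true(all(X >= 0 & X <= 1))
  expect_false(any(is.na(X)))
  # cpg block is identical across cells within a gene
  pr <- feats$tensor$pairs
  for (g in sim$tss$gene_id[c(1, 17)]) {
    rows <- which(pr$gene_id == g)
    expect_equal(apply(feats$tensor$cpg_ratio[rows, ], 2, sd),
                 rep(0, 20), ignore_attr = TRUE)
  }
  expect_error(
    assemble_features(sim$tss, feats$metacells, sim$calls, sim$genome,
                      gene_subset = "nope"),
    "unknown gene")
})

test_that("identical meta-cell membership gives identical rate blocks", {
  sim <- small_sim()
  mc <- small_features()$metacells
  mc2 <- mc
  mc2$members[[2]] <- mc2$members[[1]]     # force equal membership
  tensor <- assemble_features(sim$tss, mc2, sim$calls, sim$genome,
                              cell_subset = mc$cell_ids[1:4])
  pr <- tensor$pairs
  c1 <- mc$cell_ids[1]; c2 <- mc$cell_ids[2]
  r1 <- tensor$meth_rate[pr$cell_id == c1, ]
  r2 <- tensor$meth_rate[pr$cell_id == c2, ]
  expect_equal(r1, r2)
})

test_that("per-bin rates conserve pooled promoter counts", {
  sim <- small_sim()
  feats <- small_features()
  tensor <- feats$tensor
  mc <- feats$metacells
  pr <- tensor$pairs
  flank <- 5000L
  set.seed(22)
  for (it in 1:20) {
    gi <- sample(nrow(sim$tss), 1)
    ci <- sample(length(mc$members), 1)
    gene <- sim$tss[gi, ]
    members <- mc$members[[ci]]
    # oracle: pool all member calls in the promoter window
    nm <- nt <- 0
    for (j in members) {
      cc <- sim$calls[[j]]
      w <- cc$chrom == gene$chrom & cc$pos >= gene$tss - flank &
        cc$pos <= gene$tss + flank
      nm <- nm + sum(cc$n_meth[w])
      nt <- nt + sum(cc$n_meth[w] + cc$n_unmeth[w])
    }
    row <- which(pr$gene_id == gene$gene_id &
                   pr$cell_id == mc$cell_ids[ci])
    mask <- tensor$meth_mask[row, ]
    if (nt == 0) { expect_true(all(mask)); next }
    # per-bin totals from the same oracle pooling
    model <- build_promoter_model(gene)
    bin_tot <- bin_meth <- numeric(20)
    for (j in members) {
      cc <- sim$calls[[j]]
      on <- which(cc$chrom == gene$chrom)
      for (b in 1:20) {
        inb <- cc$pos[on] - 1 >= model$bins$start0[b] &
          cc$pos[on] - 1 < model$bins$end0[b]
        bin_tot[b] <- bin_tot[b] + sum((cc$n_meth + cc$n_unmeth)[on][inb])
        bin_meth[b] <- bin_meth[b] + sum(cc$n_meth[on][inb])
      }
    }
    rates <- tensor$meth_rate[row, ]
    expect_equal(rates[!mask], (bin_meth / pmax(bin_tot, 1))[!mask],
                 ignore_attr = TRUE)
    # count-weighted mean of unmasked bin rates == pooled promoter level
    expect_equal(sum(rates[!mask] * bin_tot[!mask]) / sum(bin_tot[!mask]),
                 nm / nt)
  }
})

test_that("reversing a gene's strand reverses its feature vectors", {
  sim <- small_sim()
  mc <- small_features()$metacells
  tss_fwd <- sim$tss
  tss_rev <- sim$tss
  g <- tss_fwd$gene_id[3]
  tss_rev$strand[3] <- setdiff(c("+", "-"), tss_fwd$strand[3])
  cells <- mc$cell_ids[1:3]
  t_f <- assemble_features(tss_fwd, mc, sim$calls, sim$genome,
                           gene_subset = g, cell_subset = cells)
  t_r <- assemble_features(tss_rev, mc, sim$calls, sim$genome,
                           gene_subset = g, cell_subset = cells)
  expect_equal(t_f$cpg_ratio[1, ], rev(t_r$cpg_ratio[1, ]))
  for (i in seq_along(cells)) {
    expect_equal(t_f$meth_rate[i, ], rev(t_r$meth_rate[i, ]))
    expect_equal(t_f$meth_mask[i, ], rev(t_r$meth_mask[i, ]))
  }
})

test_that("feature tensor serializes to TSV", {
  tensor <- small_features()$tensor
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tensor(tensor, path, masks = TRUE)
  dt <- data.table::fread(path, nrows = 5)
  expect_true(all(c("gene_id", "cell_id", "cpg_01", "mr_20", "mask_01")
                  %in% names(dt)))
})
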