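test_that("promoter methylation matrix matches hand-computed ratios", {
  tss <- rbind(mk_tss("g1", tss = 10001L), mk_tss("g2", tss = 30001L))
  # g1 window [5001, 15001]; g2 window [25001, 35001]
  calls <- list(
    c1 = mk_calls("c1", list(c(6000, 3, 1), c(14000, 0, 2),   # g1: 3/6
                             c(26000, 2, 0))),                # g2: 2/2
    c2 = mk_calls("c2", list(c(7000, 3, 1))))                 # g1: 0.75, g2 missing
  pmm <- compute_promoter_methylation_matrix(calls, tss)
  expect_equal(pmm$values["g1", "c1"], 3 / 6)
  expect_equal(pmm$values["g2", "c1"], 1)
  expect_equal(pmm$values["g1", "c2"], 0.75)
  # missing promoter imputed with the cell mean over covered promoters
  expect_true(pmm$missing_mask["g2", "c2"])
  expect_equal(pmm$values["g2", "c2"], 0.75)
  expect_false(any(is.na(pmm$values)))
  # a record just outside the window does not count
  calls$c1 <- mk_calls("c1", list(c(5000, 5, 0), c(6000, 3, 1),
                                  c(26000, 2, 0)))
  pmm2 <- compute_promoter_methylation_matrix(calls, tss)
  expect_equal(pmm2$values["g1", "c1"], 0.75)
  expect_error(
    compute_promoter_methylation_matrix(
      list(c1 = calls$c1, c2 = mk_calls("c2", list(c(99999, 1, 0)))), tss),
    "c2")
})

test_that("select_variable_promoters ranks by population variance", {
  m <- rbind(a = c(0.5, 0.5, 0.5),       # var 0
             b = c(0.2, 0.5, 0.8),
             c = c(0.0, 0.5, 1.0),
             d = c(0.4, 0.5, 0.6))
  popvar <- apply(m, 1, function(r) mean(r^2) - mean(r)^2)   # oracle
  expect_identical(select_variable_promoters(m, 2),
                   order(-popvar)[1:2])
  expect_identical(select_variable_promoters(m, 99),
                   order(-popvar, seq_len(4)))
  # constant row never selected ahead of positive-variance rows
  expect_false(1L %in% select_variable_promoters(m, 3))
  # ties break by ascending index
  m2 <- rbind(x = c(0, 1), y = c(0, 1), z = c(0.5, 0.5))
  expect_identical(select_variable_promoters(m2, 2), c(1L, 2L))
  expect_error(select_variable_promoters(m, 0))
})

test_that("PCA embedding preserves structure and fixes signs", {
  set.seed(10)
  vals <- matrix(runif(20 * 8), 20, 8)
  vals[, 5] <- vals[, 2]                         # duplicated cell
  colnames(vals) <- paste0("c", 1:8)
  emb <- compute_pca_embedding(vals, d = 3)
  expect_equal(emb[2, ], emb[5, ])
  # with all components, embedding distances equal centred-data distances
  emb_full <- compute_pca_embedding(vals, d = 8)
  xc <- scale(t(vals), scale = FALSE)
  expect_equal(as.matrix(dist(emb_full)), as.matrix(dist(xc)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # d = 1 on a rank-1 matrix: distances preserved exactly
  r1 <- outer(runif(6), runif(5))
  emb1 <- compute_pca_embedding(r1, d = 1)
  expect_equal(as.matrix(dist(emb1)),
               as.matrix(dist(scale(t(r1), scale = FALSE))),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(compute_pca_embedding(vals, d = 25), "exceeds")
  # deterministic sign: recomputation is identical
  expect_identical(compute_pca_embedding(vals, d = 3), emb)
})

test_that("build_metacells matches a brute-force k-NN oracle", {
  set.seed(11)
  emb <- matrix(rnorm(50 * 4), 50, 4)
  k <- 5L
  mc <- build_metacells(emb, k = k)
  expect_length(mc$members, 50L)
  for (i in seq_len(50)) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2))    # oracle distances
    ord <- order(d, seq_along(d))
    ord <- ord[ord != i]
    expect_identical(mc$members[[i]], sort(c(i, ord[1:k])))
    expect_true(i %in% mc$members[[i]])
    expect_length(mc$members[[i]], k + 1L)
  }
})

test_that("build_metacells tie rule, self-exclusion and errors", {
  emb <- matrix(c(0, 1, 2), ncol = 1)            # collinear, equal spacing
  mc <- build_metacells(emb, k = 1)
  expect_identical(mc$members[[2]], c(1L, 2L))   # tie -> smaller index
  mc2 <- build_metacells(emb, k = 1, include_self = FALSE)
  expect_identical(mc2$members[[2]], 1L)
  expect_error(build_metacells(emb, k = 3), "smaller k")
})

test_that("build_metacells is permutation-equivariant", {
  set.seed(12)
  emb <- matrix(rnorm(30 * 3), 30, 3)
  mc <- build_metacells(emb, k = 4)
  perm <- sample(30)
  mcp <- build_metacells(emb[perm, , drop = FALSE], k = 4)
  # row i of permuted embedding is original cell perm[i]
  inv <- match(seq_len(30), perm)
  for (i in seq_len(30))
    expect_identical(sort(perm[mcp$members[[inv[i]]]]), mc$members[[i]])
})

test_that("most neighbours share the cell type on separated populations", {
  sim <- small_sim()
  pmm <- compute_promoter_methylation_matrix(sim$calls, sim$tss)
  vp <- select_variable_promoters(pmm)
  emb <- compute_pca_embedding(pmm, vp, d = 10)
  mc <- build_metacells(emb, k = 8)
  types <- sim$methylomes$cell_types
  frac_same <- vapply(seq_along(mc$members), function(i) {
    nb <- setdiff(mc$members[[i]], i)
    mean(types[nb] == types[i])
  }, 0)
  expect_gte(mean(frac_same), 0.95)
})

test_that("adjacency_difference counts changed edges", {
  mems <- list(c(1L, 2L, 3L), c(1L, 2L, 3L), c(2L, 3L, 4L), c(1L, 3L, 4L))
  a <- mk_metacells(mems, k = 2L)
  expect_equal(adjacency_difference(a, a), 0)
  # fully disjoint neighbour sets (5 cells, k = 2) -> 1 either way
  a5 <- mk_metacells(list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(3L, 4L, 5L),
                          c(1L, 4L, 5L), c(1L, 2L, 5L)),
                     cell_ids = as.character(1:5), k = 2L)
  b5 <- mk_metacells(list(c(1L, 4L, 5L), c(1L, 2L, 5L), c(1L, 2L, 3L),
                          c(2L, 3L, 4L), c(3L, 4L, 5L)),
                     cell_ids = as.character(1:5), k = 2L)
  expect_equal(adjacency_difference(a5, b5), 1)
  expect_equal(adjacency_difference(a5, b5, convention = "symmetric"), 1)
  # one changed neighbour among 10 cells with k = 3 -> 1/30
  set.seed(13)
  emb <- matrix(rnorm(10 * 2), 10, 2)
  m1 <- build_metacells(emb, k = 3)
  m2 <- m1
  old <- m2$members[[1]]
  swap_out <- max(setdiff(old, 1L))
  swap_in <- setdiff(1:10, old)[1]
  m2$members[[1]] <- sort(c(setdiff(old, swap_out), swap_in))
  expect_equal(adjacency_difference(m1, m2), 1 / 30)
  expect_equal(adjacency_difference(m1, m2, convention = "symmetric"),
               2 / 30)
  bad <- m1; bad$cell_ids <- paste0("x", 1:10)
  expect_error(adjacency_difference(m1, bad), "different cell sets")
})

test_that("metacell map serializes to TSV", {
  mc <- mk_metacells(list(c(1L, 2L), c(1L, 2L)), cell_ids = c("a", "b"),
                     k = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metacell_map(mc, path)
  dt <- data.table::fread(path)
  expect_identical(dt$members, c("a,b", "a,b"))
})
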