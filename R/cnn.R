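# Minimal 1-D convolutional network for the binned promoter features:
# conv (filters x kernel, ReLU, 2 input channels) -> max-pool -> dropout
# -> dense ReLU -> linear scalar. Trained with Adam on MSE with early
# stopping on a held-out validation split. Pure matrix algebra, CPU-only,
# bit-reproducible for a fixed seed under single-threaded BLAS.

# Run code with a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

relu <- function(x) (x > 0) * x

cnn_arch <- function(n_bins, n_filters, kernel, pool, dense) {
  conv_out <- n_bins - kernel + 1L
  if (conv_out < 1L) abort_validation("kernel larger than number of bins")
  n_groups <- conv_out %/% pool
  if (n_groups < 1L) abort_validation("pool size larger than conv output")
  # im2col index: row j = output position, columns = kernel offsets for
  # channel 1 (cpg) then channel 2 (meth rate)
  idx <- cbind(
    outer(seq_len(conv_out), seq_len(kernel) - 1L, `+`),
    outer(seq_len(conv_out), seq_len(kernel) - 1L, `+`) + n_bins)
  list(n_bins = n_bins, n_filters = n_filters, kernel = kernel, pool = pool,
       dense = dense, conv_out = conv_out, n_groups = n_groups,
       im2col = idx, in_per_pos = 2L * kernel)
}

cnn_init <- function(arch) {
  he <- function(n_in, n_out)
    matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  flat <- arch$n_groups * arch$n_filters
  list(W1 = he(arch$in_per_pos, arch$n_filters),
       b1 = numeric(arch$n_filters),
       W2 = he(flat, arch$dense), b2 = numeric(arch$dense),
       W3 = he(arch$dense, 1L), b3 = 0)
}

# Forward pass; returns activations needed for backprop when cache = TRUE.
cnn_forward <- function(par, arch, X, drop_mask = NULL, cache = FALSE) {
  B <- nrow(X)
  Zc <- X[, as.vector(arch$im2col), drop = FALSE]
  dim(Zc) <- c(B * arch$conv_out, arch$in_per_pos)
  A1 <- Zc %*% par$W1
  A1 <- A1 + rep(par$b1, each = nrow(A1))
  H1 <- relu(A1)                                  # (B*conv_out) x filters
  # max-pool over `pool` consecutive positions
  G <- arch$n_groups
  Pm <- matrix(-Inf, B * G, arch$n_filters)
  win <- matrix(0L, B * G, arch$n_filters)        # winning position offset
  for (o in seq_len(arch$pool)) {
    j <- arch$pool * (rep(seq_len(G), each = B) - 1L) + o   # position index
    rows <- rep(seq_len(B), times = G) + B * (j - 1L)
    cand <- H1[rows, , drop = FALSE]
    better <- cand > Pm
    Pm[better] <- cand[better]
    win[better] <- o
  }
  Flat <- Pm
  dim(Flat) <- c(B, G * arch$n_filters)
  if (!is.null(drop_mask)) Flat <- Flat * drop_mask
  A2 <- Flat %*% par$W2
  A2 <- A2 + rep(par$b2, each = B)
  H2 <- relu(A2)
  out <- drop(H2 %*% par$W3) + par$b3
  if (!cache) return(out)
  list(out = out, Zc = Zc, H1 = H1, win = win, Flat = Flat, H2 = H2, B = B)
}

cnn_backward <- function(par, arch, fw, y, drop_mask) {
  B <- fw$B
  G <- arch$n_groups
  dout <- 2 * (fw$out - y) / B                    # d MSE / d out
  gW3 <- crossprod(fw$H2, dout)
  gb3 <- sum(dout)
  dH2 <- outer(dout, drop(par$W3)) * (fw$H2 > 0)
  gW2 <- crossprod(fw$Flat, dH2)
  gb2 <- colSums(dH2)
  dFlat <- tcrossprod(dH2, par$W2)
  if (!is.null(drop_mask)) dFlat <- dFlat * drop_mask
  dPm <- dFlat
  dim(dPm) <- c(B * G, arch$n_filters)
  # route pooled gradients back to winning conv positions
  dH1 <- matrix(0, B * arch$conv_out, arch$n_filters)
  base_rows <- rep(seq_len(B), times = G)
  grp <- rep(seq_len(G), each = B)
  for (o in seq_len(arch$pool)) {
    sel <- fw$win == o
    if (!any(sel)) next
    j <- arch$pool * (grp - 1L) + o
    target <- base_rows + B * (j - 1L)
    selw <- which(sel)
    src <- ((selw - 1L) %% (B * G)) + 1L
    colw <- ((selw - 1L) %/% (B * G)) + 1L
    dH1[cbind(target[src], colw)] <- dPm[selw]
  }
  dA1 <- dH1 * (fw$H1 > 0)
  gW1 <- crossprod(fw$Zc, dA1)
  gb1 <- colSums(dA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

adam_step <- function(state, par, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, par = par)
}

cnn_fit <- function(X, y, n_bins, n_filters = 50L, kernel = 5L, pool = 4L,
                    dropout = 0.2, patience = 10L, dense = 64L,
                    lr = 5e-3, batch_size = 128L, max_epochs = 150L,
                    val_frac = 0.1, seed = 1L, verbose = FALSE) {
  arch <- cnn_arch(n_bins, n_filters, kernel, pool, dense)
  n <- nrow(X)
  with_seed(seed, {
    par <- cnn_init(arch)
    n_val <- max(1L, round(val_frac * n))
    if (n_val >= n) abort_validation("too few samples for a validation split")
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
    ntr <- length(tr_idx)
    state <- list(m = lapply(par, function(w) w * 0),
                  v = lapply(par, function(w) w * 0))
    best <- list(par = par, mse = Inf, epoch = 0L)
    t_adam <- 0L
    epochs_no_improve <- 0L
    keep <- 1 - dropout
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(ntr)
      for (b0 in seq(1L, ntr, by = batch_size)) {
        bi <- perm[b0:min(b0 + batch_size - 1L, ntr)]
        Xb <- Xtr[bi, , drop = FALSE]
        drop_mask <- if (dropout > 0)
          matrix(rbinom(length(bi) * arch$n_groups * arch$n_filters, 1L,
                        keep) / keep,
                 length(bi), arch$n_groups * arch$n_filters)
        fw <- cnn_forward(par, arch, Xb, drop_mask, cache = TRUE)
        if (!all(is.finite(fw$out)))
          stop("non-finite CNN output during training (epoch ", epoch, ")")
        grad <- cnn_backward(par, arch, fw, ytr[bi], drop_mask)
        t_adam <- t_adam + 1L
        upd <- adam_step(state, par, grad, lr, t_adam)
        state <- upd$state; par <- upd$par
      }
      val_pred <- cnn_forward(par, arch, Xval)
      val_mse <- mean((val_pred - yval)^2)
      if (!is.finite(val_mse))
        stop("non-finite validation loss at epoch ", epoch)
      if (verbose)
        message(sprintf("epoch %d: val MSE %.6f", epoch, val_mse))
      if (val_mse < best$mse - 1e-9) {
        best <- list(par = par, mse = val_mse, epoch = epoch)
        epochs_no_improve <- 0L
      } else {
        epochs_no_improve <- epochs_no_improve + 1L
        if (epochs_no_improve >= patience) break
      }
    }
    list(par = best$par, arch = arch, val_mse = best$mse,
         best_epoch = best$epoch)
  })
}

cnn_predict_fit <- function(fit, X, chunk = 8192L) {
  n <- nrow(X)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    out[bi] <- cnn_forward(fit$par, fit$arch, X[bi, , drop = FALSE])
  }
  out
}
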