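# Forward pass.  The batch is carried through the convolutional stack in a
# channel-fastest flattened layout so that strided windows and BLAS matrix
# products do the heavy lifting; the token-level transformer runs per
# sample (token sequences are short).
#
# Stage order: temporal conv (same padding, no activation) -> batch norm ->
# depthwise spatial conv over all channels -> batch norm -> ELU -> average
# pool (pool1) -> dropout -> separable conv (depthwise temporal + pointwise)
# -> batch norm -> ELU -> average pool (pool2) -> dropout -> token sequence
# [d x F2] -> + positional encoding -> transformer block(s) -> global
# average pooling -> dense softmax.  The flatten head replaces the
# transformer and GAP with a flatten + dense layer (EEGNet-style baseline).

.bn_forward <- function(Z, bn, training, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(Z)
    v <- pmax(rowMeans(Z^2) - mu^2, 0)
  } else {
    mu <- bn$rmean
    v <- bn$rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (Z - mu) * inv
  list(out = bn$gamma * xhat + bn$beta, xhat = xhat, inv = inv,
       mu = mu, v = v)
}

# Average pooling along the middle axis of an [F2, S, N] array; the
# trailing remainder that does not fill a window is truncated.
.avg_pool <- function(A, pool) {
  d <- dim(A)
  s_out <- d[2] %/% pool
  A <- A[, seq_len(s_out * pool), , drop = FALSE]
  dim(A) <- c(d[1], pool, s_out, d[3])
  P <- A[, 1, , , drop = FALSE]
  if (pool > 1) for (p in 2:pool) P <- P + A[, p, , , drop = FALSE]
  P <- P / pool
  dim(P) <- c(d[1], s_out, d[3])
  P
}

.dropout_mask <- function(dims, rate) {
  keep <- 1 - rate
  array((stats::runif(prod(dims)) < keep) / keep, dims)
}

# Core forward.  X is [N, C, S].  Returns logits/probs plus (optionally)
# the intermediates needed by the backward pass and the batch-norm running
# updates.
.ertnet_forward <- function(model, X, training = FALSE, keep = FALSE,
                            bn_momentum = 0.9) {
  cf <- model$config
  p <- model$params
  stopifnot(length(dim(X)) == 3L, dim(X)[2] == cf$n_channels,
            dim(X)[3] == cf$n_samples)
  N <- dim(X)[1]
  S <- cf$n_samples; C <- cf$n_channels
  Tk <- cf$T; F1 <- cf$F1; D <- cf$D; F2 <- cf$F2
  st <- list()

  # channel-fastest flattening (c, t, n); the fused temporal-conv +
  # batch-norm + spatial-conv front runs in compiled code (src/engine.cpp)
  Xct <- aperm(X, c(2, 3, 1))                      # [C, S, N]
  ex <- cpp_extract_fwd(Xct, p$Wt, p$Ws, p$bn1$gamma, p$bn1$beta,
                        p$bn1$rmean, p$bn1$rvar, training)
  Z2 <- ex$Z2                                      # [F2, S*N]
  b1 <- list(mu = as.vector(ex$mu), v = as.vector(ex$v),
             inv = as.vector(ex$inv))

  b2 <- .bn_forward(Z2, p$bn2, training)
  A2 <- elu(b2$out, cf$elu_alpha)
  P1 <- .avg_pool(array(A2, c(F2, S, N)), cf$pool1)   # [F2, S1, N]
  S1 <- dim(P1)[2]
  mask1 <- NULL
  if (training && cf$dropout > 0) {
    mask1 <- .dropout_mask(dim(P1), cf$dropout)
    P1 <- P1 * mask1
  }

  sepk <- cf$sep_kernel
  pl2 <- (sepk - 1L) %/% 2L
  Ppad <- array(0, c(F2, S1 + sepk - 1L, N))
  Ppad[, (pl2 + 1L):(pl2 + S1), ] <- P1
  dw <- array(0, c(F2, S1, N))
  for (tau in seq_len(sepk)) {
    dw <- dw + Ppad[, tau:(tau + S1 - 1L), , drop = FALSE] * p$Wsep_d[tau, ]
  }
  dwm <- dw
  dim(dwm) <- c(F2, S1 * N)
  Z3 <- crossprod(p$Wsep_p, dwm)

  b3 <- .bn_forward(Z3, p$bn3, training)
  A3 <- elu(b3$out, cf$elu_alpha)
  P2 <- .avg_pool(array(A3, c(F2, S1, N)), cf$pool2)  # [F2, d, N]
  d_tok <- dim(P2)[2]
  mask2 <- NULL
  if (training && cf$dropout > 0) {
    mask2 <- .dropout_mask(dim(P2), cf$dropout)
    P2 <- P2 * mask2
  }

  if (cf$head == "transformer") {
    Xtok <- aperm(P2, c(2, 1, 3))                  # [d, F2, N]
    pe <- positional_encoding(d_tok, F2)
    for (n in seq_len(N)) Xtok[, , n] <- Xtok[, , n] + pe
    blocks_cache <- if (keep)
      lapply(seq_len(cf$n_blocks), function(b) vector("list", N)) else NULL
    for (b in seq_len(cf$n_blocks)) {
      bp <- p$blocks[[b]]
      for (n in seq_len(N)) {
        Xn <- matrix(Xtok[, , n], d_tok, F2)
        mh <- .mha_forward(Xn, bp$mha, keep = keep)
        mo <- if (keep) mh$out else mh
        l1 <- .layer_norm_forward(Xn + mo, bp$ln1_gamma, bp$ln1_beta)
        ff_pre <- l1$out %*% bp$ff_W + rep(bp$ff_b, each = d_tok)
        ff <- elu(ff_pre, cf$elu_alpha)
        l2 <- .layer_norm_forward(l1$out + ff, bp$ln2_gamma, bp$ln2_beta)
        if (keep) {
          blocks_cache[[b]][[n]] <- list(X = Xn, mha = mh, l1 = l1,
                                         ff_pre = ff_pre, l2 = l2)
        }
        Xtok[, , n] <- l2$out
      }
    }
    G <- matrix(colMeans(matrix(Xtok, d_tok)), F2, N)
    logits <- crossprod(p$Wd, G) + p$bd
    if (keep) {
      st$Xtok <- Xtok; st$G <- G; st$blocks_cache <- blocks_cache
      st$d_tok <- d_tok
    }
  } else {
    Feat <- P2
    dim(Feat) <- c(F2 * d_tok, N)
    logits <- crossprod(p$Wd, Feat) + p$bd
    if (keep) { st$Feat <- Feat; st$d_tok <- d_tok }
  }
  probs <- t(softmax_rows(t(logits)))              # [K, N]

  out <- list(logits = logits, probs = probs)
  if (training) {
    m <- bn_momentum
    out$bn_updates <- list(
      bn1 = list(rmean = m * p$bn1$rmean + (1 - m) * b1$mu,
                 rvar = m * p$bn1$rvar + (1 - m) * b1$v),
      bn2 = list(rmean = m * p$bn2$rmean + (1 - m) * b2$mu,
                 rvar = m * p$bn2$rvar + (1 - m) * b2$v),
      bn3 = list(rmean = m * p$bn3$rmean + (1 - m) * b3$mu,
                 rvar = m * p$bn3$rvar + (1 - m) * b3$v))
  }
  if (keep) {
    st$Xct <- Xct
    st$Z1 <- ex$Z1
    st$b1 <- b1
    st$b2 <- b2; st$A2pre <- b2$out; st$S1 <- S1
    st$mask1 <- mask1; st$Ppad <- Ppad; st$dwm <- dwm
    st$b3 <- b3; st$A3pre <- b3$out; st$mask2 <- mask2
    st$N <- N
    out$stash <- st
  }
  out
}

#' Predict class probabilities for an epoch set
#'
#' Runs the model in inference mode (batch-norm running statistics, no
#' dropout).
#'
#' @param object An `ertnet_model`.
#' @param ep An [epoch_set()] (or a bare `[N, C, S]` array).
#' @param batch_size Forward batch size.
#' @param ... Unused.
#' @return A numeric matrix `[N, K]` of class probabilities; rows sum to 1.
#' @export
predict.ertnet_model <- function(object, ep, batch_size = 128L, ...) {
  X <- if (inherits(ep, "epoch_set")) ep$epochs else ep
  N <- dim(X)[1]
  K <- object$config$n_classes
  out <- matrix(0, N, K)
  at <- 1L
  while (at <= N) {
    idx <- at:min(at + batch_size - 1L, N)
    fw <- .ertnet_forward(object, X[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- t(fw$probs)
    at <- at + batch_size
  }
  colnames(out) <- if (inherits(ep, "epoch_set") &&
                        length(ep$label_names) == K) ep$label_names else NULL
  out
}
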