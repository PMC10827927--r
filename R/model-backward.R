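# Backpropagation through the full architecture.  Gradients mirror the
# parameter list produced by build_ertnet(); batch-norm gradients use the
# batch statistics captured in the forward stash (training mode).

.bn_backward <- function(dY, cache, gamma) {
  dxhat <- dY * gamma
  xhat <- cache$xhat
  dZ <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dZ = dZ, dgamma = rowSums(dY * xhat), dbeta = rowSums(dY))
}

# Scatter the gradient of an average pool back over its input axis; input
# positions truncated by the pool get zero gradient.
.avg_pool_backward <- function(dP, pool, s_in) {
  d <- dim(dP)                                    # [F2, s_out, N]
  out <- array(0, c(d[1], s_in, d[3]))
  g <- dP / pool
  for (p in seq_len(pool)) {
    out[, (seq_len(d[2]) - 1L) * pool + p, ] <- g
  }
  out
}

.mha_backward <- function(Xn, mh, p, dM) {
  F2 <- ncol(Xn)
  n_heads <- dim(p$Wq)[3]
  scf <- 1 / sqrt(F2)
  dWo <- crossprod(mh$concat, dM)
  dConcat <- tcrossprod(dM, p$Wo)
  dWq <- array(0, dim(p$Wq)); dWk <- dWq; dWv <- dWq
  dX <- matrix(0, nrow(Xn), F2)
  for (h in seq_len(n_heads)) {
    hh <- mh$heads[[h]]
    cols <- ((h - 1) * F2 + 1):(h * F2)
    dH <- dConcat[, cols, drop = FALSE]
    dA <- tcrossprod(dH, hh$V)
    dV <- crossprod(hh$A, dH)
    dS <- hh$A * (dA - rowSums(dA * hh$A)) * scf
    dQ <- dS %*% hh$K
    dK <- crossprod(dS, hh$Q)
    dWq[, , h] <- crossprod(Xn, dQ)
    dWk[, , h] <- crossprod(Xn, dK)
    dWv[, , h] <- crossprod(Xn, dV)
    dX <- dX + tcrossprod(dQ, p$Wq[, , h]) + tcrossprod(dK, p$Wk[, , h]) +
      tcrossprod(dV, p$Wv[, , h])
  }
  list(dX = dX, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# Full backward pass; dLogits is [K, N] (typically (probs - onehot)/N for
# mean cross-entropy).  Returns a gradient list shaped like model$params.
.ertnet_backward <- function(model, st, dLogits) {
  cf <- model$config
  p <- model$params
  N <- st$N
  F1 <- cf$F1; D <- cf$D; F2 <- cf$F2
  S <- cf$n_samples; C <- cf$n_channels
  S1 <- st$S1; d_tok <- st$d_tok
  g <- list()

  if (cf$head == "transformer") {
    g$Wd <- tcrossprod(st$G, dLogits)             # [F2, K]
    g$bd <- rowSums(dLogits)
    dG <- p$Wd %*% dLogits                        # [F2, N]
    dXtok <- array(0, c(d_tok, F2, N))
    for (n in seq_len(N)) {
      dXtok[, , n] <- matrix(dG[, n] / d_tok, d_tok, F2, byrow = TRUE)
    }
    g$blocks <- lapply(p$blocks, function(bp) list(
      mha = list(Wq = array(0, dim(bp$mha$Wq)), Wk = array(0, dim(bp$mha$Wk)),
                 Wv = array(0, dim(bp$mha$Wv)), Wo = matrix(0, nrow(bp$mha$Wo),
                                                            ncol(bp$mha$Wo))),
      ln1_gamma = numeric(F2), ln1_beta = numeric(F2),
      ff_W = matrix(0, F2, F2), ff_b = numeric(F2),
      ln2_gamma = numeric(F2), ln2_beta = numeric(F2)))
    for (b in rev(seq_len(cf$n_blocks))) {
      bp <- p$blocks[[b]]
      gb <- g$blocks[[b]]
      for (n in seq_len(N)) {
        cb <- st$blocks_cache[[b]][[n]]
        dX2 <- matrix(dXtok[, , n], d_tok, F2)
        gb$ln2_gamma <- gb$ln2_gamma + colSums(dX2 * cb$l2$xhat)
        gb$ln2_beta <- gb$ln2_beta + colSums(dX2)
        dsum2 <- .layer_norm_backward(dX2, cb$l2, bp$ln2_gamma)
        dff <- dsum2 * elu_grad(cb$ff_pre, cf$elu_alpha)
        gb$ff_W <- gb$ff_W + crossprod(cb$l1$out, dff)
        gb$ff_b <- gb$ff_b + colSums(dff)
        dX1 <- dsum2 + tcrossprod(dff, bp$ff_W)
        gb$ln1_gamma <- gb$ln1_gamma + colSums(dX1 * cb$l1$xhat)
        gb$ln1_beta <- gb$ln1_beta + colSums(dX1)
        dsum1 <- .layer_norm_backward(dX1, cb$l1, bp$ln1_gamma)
        mb <- .mha_backward(cb$X, cb$mha, bp$mha, dsum1)
        gb$mha$Wq <- gb$mha$Wq + mb$dWq
        gb$mha$Wk <- gb$mha$Wk + mb$dWk
        gb$mha$Wv <- gb$mha$Wv + mb$dWv
        gb$mha$Wo <- gb$mha$Wo + mb$dWo
        dXtok[, , n] <- dsum1 + mb$dX
      }
      g$blocks[[b]] <- gb
    }
    dP2 <- aperm(dXtok, c(2, 1, 3))               # [F2, d, N]
  } else {
    g$Wd <- tcrossprod(st$Feat, dLogits)
    g$bd <- rowSums(dLogits)
    dP2 <- array(p$Wd %*% dLogits, c(F2, d_tok, N))
  }

  if (!is.null(st$mask2)) dP2 <- dP2 * st$mask2
  dA3 <- .avg_pool_backward(dP2, cf$pool2, S1)
  dim(dA3) <- c(F2, S1 * N)
  dZ3bn <- dA3 * elu_grad(st$A3pre, cf$elu_alpha)
  b3 <- .bn_backward(dZ3bn, st$b3, p$bn3$gamma)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  dZ3 <- b3$dZ                                    # [F2, S1*N]

  g$Wsep_p <- tcrossprod(st$dwm, dZ3)             # [F2, F2]
  ddw <- array(p$Wsep_p %*% dZ3, c(F2, S1, N))
  sepk <- cf$sep_kernel
  pl2 <- (sepk - 1L) %/% 2L
  g$Wsep_d <- matrix(0, sepk, F2)
  dPpad <- array(0, c(F2, S1 + sepk - 1L, N))
  for (tau in seq_len(sepk)) {
    sl <- st$Ppad[, tau:(tau + S1 - 1L), , drop = FALSE]
    g$Wsep_d[tau, ] <- rowSums(matrix(sl * ddw, F2))
    dPpad[, tau:(tau + S1 - 1L), ] <-
      dPpad[, tau:(tau + S1 - 1L), , drop = FALSE] + ddw * p$Wsep_d[tau, ]
  }
  dP1 <- dPpad[, (pl2 + 1L):(pl2 + S1), , drop = FALSE]

  if (!is.null(st$mask1)) dP1 <- dP1 * st$mask1
  dA2 <- .avg_pool_backward(dP1, cf$pool1, S)
  dim(dA2) <- c(F2, S * N)
  dZ2bn <- dA2 * elu_grad(st$A2pre, cf$elu_alpha)
  b2 <- .bn_backward(dZ2bn, st$b2, p$bn2$gamma)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  dZ2 <- b2$dZ                                    # [F2, S*N]

  eb <- cpp_extract_bwd(st$Xct, st$Z1, st$b1$mu, st$b1$inv,
                        p$bn1$gamma, p$bn1$beta, p$Ws, dZ2, cf$T)
  g$Ws <- eb$dWs
  g$bn1 <- list(gamma = as.vector(eb$dgamma), beta = as.vector(eb$dbeta))
  g$Wt <- eb$dWt
  g
}
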