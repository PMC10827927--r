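# Independent reference implementations used as oracles.  All are written
# as plain loops, deliberately sharing no code with the package internals.

# Brute-force multi-head attention: loops over heads, rows and scores.
oracle_mha <- function(X, params) {
  d <- nrow(X); F2 <- ncol(X)
  n_heads <- dim(params$Wq)[3]
  concat <- matrix(0, d, 0)
  for (h in seq_len(n_heads)) {
    Q <- X %*% params$Wq[, , h]
    K <- X %*% params$Wk[, , h]
    V <- X %*% params$Wv[, , h]
    H <- matrix(0, d, F2)
    for (i in seq_len(d)) {
      scores <- numeric(d)
      for (j in seq_len(d)) {
        scores[j] <- sum(Q[i, ] * K[j, ]) / sqrt(F2)
      }
      w <- exp(scores - max(scores))
      w <- w / sum(w)
      for (j in seq_len(d)) H[i, ] <- H[i, ] + w[j] * V[j, ]
    }
    concat <- cbind(concat, H)
  }
  concat %*% params$Wo
}

# Straight-loop forward pass of the whole network for one epoch in
# inference mode (running batch-norm statistics, no dropout).
oracle_forward <- function(model, x) {
  cf <- model$config
  p <- model$params
  C <- cf$n_channels; S <- cf$n_samples
  elu1 <- function(v) ifelse(v > 0, v, cf$elu_alpha * (exp(v) - 1))

  # temporal conv, same padding (cross-correlation, left pad (T-1)%/%2)
  pl <- (cf$T - 1) %/% 2
  Z1 <- array(0, c(cf$F1, C, S))
  for (f in seq_len(cf$F1)) {
    for (c in seq_len(C)) {
      for (t in seq_len(S)) {
        acc <- 0
        for (tau in seq_len(cf$T)) {
          src <- t + tau - 1 - pl
          if (src >= 1 && src <= S) acc <- acc + p$Wt[tau, f] * x[c, src]
        }
        Z1[f, c, t] <- acc
      }
    }
  }
  # batch norm 1 (running stats)
  for (f in seq_len(cf$F1)) {
    Z1[f, , ] <- p$bn1$gamma[f] *
      (Z1[f, , ] - p$bn1$rmean[f]) / sqrt(p$bn1$rvar[f] + 1e-5) +
      p$bn1$beta[f]
  }
  # depthwise spatial conv, ELU after batch norm 2
  F2 <- cf$F2
  Z2 <- matrix(0, F2, S)
  for (f in seq_len(cf$F1)) {
    for (dd in seq_len(cf$D)) {
      row <- (f - 1) * cf$D + dd
      for (t in seq_len(S)) {
        Z2[row, t] <- sum(p$Ws[, dd, f] * Z1[f, , t])
      }
    }
  }
  for (r in seq_len(F2)) {
    Z2[r, ] <- p$bn2$gamma[r] *
      (Z2[r, ] - p$bn2$rmean[r]) / sqrt(p$bn2$rvar[r] + 1e-5) + p$bn2$beta[r]
  }
  A2 <- elu1(Z2)
  # average pool 1
  S1 <- S %/% cf$pool1
  P1 <- matrix(0, F2, S1)
  for (r in seq_len(F2)) {
    for (t in seq_len(S1)) {
      P1[r, t] <- mean(A2[r, ((t - 1) * cf$pool1 + 1):(t * cf$pool1)])
    }
  }
  # separable: depthwise temporal then pointwise
  pl2 <- (cf$sep_kernel - 1) %/% 2
  DW <- matrix(0, F2, S1)
  for (r in seq_len(F2)) {
    for (t in seq_len(S1)) {
      acc <- 0
      for (tau in seq_len(cf$sep_kernel)) {
        src <- t + tau - 1 - pl2
        if (src >= 1 && src <= S1) acc <- acc + p$Wsep_d[tau, r] * P1[r, src]
      }
      DW[r, t] <- acc
    }
  }
  Z3 <- matrix(0, F2, S1)
  for (g in seq_len(F2)) {
    for (t in seq_len(S1)) {
      Z3[g, t] <- sum(p$Wsep_p[, g] * DW[, t])
    }
  }
  for (r in seq_len(F2)) {
    Z3[r, ] <- p$bn3$gamma[r] *
      (Z3[r, ] - p$bn3$rmean[r]) / sqrt(p$bn3$rvar[r] + 1e-5) + p$bn3$beta[r]
  }
  A3 <- elu1(Z3)
  d_tok <- S1 %/% cf$pool2
  P2 <- matrix(0, F2, d_tok)
  for (r in seq_len(F2)) {
    for (t in seq_len(d_tok)) {
      P2[r, t] <- mean(A3[r, ((t - 1) * cf$pool2 + 1):(t * cf$pool2)])
    }
  }
  # tokens, positional encoding, transformer blocks
  Xtok <- t(P2)
  if (cf$head == "transformer") {
    pe <- matrix(0, d_tok, F2)
    for (pp in seq_len(d_tok)) {
      for (j in seq_len(F2)) {
        ii <- 2 * ((j - 1) %/% 2)
        ang <- (pp - 1) / 10000^(ii / F2)
        pe[pp, j] <- if (j %% 2 == 1) sin(ang) else cos(ang)
      }
    }
    Xtok <- Xtok + pe
    ln <- function(M, gam, bet) {
      out <- M
      for (i in seq_len(nrow(M))) {
        mu <- mean(M[i, ])
        vv <- mean((M[i, ] - mu)^2)
        out[i, ] <- gam * (M[i, ] - mu) / sqrt(vv + 1e-5) + bet
      }
      out
    }
    for (b in seq_len(cf$n_blocks)) {
      bp <- p$blocks[[b]]
      X1 <- ln(Xtok + oracle_mha(Xtok, bp$mha), bp$ln1_gamma, bp$ln1_beta)
      FF <- elu1(X1 %*% bp$ff_W + matrix(bp$ff_b, d_tok, F2, byrow = TRUE))
      Xtok <- ln(X1 + FF, bp$ln2_gamma, bp$ln2_beta)
    }
    gap <- colMeans(Xtok)
    logits <- as.vector(t(p$Wd) %*% gap) + p$bd
  } else {
    logits <- as.vector(t(p$Wd) %*% as.vector(P2)) + p$bd
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

# O(n^2) pairwise AUC with ties counting one half.
oracle_auc_pairwise <- function(scores, positive) {
  x <- scores[positive]; y <- scores[!positive]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
    }
  }
  total / (length(x) * length(y))
}

# Exact two-sided Wilcoxon signed-rank p-value by enumerating all sign
# assignments (n <= ~14).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  dev_obs <- abs(v_obs - ev)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    v <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L])
    if (abs(v - ev) >= dev_obs - 1e-9) count <- count + 1L
  }
  count / 2^n
}

# Periodogram band power of one trace.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  fr <- (1:(n %/% 2 - 1)) * fs / n
  sum(sp[fr >= lo & fr < hi])
}

# Log-log periodogram slope (averaged over segments).
periodogram_slope <- function(x) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  fr <- 1:(n %/% 2 - 1)
  stats::coef(stats::lm(log(sp) ~ log(fr)))[2]
}
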