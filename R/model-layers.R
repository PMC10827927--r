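# Transformer building blocks operating on a token matrix X [d x F2].
# Heads are full feature-width, as the printed projection shapes dictate:
# every W^Q_i, W^K_i, W^V_i is F2 x F2 (d_k = F2) and the concatenated
# heads are projected back by W^O of shape (n F2) x F2.

#' Parameters for a full-width multi-head attention layer
#'
#' @param F2 Token feature width.
#' @param n_heads Number of heads.
#' @param init `"glorot"` for seeded Glorot-uniform draws or `"zero"`.
#' @return A list with arrays `Wq`, `Wk`, `Wv` of shape `[F2, F2, n_heads]`
#'   and `Wo` of shape `[n_heads * F2, F2]`.
#' @export
mha_params <- function(F2, n_heads, init = c("glorot", "zero")) {
  init <- match.arg(init)
  draw <- function(nr, nc) {
    if (init == "zero") return(matrix(0, nr, nc))
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  proj <- function() {
    a <- array(0, c(F2, F2, n_heads))
    for (h in seq_len(n_heads)) a[, , h] <- draw(F2, F2)
    a
  }
  list(Wq = proj(), Wk = proj(), Wv = proj(), Wo = draw(n_heads * F2, F2))
}

# Internal MHA forward keeping per-head intermediates for backprop.
.mha_forward <- function(X, p, keep = FALSE) {
  F2 <- ncol(X)
  n_heads <- dim(p$Wq)[3]
  d <- nrow(X)
  sc <- 1 / sqrt(F2)
  concat <- matrix(0, d, n_heads * F2)
  inter <- if (keep) vector("list", n_heads) else NULL
  for (h in seq_len(n_heads)) {
    Q <- X %*% p$Wq[, , h]
    K <- X %*% p$Wk[, , h]
    V <- X %*% p$Wv[, , h]
    A <- softmax_rows(Q %*% t(K) * sc)
    concat[, ((h - 1) * F2 + 1):(h * F2)] <- A %*% V
    if (keep) inter[[h]] <- list(Q = Q, K = K, V = V, A = A)
  }
  out <- concat %*% p$Wo
  if (keep) list(out = out, concat = concat, heads = inter) else out
}

#' Full-width multi-head self-attention
#'
#' Computes `Concat(head_1, ..., head_n) W^O` with
#' `head_i = softmax(X W^Q_i (X W^K_i)^T / sqrt(d_k)) X W^V_i`, where every
#' head spans the full feature width (`d_k = F2`).  Attention weights in
#' every softmax row sum to one.
#'
#' @param X Token matrix `[d x F2]` with `d >= 1`.
#' @param params A parameter list as produced by [mha_params()].
#' @return The attended token matrix `[d x F2]`.
#' @export
multi_head_attention <- function(X, params) {
  X <- as.matrix(X)
  F2 <- ncol(X)
  assert_that(all(dim(params$Wq)[1:2] == F2) &&
                nrow(params$Wo) == dim(params$Wq)[3] * F2 &&
                ncol(params$Wo) == F2,
              "attention parameter shapes do not match X")
  .mha_forward(X, params)
}

# Row-wise layer normalization with affine terms; eps stabilises constant
# rows.  Returns the output plus the normalised rows and scales needed by
# the backward pass.
.layer_norm_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, gamma, `*`) + rep(beta, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.layer_norm_backward <- function(dY, cache, gamma) {
  dxhat <- sweep(dY, 2L, gamma, `*`)
  xhat <- cache$xhat
  (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
}

#' Parameters for one transformer encoder block
#'
#' @param F2 Token feature width.
#' @param n_heads Number of attention heads.
#' @param init Weight initialisation passed to [mha_params()].
#' @return A list with `mha` parameters, layer-norm affine pairs
#'   (`ln1_gamma`, `ln1_beta`, `ln2_gamma`, `ln2_beta`) and the single-layer
#'   feed-forward weights `ff_W` `[F2 x F2]`, `ff_b`.
#' @export
transformer_block_params <- function(F2, n_heads, init = "glorot") {
  lim <- sqrt(6 / (2 * F2))
  ff_W <- if (init == "zero") matrix(0, F2, F2) else
    matrix(stats::runif(F2 * F2, -lim, lim), F2, F2)
  list(mha = mha_params(F2, n_heads, init),
       ln1_gamma = rep(1, F2), ln1_beta = rep(0, F2),
       ff_W = ff_W, ff_b = rep(0, F2),
       ln2_gamma = rep(1, F2), ln2_beta = rep(0, F2))
}

#' Transformer encoder block
#'
#' `X1 = LayerNorm(X + MHA(X))`, then `X' = LayerNorm(X1 + FF(X1))` where
#' the feed-forward part is a single ELU-activated dense layer `F2 -> F2`.
#' Shape is preserved.
#'
#' @param X Token matrix `[d x F2]`.
#' @param params Block parameters from [transformer_block_params()].
#' @param elu_alpha ELU decay factor for the feed-forward activation.
#' @return The transformed token matrix `[d x F2]`.
#' @export
transformer_block <- function(X, params, elu_alpha = 1) {
  X <- as.matrix(X)
  m <- .mha_forward(X, params$mha)
  l1 <- .layer_norm_forward(X + m, params$ln1_gamma, params$ln1_beta)
  ff <- elu(l1$out %*% params$ff_W +
              rep(params$ff_b, each = nrow(X)), elu_alpha)
  .layer_norm_forward(l1$out + ff, params$ln2_gamma, params$ln2_beta)$out
}
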