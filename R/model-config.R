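# Architecture configuration.  Every architectural symbol of the network is
# held in one validated object; the pointwise-kernel count F2 is always
# F1 * D and cannot be set inconsistently.

#' ERTNet architecture configuration
#'
#' @param n_channels Number of EEG channels C.
#' @param n_samples Samples per epoch S.
#' @param n_classes Number of output classes K.
#' @param F1 Number of temporal convolution kernels.
#' @param T Temporal kernel length in samples; must not exceed `n_samples`.
#' @param D Spatial depth multiplier (spatial kernels per temporal kernel).
#' @param F2 Pointwise kernel count; must equal `F1 * D` (the default).
#' @param pool1 First average-pool length (default 4).
#' @param pool2 Second average-pool length (default 8).
#' @param sep_kernel Depthwise temporal kernel length inside the separable
#'   block (default 16).
#' @param n_heads Number of attention heads n (default 8).  Heads are full
#'   feature-width: each projection is F2 x F2 and the output projection is
#'   (n F2) x F2.
#' @param n_blocks Number of transformer encoder blocks (default 1).
#' @param dropout Dropout rate in the extraction stack; 0.5 for
#'   subject-dependent work, 0.25 for subject-independent (default 0.5).
#' @param elu_alpha ELU decay factor alpha (default 1).
#' @param ff_dim Feed-forward width (default F2; the single-layer
#'   feed-forward requires `ff_dim == F2`).
#' @param head `"transformer"` (the full model) or `"flatten"` (an
#'   EEGNet-style baseline: same extraction stack, flatten + dense head,
#'   used as the transfer-learning source).
#' @return An object of class `ertnet_config`.
#' @export
ertnet_config <- function(n_channels, n_samples, n_classes,
                          F1 = 8, T = 64, D = 4, F2 = F1 * D,
                          pool1 = 4, pool2 = 8, sep_kernel = 16,
                          n_heads = 8, n_blocks = 1, dropout = 0.5,
                          elu_alpha = 1, ff_dim = F1 * D,
                          head = c("transformer", "flatten")) {
  head <- match.arg(head)
  for (v in c(n_channels, n_samples, n_classes, F1, T, D, pool1, pool2,
              sep_kernel, n_heads)) {
    assert_that(is_count(v), "architecture sizes must be positive integers")
  }
  assert_that(F2 == F1 * D,
              sprintf("F2 must equal F1 x D (= %d), got %d", F1 * D, F2))
  assert_that(T <= n_samples,
              sprintf("temporal kernel length T=%d exceeds n_samples=%d",
                      T, n_samples))
  assert_that(n_blocks >= 0 && n_blocks == round(n_blocks),
              "n_blocks must be a non-negative integer")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  s1 <- n_samples %/% pool1
  d_tokens <- s1 %/% pool2
  assert_that(d_tokens >= 1,
              "pooling removes all time steps; reduce pool1/pool2")
  assert_that(ff_dim == F2, "single-layer feed-forward requires ff_dim == F2")
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 F1 = as.integer(F1), T = as.integer(T), D = as.integer(D),
                 F2 = as.integer(F2), pool1 = as.integer(pool1),
                 pool2 = as.integer(pool2), sep_kernel = as.integer(sep_kernel),
                 n_heads = as.integer(n_heads), n_blocks = as.integer(n_blocks),
                 dropout = dropout, elu_alpha = elu_alpha,
                 ff_dim = as.integer(ff_dim), head = head,
                 s1 = as.integer(s1), d_tokens = as.integer(d_tokens)),
            class = "ertnet_config")
}

#' @export
print.ertnet_config <- function(x, ...) {
  cat(sprintf(paste0("<ertnet_config> C=%d S=%d K=%d | F1=%d T=%d D=%d F2=%d | ",
                     "pools %d/%d, %d head(s) x %d block(s), dropout %g, %s head\n"),
              x$n_channels, x$n_samples, x$n_classes, x$F1, x$T, x$D, x$F2,
              x$pool1, x$pool2, x$n_heads, x$n_blocks, x$dropout, x$head))
  cat(sprintf("  token sequence: d=%d x F2=%d\n", x$d_tokens, x$F2))
  invisible(x)
}

#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `alpha * (exp(x) - 1)` otherwise;
#' continuous at 0 and bounded below by `-alpha`.
#'
#' @param x Numeric input (vectorised).
#' @param alpha Decay factor for negative inputs (default 1).
#' @return Elementwise ELU of `x`.
#' @export
elu <- function(x, alpha = 1) {
  neg <- which(x <= 0)                     # NaN-safe: non-finite pass through
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

# Derivative of ELU at the pre-activation value.
elu_grad <- function(x, alpha = 1) {
  neg <- which(x <= 0)
  x[-neg] <- 1
  x[neg] <- alpha * exp(x[neg])
  if (length(neg) == 0L) x[] <- 1
  x
}

#' Sinusoidal positional encoding
#'
#' The fixed table `PE[p, 2i+1] = sin(p / 10000^(2i/F2))`,
#' `PE[p, 2i+2] = cos(...)` for 0-based positions `p = 0 .. d-1`, added to
#' the token sequence so attention can exploit temporal order.
#'
#' @param d Number of token positions.
#' @param F2 Token feature width.
#' @return A `d x F2` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(d, F2) {
  assert_that(d >= 1 && F2 >= 1, "d and F2 must be >= 1")
  pos <- seq_len(d) - 1
  pe <- matrix(0, d, F2)
  for (j in seq_len(F2)) {
    i2 <- 2 * ((j - 1) %/% 2)              # exponent uses the sin/cos pair index
    angle <- pos / 10000^(i2 / F2)
    pe[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

#' Minimum detectable frequency of a temporal kernel
#'
#' A kernel of length `T` samples at sampling rate `Sr` cannot resolve
#' oscillations slower than `Fmin = Sr / T` Hz: one full cycle must fit
#' inside the kernel.
#'
#' @param sampling_rate Sampling rate Sr in Hz.
#' @param kernel_length Temporal kernel length T in samples (>= 1).
#' @return `Sr / T` in Hz.
#' @export
min_detectable_frequency <- function(sampling_rate, kernel_length) {
  assert_that(is.numeric(kernel_length) && length(kernel_length) == 1L &&
                kernel_length >= 1, "kernel_length must be >= 1")
  assert_that(sampling_rate > 0, "sampling_rate must be positive")
  sampling_rate / kernel_length
}
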