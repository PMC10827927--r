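#' @keywords internal
#' @useDynLib ertnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal assertion helper: stop with a clear message.
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Row-wise softmax of a matrix, numerically stabilised.
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# RMS of a numeric vector.
rms <- function(x) sqrt(mean(x^2))

# Seed helper: derive a child seed from a base seed and an index, kept
# within the 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + index * 9176) %% 2147483647)
}
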