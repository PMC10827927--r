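# Model construction, parameter bookkeeping and checkpoints.
#
# Parameter layout (feature index convention: the F2 feature produced by
# spatial kernel d of temporal kernel f is (f-1)*D + d):
#   Wt      [T, F1]            temporal kernels (no bias; batch norm follows)
#   bn1     gamma/beta/rmean/rvar, one per F1 map
#   Ws      [C, D, F1]         depthwise spatial kernels (full channel span)
#   bn2     per F2 map
#   Wsep_d  [sep_kernel, F2]   separable block: depthwise temporal kernels
#   Wsep_p  [F2, F2]           separable block: pointwise mixing
#   bn3     per F2 map
#   blocks  transformer block parameter lists (see transformer_block_params)
#   Wd, bd  decision layer (flatten head uses Wd [d*F2, K])

.glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

.bn_init <- function(k) {
  list(gamma = rep(1, k), beta = rep(0, k), rmean = rep(0, k), rvar = rep(1, k))
}

#' Build and initialise a model
#'
#' Initialises all weights with seeded Glorot-uniform draws (batch-norm
#' scale 1, shift 0); convolution biases are omitted because every
#' convolution is immediately followed by batch normalisation.
#'
#' @param config An [ertnet_config()].
#' @param seed Integer seed for the weight draws.
#' @return An object of class `ertnet_model` holding `config` and `params`.
#' @export
build_ertnet <- function(config, seed = 1L) {
  assert_that(inherits(config, "ertnet_config"), "config must be an ertnet_config")
  set.seed(seed)
  cf <- config
  params <- list(
    Wt = .glorot(c(cf$T, cf$F1), cf$T, cf$F1),
    bn1 = .bn_init(cf$F1),
    Ws = .glorot(c(cf$n_channels, cf$D, cf$F1), cf$n_channels, cf$D),
    bn2 = .bn_init(cf$F2),
    Wsep_d = .glorot(c(cf$sep_kernel, cf$F2), cf$sep_kernel, 1),
    Wsep_p = .glorot(c(cf$F2, cf$F2), cf$F2, cf$F2),
    bn3 = .bn_init(cf$F2))
  if (cf$head == "transformer") {
    params$blocks <- lapply(seq_len(cf$n_blocks), function(b)
      transformer_block_params(cf$F2, cf$n_heads))
    params$Wd <- .glorot(c(cf$F2, cf$n_classes), cf$F2, cf$n_classes)
  } else {
    params$blocks <- list()
    params$Wd <- .glorot(c(cf$d_tokens * cf$F2, cf$n_classes),
                         cf$d_tokens * cf$F2, cf$n_classes)
  }
  params$bd <- rep(0, cf$n_classes)
  structure(list(config = cf, params = params, seed = as.integer(seed)),
            class = "ertnet_model")
}

#' @export
print.ertnet_model <- function(x, ...) {
  pc <- parameter_count(x)
  cat(sprintf("<ertnet_model> %s head, %s trainable parameters\n",
              x$config$head, format(pc$total, big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Trainable-parameter count, itemised per layer
#'
#' Batch-norm running statistics are not counted (not trainable).
#'
#' @param model An `ertnet_model`.
#' @return A list with `total` and a named `by_layer` breakdown.
#' @export
parameter_count <- function(model) {
  cf <- model$config
  by <- c(
    temporal_conv = cf$F1 * cf$T,
    bn1 = 2 * cf$F1,
    spatial_depthwise = cf$F1 * cf$D * cf$n_channels,
    bn2 = 2 * cf$F2,
    separable_depthwise = cf$F2 * cf$sep_kernel,
    separable_pointwise = cf$F2 * cf$F2,
    bn3 = 2 * cf$F2)
  if (cf$head == "transformer" && cf$n_blocks > 0) {
    per_block <- cf$n_heads * 3 * cf$F2^2 +        # per-head Q, K, V projections
      cf$n_heads * cf$F2 * cf$F2 +                 # output projection (nF2 x F2)
      2 * 2 * cf$F2 +                              # two layer norms
      cf$F2 * cf$F2 + cf$F2                        # single-layer feed-forward
    by <- c(by, transformer_blocks = cf$n_blocks * per_block)
  }
  by <- c(by, decision = length(model$params$Wd) + length(model$params$bd))
  list(total = sum(by), by_layer = as.list(by))
}

# Extraction-stack parameter names shared by the transformer model and the
# flatten-head baseline; the unit of transfer learning.
.extractor_param_names <- c("Wt", "bn1", "Ws", "bn2", "Wsep_d", "Wsep_p", "bn3")

#' Save a model checkpoint
#'
#' Portable JSON archive holding the configuration and every named weight
#' array (including batch-norm running statistics) at full precision.
#'
#' @param model An `ertnet_model`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  enc <- function(x) {
    if (is.list(x)) return(lapply(x, enc))
    list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
  obj <- list(config = unclass(model$config), params = enc(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path A `.json` checkpoint written by [save_checkpoint()].
#' @return The restored `ertnet_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      d <- as.integer(unlist(x$dim))
      v <- as.numeric(unlist(x$data))
      if (length(d) > 1) array(v, d) else v
    } else {
      lapply(x, dec)
    }
  }
  cfl <- lapply(obj$config, function(v) if (is.list(v)) unlist(v) else v)
  cf <- ertnet_config(cfl$n_channels, cfl$n_samples, cfl$n_classes,
                      F1 = cfl$F1, T = cfl$T, D = cfl$D, F2 = cfl$F2,
                      pool1 = cfl$pool1, pool2 = cfl$pool2,
                      sep_kernel = cfl$sep_kernel, n_heads = cfl$n_heads,
                      n_blocks = cfl$n_blocks, dropout = cfl$dropout,
                      elu_alpha = cfl$elu_alpha, head = cfl$head)
  structure(list(config = cf, params = dec(obj$params), seed = NA_integer_),
            class = "ertnet_model")
}
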