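# Transfer learning: copy a tuned feature-extraction stack (for example
# from the flatten-head EEGNet-style baseline) into a transformer model
# whose extraction geometry matches, leaving the transformer and decision
# head freshly initialised.

#' Initialise a model from a source feature extractor
#'
#' Copies the temporal, spatial and separable convolution weights and all
#' extraction-stack batch-norm parameters (including running statistics)
#' bit-exactly from `source` into `target`.  Both models must share the
#' extraction geometry (C, F1, T, D, F2 and the separable kernel length);
#' any mismatch aborts with the offending layers named.
#'
#' @param target The model to initialise (typically transformer-headed).
#' @param source A trained `ertnet_model` or the path of a checkpoint
#'   written by [save_checkpoint()].
#' @return `target` with the extractor parameters replaced.
#' @export
transfer_init <- function(target, source) {
  if (is.character(source)) source <- load_checkpoint(source)
  assert_that(inherits(target, "ertnet_model") &&
                inherits(source, "ertnet_model"),
              "target and source must be ertnet_model objects")
  bad <- character(0)
  for (nm in .extractor_param_names) {
    tp <- target$params[[nm]]
    sp <- source$params[[nm]]
    same <- if (is.list(tp)) {
      all(vapply(names(tp), function(f) length(tp[[f]]) == length(sp[[f]]),
                 TRUE))
    } else {
      identical(dim(tp) %||% length(tp), dim(sp) %||% length(sp))
    }
    if (!same) bad <- c(bad, nm)
  }
  if (length(bad) > 0) {
    stop(sprintf("transfer error: extractor shape mismatch in layer(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in .extractor_param_names) {
    target$params[[nm]] <- source$params[[nm]]
  }
  target
}

#' Forward the feature-extraction stack only
#'
#' Runs an epoch batch through the convolutional extraction stack in
#' inference mode and returns the token sequences before positional
#' encoding, for inspecting or comparing extractor activations (e.g. after
#' [transfer_init()]).
#'
#' @param model An `ertnet_model`.
#' @param X An `[N, C, S]` array or an [epoch_set()].
#' @return An `[F2, d, N]` array of extractor outputs.
#' @export
extract_features <- function(model, X) {
  if (inherits(X, "epoch_set")) X <- X$epochs
  cf <- model$config
  # run a transformer-free twin so the head is never consulted
  twin <- model
  twin$config$n_blocks <- 0L
  if (cf$head == "transformer") {
    fw <- .ertnet_forward(twin, X, training = FALSE, keep = TRUE)
    out <- aperm(fw$stash$Xtok, c(2, 1, 3))
    pe <- positional_encoding(cf$d_tokens, cf$F2)
    for (n in seq_len(dim(out)[3])) {
      out[, , n] <- out[, , n] - t(pe)
    }
    out
  } else {
    fw <- .ertnet_forward(model, X, training = FALSE, keep = TRUE)
    array(fw$stash$Feat, c(cf$F2, cf$d_tokens, dim(X)[1]))
  }
}
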