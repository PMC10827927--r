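# Training loop (Adam on the built-in backprop engine) and evaluation
# metrics.

#' Training configuration
#'
#' Defaults: Adam at learning rate 1e-3, batches of 64, up to 100 passes
#' with patience-10 early stopping monitored on a 10% validation slice of
#' the training data, categorical cross-entropy loss.
#'
#' @param epochs Maximum training passes over the data.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Integer seed controlling shuffling, dropout and the
#'   validation split; a seeded single-threaded run is reproducible.
#' @param early_stop_patience Passes without validation-loss improvement
#'   before stopping; 0 disables early stopping.
#' @param validation_split Fraction of the training data held out to
#'   monitor early stopping.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-3, optimizer = "adam",
                         seed = 1L, early_stop_patience = 10L,
                         validation_split = 0.1, verbose = FALSE) {
  assert_that(optimizer == "adam", "only the adam optimizer is implemented")
  assert_that(is_count(epochs) && is_count(batch_size),
              "epochs and batch_size must be positive integers")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_split = validation_split, verbose = verbose),
            class = "train_config")
}

# Recursive Adam step over the nested gradient tree; entries present in
# params but absent from grads (batch-norm running stats) are untouched.
.adam_step <- function(params, grads, state, lr, t,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.list(gr)) {
      if (is.null(state[[nm]])) state[[nm]] <- list()
      res <- .adam_step(params[[nm]], gr, state[[nm]], lr, t, b1, b2, eps)
      params[[nm]] <- res$params
      state[[nm]] <- res$state
    } else {
      if (is.null(state[[nm]])) {
        state[[nm]] <- list(m = gr * 0, v = gr * 0)
      }
      st <- state[[nm]]
      st$m <- b1 * st$m + (1 - b1) * gr
      st$v <- b2 * st$v + (1 - b2) * gr^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]] <- st
    }
  }
  list(params = params, state = state)
}

.onehot <- function(labels, K) {
  Y <- matrix(0, K, length(labels))
  Y[cbind(labels + 1L, seq_along(labels))] <- 1
  Y
}

.ce_loss <- function(probs, labels) {
  p <- probs[cbind(labels + 1L, seq_along(labels))]
  -mean(log(pmax(p, 1e-12)))
}

#' Fit a model
#'
#' Minibatch training with Adam and categorical cross-entropy.  Shuffling,
#' dropout and the validation split all derive from `config$seed`, so a
#' single-threaded run is exactly reproducible.  A non-finite loss aborts
#' with diagnostics.
#'
#' @param model An `ertnet_model` from [build_ertnet()].
#' @param train_ep Training [epoch_set()] (labels required).
#' @param config A [train_config()].
#' @return A list with `model` (trained), `history` (per-epoch data frame
#'   with loss/accuracy and validation metrics when monitored).
#' @export
fit <- function(model, train_ep, config = train_config()) {
  assert_that(inherits(train_ep, "epoch_set") && n_epochs(train_ep) > 0,
              "training data must be a non-empty epoch_set")
  cf <- model$config
  K <- cf$n_classes
  set.seed(config$seed)
  N_all <- n_epochs(train_ep)

  val_idx <- integer(0)
  if (config$early_stop_patience > 0 && config$validation_split > 0 &&
      N_all >= 20) {
    n_val <- max(1L, round(config$validation_split * N_all))
    val_idx <- sample.int(N_all, n_val)
  }
  tr_idx <- setdiff(seq_len(N_all), val_idx)
  Xtr <- train_ep$epochs[tr_idx, , , drop = FALSE]
  ytr <- train_ep$labels[tr_idx]
  has_val <- length(val_idx) > 0
  if (has_val) {
    Xval <- train_ep$epochs[val_idx, , , drop = FALSE]
    yval <- train_ep$labels[val_idx]
  }

  state <- list()
  t_step <- 0L
  hist <- list()
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  N <- length(ytr)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0
    at <- 1L
    while (at <= N) {
      idx <- ord[at:min(at + config$batch_size - 1L, N)]
      Xb <- Xtr[idx, , , drop = FALSE]
      yb <- ytr[idx]
      fw <- .ertnet_forward(model, Xb, training = TRUE, keep = TRUE)
      loss <- .ce_loss(fw$probs, yb)
      if (!is.finite(loss)) {
        stop(sprintf(paste0("divergence: non-finite loss at epoch %d ",
                            "(batch mean |logit| = %g); lower the learning rate"),
                     epoch, mean(abs(fw$logits))), call. = FALSE)
      }
      nb <- length(yb)
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct + sum(max.col(t(fw$probs)) - 1L == yb)
      dLogits <- (fw$probs - .onehot(yb, K)) / nb
      grads <- .ertnet_backward(model, fw$stash, dLogits)
      t_step <- t_step + 1L
      res <- .adam_step(model$params, grads, state, config$learning_rate,
                        t_step)
      model$params <- res$params
      state <- res$state
      for (bnm in names(fw$bn_updates)) {
        model$params[[bnm]]$rmean <- fw$bn_updates[[bnm]]$rmean
        model$params[[bnm]]$rvar <- fw$bn_updates[[bnm]]$rvar
      }
      at <- at + config$batch_size
    }
    row <- data.frame(epoch = epoch, loss = ep_loss / N,
                      accuracy = ep_correct / N,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (has_val) {
      pv <- predict(model, Xval)
      row$val_loss <- .ce_loss(t(pv), yval)
      row$val_accuracy <- mean(max.col(pv) - 1L == yval)
      if (row$val_loss < best$loss - 1e-6) {
        best <- list(loss = row$val_loss, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) {
          hist[[length(hist) + 1L]] <- row
          if (config$verbose) message(sprintf("early stop at epoch %d", epoch))
          model$params <- best$params
          break
        }
      }
    }
    hist[[length(hist) + 1L]] <- row
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f%s", epoch, row$loss,
                      row$accuracy,
                      if (has_val) sprintf("  val_loss %.4f  val_acc %.3f",
                                           row$val_loss, row$val_accuracy)
                      else ""))
    }
  }
  list(model = model, history = do.call(rbind, hist))
}

# Trapezoidal ROC AUC for a binary task; ties in scores are grouped into
# one ROC vertex, so constant scores give exactly 0.5.
.auc_trapezoid <- function(scores, positive) {
  P <- sum(positive); Np <- sum(!positive)
  if (P == 0 || Np == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- positive[o]
  grp <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[grp] / P)
  fpr <- c(0, cumsum(!y)[grp] / Np)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate a trained model on a test epoch set
#'
#' @param model A trained `ertnet_model`.
#' @param test_ep Test [epoch_set()].
#' @param fold Optional fold index carried into the result.
#' @return A `fold_result`: `accuracy` (percent), `auc_macro` (mean
#'   one-vs-rest trapezoidal ROC AUC over classes present in the test set;
#'   `NA` if only one class is present), `per_class_auc`, and
#'   `confusion_matrix` (rows = true class, columns = predicted).
#' @export
evaluate <- function(model, test_ep, fold = NA_integer_) {
  probs <- predict(model, test_ep)
  pred <- max.col(probs) - 1L
  y <- test_ep$labels
  K <- model$config$n_classes
  cm <- matrix(0L, K, K,
               dimnames = list(true = test_ep$label_names,
                               predicted = test_ep$label_names))
  for (i in seq_along(y)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  per_auc <- vapply(seq_len(K), function(k) {
    .auc_trapezoid(probs[, k], y == k - 1L)
  }, 0)
  names(per_auc) <- test_ep$label_names
  present <- !is.na(per_auc)
  structure(list(fold = fold,
                 accuracy = 100 * mean(pred == y),
                 auc_macro = if (any(present)) mean(per_auc[present]) else NA_real_,
                 per_class_auc = per_auc,
                 confusion_matrix = cm,
                 n = length(y)),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result%s> accuracy %.2f%%, macro AUC %s, n = %d\n",
              if (is.na(x$fold)) "" else sprintf(" %d", x$fold),
              x$accuracy,
              if (is.na(x$auc_macro)) "NA" else sprintf("%.4f", x$auc_macro),
              x$n))
  invisible(x)
}
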