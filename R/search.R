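# Hyperparameter search and one-dimensional sweeps.

#' Integer hyperparameter search space
#'
#' Inclusive integer ranges for the four tuned architecture symbols.
#' Defaults follow the customary tuning ranges for this architecture
#' family: F1 in \[4, 20\], T in \[5, 100\], D in \[1, 5\], heads in
#' \[4, 20\].
#'
#' @param F1,T,D,heads Length-2 integer vectors `(min, max)`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(F1 = c(4L, 20L), T = c(5L, 100L), D = c(1L, 5L),
                         heads = c(4L, 20L)) {
  for (r in list(F1, T, D, heads)) {
    assert_that(length(r) == 2 && all(r == round(r)) && r[1] <= r[2],
                "ranges must be inclusive integer (min, max) pairs")
  }
  structure(list(F1 = as.integer(F1), T = as.integer(T), D = as.integer(D),
                 heads = as.integer(heads)),
            class = "search_space")
}

#' Random hyperparameter search
#'
#' Samples integer configurations uniformly from the space (a random-search
#' stand-in for tree-structured Parzen estimation), always honouring
#' `F2 = F1 x D`, evaluates each by cross-validated mean accuracy, and
#' returns the best configuration with the full trial log.
#'
#' @param ep Labelled [epoch_set()] used for evaluation.
#' @param space A [search_space()].
#' @param budget Number of trials (>= 1).
#' @param tc A [train_config()]; per-trial seeds derive from `tc$seed`.
#' @param k Cross-validation folds per trial (default 2, kept small because
#'   each trial trains k models).
#' @param ... Fixed arguments passed to [ertnet_config()] (e.g. `pool1`,
#'   `n_blocks`, `dropout`).
#' @return A list with `best` (config of the best trial), `best_accuracy`,
#'   and `trials` (data frame: F1, T, D, heads, F2, accuracy).
#' @export
hyperparameter_search <- function(ep, space = search_space(), budget = 10L,
                                  tc = train_config(), k = 2L, ...) {
  assert_that(is_count(budget), "budget must be >= 1")
  d <- dim(ep$epochs)
  set.seed(tc$seed)
  draws <- data.frame(
    F1 = sample(space$F1[1]:space$F1[2], budget, replace = TRUE),
    T = sample(space$T[1]:space$T[2], budget, replace = TRUE),
    D = sample(space$D[1]:space$D[2], budget, replace = TRUE),
    heads = sample(space$heads[1]:space$heads[2], budget, replace = TRUE))
  draws$T <- pmin(draws$T, d[3])
  trials <- draws
  trials$F2 <- trials$F1 * trials$D
  trials$accuracy <- NA_real_
  best <- NULL; best_acc <- -Inf
  for (i in seq_len(budget)) {
    cfg <- ertnet_config(n_channels = d[2], n_samples = d[3],
                         n_classes = length(ep$label_names),
                         F1 = draws$F1[i], T = draws$T[i], D = draws$D[i],
                         n_heads = draws$heads[i], ...)
    tci <- tc; tci$seed <- derive_seed(tc$seed, 3000L + i)
    cv <- kfold_cv(ep, cfg, tci, k = k)
    trials$accuracy[i] <- cv$summary$accuracy_mean
    if (trials$accuracy[i] > best_acc) {
      best_acc <- trials$accuracy[i]
      best <- cfg
    }
  }
  list(best = best, best_accuracy = best_acc, trials = trials)
}

#' Accuracy sweep over one architecture parameter
#'
#' Runs a cross-validated evaluation for each value of `T` (temporal
#' kernel length) or `n_blocks` (transformer block count) and tabulates
#' the accuracy curve.
#'
#' @param ep Labelled [epoch_set()].
#' @param parameter `"T"` or `"n_blocks"`.
#' @param values Integer vector of parameter values (non-empty).
#' @param tc A [train_config()].
#' @param k Cross-validation folds per value (default 2).
#' @param ... Fixed arguments passed to [ertnet_config()].
#' @return A data frame with one row per value: `value`, `accuracy_mean`,
#'   `accuracy_sd`, `auc_mean`.
#' @export
sweep_parameter <- function(ep, parameter = c("T", "n_blocks"), values,
                            tc = train_config(), k = 2L, ...) {
  parameter <- match.arg(parameter)
  assert_that(length(values) >= 1, "values must be non-empty")
  d <- dim(ep$epochs)
  rows <- lapply(values, function(v) {
    args <- list(n_channels = d[2], n_samples = d[3],
                 n_classes = length(ep$label_names), ...)
    args[[if (parameter == "T") "T" else "n_blocks"]] <- v
    cfg <- do.call(ertnet_config, args)
    cv <- kfold_cv(ep, cfg, tc, k = k)
    data.frame(value = v, accuracy_mean = cv$summary$accuracy_mean,
               accuracy_sd = cv$summary$accuracy_sd,
               auc_mean = cv$summary$auc_mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  out
}
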