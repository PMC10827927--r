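# Evaluation protocols: stratified holdout, stratified k-fold CV and
# leave-one-subject-out CV.  Every protocol guarantees disjoint train/test
# index sets; k-fold here is segment-level (as is common for
# subject-dependent emotion benchmarks), so epochs of one subject can land
# on both sides of a fold unless losocv() is used instead.

#' Stratified holdout split
#'
#' Seeded shuffle preserving per-class proportions within rounding.
#'
#' @param ep An [epoch_set()].
#' @param ratio Training fraction (default 0.8, an 8:2 split); must leave
#'   both parts non-empty.
#' @param seed Integer seed.
#' @param stratify Stratify by class label (default) or split plainly.
#' @return A list with `train` and `test` epoch sets and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
holdout_split <- function(ep, ratio = 0.8, seed = 1L, stratify = TRUE) {
  N <- n_epochs(ep)
  assert_that(ratio > 0 && ratio < 1, "ratio must be strictly inside (0, 1)")
  set.seed(seed)
  train_idx <- integer(0)
  if (stratify) {
    for (k in sort(unique(ep$labels))) {
      idx <- which(ep$labels == k)
      n_tr <- round(ratio * length(idx))
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  } else {
    train_idx <- sample.int(N, round(ratio * N))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(N), train_idx)
  assert_that(length(train_idx) > 0 && length(test_idx) > 0,
              "both split parts must be non-empty")
  list(train = subset_epochs(ep, train_idx),
       test = subset_epochs(ep, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# Stratified fold assignment; classes with fewer members than k trigger a
# warning and a plain (unstratified) split.
.fold_assignment <- function(labels, k, seed) {
  set.seed(seed)
  N <- length(labels)
  fold <- integer(N)
  counts <- table(labels)
  if (any(counts < k)) {
    warning(sprintf("class with < %d members: falling back to a plain split", k))
    fold[sample.int(N)] <- rep_len(seq_len(k), N)
  } else {
    for (lv in names(counts)) {
      idx <- sample(which(labels == as.integer(lv)))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Folds are disjoint, cover every epoch, and are stratified by class.  A
#' fresh model is built and trained per fold.
#'
#' @param ep An [epoch_set()].
#' @param model_config An [ertnet_config()] matching the epoch geometry.
#' @param tc A [train_config()]; per-fold seeds derive from `tc$seed`.
#' @param k Number of folds (default 10; must be >= 2 and <= n epochs).
#' @return A list with `folds` (per-fold `fold_result`s) and `summary`
#'   (mean and sd of accuracy and macro AUC).
#' @export
kfold_cv <- function(ep, model_config, tc = train_config(), k = 10L) {
  N <- n_epochs(ep)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(N >= k, "need at least k epochs")
  fold <- .fold_assignment(ep$labels, k, tc$seed)
  results <- vector("list", k)
  for (i in seq_len(k)) {
    te <- which(fold == i)
    tr <- which(fold != i)
    model <- build_ertnet(model_config, seed = derive_seed(tc$seed, i))
    tci <- tc; tci$seed <- derive_seed(tc$seed, 1000L + i)
    trained <- fit(model, subset_epochs(ep, tr), tci)$model
    results[[i]] <- evaluate(trained, subset_epochs(ep, te), fold = i)
  }
  accs <- vapply(results, `[[`, 0, "accuracy")
  aucs <- vapply(results, `[[`, 0, "auc_macro")
  list(folds = results,
       summary = list(accuracy_mean = mean(accs), accuracy_sd = stats::sd(accs),
                      auc_mean = mean(aucs, na.rm = TRUE),
                      auc_sd = stats::sd(aucs[!is.na(aucs)])),
       fold_assignment = fold)
}

#' Leave-one-subject-out cross-validation
#'
#' Each round trains on all subjects but one and tests on the held-out
#' subject, so no test subject's epochs ever appear in training.  The
#' dropout rate is set to the subject-independent default of 0.25.
#'
#' @param ep An [epoch_set()] with at least 2 subjects.
#' @param model_config An [ertnet_config()].
#' @param tc A [train_config()].
#' @param dropout Dropout used for the subject-independent protocol
#'   (default 0.25).
#' @return A list with `per_subject` results, `accuracy_mean` and
#'   `subjects`.
#' @export
losocv <- function(ep, model_config, tc = train_config(), dropout = 0.25) {
  subjects <- unique(ep$subject_ids)
  assert_that(length(subjects) >= 2,
              "leave-one-subject-out needs at least 2 subjects")
  model_config$dropout <- dropout
  results <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    te <- which(ep$subject_ids == subjects[i])
    tr <- which(ep$subject_ids != subjects[i])
    model <- build_ertnet(model_config, seed = derive_seed(tc$seed, i))
    tci <- tc; tci$seed <- derive_seed(tc$seed, 2000L + i)
    trained <- fit(model, subset_epochs(ep, tr), tci)$model
    r <- evaluate(trained, subset_epochs(ep, te))
    r$subject <- subjects[i]
    results[[i]] <- r
  }
  accs <- vapply(results, `[[`, 0, "accuracy")
  list(per_subject = results, accuracy_mean = mean(accs),
       accuracy_sd = stats::sd(accs), subjects = subjects)
}
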