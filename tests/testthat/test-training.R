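# Training loop, evaluation metrics, protocols and statistical machinery.

test_that("splitting protocols partition epochs without leakage", {
  ep <- tiny_task(n_per_class = 50, n_subjects = 4)

  sp <- holdout_split(ep, 0.8, seed = 3)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(100L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  # stratification: 40/10 per class
  expect_identical(as.vector(table(sp$train$labels)), c(40L, 40L))
  expect_identical(as.vector(table(sp$test$labels)), c(10L, 10L))
  # seeded determinism
  sp2 <- holdout_split(ep, 0.8, seed = 3)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(holdout_split(ep, 1.0), "inside")

  fold <- ertnet:::.fold_assignment(ep$labels, 10, seed = 5)
  expect_identical(sort(unique(fold)), 1:10)
  for (i in 1:10) {
    expect_identical(as.vector(table(ep$labels[fold == i])), c(5L, 5L))
  }
  expect_warning(ertnet:::.fold_assignment(c(0L, rep(1L, 20)), 5, 1),
                 "plain split")
})

test_that("fit learns a separable task, is seeded, and freezes at lr 0", {
  ep <- tiny_task(n_per_class = 40)
  cfg <- tiny_config()
  m0 <- build_ertnet(cfg, seed = 51)

  r1 <- fit(m0, ep, quick_tc())
  expect_gt(utils::tail(r1$history$accuracy, 1), 0.9)
  # loss non-increasing over a window on this learnable task
  ml <- r1$history$loss
  expect_lt(min(ml), ml[1])

  r2 <- fit(m0, ep, quick_tc())
  expect_identical(utils::tail(r1$history$loss, 1),
                   utils::tail(r2$history$loss, 1))

  r0 <- fit(m0, ep, quick_tc(learning_rate = 0, epochs = 2))
  expect_equal(r0$model$params$Wt, m0$params$Wt, tolerance = 0)
  expect_equal(r0$model$params$Wd, m0$params$Wd, tolerance = 0)
})

test_that("kfold_cv yields disjoint covering folds and near-perfect accuracy
          on a saturating task", {
  ep <- tiny_task(n_per_class = 30, amplitude = 4)
  cfg <- tiny_config()
  cv <- kfold_cv(ep, cfg, quick_tc(epochs = 20), k = 3)
  expect_length(cv$folds, 3)
  expect_identical(sort(unique(cv$fold_assignment)), 1:3)
  expect_gt(cv$summary$accuracy_mean, 90)
  expect_error(kfold_cv(ep, cfg, quick_tc(), k = 1), ">= 2")
})

test_that("losocv never trains on the held-out subject", {
  ep <- tiny_task(n_per_class = 30, n_subjects = 3, amplitude = 4)
  cfg <- tiny_config()
  lv <- losocv(ep, cfg, quick_tc())
  expect_length(lv$per_subject, 3)
  expect_setequal(lv$subjects, unique(ep$subject_ids))
  # same generative process per subject: LOSOCV close to k-fold
  cv <- kfold_cv(ep, cfg, quick_tc(), k = 3)
  expect_lt(abs(lv$accuracy_mean - cv$summary$accuracy_mean), 10)
  one <- subset_epochs(ep, ep$subject_ids == "s01")
  expect_error(losocv(one, cfg, quick_tc()), "2 subjects")
})

test_that("evaluate computes confusion-consistent accuracy and sane AUC", {
  ep <- tiny_task(n_per_class = 40, amplitude = 4)
  m <- fit(build_ertnet(tiny_config(), seed = 61), ep, quick_tc())$model
  r <- evaluate(m, ep)
  expect_identical(sum(r$confusion_matrix), n_epochs(ep))
  expect_identical(as.integer(rowSums(r$confusion_matrix)),
                   as.integer(table(factor(ep$labels, levels = 0:1))))
  expect_equal(r$accuracy,
               100 * sum(diag(r$confusion_matrix)) / n_epochs(ep))
  expect_true(r$auc_macro >= 0 && r$auc_macro <= 1)

  # random scores on balanced labels: AUC ~ 0.5
  set.seed(9)
  sc <- stats::runif(2000)
  y <- rep(c(TRUE, FALSE), 1000)
  expect_equal(ertnet:::.auc_trapezoid(sc, y), 0.5, tolerance = 0.05)
  # perfect separation
  expect_identical(ertnet:::.auc_trapezoid(c(.9, .8, .2, .1),
                                           c(TRUE, TRUE, FALSE, FALSE)), 1)
  # constant scores sit on the chance diagonal
  expect_identical(ertnet:::.auc_trapezoid(rep(0.5, 10),
                                           rep(c(TRUE, FALSE), 5)), 0.5)
})

test_that("trapezoidal and rank-based AUC agree on tie-free scores", {
  set.seed(10)
  for (i in 1:20) {
    sc <- stats::rnorm(60)
    y <- stats::runif(60) < 0.4
    if (!any(y) || all(y)) next
    mw <- ertnet:::.delong_placements(sc[y], sc[!y])$auc
    expect_equal(ertnet:::.auc_trapezoid(sc, y), mw, tolerance = 1e-10)
  }
})

test_that("wilcoxon signed-rank matches exact enumeration and handles
          degenerate input", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p, 1)

  # n = 10, all differences positive: two-sided exact p = 2 / 2^10
  a <- 1:10 + 0.5
  b <- as.numeric(1:10)
  r <- wilcoxon_signed_rank(a, b)
  expect_equal(r$p, 2 / 2^10, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  set.seed(12)
  for (i in 1:5) {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    got <- wilcoxon_signed_rank(x, y)$p
    want <- oracle_wilcoxon_exact(x - y)
    expect_equal(got, want, tolerance = 0.005)
  }
})

test_that("DeLong AUC equals the pairwise oracle and identical scores give
          p = 1", {
  set.seed(13)
  y <- stats::runif(50) < 0.5
  y[1] <- TRUE; y[2] <- FALSE
  s1 <- stats::rnorm(50) + y
  s2 <- 0.8 * s1 + 0.2 * stats::rnorm(50)
  r <- delong_test(s1, s2, y)
  expect_equal(r$auc1, oracle_auc_pairwise(s1, y), tolerance = 1e-12)
  expect_equal(r$auc2, oracle_auc_pairwise(s2, y), tolerance = 1e-12)
  expect_true(r$p >= 0 && r$p <= 1)

  ri <- delong_test(s1, s1, y)
  expect_identical(ri$z, 0)
  expect_identical(ri$p, 1)
  expect_error(delong_test(s1, s2, rep(TRUE, 50)), "both classes")
})

test_that("DeLong agrees with the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- rep(c(TRUE, FALSE), each = 40)
  s1 <- stats::rnorm(80) + y
  s2 <- stats::rnorm(80) + 0.5 * y
  ours <- delong_test(s1, s2, y)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)), tolerance = 1e-8)
})

test_that("multiclass DeLong runs one-vs-rest with Bonferroni", {
  set.seed(15)
  y <- rep(0:2, each = 30)
  s1 <- matrix(stats::runif(270), 90, 3)
  s1[cbind(1:90, y + 1)] <- s1[cbind(1:90, y + 1)] + 1
  s2 <- matrix(stats::runif(270), 90, 3)
  out <- delong_test(s1, s2, y)
  expect_identical(nrow(out), 3L)
  expect_true(all(out$p_bonferroni >= out$p - 1e-12))
  expect_true(all(out$p_bonferroni <= 1))
})

test_that("transfer_init copies the extractor bit-exactly and errors on
          mismatch", {
  cfg_t <- tiny_config()
  cfg_s <- tiny_config(head = "flatten", n_blocks = 0L)
  target <- build_ertnet(cfg_t, seed = 71)
  source <- build_ertnet(cfg_s, seed = 72)
  source$params$Wt <- source$params$Wt + 1        # make them distinguishable

  moved <- transfer_init(target, source)
  for (nm in c("Wt", "Ws", "Wsep_d", "Wsep_p")) {
    expect_identical(moved$params[[nm]], source$params[[nm]])
  }
  expect_identical(moved$params$bn1, source$params$bn1)
  # head stays freshly initialised
  expect_identical(moved$params$blocks, target$params$blocks)

  # extractor activations now agree between source and target
  X <- array(stats::rnorm(3 * 4 * 64), c(3, 4, 64))
  expect_equal(extract_features(moved, X), extract_features(source, X),
               tolerance = 1e-6)

  bad <- build_ertnet(tiny_config(F1 = 4L, D = 1L), seed = 73)
  expect_error(transfer_init(bad, source), "Wt")

  # checkpoint path as source
  path <- file.path(withr::local_tempdir(), "src.json")
  save_checkpoint(source, path)
  moved2 <- transfer_init(target, path)
  expect_equal(moved2$params$Wt, source$params$Wt, tolerance = 1e-12)
})

test_that("random search honours bounds and the F2 rule", {
  ep <- tiny_task(n_per_class = 12)
  space <- search_space(F1 = c(2, 3), T = c(4, 8), D = c(1, 2),
                        heads = c(1, 2))
  sr <- hyperparameter_search(ep, space, budget = 2,
                              tc = quick_tc(epochs = 2), k = 2,
                              pool1 = 2, pool2 = 2, sep_kernel = 4,
                              dropout = 0)
  expect_identical(nrow(sr$trials), 2L)
  expect_true(all(sr$trials$F1 >= 2 & sr$trials$F1 <= 3))
  expect_true(all(sr$trials$F2 == sr$trials$F1 * sr$trials$D))
  expect_s3_class(sr$best, "ertnet_config")
  expect_identical(sr$best$F2, sr$best$F1 * sr$best$D)
})

test_that("sweep returns one row per value", {
  ep <- tiny_task(n_per_class = 12)
  tab <- sweep_parameter(ep, "n_blocks", c(1L), tc = quick_tc(epochs = 2),
                         k = 2, F1 = 2, T = 8, D = 2, pool1 = 2, pool2 = 2,
                         sep_kernel = 4, n_heads = 2, dropout = 0)
  expect_identical(nrow(tab), 1L)
  tab2 <- sweep_parameter(ep, "T", c(4L, 8L), tc = quick_tc(epochs = 2),
                          k = 2, F1 = 2, D = 2, pool1 = 2, pool2 = 2,
                          sep_kernel = 4, n_heads = 2, dropout = 0)
  expect_identical(nrow(tab2), 2L)
  expect_identical(tab2$value, c(4L, 8L))
})

test_that("divergence is reported as an error with diagnostics", {
  ep <- tiny_task(n_per_class = 10)
  m <- build_ertnet(tiny_config(), seed = 81)
  m$params$Wt[1] <- NaN
  expect_error(fit(m, ep, quick_tc(epochs = 2)), "divergence|non-finite")
})
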