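# Statistical comparison machinery: Wilcoxon signed-rank for paired CV
# scores and the fast DeLong test for correlated AUCs on a shared test set.

#' Wilcoxon signed-rank test for paired scores
#'
#' Two-sided test on paired differences; zero differences are dropped
#' first.  The exact null distribution is used for n <= 25 untied
#' differences, otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b Equal-length numeric vectors of paired scores.
#' @return A list with `statistic` (the signed-rank sum V), `p`, `n` (pairs
#'   retained), and `method`.  All-zero differences give `p = 1`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  assert_that(length(a) == length(b), "paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate"))
  }
  if (n < 5L) warning("fewer than 5 non-zero differences; test is weak")
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= 12L) {
    # exact by sign-flip enumeration (handles tied |differences|): the
    # null distribution of V is symmetric about n(n+1)/4
    bits <- as.matrix(expand.grid(rep(list(0:1), n)))
    v_all <- as.vector(bits %*% r)
    ev <- n * (n + 1) / 4
    p <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
    return(list(statistic = v_obs, p = p, n = n, method = "exact"))
  }
  exact <- n <= 25L && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

# Placements for the fast DeLong algorithm via midranks: for each positive
# score the fraction of negatives it beats (ties count 1/2), and vice
# versa.
.delong_placements <- function(x, y) {
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  V10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(auc = mean(V10), V10 = V10, V01 = V01)
}

.delong_binary <- function(s1, s2, positive) {
  p1 <- .delong_placements(s1[positive], s1[!positive])
  p2 <- .delong_placements(s2[positive], s2[!positive])
  m <- sum(positive); n <- sum(!positive)
  S10 <- stats::cov(cbind(p1$V10, p2$V10))
  S01 <- stats::cov(cbind(p1$V01, p2$V01))
  S <- S10 / m + S01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  z <- if (v < 1e-14) 0 else (p1$auc - p2$auc) / sqrt(v)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z,
       p = if (v < 1e-14) 1 else 2 * stats::pnorm(-abs(z)))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score sets over the same labelled test items
#' using the fast DeLong construction: each AUC is the Mann-Whitney
#' statistic and the variance/covariance of the paired difference comes
#' from the structural components (placements) over positives and
#' negatives; the two-sided p-value is normal.  For K > 2 classes the test
#' runs one-vs-rest per class with Bonferroni correction across classes.
#'
#' @param scores1,scores2 Numeric vectors (binary task: score of the
#'   positive class) or `[N x K]` matrices of per-class scores from two
#'   models on the same items.
#' @param labels Binary labels (0/1 or logical) for vector scores; integer
#'   class codes `0..K-1` for matrix scores.
#' @return Binary: list `auc1`, `auc2`, `z`, `p`.  Multiclass: a data frame
#'   with one row per class (`auc1`, `auc2`, `z`, `p`,
#'   `p_bonferroni`).
#' @export
delong_test <- function(scores1, scores2, labels) {
  if (is.matrix(scores1)) {
    K <- ncol(scores1)
    assert_that(is.matrix(scores2) && ncol(scores2) == K,
                "both score matrices must have K columns")
    rows <- lapply(seq_len(K), function(k) {
      pos <- labels == k - 1L
      assert_that(any(pos) && any(!pos),
                  sprintf("class %d absent from the test labels", k - 1L))
      r <- .delong_binary(scores1[, k], scores2[, k], pos)
      data.frame(class = k - 1L, auc1 = r$auc1, auc2 = r$auc2, z = r$z,
                 p = r$p)
    })
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(out$p * K, 1)
    return(out)
  }
  positive <- as.logical(labels)
  assert_that(any(positive) && any(!positive),
              "both classes must be present in the labels")
  assert_that(length(scores1) == length(scores2) &&
                length(scores1) == length(positive),
              "scores and labels must align on the same test items")
  .delong_binary(scores1, scores2, positive)
}
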