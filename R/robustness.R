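#' Label-permutation significance test for cross-validated AUC
#'
#' The true statistic is the pooled out-of-fold CV AUC of the soft-voting
#' ensemble (or a subset of base models) on the real labels. Each
#' iteration shuffles the labels *before* fold assignment and re-runs the
#' entire CV pipeline, preserving every fitting step under the null. The
#' p-value uses the +1-smoothed estimator
#' \eqn{p = (1 + \#\{AUC_{perm} \ge AUC_{true}\}) / (n_{iter} + 1)}, so the
#' smallest attainable value at 1,000 iterations is 1/1001 < 0.001.
#'
#' @inheritParams run_cv
#' @param n_iter Number of permutations.
#' @param models Base models included in the vote.
#' @return List of class `cdi_permutation`: `true_auc`,
#'   `mean_permuted_auc`, `p_value`, `n_iter`, and the vector of permuted
#'   AUCs.
#' @export
permutation_test <- function(X, y, n_iter = 1000, k = 5, seed = 1L,
                             params = default_base_params(),
                             models = c("rf", "xgb", "svm")) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  y <- as.integer(y)
  vote_auc <- function(yy, seed_i) {
    res <- cv_oof(X, yy, k = k, seed = seed_i, params = params)
    auc_rank(yy, rowMeans(res$oof[, models, drop = FALSE]))
  }
  true_auc <- vote_auc(y, seed)
  perm <- vapply(seq_len(n_iter), function(i) {
    set.seed(seed + i)
    vote_auc(sample(y), seed + i)
  }, numeric(1))
  structure(
    list(true_auc = true_auc, mean_permuted_auc = mean(perm),
         p_value = (1 + sum(perm >= true_auc)) / (n_iter + 1),
         n_iter = n_iter, permuted_auc = perm),
    class = "cdi_permutation"
  )
}

#' Bootstrap confidence intervals for pooled out-of-fold performance
#'
#' Stratified resampling (with replacement, within each class) of the
#' pooled out-of-fold (label, probability) pairs; AUC and F1 are recomputed
#' per replicate and summarized by percentile intervals. Pair resampling —
#' rather than refitting models per replicate — quantifies the sampling
#' variability of the performance estimate at desk scale; set
#' `refit = TRUE` (with a model-fitting closure via `cv_args`) to rerun
#' the full CV per replicate at reduced iteration counts.
#'
#' @param y Binary labels of the pooled out-of-fold predictions.
#' @param proba Pooled out-of-fold probabilities.
#' @param n_iter Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param threshold Threshold for F1.
#' @param refit Refit the CV pipeline per replicate (expensive).
#' @param X,cv_args Design matrix and extra [run_cv()] arguments, only used
#'   when `refit = TRUE`.
#' @return Data frame with one row per metric: metric, mean, ci_low,
#'   ci_high, level, n_iter.
#' @export
bootstrap_ci <- function(y, proba, n_iter = 1000, level = 0.95, seed = 1L,
                         threshold = 0.5, refit = FALSE, X = NULL,
                         cv_args = list()) {
  y <- as.integer(y)
  set.seed(seed)
  i1 <- which(y == 1); i0 <- which(y == 0)
  stat <- function(yy, pp) {
    c(auc = auc_rank(yy, pp),
      f1 = compute_metrics(yy, pp, threshold)$f1)
  }
  reps <- vapply(seq_len(n_iter), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    if (refit) {
      cv <- do.call(run_cv, c(list(X = X[idx, , drop = FALSE], y = y[idx],
                                   seed = seed + b), cv_args))
      stat(y[idx], cv$oof[, "ensemble"])
    } else {
      stat(y[idx], proba[idx])
    }
  }, numeric(2))
  alpha <- (1 - level) / 2
  out <- do.call(rbind, lapply(rownames(reps), function(m) {
    q <- stats::quantile(reps[m, ], c(alpha, 1 - alpha), names = FALSE)
    data.frame(metric = m, mean = mean(reps[m, ]), ci_low = q[1],
               ci_high = q[2], level = level, n_iter = n_iter,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
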