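#' Shapley attribution by kernel-weighted coalition regression
#'
#' Explains a probabilistic model around a background sample using the
#' Kernel SHAP formulation: coalitions of features are scored by the model
#' value \eqn{v(S)} — the mean prediction over the background with the
#' coalition's features set to the explained sample's values (marginal /
#' interventional expectations) — and the attributions solve the
#' kernel-weighted least-squares problem whose solution is the Shapley
#' value, subject to the local-accuracy constraint that attributions plus
#' the base value sum exactly to the model's prediction.
#'
#' For `p <= exact_limit` features all \eqn{2^p - 2} proper coalitions are
#' enumerated with exact kernel weights, which recovers exhaustive Shapley
#' values. For larger `p`, coalition sizes are sampled proportionally to
#' the kernel weight (in complementary pairs) and the regression is solved
#' on the sample; local accuracy still holds exactly by the constraint.
#'
#' @param pred_fun Function mapping a numeric matrix (same columns as `X`)
#'   to a numeric prediction per row.
#' @param X Sample-by-feature matrix of instances to explain.
#' @param background Sample-by-feature matrix of background instances.
#' @param n_coalitions Number of sampled coalitions for the approximate
#'   path; default `max(4 * p, 300)` (ignored when enumerating).
#' @param exact_limit Enumerate all coalitions when `p <= exact_limit`.
#' @param seed Integer seed for coalition sampling.
#' @param model Tag stored on the result (e.g. "rf").
#' @return Object of class `cdi_attribution`: `values` (samples x features
#'   attribution matrix), `base_value` (mean background prediction),
#'   `model`.
#' @export
kernel_shap <- function(pred_fun, X, background, n_coalitions = NULL,
                        exact_limit = 12, seed = NULL, model = "model") {
  X <- as.matrix(X)
  background <- as.matrix(background)
  p <- ncol(X)
  stopifnot(p >= 1, ncol(background) == p)
  f0 <- mean(pred_fun(background))
  fx <- pred_fun(X)
  if (p == 1) {
    values <- matrix(fx - f0, ncol = 1, dimnames = list(rownames(X), colnames(X)))
    return(.attribution(values, f0, model))
  }
  if (p <= exact_limit) {
    Z <- .all_coalitions(p)
    s <- rowSums(Z)
    w <- (p - 1) / (choose(p, s) * s * (p - s))
  } else {
    if (!is.null(seed)) set.seed(seed)
    m <- if (is.null(n_coalitions)) max(4L * p, 300L) else as.integer(n_coalitions)
    Z <- .sample_coalitions(p, m)
    w <- rep(1, nrow(Z))  # sampling is already proportional to the kernel
  }
  V <- .coalition_values(pred_fun, X, background, Z)
  phi <- .solve_kernel_shap(Z, w, V, fx, f0)
  dimnames(phi) <- list(rownames(X), colnames(X))
  .attribution(phi, f0, model)
}

.attribution <- function(values, base_value, model) {
  structure(list(values = values, base_value = base_value, model = model),
            class = "cdi_attribution")
}

.all_coalitions <- function(p) {
  g <- as.matrix(expand.grid(rep(list(0:1), p)))
  g <- g[rowSums(g) > 0 & rowSums(g) < p, , drop = FALSE]
  dimnames(g) <- NULL
  g
}

# Paired coalition sampling: sizes drawn with probability proportional to
# the Shapley kernel mass per size, subsets uniform within size, each
# sampled subset included together with its complement.
.sample_coalitions <- function(p, m) {
  sizes <- seq_len(p - 1)
  prob <- 1 / (sizes * (p - sizes))
  half <- ceiling(m / 2)
  s <- sample(sizes, half, replace = TRUE, prob = prob / sum(prob))
  Z <- matrix(0L, 2L * half, p)
  for (j in seq_len(half)) {
    on <- sample.int(p, s[j])
    Z[2L * j - 1L, on] <- 1L
    Z[2L * j, -on] <- 1L
  }
  Z
}

# v(S) per coalition (rows of Z) and explained sample: mean prediction over
# the background with coalition features replaced by the sample's values.
.coalition_values <- function(pred_fun, X, background, Z) {
  m <- nrow(Z); nbg <- nrow(background); p <- ncol(X)
  base <- background[rep(seq_len(nbg), times = m), , drop = FALSE]
  mask <- matrix(as.logical(Z[rep(seq_len(m), each = nbg), ]), ncol = p)
  V <- matrix(NA_real_, m, nrow(X))
  for (i in seq_len(nrow(X))) {
    M <- base
    xrep <- matrix(X[i, ], nrow(M), p, byrow = TRUE)
    M[mask] <- xrep[mask]
    colnames(M) <- colnames(X)
    preds <- pred_fun(M)
    V[, i] <- colMeans(matrix(preds, nrow = nbg))
  }
  V
}

# Constrained weighted least squares: eliminate the last feature through
# the local-accuracy constraint sum(phi) = fx - f0 and solve the reduced
# system once for all explained samples (shared design).
.solve_kernel_shap <- function(Z, w, V, fx, f0) {
  p <- ncol(Z)
  A <- Z[, -p, drop = FALSE] - Z[, p]
  AtW <- t(A * w)
  G <- AtW %*% A
  diag(G) <- diag(G) + 1e-10
  total <- fx - f0
  B <- (V - f0) - outer(Z[, p], total)
  phi_red <- solve(G, AtW %*% B)
  phi <- rbind(phi_red, total - colSums(phi_red))
  t(phi)
}

#' Explain the ensemble's base models and their consensus
#'
#' Runs the coalition explainer ([kernel_shap()]) on each base model's
#' class-1 probability function (on the model's standardized feature
#' scale) and averages the three attribution matrices into the consensus
#' attribution. By linearity of the mean, the consensus inherits local
#' accuracy with respect to the soft-vote probability.
#'
#' @param model A fitted `cdi_ensemble`.
#' @param X Sample-by-feature matrix (raw scale) of instances to explain.
#' @param background Background instances (raw scale); defaults to `X`.
#' @param n_coalitions,exact_limit,seed Passed to [kernel_shap()].
#' @param models Base models to explain.
#' @return Named list of `cdi_attribution` objects (one per base model
#'   plus `consensus`).
#' @export
explain_ensemble <- function(model, X, background = X, n_coalitions = NULL,
                             exact_limit = 12, seed = 1L,
                             models = c("rf", "xgb", "svm")) {
  X <- as.matrix(X)[, model$features, drop = FALSE]
  background <- as.matrix(background)[, model$features, drop = FALSE]
  Xs <- apply_scaler(model$scaler, X)
  Bs <- apply_scaler(model$scaler, background)
  out <- lapply(models, function(k) {
    fit <- model$models[[k]]
    kernel_shap(function(m) predict_base(fit, k, m), Xs, Bs,
                n_coalitions = n_coalitions, exact_limit = exact_limit,
                seed = seed, model = k)
  })
  names(out) <- models
  out$consensus <- consensus_attributions(out)
  out
}

#' Consensus attribution: arithmetic mean of base-model attributions
#'
#' @param matrices List of `cdi_attribution` objects with identical
#'   sample/gene ordering.
#' @return A `cdi_attribution` tagged "consensus" whose values and base
#'   value are the elementwise means.
#' @export
consensus_attributions <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  dims <- lapply(matrices, function(a) dimnames(a$values))
  ok <- all(vapply(matrices, function(a) {
    identical(dim(a$values), dim(matrices[[1]]$values)) &&
      identical(dimnames(a$values), dims[[1]])
  }, logical(1)))
  if (!ok) stop("attribution matrices must share shape and sample/gene ordering")
  values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  base <- mean(vapply(matrices, `[[`, numeric(1), "base_value"))
  .attribution(values, base, "consensus")
}

#' Global gene importance from an attribution matrix
#'
#' Mean absolute attribution per gene across all samples, ranked in
#' descending order with lexicographic tie-breaking on the symbol.
#'
#' @param attrib A `cdi_attribution`.
#' @return Data frame with gene, mean_abs_shap, rank (1 = most important),
#'   ordered by rank.
#' @export
global_importance <- function(attrib) {
  v <- attrib$values
  stopifnot(nrow(v) >= 1)
  mas <- colMeans(abs(v))
  genes <- colnames(v)
  if (is.null(genes)) genes <- sprintf("feature_%03d", seq_along(mas))
  ord <- order(-mas, genes)
  data.frame(gene = genes[ord], mean_abs_shap = unname(mas[ord]),
             rank = seq_along(mas), stringsAsFactors = FALSE)
}

#' Cross-cohort consistency of importance rankings
#'
#' Pairwise Spearman rank correlation of the per-gene mean-|attribution|
#' vectors across cohorts (on their shared gene universe), plus the number
#' of cohorts in which each gene appears in the top `k`.
#'
#' @param rankings Named list of importance tables ([global_importance()]).
#' @param k Top-list size.
#' @return List with `spearman` (cohort-by-cohort correlation matrix),
#'   `topk_counts` (named integer vector over the shared genes), `k`.
#' @export
cross_cohort_consistency <- function(rankings, k = 20) {
  stopifnot(length(rankings) >= 2)
  shared <- sort(Reduce(intersect, lapply(rankings, `[[`, "gene")))
  if (length(shared) == 0) stop("rankings share no genes")
  imp <- vapply(rankings, function(r) {
    stats::setNames(r$mean_abs_shap, r$gene)[shared]
  }, numeric(length(shared)))
  rho <- stats::cor(imp, method = "spearman")
  counts <- integer(length(shared))
  names(counts) <- shared
  k_eff <- min(k, length(shared))
  for (j in seq_len(ncol(imp))) {
    top <- shared[order(-imp[, j], shared)][seq_len(k_eff)]
    counts[top] <- counts[top] + 1L
  }
  list(spearman = rho, topk_counts = counts, k = k_eff)
}

#' Per-gene mechanosensitivity score from strain-cohort attributions
#'
#' For each gene, the raw score is the absolute difference between its mean
#' attribution over mechanically strained samples and over control
#' samples; scores are min-max normalized to `[0, 1]` across genes and
#' categorized as highly (> 0.6), moderately (0.3-0.6, boundaries
#' inclusive) or low (< 0.3) mechanosensitive.
#'
#' @param attrib Consensus `cdi_attribution` on the strain cohort.
#' @param strain_mask Logical per-sample vector, TRUE for strained samples.
#' @param cuts Category cut points (low/moderate and moderate/high).
#' @return Data frame with gene, raw_diff, score, category.
#' @export
mechanosensitivity <- function(attrib, strain_mask, cuts = c(0.3, 0.6)) {
  v <- attrib$values
  strain_mask <- as.logical(strain_mask)
  stopifnot(length(strain_mask) == nrow(v))
  if (!any(strain_mask) || !any(!strain_mask)) {
    stop("both strain and control groups must be non-empty")
  }
  raw <- abs(colMeans(v[strain_mask, , drop = FALSE]) -
               colMeans(v[!strain_mask, , drop = FALSE]))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all raw mechanosensitivity differences are equal; scores set to 0")
    score <- rep(0, length(raw))
  } else {
    score <- (raw - rng[1]) / diff(rng)
  }
  category <- ifelse(score > cuts[2], "high",
                     ifelse(score >= cuts[1], "moderate", "low"))
  genes <- colnames(v)
  if (is.null(genes)) genes <- sprintf("feature_%03d", seq_along(raw))
  data.frame(gene = genes, raw_diff = unname(raw), score = unname(score),
             category = category, stringsAsFactors = FALSE)
}
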