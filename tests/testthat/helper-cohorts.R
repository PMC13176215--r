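# Small cohort specs used across test files. Sizes are kept modest so the
# whole suite stays fast; effect sizes follow the generator defaults unless
# a test needs a specific regime.

small_spec <- function(seed = 1L, ...) {
  args <- list(
    n_genes = 200, n_datasets = 2,
    samples_per_condition = c(healthy = 10, early = 4, advanced = 10),
    n_deg_up = 24, n_deg_down = 6, n_mechano = 8,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_spec, args)
}

# Train a lightweight ensemble on the planted DEGs of a cohort.
fit_on_truth <- function(cohort, seed = 1L, ...) {
  feats <- sort(cohort$truth$deg_genes$gene)
  X <- t(cohort$expr[feats, , drop = FALSE])
  fit_ensemble(X, cohort$meta$class, seed = seed, ...)
}

# Brute-force marginal Shapley values: exhaustive enumeration of all
# coalitions via the permutation-weight formula. Independent of the
# kernel-regression implementation under test.
brute_force_shapley <- function(f, x, bg) {
  p <- length(x)
  v <- function(S) {
    M <- bg
    if (length(S) > 0) {
      M[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
    }
    mean(f(M))
  }
  phi <- numeric(p)
  for (j in seq_len(p)) {
    rest <- setdiff(seq_len(p), j)
    subsets <- unlist(lapply(0:length(rest), function(m) {
      utils::combn(rest, m, simplify = FALSE)
    }), recursive = FALSE)
    phi[j] <- sum(vapply(subsets, function(S) {
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      w * (v(c(S, j)) - v(S))
    }, numeric(1)))
  }
  phi
}
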