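test_that("coalition attributions match exhaustive Shapley values on toy models", {
  set.seed(20)
  n <- 30; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0)
  m <- fit_ensemble(X, y, seed = 21)
  Xs <- cdindex:::apply_scaler(m$scaler, X)
  for (k in c("rf", "xgb", "svm")) {
    f <- function(mm) cdindex:::predict_base(m$models[[k]], k, mm)
    at <- kernel_shap(f, Xs[1:4, , drop = FALSE], Xs, model = k)
    oracle <- t(vapply(1:4, function(i) brute_force_shapley(f, Xs[i, ], Xs),
                       numeric(p)))
    expect_equal(unname(at$values), oracle, tolerance = 1e-8)
    # local accuracy at tree-exact tolerance
    pred <- f(Xs[1:4, , drop = FALSE])
    expect_equal(at$base_value + rowSums(at$values), pred, tolerance = 1e-6)
  }
})

test_that("sampled-coalition attributions are exact for additive models", {
  set.seed(22)
  p <- 40
  w <- runif(p, -1, 1)
  f <- function(M) as.vector(M %*% w)
  X <- matrix(rnorm(6 * p), 6, p, dimnames = list(NULL, paste0("g", 1:p)))
  bg <- matrix(rnorm(25 * p), 25, p, dimnames = list(NULL, paste0("g", 1:p)))
  at <- kernel_shap(f, X, bg, n_coalitions = 300, seed = 23)
  exact <- sweep(X, 2, colMeans(bg)) %*% diag(w)
  expect_equal(unname(at$values), unname(exact), tolerance = 1e-8)
})

test_that("null models and irrelevant features get zero attribution", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  at0 <- kernel_shap(function(M) rep(0.7, nrow(M)), X, X, model = "const")
  expect_equal(at0$base_value, 0.7)
  expect_equal(unname(at0$values), matrix(0, 10, 4), tolerance = 1e-10)
  # model using one feature only
  f1 <- function(M) plogis(M[, 2])
  at1 <- kernel_shap(f1, X, X, model = "single")
  expect_lt(max(abs(at1$values[, c(1, 3, 4)])), 1e-10)
  expect_gt(max(abs(at1$values[, 2])), 0.01)
})

test_that("consensus is the elementwise mean and inherits local accuracy", {
  mk <- function(seed) {
    set.seed(seed)
    cdindex:::.attribution(matrix(rnorm(12), 3, 4,
                                  dimnames = list(paste0("s", 1:3), paste0("g", 1:4))),
                           rnorm(1), "m")
  }
  mats <- list(mk(1), mk(2), mk(3))
  cons <- consensus_attributions(mats)
  expect_equal(cons$values,
               (mats[[1]]$values + mats[[2]]$values + mats[[3]]$values) / 3)
  expect_equal(cons$base_value,
               mean(c(mats[[1]]$base_value, mats[[2]]$base_value, mats[[3]]$base_value)))
  expect_equal(consensus_attributions(list(mats[[1]], mats[[1]], mats[[1]]))$values,
               mats[[1]]$values, tolerance = 1e-14)
  bad <- mk(4); bad$values <- bad$values[, c(2, 1, 3, 4)]
  expect_error(consensus_attributions(list(mats[[1]], bad)), "ordering")
})

test_that("consensus local accuracy holds against the soft-vote probability", {
  sc <- simulate_cohort(small_spec(seed = 24, n_datasets = 1, n_genes = 60,
                                   n_deg_up = 8, n_deg_down = 2, n_mechano = 3,
                                   batch_shift_sd = 0, batch_scale_sd = 0))
  m <- fit_on_truth(sc, seed = 25)
  X <- t(sc$expr[m$features, 1:10])
  ex <- explain_ensemble(m, X, background = t(sc$expr[m$features, ]), seed = 26)
  vote <- predict(m, X, type = "ensemble")
  expect_equal(unname(ex$consensus$base_value + rowSums(ex$consensus$values)),
               unname(vote), tolerance = 1e-8)
})

test_that("global importance ranks by mean absolute attribution with lexicographic ties", {
  v <- matrix(c(0.2, -0.2, 0, 0, 0.1, 0.3), 2, 3,
              dimnames = list(NULL, c("zeta", "alpha", "mid")))
  imp <- global_importance(cdindex:::.attribution(v, 0, "x"))
  expect_equal(imp$mean_abs_shap, c(0.2, 0.2, 0))
  # tie between zeta (0.2) and mid (0.2): alphabetical order wins
  expect_identical(imp$gene, c("mid", "zeta", "alpha"))
  expect_identical(imp$rank, 1:3)
  set.seed(27)
  vr <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("g", 1:5)))
  impr <- global_importance(cdindex:::.attribution(vr, 0, "x"))
  expect_equal(sort(impr$mean_abs_shap, decreasing = TRUE),
               unname(sort(colMeans(abs(vr)), decreasing = TRUE)))
})

test_that("cross-cohort consistency detects identical, reversed and random rankings", {
  genes <- sprintf("G%02d", 1:93)
  set.seed(28)
  base_imp <- sort(runif(93), decreasing = TRUE)
  mk_rank <- function(values) {
    data.frame(gene = genes, mean_abs_shap = values)
  }
  same <- lapply(1:5, function(i) mk_rank(base_imp))
  names(same) <- paste0("c", 1:5)
  rep1 <- cross_cohort_consistency(same, k = 20)
  expect_true(all(abs(rep1$spearman - 1) < 1e-12))
  expect_equal(sort(unname(rep1$topk_counts), decreasing = TRUE)[1:20], rep(5L, 20))
  rev2 <- list(a = mk_rank(base_imp), b = mk_rank(rev(base_imp)))
  expect_equal(cross_cohort_consistency(rev2)$spearman["a", "b"], -1)
  # random rankings center near zero correlation
  rhos <- replicate(100, {
    r <- list(a = mk_rank(sample(base_imp)), b = mk_rank(sample(base_imp)))
    cross_cohort_consistency(r)$spearman["a", "b"]
  })
  expect_lt(abs(mean(rhos)), 0.1)
  bad <- list(a = mk_rank(base_imp),
              b = data.frame(gene = paste0("X", 1:5), mean_abs_shap = runif(5)))
  expect_error(cross_cohort_consistency(bad), "share no genes")
})

test_that("mechanosensitivity scores normalize to [0,1] and honor the category cuts", {
  v <- rbind(strain1 = c(1.0, 0.5, 0.30, 0.1),
             strain2 = c(1.0, 0.5, 0.30, 0.1),
             ctrl1 = c(0.0, 0.2, 0.25, 0.1),
             ctrl2 = c(0.0, 0.2, 0.25, 0.1))
  colnames(v) <- c("big", "mid", "small", "flat")
  at <- cdindex:::.attribution(v, 0, "consensus")
  tab <- mechanosensitivity(at, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab$raw_diff, c(1.0, 0.3, 0.05, 0))
  expect_equal(range(tab$score), c(0, 1))
  expect_equal(tab$category, c("high", "moderate", "low", "low"))
  # boundary scores 0.3 and 0.6 are moderate
  expect_equal(unname(cut_cat <- mechanosensitivity(
    cdindex:::.attribution(rbind(a = c(1, 0.6, 0.3, 0), b = c(1, 0.6, 0.3, 0),
                                 c = c(0, 0, 0, 0), d = c(0, 0, 0, 0)),
                           0, "consensus"),
    c(TRUE, TRUE, FALSE, FALSE))$category), c("high", "moderate", "moderate", "low"))
  # min-max scores invariant to affine rescaling of the attribution scale
  at2 <- cdindex:::.attribution(v * 7 , 0, "consensus")
  tab2 <- mechanosensitivity(at2, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tab2$score, tab$score, tolerance = 1e-12)
  # categories always partition the gene set
  expect_equal(sum(table(tab$category)), ncol(v))
  expect_error(mechanosensitivity(at, rep(TRUE, 4)), "non-empty")
  expect_warning(
    mechanosensitivity(cdindex:::.attribution(matrix(1, 4, 3), 0, "c"),
                       c(TRUE, TRUE, FALSE, FALSE)),
    "equal")
})

test_that("planted strain-responsive genes carry the attribution contrast", {
  spec <- small_spec(seed = 29, n_genes = 150, strain_effect = 2,
                     batch_shift_sd = 0.5)
  tr <- simulate_cohort(spec)
  st <- simulate_strain_cohort(spec)
  m <- fit_on_truth(tr, seed = 30)
  Xs <- t(st$expr[m$features, ])
  ex <- explain_ensemble(m, Xs, background = Xs[!st$meta$strain, ],
                         n_coalitions = 400, seed = 31)
  mech <- mechanosensitivity(ex$consensus, st$meta$strain)
  planted <- st$truth$mechano_genes
  others <- setdiff(mech$gene, planted)
  # strain-responsive genes dominate the raw contrast on average
  expect_gt(mean(mech$raw_diff[mech$gene %in% planted]),
            2 * mean(mech$raw_diff[mech$gene %in% others]))
  # with zero strain effect no gene reaches a stable high category
  spec0 <- small_spec(seed = 29, n_genes = 150, strain_effect = 0,
                      batch_shift_sd = 0.5)
  st0 <- simulate_strain_cohort(spec0)
  ex0 <- explain_ensemble(m, t(st0$expr[m$features, ]),
                          background = Xs[!st$meta$strain, ],
                          n_coalitions = 400, seed = 32)
  mech0 <- mechanosensitivity(ex0$consensus, st0$meta$strain)
  expect_lt(max(mech0$raw_diff), max(mech$raw_diff))
})
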