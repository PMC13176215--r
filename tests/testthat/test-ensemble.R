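test_that("stratified folds preserve class ratios and partition the samples", {
  y <- rep(c(1L, 0L), c(60, 60))
  f <- stratified_kfold(y, k = 5, seed = 1)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 12)
    expect_equal(sum(f == k & y == 0), 12)
  }
  # the 59/63 split: per-fold counts within 1 of proportionality
  y2 <- rep(c(1L, 0L), c(59, 63))
  f2 <- stratified_kfold(y2, k = 5, seed = 2)
  expect_equal(as.integer(sort(table(f2[y2 == 1]))), c(11L, 12L, 12L, 12L, 12L))
  expect_equal(as.integer(sort(table(f2[y2 == 0]))), c(12L, 12L, 13L, 13L, 13L))
  expect_equal(length(f2), 122)
  expect_error(stratified_kfold(rep(c(1L, 0L), c(3, 50)), k = 5), "fewer")
})

test_that("soft vote is the arithmetic mean", {
  expect_equal(soft_vote(c(0.9, 0.6, 0.6)), 0.7)
  expect_equal(soft_vote(c(0.3, 0.3, 0.3)), 0.3)
  set.seed(3)
  m <- matrix(runif(300), 100, 3)
  expect_equal(soft_vote(m), (m[, 1] + m[, 2] + m[, 3]) / 3)
})

test_that("metrics match brute-force definitions and pROC", {
  set.seed(4)
  y <- rbinom(80, 1, 0.5)
  p <- runif(80)
  p[sample(80, 10)] <- p[sample(80, 10)]  # introduce ties
  met <- compute_metrics(y, p)
  # all-pairs concordance oracle for AUC
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  conc <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                      ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(met$auc, conc, tolerance = 1e-12)
  expect_equal(met$auc,
               as.numeric(suppressMessages(
                 pROC::auc(y, p, direction = "<", levels = c(0, 1)))),
               tolerance = 1e-9)
  expect_equal(met$brier, mean((p - y)^2))
  # degenerate predictors
  expect_equal(compute_metrics(y, rep(0.5, 80))$auc, 0.5)
  expect_equal(compute_metrics(y, rep(0.5, 80))$brier, 0.25)
  perfect <- compute_metrics(y, y * 0.98 + 0.01)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)
  expect_error(auc_rank(rep(1, 5), runif(5)), "both classes")
})

test_that("ensemble probability is exactly the mean of base probabilities", {
  sc <- simulate_cohort(small_spec(seed = 5, n_datasets = 1,
                                   batch_shift_sd = 0, batch_scale_sd = 0))
  m <- fit_on_truth(sc, seed = 6)
  X <- t(sc$expr[m$features, ])
  pr <- predict(m, X, type = "all")
  expect_identical(pr[, "ensemble"], rowMeans(pr[, c("rf", "xgb", "svm")]))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(predict(m, X[, -1]), "missing model features")
})

test_that("held-out rows never influence the fitted standardizer", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  tr <- 1:40
  s1 <- cdindex:::fit_scaler(X[tr, ])
  X2 <- X
  X2[-tr, ] <- X2[-tr, ] + 100  # perturb only held-out rows
  s2 <- cdindex:::fit_scaler(X2[tr, ])
  expect_identical(s1, s2)
})

test_that("cross-validation separates a planted cohort and is deterministic", {
  spec <- cohort_spec(
    n_genes = 400, n_datasets = 1, batch_shift_sd = 0, batch_scale_sd = 0,
    samples_per_condition = c(healthy = 60, advanced = 60),
    condition_grades = c(healthy = 0, advanced = 1),
    n_deg_up = 74, n_deg_down = 19, deg_effect = 1.5, n_mechano = 0, seed = 8
  )
  sc <- simulate_cohort(spec)
  X <- t(sc$expr[sort(sc$truth$deg_genes$gene), ])
  y <- sc$meta$class
  cv <- run_cv(X, y, k = 5, seed = 9)
  ens <- cv$metrics[cv$metrics$model == "ensemble", ]
  expect_gt(ens$auc, 0.95)
  expect_lt(ens$cv_train_gap, 0.1)
  expect_equal(ens$cv_train_gap, ens$train_auc - ens$auc)
  # determinism: identical folds and metrics on rerun
  cv2 <- run_cv(X, y, k = 5, seed = 9)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$metrics, cv2$metrics)
  # invariance to sample ordering (fold assignment keyed to sorted ids)
  perm <- sample(nrow(X))
  cv3 <- run_cv(X[perm, ], y[perm], k = 5, seed = 9)
  expect_equal(cv3$oof[rownames(X), "ensemble"], cv$oof[, "ensemble"],
               tolerance = 1e-9)
  # shuffled labels destroy the signal
  set.seed(10)
  cvnull <- run_cv(X, sample(y), k = 5, seed = 9)
  expect_lt(abs(cvnull$metrics$auc[cvnull$metrics$model == "ensemble"] - 0.5), 0.15)
})

test_that("randomized search samples within the stated ranges and n_iter=1 returns its draw", {
  space <- default_hyperparam_space()
  set.seed(11)
  for (i in 1:50) {
    h <- cdindex:::sample_hyperparams(space, "xgb")
    expect_true(h$nrounds >= 50 && h$nrounds <= 400)
    expect_true(h$max_depth >= 2 && h$max_depth <= 8)
    expect_true(h$learning_rate >= 0.01 && h$learning_rate <= 0.31)
    expect_true(h$subsample >= 0.5 && h$subsample <= 1)
    s <- cdindex:::sample_hyperparams(space, "svm")
    expect_true(s$cost >= 0.01 && s$cost <= 50)
    expect_true(s$kernel %in% c("radial", "linear"))
    r <- cdindex:::sample_hyperparams(space, "rf")
    expect_true(r$num_trees >= 100 && r$num_trees <= 500)
  }
  # degenerate search: one draw is the selected configuration
  sc <- simulate_cohort(small_spec(seed = 12, n_datasets = 1,
                                   batch_shift_sd = 0, batch_scale_sd = 0))
  X <- t(sc$expr[sort(sc$truth$deg_genes$gene), ])
  Xs <- cdindex:::apply_scaler(cdindex:::fit_scaler(X), X)
  y <- sc$meta$class
  tuned <- cdindex:::tune_base_model("xgb", Xs, y, space, n_iter = 1, seed = 13)
  set.seed(13)
  expected <- cdindex:::sample_hyperparams(space, "xgb")
  expect_identical(tuned$params, expected)
})

test_that("ablation covers all seven configurations consistently", {
  sc <- simulate_cohort(small_spec(seed = 14, n_datasets = 1,
                                   batch_shift_sd = 0, batch_scale_sd = 0))
  X <- t(sc$expr[sort(sc$truth$deg_genes$gene), ])
  y <- sc$meta$class
  ab <- ablation(X, y, k = 3, seed = 15)
  expect_equal(nrow(ab), 7)
  expect_setequal(ab$n_models, c(1, 1, 1, 2, 2, 2, 3))
  # singleton rows equal the base model's own out-of-fold metrics
  res <- cdindex:::cv_oof(X, y, k = 3, seed = 15)
  svm_only <- compute_metrics(y, res$oof[, "svm"])
  expect_equal(ab$auc[ab$configuration == "svm"], svm_only$auc)
  pair <- compute_metrics(y, rowMeans(res$oof[, c("rf", "svm")]))
  expect_equal(ab$auc[ab$configuration == "rf+svm"], pair$auc)
  expect_equal(ab$auc[ab$configuration == "rf+xgb+svm"],
               compute_metrics(y, res$oof[, "ensemble"])$auc)
})

test_that("single-class training splits are rejected", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_error(fit_ensemble(X, rep(1L, 10)), "single class")
})
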