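#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds so that each fold's class counts
#' differ from perfect proportionality by at most one sample per class.
#'
#' @param labels Binary (0/1) class vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 5, seed = NULL) {
  labels <- as.integer(labels)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    }
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Default hyperparameter search space for the three base learners
#'
#' Ranges: random forest — trees 100-500, depth \{3, 5, 7, 10, unbounded\},
#' feature fraction \{sqrt, log2, 0.3-0.7\}; gradient boosting — rounds
#' 50-400, depth 2-8, learning rate 0.01-0.31 (log scale), subsample
#' 0.5-1; margin classifier — C 0.01-50 and gamma 1e-4-1e-1 (both log
#' scale), kernel \{radial, linear\}.
#'
#' @return Nested list of per-model parameter ranges.
#' @export
default_hyperparam_space <- function() {
  list(
    rf = list(num_trees = c(100L, 500L), max_depth = c(3L, 5L, 7L, 10L, 0L),
              max_features = list("sqrt", "log2", c(0.3, 0.7))),
    xgb = list(nrounds = c(50L, 400L), max_depth = c(2L, 8L),
               learning_rate = c(0.01, 0.31), subsample = c(0.5, 1.0)),
    svm = list(cost = c(0.01, 50), gamma = c(1e-4, 1e-1),
               kernel = c("radial", "linear"))
  )
}

#' Fixed modest hyperparameters for the three base learners
#'
#' A lightweight configuration used when randomized search is disabled —
#' e.g. inside permutation loops where the cross-validation pipeline is
#' re-run many hundreds of times.
#'
#' @return Nested list of per-model parameters.
#' @export
default_base_params <- function() {
  list(
    rf = list(num_trees = 100L, max_depth = 0L, max_features = "sqrt"),
    xgb = list(nrounds = 40L, max_depth = 3L, learning_rate = 0.3, subsample = 1.0),
    svm = list(cost = 1, gamma = NULL, kernel = "radial")
  )
}

# One random draw from a model's search space. Multiplicative parameters
# (learning rate, C, gamma) are sampled log-uniformly.
sample_hyperparams <- function(space, kind) {
  sp <- space[[kind]]
  runif_int <- function(r) sample(seq(r[1], r[2]), 1L)
  runif_log <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  switch(kind,
    rf = {
      mf <- sp$max_features[[sample.int(length(sp$max_features), 1L)]]
      if (is.numeric(mf)) mf <- stats::runif(1, mf[1], mf[2])
      list(num_trees = runif_int(sp$num_trees),
           max_depth = sample(sp$max_depth, 1L),
           max_features = mf)
    },
    xgb = list(nrounds = runif_int(sp$nrounds),
               max_depth = runif_int(sp$max_depth),
               learning_rate = runif_log(sp$learning_rate),
               subsample = stats::runif(1, sp$subsample[1], sp$subsample[2])),
    svm = list(cost = runif_log(sp$cost),
               gamma = runif_log(sp$gamma),
               kernel = sample(sp$kernel, 1L)),
    stop("unknown model kind: ", kind)
  )
}

# ---- scaling ---------------------------------------------------------------

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, X) {
  scale(X, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

# ---- base models -----------------------------------------------------------

.mtry_from <- function(max_features, p) {
  m <- if (identical(max_features, "sqrt")) sqrt(p)
  else if (identical(max_features, "log2")) log2(p)
  else max_features * p
  max(1L, min(p, floor(m)))
}

fit_base_model <- function(kind, X, y, params, seed = 1L) {
  y <- factor(y, levels = c(0, 1))
  if (length(unique(y[!is.na(y)])) < 2 || any(table(y) == 0)) {
    stop("training split contains a single class; cannot fit ", kind)
  }
  switch(kind,
    rf = ranger::ranger(
      x = X, y = y, probability = TRUE,
      num.trees = params$num_trees,
      max.depth = params$max_depth,
      mtry = .mtry_from(params$max_features, ncol(X)),
      num.threads = 1L, seed = seed
    ),
    xgb = {
      dtr <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth,
                      eta = params$learning_rate,
                      subsample = params$subsample,
                      nthread = 1L, seed = seed),
        data = dtr, nrounds = params$nrounds, verbose = 0
      )
    },
    svm = {
      set.seed(seed)  # Platt-style probability calibration resamples internally
      g <- params$gamma
      if (is.null(g)) g <- 1 / ncol(X)
      e1071::svm(x = X, y = y, kernel = params$kernel, cost = params$cost,
                 gamma = g, probability = TRUE)
    },
    stop("unknown model kind: ", kind)
  )
}

predict_base <- function(fit, kind, X) {
  switch(kind,
    rf = unname(stats::predict(fit, data = X, num.threads = 1L)$predictions[, "1"]),
    xgb = unname(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1L))),
    svm = unname(attr(stats::predict(fit, X, probability = TRUE),
                      "probabilities")[, "1"]),
    stop("unknown model kind: ", kind)
  )
}

# Randomized search for one base model: n_iter draws evaluated by inner
# stratified CV AUC on the training split only; best config returned.
tune_base_model <- function(kind, X, y, space, n_iter = 80, inner_k = 3,
                            seed = 1L) {
  set.seed(seed)
  configs <- lapply(seq_len(n_iter), function(i) sample_hyperparams(space, kind))
  folds <- stratified_kfold(y, k = inner_k, seed = seed + 1L)
  aucs <- vapply(seq_along(configs), function(ci) {
    oof <- numeric(length(y))
    for (f in seq_len(inner_k)) {
      tr <- folds != f
      fit <- fit_base_model(kind, X[tr, , drop = FALSE], y[tr],
                            configs[[ci]], seed = seed + 13L * ci + f)
      oof[!tr] <- predict_base(fit, kind, X[!tr, , drop = FALSE])
    }
    auc_rank(y, oof)
  }, numeric(1))
  list(params = configs[[which.max(aucs)]], cv_auc = max(aucs))
}

#' Fit the three-model soft-voting ensemble on a training split
#'
#' Fits the per-feature standardizer on the training data only, optionally
#' tunes each base model by randomized search (inner stratified CV on the
#' training split), then fits the random forest, gradient-boosted trees and
#' calibrated margin classifier on the standardized training data. The
#' ensemble prediction is the equal-weight (1/3) arithmetic mean of the
#' three class-1 probabilities.
#'
#' @param X Sample-by-feature numeric matrix (features = selected DEGs).
#' @param y Binary 0/1 labels.
#' @param params Fixed per-model hyperparameters ([default_base_params()]);
#'   ignored for tuned models when `tune = TRUE`.
#' @param tune Run randomized hyperparameter search per base model.
#' @param space Search space ([default_hyperparam_space()]).
#' @param search_iter Randomized-search iterations per model.
#' @param inner_k Inner CV folds for the search.
#' @param seed Integer seed.
#' @return Object of class `cdi_ensemble`: base model fits, standardizer,
#'   feature list, voting weights, and the hyperparameters used.
#' @export
fit_ensemble <- function(X, y, params = default_base_params(), tune = FALSE,
                         space = default_hyperparam_space(), search_iter = 80,
                         inner_k = 3, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  kinds <- c("rf", "xgb", "svm")
  used <- params
  if (tune) {
    for (k in kinds) {
      used[[k]] <- tune_base_model(k, Xs, y, space, n_iter = search_iter,
                                   inner_k = inner_k, seed = seed)$params
    }
  }
  models <- lapply(seq_along(kinds), function(i) {
    fit_base_model(kinds[i], Xs, y, used[[kinds[i]]], seed = seed + i)
  })
  names(models) <- kinds
  structure(
    list(models = models, scaler = scaler, features = colnames(X),
         params = used, weights = rep(1 / 3, 3), seed = seed),
    class = "cdi_ensemble"
  )
}

#' Predict class-1 probabilities from a fitted ensemble
#'
#' @param object A `cdi_ensemble` from [fit_ensemble()].
#' @param X_new Sample-by-feature matrix containing at least the model's
#'   features (extra columns are ignored; missing ones are an error).
#' @param type "ensemble" for the soft-vote probability, "all" for a matrix
#'   with per-model columns plus the ensemble.
#' @param models Base models to include in the vote (default all three).
#' @param ... Unused.
#' @return Numeric vector (or matrix for `type = "all"`) of probabilities.
#' @export
predict.cdi_ensemble <- function(object, X_new,
                                 type = c("ensemble", "all"),
                                 models = names(object$models), ...) {
  type <- match.arg(type)
  X_new <- as.matrix(X_new)
  missing <- setdiff(object$features, colnames(X_new))
  if (length(missing) > 0) {
    stop("missing model features: ", paste(missing, collapse = ", "))
  }
  Xs <- apply_scaler(object$scaler, X_new[, object$features, drop = FALSE])
  probs <- vapply(models, function(k) predict_base(object$models[[k]], k, Xs),
                  numeric(nrow(Xs)))
  probs <- matrix(probs, nrow = nrow(Xs), dimnames = list(rownames(X_new), models))
  ens <- rowMeans(probs)
  if (type == "ensemble") return(ens)
  cbind(probs, ensemble = ens)
}

#' Equal-weight soft vote over base-model probabilities
#'
#' @param probas Numeric vector of one probability per base model, or a
#'   sample-by-model matrix.
#' @return The arithmetic mean (per sample for a matrix).
#' @export
soft_vote <- function(probas) {
  if (is.matrix(probas)) rowMeans(probas) else mean(probas)
}

# ---- metrics ---------------------------------------------------------------

#' Rank-based (Mann-Whitney) AUC with tie correction
#'
#' @param y Binary 0/1 labels (both classes present).
#' @param proba Predicted scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y, proba) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes present")
  r <- rank(proba)  # midranks handle ties as half-concordances
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for probabilistic predictions
#'
#' Accuracy, precision, recall and F1 at the stated threshold, rank-based
#' AUC, and the Brier score (mean squared difference between probability
#' and outcome).
#'
#' @inheritParams auc_rank
#' @param threshold Classification cut for the thresholded metrics.
#' @return Named list of metric values.
#' @export
compute_metrics <- function(y, proba, threshold = 0.5) {
  y <- as.integer(y)
  pred <- as.integer(proba >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(
    accuracy = mean(pred == y), precision = precision, recall = recall,
    f1 = f1, auc = auc_rank(y, proba), brier = mean((proba - y)^2)
  )
}

# Out-of-fold probabilities for all base models + ensemble under stratified
# k-fold CV. The standardizer and (optional) hyperparameter search are
# re-fit within each fold's training split only, so held-out rows never
# touch any fitted statistic. Fold assignment is keyed to sorted sample ids
# when rownames are present, making the result invariant to row order.
cv_oof <- function(X, y, k = 5, seed = 1L, params = default_base_params(),
                   tune = FALSE, space = default_hyperparam_space(),
                   search_iter = 80, compute_train_auc = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  # work in sorted-sample-id order so the whole CV (fold assignment and
  # model fits) is invariant to the caller's row ordering
  ord <- if (!is.null(rownames(X))) order(rownames(X)) else seq_len(n)
  Xo <- X[ord, , drop = FALSE]
  yo <- y[ord]
  folds_o <- stratified_kfold(yo, k = k, seed = seed)
  kinds <- c("rf", "xgb", "svm")
  oof_o <- matrix(NA_real_, n, 3, dimnames = list(rownames(Xo), kinds))
  train_auc <- matrix(NA_real_, k, 3, dimnames = list(NULL, kinds))
  for (f in seq_len(k)) {
    tr <- folds_o != f
    fit <- fit_ensemble(Xo[tr, , drop = FALSE], yo[tr], params = params,
                        tune = tune, space = space, search_iter = search_iter,
                        seed = seed + 100L * f)
    pr <- predict(fit, Xo[!tr, , drop = FALSE], type = "all")
    oof_o[!tr, ] <- pr[, kinds]
    if (compute_train_auc) {
      ptr <- predict(fit, Xo[tr, , drop = FALSE], type = "all")
      train_auc[f, ] <- vapply(kinds, function(kd) auc_rank(yo[tr], ptr[, kd]),
                               numeric(1))
    }
  }
  inv <- order(ord)
  folds <- folds_o[inv]
  oof <- oof_o[inv, , drop = FALSE]
  rownames(oof) <- rownames(X)
  list(oof = cbind(oof, ensemble = rowMeans(oof)), folds = folds,
       train_auc = train_auc, y = y)
}

#' Stratified cross-validation of the ensemble and its base models
#'
#' Runs leakage-safe stratified k-fold CV (in-fold standardization and,
#' optionally, in-fold randomized hyperparameter search), pools the
#' out-of-fold probabilities, and computes per-model and ensemble metrics
#' on the pooled predictions. The training AUC is computed on each fold's
#' training split and averaged; its difference from the out-of-fold AUC
#' (the CV-train gap) is an overfitting indicator.
#'
#' @inheritParams fit_ensemble
#' @param k Number of folds.
#' @param threshold Classification threshold for accuracy/precision/
#'   recall/F1.
#' @return List with `metrics` (data.frame, one row per model and for the
#'   ensemble), `oof` (pooled out-of-fold probability matrix), `folds`
#'   (fold assignment) and `y`.
#' @export
run_cv <- function(X, y, k = 5, seed = 1L, params = default_base_params(),
                   tune = FALSE, space = default_hyperparam_space(),
                   search_iter = 80, threshold = 0.5) {
  res <- cv_oof(X, y, k = k, seed = seed, params = params, tune = tune,
                space = space, search_iter = search_iter,
                compute_train_auc = TRUE)
  models <- colnames(res$oof)
  metrics <- do.call(rbind, lapply(models, function(m) {
    met <- compute_metrics(res$y, res$oof[, m], threshold = threshold)
    tr_auc <- if (m == "ensemble") {
      mean(rowMeans(res$train_auc))
    } else {
      mean(res$train_auc[, m])
    }
    data.frame(model = m, as.data.frame(met), train_auc = tr_auc,
               cv_train_gap = tr_auc - met$auc, stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  list(metrics = metrics, oof = res$oof, folds = res$folds, y = res$y)
}

#' Ablation over all non-empty base-model subsets
#'
#' Evaluates every combination of the three base models (7 in total) on the
#' same out-of-fold probabilities: a subset's vote is the equal-weight mean
#' of its members' probabilities, and singleton subsets are the base model
#' alone.
#'
#' @inheritParams run_cv
#' @return Data frame with one row per configuration and the metrics of
#'   [compute_metrics()].
#' @export
ablation <- function(X, y, k = 5, seed = 1L, params = default_base_params(),
                     threshold = 0.5) {
  res <- cv_oof(X, y, k = k, seed = seed, params = params)
  kinds <- c("rf", "xgb", "svm")
  subsets <- unlist(lapply(seq_along(kinds), function(m) {
    utils::combn(kinds, m, simplify = FALSE)
  }), recursive = FALSE)
  out <- do.call(rbind, lapply(subsets, function(s) {
    proba <- rowMeans(res$oof[, s, drop = FALSE])
    data.frame(configuration = paste(s, collapse = "+"),
               n_models = length(s),
               as.data.frame(compute_metrics(res$y, proba, threshold)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
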