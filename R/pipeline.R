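#' Default configuration for the end-to-end CDI pipeline
#'
#' Collects every analysis constant in one declarative object: the
#' synthetic cohort spec (or paths to on-disk TSV inputs), the DEG
#' thresholds (FDR 0.05, |log2FC| 0.5), the cross-validation block (5
#' folds, 80 randomized-search iterations when tuning), the robustness
#' iteration counts, the mechanosensitivity cuts (0.3/0.6) and the
#' enrichment settings.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param ... Named overrides merged (shallowly per block) into the
#'   defaults, e.g. `deg = list(fdr_max = 0.1)`.
#' @return A nested configuration list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    spec = cohort_spec(seed = seed),
    strain = list(n_per_group = 9, grade = 0.5),
    deg = list(fdr_max = 0.05, lfc_min = 0.5),
    cv = list(k = 5, tune = FALSE, search_iter = 80, threshold = 0.5),
    robustness = list(permutation_iter = 200, bootstrap_iter = 1000),
    attribution = list(n_coalitions = NULL, background_size = 50,
                       mechano_cuts = c(0.3, 0.6)),
    enrichment = list(n_sets = 50, enriched_fraction = 0.8,
                      fdr_max = 0.05, min_size = 3, max_size = 500),
    refit_full = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys mirror
#'   [pipeline_config()]; the `spec` block is passed to [cohort_spec()].
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$spec
  y$spec <- NULL
  seed <- if (!is.null(y$seed)) y$seed else 1L
  cfg <- do.call(pipeline_config, c(list(seed = seed), y[setdiff(names(y), "seed")]))
  if (!is.null(spec_args)) {
    if (!is.null(spec_args$samples_per_condition)) {
      spec_args$samples_per_condition <- unlist(spec_args$samples_per_condition)
    }
    if (!is.null(spec_args$condition_grades)) {
      spec_args$condition_grades <- unlist(spec_args$condition_grades)
    }
    cfg$spec <- do.call(cohort_spec, c(spec_args, list(seed = cfg$seed)))
  }
  cfg
}

#' Run the full synthetic-cohort CDI analysis
#'
#' Executes the stages in order: simulate (multi-batch training cohort,
#' held-out spectrum cohort, strain mini-cohort, gene-set collection),
#' harmonize (per-dataset quantile normalization + batch correction with
#' PCA diagnostics), DEG selection, ensemble cross-validation and final
#' fit, CDI scoring of the held-out cohorts, robustness (permutation test
#' and bootstrap intervals), attribution (consensus importance and
#' mechanosensitivity), and pathway enrichment with attribution-weighted
#' scores. With a fixed config the run is deterministic end to end.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table/report is
#'   written there (TSV/JSON) together with a `manifest.json` recording the
#'   configuration, seeds and artifact list.
#' @return (Invisibly) a named list with the results of every stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed

  sim <- stage("simulate", {
    train <- simulate_cohort(config$spec, role = "training")
    spectrum <- simulate_cohort(config$spec, role = "validation",
                                sample_seed = seed + 7L)
    strain <- simulate_strain_cohort(config$spec,
                                     n_per_group = config$strain$n_per_group,
                                     grade = config$strain$grade)
    sets <- simulate_gene_sets(rownames(train$expr), train$truth,
                               n_sets = config$enrichment$n_sets,
                               enriched_fraction = config$enrichment$enriched_fraction,
                               seed = seed + 11L)
    list(train = train, spectrum = spectrum, strain = strain, gene_sets = sets)
  })

  harm <- stage("harmonize", {
    # all cohorts are corrected jointly, each dataset one batch, and split
    # back afterwards — cohort-wise correction would leave per-gene
    # cross-cohort location shifts (the pooled batch mean) in place
    split_batch <- function(co, prefix) {
      mats <- lapply(split(seq_len(ncol(co$expr)), co$meta$batch),
                     function(j) co$expr[, j, drop = FALSE])
      names(mats) <- paste(prefix, names(mats), sep = ".")
      mats
    }
    mats <- c(split_batch(sim$train, "train"),
              split_batch(sim$spectrum, "val"),
              split_batch(sim$strain, "mech"))
    harmonize_cohorts(mats)
  })
  take <- function(co) {
    harm$expr[, intersect(colnames(harm$expr), co$meta$sample_id), drop = FALSE]
  }
  train_expr <- take(sim$train)
  meta <- sim$train$meta[match(colnames(train_expr), sim$train$meta$sample_id), ]

  deg <- stage("deg", {
    run_deg(train_expr, stats::setNames(meta$class, meta$sample_id),
            fdr_max = config$deg$fdr_max, lfc_min = config$deg$lfc_min)
  })
  features <- deg$gene[deg$selected]
  if (length(features) < 2) {
    stop("pipeline stage 'deg' failed: fewer than 2 genes passed selection")
  }

  Xtr <- t(train_expr[features, , drop = FALSE])
  ytr <- meta$class
  cv <- stage("train", {
    run_cv(Xtr, ytr, k = config$cv$k, seed = seed + 21L,
           tune = config$cv$tune, search_iter = config$cv$search_iter,
           threshold = config$cv$threshold)
  })
  model <- stage("train", {
    fit_ensemble(Xtr, ytr, tune = config$cv$tune,
                 search_iter = config$cv$search_iter, seed = seed + 22L)
  })

  validation <- stage("validate", {
    cohorts <- list(
      spectrum = list(expr = take(sim$spectrum), meta = sim$spectrum$meta),
      strain = list(expr = take(sim$strain), meta = sim$strain$meta)
    )
    validate_cohorts(model, cohorts)
  })

  robustness <- stage("robustness", {
    perm <- permutation_test(Xtr, ytr, n_iter = config$robustness$permutation_iter,
                             k = config$cv$k, seed = seed + 31L)
    boot <- bootstrap_ci(ytr, cv$oof[, "ensemble"],
                         n_iter = config$robustness$bootstrap_iter,
                         seed = seed + 32L)
    list(permutation = perm, bootstrap = boot)
  })

  attribution <- stage("explain", {
    bg_n <- min(config$attribution$background_size, nrow(Xtr))
    set.seed(seed + 41L)
    bg <- Xtr[.stratified_subsample(ytr, bg_n), , drop = FALSE]
    expl_train <- explain_ensemble(model, Xtr, background = bg,
                                   n_coalitions = config$attribution$n_coalitions,
                                   seed = seed + 42L)
    importance <- global_importance(expl_train$consensus)
    Xstr <- t(take(sim$strain)[features, , drop = FALSE])
    strain_mask <- sim$strain$meta$strain[
      match(rownames(Xstr), sim$strain$meta$sample_id)]
    # strain-cohort attributions are referenced to the unstrained state:
    # the control arm is the background, making raw_diff a paired contrast
    expl_strain <- explain_ensemble(model, Xstr,
                                    background = Xstr[!strain_mask, , drop = FALSE],
                                    n_coalitions = config$attribution$n_coalitions,
                                    seed = seed + 43L)
    mech <- mechanosensitivity(expl_strain$consensus, strain_mask,
                               cuts = config$attribution$mechano_cuts)
    list(train = expl_train, strain = expl_strain, importance = importance,
         mechanosensitivity = mech)
  })

  enrichment <- stage("enrich", {
    universe <- rownames(harm$expr)
    up <- deg$gene[deg$direction == "up"]
    down <- deg$gene[deg$direction == "down"]
    all_res <- enrich_collection(features, sim$gene_sets, universe,
                                 fdr_max = config$enrichment$fdr_max,
                                 min_size = config$enrichment$min_size,
                                 max_size = config$enrichment$max_size)
    dir_res <- directional_enrichment(up, down, sim$gene_sets, universe,
                                      fdr_max = config$enrichment$fdr_max,
                                      min_size = config$enrichment$min_size,
                                      max_size = config$enrichment$max_size)
    shap_scores <- pathway_shap_scores(sim$gene_sets, attribution$importance,
                                       features)
    list(all = all_res, directional = dir_res, shap_scores = shap_scores)
  })

  results <- list(
    config = config, simulated = sim, harmonization = harm$report,
    expr = harm$expr, meta = meta, deg = deg, features = features,
    cv = cv, model = model, validation = validation,
    robustness = robustness, attribution = attribution,
    enrichment = enrichment
  )
  if (!is.null(out_dir)) .write_pipeline_artifacts(results, out_dir)
  invisible(results)
}

.stratified_subsample <- function(y, n) {
  idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    sample(i, round(n * length(i) / length(y)))
  }))
  sort(idx)
}

.write_pipeline_artifacts <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  put_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    art <<- c(art, name)
  }
  put_json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    art <<- c(art, name)
  }
  write_expression_tsv(results$expr, file.path(out_dir, "expression_harmonized.tsv"))
  art <- c(art, "expression_harmonized.tsv")
  put_tsv(results$meta, "sample_metadata.tsv")
  put_tsv(results$deg, "deg_table.tsv")
  put_tsv(results$cv$metrics, "cv_metrics.tsv")
  put_tsv(results$attribution$importance, "importance.tsv")
  put_tsv(results$attribution$mechanosensitivity, "mechanosensitivity.tsv")
  put_tsv(results$enrichment$all, "enrichment_all.tsv")
  put_tsv(results$enrichment$shap_scores, "pathway_shap_scores.tsv")
  for (nm in names(results$validation)) {
    put_tsv(results$validation[[nm]]$cdi, paste0("cdi_", nm, ".tsv"))
    put_tsv(results$validation[[nm]]$summary, paste0("cdi_summary_", nm, ".tsv"))
  }
  put_json(results$harmonization, "harmonization_report.json")
  rb <- results$robustness
  put_json(list(
    permutation = rb$permutation[c("true_auc", "mean_permuted_auc", "p_value", "n_iter")],
    bootstrap = rb$bootstrap
  ), "robustness.json")
  cfg <- results$config
  cfg$spec <- unclass(cfg$spec)
  put_json(list(config = cfg, artifacts = sort(art),
                package_version = as.character(utils::packageVersion("cdindex"))),
           "manifest.json")
  invisible(art)
}

#' Score and summarize independent validation cohorts
#'
#' Applies a fitted ensemble to each cohort without any refitting: computes
#' the CDI per sample, the per-condition CDI summary, and — when the
#' cohort metadata carries both classes — the classification metrics of
#' the CDI against the cohort's class labels.
#'
#' @param model A fitted `cdi_ensemble`.
#' @param cohorts Named list; each element a list with `expr`
#'   (gene-by-sample matrix containing the model's features) and `meta`
#'   (data.frame with sample_id, condition and optionally class).
#' @return Named list per cohort: `cdi` records, `summary` by condition,
#'   and `metrics` (NULL for single-class cohorts).
#' @export
validate_cohorts <- function(model, cohorts) {
  if (length(cohorts) == 0) return(list())
  lapply(cohorts, function(co) {
    missing <- setdiff(model$features, rownames(co$expr))
    if (length(missing) > 0) {
      stop("cohort lacks model features: ", paste(missing, collapse = ", "))
    }
    X <- t(co$expr[model$features, , drop = FALSE])
    meta <- co$meta[match(rownames(X), co$meta$sample_id), ]
    rec <- compute_cdi(model, X, condition = meta$condition)
    metrics <- NULL
    if (!is.null(meta$class) && length(unique(meta$class)) == 2) {
      metrics <- as.data.frame(compute_metrics(meta$class, rec$cdi))
    }
    list(cdi = rec, summary = summarize_cdi(rec), metrics = metrics)
  })
}
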