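# cdindex

Cartilage degrades on a continuum — healthy tissue, early mechanical
damage (e.g. cartilage from partial-meniscectomy patients), advanced
osteoarthritis — but most transcriptomic classifiers treat it as a binary
label. `cdindex` implements, end to end in R, a pipeline that converts
multi-cohort cartilage gene-expression data into a continuous
**Cartilage Degradation Index (CDI)** and explains it:

1. **Harmonization** — per-dataset quantile normalization, intersection to
   the common gene set, and parametric empirical-Bayes (ComBat) batch
   correction with PCA diagnostics of batch structure.
2. **Signature selection** — per-gene Welch *t* tests (OA vs non-OA),
   Benjamini–Hochberg FDR, and the dual gate `FDR < 0.05` and
   `|log2FC| > 0.5`.
3. **Ensemble CDI** — a random forest, gradient-boosted trees, and a
   Platt-calibrated SVM trained with in-fold scaling and (optionally)
   in-fold randomized hyperparameter search under stratified 5-fold CV.
   The equal-weight soft-vote probability
   `p = (p_RF + p_XGB + p_SVM) / 3` **is** the CDI, with risk zones
   `[0,0.2]` low, `(0.2,0.5]` intermediate, `(0.5,0.8)` elevated,
   `[0.8,1]` high.
4. **Robustness** — label-permutation significance of the CV AUC (smoothed
   `p = (1 + #{AUC_perm >= AUC_true}) / (n_iter + 1)`) and stratified
   bootstrap confidence intervals on pooled out-of-fold predictions.
5. **Attribution** — Shapley values for each base model via
   kernel-weighted coalition regression (exact enumeration at small
   feature counts), a consensus attribution (elementwise mean, locally
   accurate against the CDI itself), mean-|SHAP| gene rankings,
   cross-cohort Spearman consistency, and a per-gene **mechanosensitivity
   score** `|mean SHAP(strain) − mean SHAP(control)|`, min-max normalized
   and categorized at 0.3/0.6.
6. **Pathway enrichment** — one-sided Fisher/hypergeometric
   over-representation of the signature against GMT collections with
   per-collection FDR, directional (up/down) analyses, and an
   attribution-weighted pathway score (mean member importance).

A synthetic multi-dataset generator with planted ground truth — batch
effects, differentially expressed genes, a healthy → early → advanced
degradation spectrum, and strain-responsive genes — makes the whole
pipeline testable offline. It is first-class, tested code, not a fixture.

## Worked example

Simulate a three-dataset training cohort and an independent validation
cohort from the same population, harmonize them jointly (each dataset is
one batch), select the signature, train the ensemble, and score the
held-out samples:

```r
library(cdindex)

spec <- cohort_spec(n_genes = 500, seed = 42)
train <- simulate_cohort(spec)
valid <- simulate_cohort(spec, role = "validation", sample_seed = 1042L)

by_batch <- function(co, prefix) {
  m <- lapply(split(seq_len(ncol(co$expr)), co$meta$batch),
              function(j) co$expr[, j])
  names(m) <- paste(prefix, names(m), sep = "."); m
}
harm <- harmonize_cohorts(c(by_batch(train, "train"), by_batch(valid, "val")))
round(unlist(harm$report), 3)
#> pc1_variance_before  pc1_variance_after  batch_assoc_before   batch_assoc_after
#>               0.213               0.126               0.999               0.000
#>      n_common_genes
#>             500.000

tr <- intersect(colnames(harm$expr), train$meta$sample_id)
meta <- train$meta[match(tr, train$meta$sample_id), ]
deg <- run_deg(harm$expr[, tr], setNames(meta$class, meta$sample_id))
table(deg$direction)
#> down none   up
#>   19  409   72

features <- deg$gene[deg$selected]
X <- t(harm$expr[features, tr])
cv <- run_cv(X, meta$class, k = 5, seed = 42)
cv$metrics[, c("model", "accuracy", "f1", "auc", "brier", "cv_train_gap")]
#>      model accuracy    f1 auc    brier cv_train_gap
#> 1       rf    1.000 1.000   1 0.023166     0.000000
#> 2      xgb    0.992 0.992   1 0.014495     0.000278
#> 3      svm    1.000 1.000   1 0.000717     0.000000
#> 4 ensemble    1.000 1.000   1 0.008777     0.000000

model <- fit_ensemble(X, meta$class, seed = 42)
va <- intersect(colnames(harm$expr), valid$meta$sample_id)
vmeta <- valid$meta[match(va, valid$meta$sample_id), ]
cdi <- compute_cdi(model, t(harm$expr[features, va]), condition = vmeta$condition)
summarize_cdi(cdi)
#>   condition  mean     sd  n singleton
#> 1  advanced 0.970 0.0150 60     FALSE
#> 2     early 0.047 0.0148 18     FALSE
#> 3   healthy 0.014 0.0089 42     FALSE
```

Before correction, batch membership explains PC1 almost perfectly
(`batch_assoc_before ≈ 1`); afterwards it explains essentially none of it.
The planted 74-up/19-down signature is recovered (72 + 19 selected genes),
the ensemble separates the held-out classes, and — although early-damage
samples were labelled "non-OA" during training — their mean CDI (0.047)
lands strictly between healthy (0.014) and advanced (0.970), which is the
point of reading the probability out as a continuous index. On noisier,
less separable data the spacing widens toward the intermediate zone.

`run_pipeline(pipeline_config(seed = 1))` runs the same flow plus
robustness, attribution, mechanosensitivity and enrichment stages from a
single declarative config (YAML via `read_pipeline_config()`), writing
TSV/JSON artifacts and a manifest.

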