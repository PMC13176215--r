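---
title: "Methods: a continuous Cartilage Degradation Index from multi-cohort transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a continuous Cartilage Degradation Index from multi-cohort transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdindex)
```

## The problem

Osteoarthritis degrades articular cartilage progressively: healthy tissue,
early mechanical damage (for example cartilage from arthroscopic partial
meniscectomy patients), and advanced disease form a continuum rather than
two classes. Public expression datasets covering this continuum come from
different platforms and laboratories, so technical batch variance usually
dwarfs the biological signal. `cdindex` implements a pipeline that (i)
harmonizes several log2 expression datasets into one matrix, (ii) selects a
differential-expression signature between OA and non-OA samples, (iii)
trains a soft-voting ensemble classifier on that signature, and (iv) reads
the ensemble's class-1 probability out directly as a continuous 0-1
**Cartilage Degradation Index (CDI)**. Because the score is a probability,
a sample's position between 0 and 1 — not a hard threshold — is the
result: early-damage samples are expected to land between healthy and
advanced-OA samples. Attribution and enrichment stages then explain which
genes and pathways carry the score.

Everything is exercised on a bundled synthetic-cohort generator with known
ground truth, so every stage is testable offline; no repository data are
downloaded.

## Synthetic cohorts: what the generator emulates

`simulate_cohort()` draws gene-by-sample log2 expression under an additive
model per gene $g$ and sample $s$ in dataset (batch) $b$:

$$y_{gs} = \mu_g + \mathrm{grade}(s)\, d_g\, \beta\, [g \in \mathrm{DEG}]
         + \mathrm{strain}(s)\, d_g\, \tau\, [g \in \mathrm{mechano}]
         + \gamma_{bg} + \delta_{bg}\, \varepsilon_{gs}.$$

* **Baselines** $\mu_g \sim U(4, 10)$ log2 units, per-gene noise SD drawn
  from `noise_sd * c(0.8, 1.2)` (default noise 0.5 log2 units, typical for
  normalized expression data).
* **Degradation grades** default to 0 (healthy), 0.4 (early/meniscectomy-
  like), 1 (advanced). The binary training class is `grade >= 0.5`, so
  early samples are labelled non-OA at train time; a working CDI should
  nevertheless place them mid-spectrum at predict time. Grade 0.4 echoes
  the observed ordering of mean CDI values across the three stages.
* **Batch effects** are additive ($\gamma_{bg} \sim N(0, 2^2)$) plus
  multiplicative ($\delta_{bg} = e^{N(0, 0.15^2)}$) — exactly the
  location/scale form the parametric empirical-Bayes corrector assumes.
  This is deliberate: parameter-recovery tests are only meaningful under
  the assumed model, and robustness to model misspecification is out of
  scope. With the default shift SD the first principal component is
  dominated by dataset membership before correction, reproducing the
  classic diagnostic picture.
* **Planted signature**: 74 up- and 19 down-regulated genes (the 93-gene
  structure) with effect $\beta$ (|log2FC| at full grade), default 1.0 —
  comfortably above the 0.5 selection gate.
* **Strain mini-cohort** (`simulate_strain_cohort()`): a single-dataset
  9-vs-9 control/strain design at fixed grade 0.5, emulating chondrocytes
  under in vitro cyclic tensile strain. A planted subset of the DEGs
  (default 16, the high+moderate mechanosensitivity count) shifts by
  $\tau$ **in the gene's disease direction** — stressed chondrocytes move
  toward the degradative expression program, which is the premise that
  makes a disease classifier sensitive to mechanical stress at all. The
  default $\tau = 2$ log2 units (4-fold) reflects the strong acute
  induction of mechanoresponsive genes in controlled in vitro loading; a
  response at the 1.0 level would sit at the sampling-noise floor of a
  9-vs-9 comparison.

**Held-out cohorts.** Gene-level ground truth (baselines, planted DEG and
mechano identities) is a function of `spec$seed` only; sample-level draws
use a separate `sample_seed`. Validation cohorts are therefore fresh
samples of the *same* population — re-seeding the whole spec would redraw
the signature itself. In the pipeline, all cohorts (training, spectrum
validation, strain) are harmonized **jointly**, each dataset one batch,
and split back afterwards; cohort-wise correction would leave per-gene
cross-cohort location shifts (the pooled batch mean is not removed by
batch correction) that compress held-out CDI scores toward mid-range.

What the generator does **not** emulate: count-level sequencing noise and
library sizes (the pipeline operates on normalized log intensities),
gene-gene correlation beyond the shared grade axis, probe-level microarray
structure, and heterogeneous per-gene effect sizes. Passing tests
therefore demonstrate the machinery is correct under its stated model, not
that real cohorts meet these assumptions — in particular, real DEG
signatures are correlated and their effects are not interchangeable.

## Harmonization

Each dataset is quantile-normalized individually (per-rank means; ties
receive the mean of the spanned reference values, so the operation is
deterministic and order-independent), all datasets are restricted to their
lexicographically sorted common gene set, and the concatenated matrix is
corrected with parametric empirical-Bayes ComBat treating each dataset as
one batch. The correction uses an intercept-only model by default — no
biological covariate is protected — because the upstream studies are
silent on covariates and an unprotected correction is the conservative
choice; `combat_correct(covariates = )` provides the switch, and the
interpretive caveat is that group differences partially confounded with
batch are attenuated. Genes that are flat within some batch (a quantile-
normalization tie artifact) cannot be scale-adjusted; they receive a
location-only batch-mean correction, and globally flat genes pass through
(variance floor `1e-8`). PCA diagnostics report the PC1 variance share and
the $R^2$ of batch on PC1 scores before and after correction; on default
synthetic cohorts the share collapses from dominant (> 0.5) to a fraction
of that, with batch $R^2$ near zero.

## Differential expression

Per gene, an unequal-variance Welch $t$-test between class 1 (OA) and
class 0 samples with Welch–Satterthwaite degrees of freedom and two-sided
p-values; Benjamini–Hochberg FDR across genes; selection requires
`fdr < 0.05` **and** `|log2FC| > 0.5`, both strict, so boundary genes are
excluded. Genes with zero variance in both groups get $t = 0$, $p = 1$
(rather than NaN) to keep the FDR step well defined. Moderated-variance
(limma-style) testing is intentionally out of scope: the feature selection
must match the pipeline it feeds.

## Ensemble and the CDI

Three base learners span three paradigms: a probability random forest
(bagging), gradient-boosted trees (boosting), and an RBF/linear SVM with
Platt-calibrated probabilities (margin maximization). The ensemble
probability is the exact equal-weight (1/3) mean of the three class-1
probabilities, and this probability **is** the CDI.

Leakage control: inside every cross-validation fold the per-feature
standardizer is fitted on the training split only, and any hyperparameter
search runs only on that split (randomized search, default 80 draws,
scored by inner 3-fold stratified AUC; learning rate, cost and kernel
width are drawn log-uniformly because they act multiplicatively).
Stratified 5-fold CV pools out-of-fold probabilities, and metrics
(accuracy/precision/recall/F1 at threshold 0.5, rank-based AUC with
midrank tie handling, Brier score) are computed on the pooled predictions.
The per-fold training AUC minus the pooled CV AUC (CV–train gap) is the
overfitting indicator. `fit_ensemble(tune = FALSE)` uses a fixed modest
configuration (100 trees; 40 boosting rounds at depth 3; RBF SVM at
C = 1), which is what the permutation machinery re-runs hundreds of times.
Fold assignment is keyed to sorted sample ids, so out-of-fold results are
invariant to row order.

Risk zones annotate the score: `[0, 0.2]` low, `(0.2, 0.5]` intermediate,
`(0.5, 0.8)` elevated, `[0.8, 1]` high. The `(0.5, 0.8)` interval needed a
name of its own ("elevated") since only the outer three are conventional.
Singleton condition groups report SD 0 with a `singleton` flag so
summaries stay total.

## Robustness

The permutation test shuffles labels **before** fold assignment and reruns
the entire CV pipeline per iteration, preserving every fitting step under
the null; the smoothed estimator $p = (1 + \#\{AUC_{perm} \ge
AUC_{true}\})/(n+1)$ makes $p < 0.001$ attainable at 1,000 iterations
exactly when no permutation beats the truth. Bootstrap confidence
intervals resample the pooled out-of-fold (label, probability) pairs
stratified within class — the only variant that is desk-scale at 1,000
replicates; `refit = TRUE` reruns the CV per replicate for the expensive
reading.

## Attribution

No Shapley library is assumed: the package implements kernel-weighted
coalition regression (Kernel SHAP) against marginal (interventional)
background expectations. For 12 or fewer features all $2^p - 2$ proper
coalitions are enumerated with exact Shapley-kernel weights, which equals
exhaustive Shapley attribution; for larger feature sets, coalition sizes
are sampled proportionally to the kernel mass in complementary pairs
(default `max(4p, 300)` coalitions) and the constrained weighted
least-squares solution is used. The local-accuracy constraint is enforced
algebraically, so attributions plus the base value reproduce each model's
prediction to machine precision, and the estimator is *exact* for
additively structured models regardless of the sampling budget. All three
base models are explained by this one mechanism rather than a tree-path
algorithm for the tree models: path-dependent tree attribution conditions
on each tree's cover distribution and does not agree with the exhaustive
marginal-expectation oracle the tests verify against, whereas a single
mechanism also makes the consensus identity below exact by construction.

The **consensus attribution** is the elementwise mean of the three base
matrices (and of their base values); by linearity it satisfies local
accuracy with respect to the soft-vote probability, i.e. with respect to
the CDI itself. Global importance is the per-gene mean |attribution| with
descending ranks and lexicographic tie-breaks; cross-cohort consistency
reports pairwise Spearman correlations of importance vectors and per-gene
top-20 membership counts.

The **mechanosensitivity score** of gene $g$ is
$|\overline{\phi_g}^{strain} - \overline{\phi_g}^{control}|$ on the strain
cohort's consensus attributions, min-max normalized over the analyzed
feature set (all selected genes, not a subset), and categorized as
high (> 0.6), moderate (0.3–0.6, boundaries inclusive per the interval
notation) or low (< 0.3). In the pipeline, strain-cohort attributions are
referenced to the **control arm** as background, turning the score into a
paired contrast ("what changed relative to unstrained cells"); the
training-cohort explanation keeps a class-stratified training subsample
(default 50) as background.

A known limitation, established with the bundled generator: when the
feature set consists of many statistically redundant genes, tree ensembles
split on a subset of them, so planted strain-responsive genes the trees
ignore receive near-zero attribution while tree-favored genes acquire
contrast through redundancy interactions. Under the default study
conditions the consensus ranking recovers roughly 50–70% of the planted
strain-responsive set in the top-16 (the SVM attribution alone does
better), and this plateau is insensitive to the strain effect size, the
coalition budget (sampled and exhaustive solutions agree), and the
background choice. Mechanosensitivity rankings from tree-containing
consensus attributions should therefore be read as importance-weighted,
not as an unbiased screen for strain response.

## Pathway enrichment

Over-representation uses the one-sided hypergeometric upper tail
(equivalently Fisher's exact test with alternative "greater") against the
measured-gene universe — the harmonized common gene set, not the whole
genome, because only measured genes could have been selected; this choice
is configurable and is the main driver of differences against web-service
defaults. Terms are size-filtered (3–500 after universe intersection,
standard ORA practice), BH-corrected per collection, and flagged at
`fdr < 0.05`. Directional analyses run the disjoint up- and down-regulated
query sets independently; because the query size enters the
hypergeometric parameters, directional and pooled analyses are not
interchangeable. The attribution-weighted pathway score is the mean
importance of a term's member genes within the feature set (0 with a
flagged zero count when the intersection is empty); it deliberately ranks
pathways by their contribution to the classifier rather than by
significance, and the two rankings can disagree.

## Numerical and design choices

* Strict inequalities at both DEG thresholds; two-sided p-values.
* Quantile-normalization tie policy: mean of spanned reference values.
* Variance floor `1e-8` for flat genes in batch correction; location-only
  correction for within-batch-flat genes.
* AUC via midranks (Mann–Whitney with half-credit for ties).
* Margin-classifier probabilities via Platt-style calibration fitted on
  the training split (the SVM implementation's internal procedure); its
  internal resampling is seeded for determinism.
* Kernel-regression ridge `1e-10` on the reduced normal equations for
  numerical stability; the local-accuracy constraint is eliminated
  algebraically, never penalized.
* Permutation p-values use the +1 smoothing; bootstrap intervals are
  percentile intervals.
* All randomness flows from explicit integer seeds; generation, folds,
  fits, explanations and resampling are reproducible bit-for-bit.

## Problem sizes used in the test suite

The suite favors a few deep, parameterised checks. Typical sizes: 120–400
genes and 28–120 samples for pipeline-level tests; 2,000–10,000 genes for
calibration checks of the test statistics; 200 and 1,000 permutation
iterations for the null-centering and significance checks (matching the
iteration counts the robustness claims are stated at); exhaustive Shapley
oracles at 3 features and additive-model oracles at 40–93 features. These
sizes were chosen so each statistical property is measured at the scale
its claim refers to while the full suite remains a routine desk run.
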