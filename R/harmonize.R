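#' Collapse probe-level rows to gene symbols by averaging
#'
#' Microarray platforms measure several probes per gene; rows mapping to the
#' same symbol are replaced by their arithmetic mean, and probes with no
#' mapping are dropped.
#'
#' @param values Probe-by-sample numeric matrix (rownames = probe ids).
#' @param probe_to_symbol Named character vector mapping probe id -> symbol.
#' @return Gene-by-sample matrix with unique symbol rownames.
#' @export
collapse_probes <- function(values, probe_to_symbol) {
  if (length(probe_to_symbol) == 0) stop("probe_to_symbol mapping is empty")
  keep <- intersect(rownames(values), names(probe_to_symbol))
  if (length(keep) == 0) stop("no probe in `values` has a symbol mapping")
  v <- values[keep, , drop = FALSE]
  sym <- probe_to_symbol[keep]
  sums <- rowsum(v, group = sym)
  counts <- as.vector(table(sym)[rownames(sums)])
  sums / counts
}

#' Restrict matrices to their common gene set
#'
#' Takes the intersection of the row (gene) sets of all matrices, sorts it
#' lexicographically for a canonical order, and returns each matrix
#' restricted to it in that shared order.
#'
#' @param matrices List of gene-by-sample matrices.
#' @return List of matrices over the identical, sorted common gene set.
#' @export
intersect_genes <- function(matrices) {
  if (length(matrices) < 1) stop("need at least one matrix")
  common <- sort(Reduce(intersect, lapply(matrices, rownames)))
  if (length(common) == 0) stop("gene intersection across matrices is empty")
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Quantile-normalize the sample columns of an expression matrix
#'
#' Forces every sample to the identical value distribution (the per-rank
#' mean of the sorted columns) while preserving within-sample rank order;
#' tied values receive the mean of the reference values they span. The
#' computation is [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param matrix Gene-by-sample numeric matrix.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Parametric empirical-Bayes batch correction
#'
#' Removes additive and multiplicative per-gene batch effects by the
#' parametric ComBat algorithm ([sva::ComBat()]): gene-wise standardization
#' against a pooled model, per-batch location/scale estimation, empirical
#' -Bayes shrinkage of the estimates toward moment-matched normal /
#' inverse-gamma priors, and back-transformation. By default no biological
#' covariates are protected (intercept-only model); pass a factor via
#' `covariates` to preserve a group structure during correction.
#'
#' Genes whose overall variance is below `variance_floor` cannot be
#' standardized and are passed through unadjusted.
#'
#' @param matrix Gene-by-sample matrix.
#' @param batch_of_sample Batch label per sample (vector in column order, or
#'   named by sample).
#' @param covariates Optional factor/vector of a biological grouping to
#'   protect, or NULL (default).
#' @param variance_floor Genes with overall variance below this are left
#'   unadjusted.
#' @param allow_single_batch If TRUE a single-batch input is returned
#'   unchanged instead of raising an error.
#' @return Corrected matrix, same shape and dimnames.
#' @export
combat_correct <- function(matrix, batch_of_sample, covariates = NULL,
                           variance_floor = 1e-8, allow_single_batch = FALSE) {
  batch <- .align_batch(batch_of_sample, colnames(matrix), ncol(matrix))
  tab <- table(batch)
  if (length(tab) < 2) {
    if (allow_single_batch) return(matrix)
    stop("combat_correct requires >= 2 batches")
  }
  if (any(tab < 2)) {
    stop("every batch needs >= 2 samples; offending batch(es): ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  mod <- NULL
  if (!is.null(covariates)) mod <- stats::model.matrix(~ factor(covariates))
  v <- apply(matrix, 1, stats::var)
  batch_v <- vapply(unique(batch), function(b) {
    apply(matrix[, batch == b, drop = FALSE], 1, stats::var)
  }, numeric(nrow(matrix)))
  # EB location/scale adjustment needs within-batch variance everywhere;
  # genes flat inside some batch get a location-only correction instead
  # (scale is undefined for them), and globally flat genes pass through.
  adjustable <- v > variance_floor & apply(batch_v > variance_floor, 1, all)
  loc_only <- v > variance_floor & !adjustable
  out <- matrix
  if (any(adjustable)) {
    corrected <- suppressMessages(
      sva::ComBat(dat = matrix[adjustable, , drop = FALSE],
                  batch = batch, mod = mod, par.prior = TRUE)
    )
    out[adjustable, ] <- corrected
  }
  if (any(loc_only)) {
    sub <- matrix[loc_only, , drop = FALSE]
    grand <- rowMeans(sub)
    for (b in unique(batch)) {
      j <- batch == b
      sub[, j] <- sub[, j] - rowMeans(sub[, j, drop = FALSE]) + grand
    }
    out[loc_only, ] <- sub
  }
  out
}

.align_batch <- function(batch_of_sample, sample_ids, n) {
  b <- batch_of_sample
  if (!is.null(names(b)) && !is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(b))
    if (length(missing) > 0) {
      stop("samples without a batch assignment: ", paste(missing, collapse = ", "))
    }
    b <- b[sample_ids]
  }
  if (length(b) != n) stop("batch assignment length does not match sample count")
  if (anyNA(b)) stop("batch assignment contains NA")
  as.character(b)
}

#' PCA diagnostics of batch structure
#'
#' Principal components of the gene-centered matrix across samples. Reports
#' the PC1 variance share and the R-squared of a one-way batch grouping on
#' the PC1 scores — before correction a dominant, batch-associated PC1 is
#' the classic signature of dataset-driven clustering.
#'
#' @inheritParams combat_correct
#' @return List with `pc1_variance` (proportion of total variance) and
#'   `batch_assoc` (R-squared of batch on PC1 scores).
#' @export
pca_batch_diagnostics <- function(matrix, batch_of_sample) {
  if (ncol(matrix) < 3) stop("PCA diagnostics need >= 3 samples")
  batch <- .align_batch(batch_of_sample, colnames(matrix), ncol(matrix))
  pr <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  pc1_share <- pr$sdev[1]^2 / sum(pr$sdev^2)
  r2 <- if (length(unique(batch)) > 1) {
    summary(stats::lm(pr$x[, 1] ~ factor(batch)))$r.squared
  } else 0
  list(pc1_variance = pc1_share, batch_assoc = r2)
}

#' Harmonize several expression datasets into one corrected matrix
#'
#' Full cross-dataset preprocessing: each dataset is quantile-normalized
#' individually, all are restricted to their (sorted) common gene set and
#' concatenated, and the combined matrix is batch-corrected with
#' [combat_correct()] treating each dataset as one batch. PCA diagnostics
#' are computed before and after correction.
#'
#' @param matrices Named list of gene-by-sample matrices (names become batch
#'   labels).
#' @param covariates Optional biological grouping passed to
#'   [combat_correct()] (vector over the concatenated samples).
#' @return List with `expr` (harmonized matrix), `batch` (per-sample batch
#'   labels) and `report` — a harmonization report with
#'   `pc1_variance_before/after`, `batch_assoc_before/after`,
#'   `n_common_genes`.
#' @export
harmonize_cohorts <- function(matrices, covariates = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  if (is.null(names(matrices))) {
    names(matrices) <- sprintf("dataset%02d", seq_along(matrices))
  }
  normed <- lapply(matrices, quantile_normalize)
  normed <- intersect_genes(normed)
  combined <- do.call(cbind, normed)
  batch <- rep(names(normed), vapply(normed, ncol, integer(1)))
  before <- pca_batch_diagnostics(combined, batch)
  corrected <- combat_correct(combined, batch, covariates = covariates,
                              allow_single_batch = TRUE)
  after <- pca_batch_diagnostics(corrected, batch)
  list(
    expr = corrected, batch = batch,
    report = list(
      pc1_variance_before = before$pc1_variance,
      pc1_variance_after = after$pc1_variance,
      batch_assoc_before = before$batch_assoc,
      batch_assoc_after = after$batch_assoc,
      n_common_genes = nrow(combined)
    )
  )
}
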