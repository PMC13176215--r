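#' Welch's unequal-variance t-test for two groups
#'
#' Two-sided Welch t statistic with Welch-Satterthwaite degrees of freedom.
#' Genes (rows) whose pooled standard error is zero — no variance in either
#' group — get `t = 0, p = 1`, which keeps downstream multiple-testing
#' correction well defined.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with `t_stat`, `df`, `p_raw`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  res <- row_welch_t(matrix(c(x, y), nrow = 1),
                     rep(c(1L, 0L), c(length(x), length(y))))
  list(t_stat = res$t_stat, df = res$df, p_raw = res$p_raw)
}

# Vectorized Welch test across matrix rows; class is 0/1 per column.
# The 1-labelled group plays the role of x (OA), 0 of y (non-OA).
row_welch_t <- function(matrix, class) {
  class <- as.integer(class)
  i1 <- class == 1L
  i0 <- class == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  if (n1 < 2 || n0 < 2) stop("each class needs >= 2 samples")
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m0 <- rowMeans(matrix[, i0, drop = FALSE])
  v1 <- rowSums((matrix[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((matrix[, i0, drop = FALSE] - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t_stat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  list(t_stat = unname(t_stat), df = unname(df), p_raw = unname(p),
       log2fc = unname(m1 - m0))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values in input order (computed by
#' [stats::p.adjust()] with `method = "BH"` after validating the input).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of FDR-adjusted values, same order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene log2 fold change between two classes
#'
#' For log2-scale data this is simply the difference of group means:
#' mean over class-1 (OA) samples minus mean over class-0 samples.
#'
#' @param matrix Gene-by-sample log2 expression matrix.
#' @param class 0/1 class per sample (column order, or named by sample).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(matrix, class) {
  class <- .align_class(class, colnames(matrix), ncol(matrix))
  if (!any(class == 1) || !any(class == 0)) stop("both classes must be non-empty")
  rowMeans(matrix[, class == 1, drop = FALSE]) -
    rowMeans(matrix[, class == 0, drop = FALSE])
}

.align_class <- function(class, sample_ids, n) {
  if (!is.null(names(class)) && !is.null(sample_ids)) class <- class[sample_ids]
  if (length(class) != n) stop("class length does not match sample count")
  if (anyNA(class)) stop("class contains NA")
  cl <- as.integer(class)
  if (!all(cl %in% c(0L, 1L))) stop("class must be binary 0/1")
  cl
}

#' Differential expression analysis between OA and non-OA samples
#'
#' Runs a per-gene Welch t-test (class 1 vs class 0), Benjamini-Hochberg
#' FDR correction, and dual-threshold selection.
#'
#' @inheritParams log2_fold_change
#' @param fdr_max,lfc_min Selection thresholds; a gene is selected iff
#'   `fdr < fdr_max` **and** `|log2fc| > lfc_min` (both strict).
#' @return A DEG table: data.frame with columns gene, log2fc, t, p, fdr,
#'   direction ("up"/"down"/"none") and selected (logical), one row per
#'   gene in input order.
#' @export
run_deg <- function(matrix, class, fdr_max = 0.05, lfc_min = 0.5) {
  class <- .align_class(class, colnames(matrix), ncol(matrix))
  w <- row_welch_t(matrix, class)
  tab <- data.frame(
    gene = rownames(matrix),
    log2fc = w$log2fc,
    t = w$t_stat,
    p = w$p_raw,
    fdr = benjamini_hochberg(w$p_raw),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  select_degs(tab, fdr_max = fdr_max, lfc_min = lfc_min)
}

#' Apply the dual FDR / fold-change selection rule to a DEG table
#'
#' @param table Data frame with at least `log2fc` and `fdr` columns.
#' @inheritParams run_deg
#' @return The table with `selected` and `direction` columns (re)computed;
#'   direction is "up"/"down" for selected genes by the sign of log2fc,
#'   "none" otherwise.
#' @export
select_degs <- function(table, fdr_max = 0.05, lfc_min = 0.5) {
  table$selected <- table$fdr < fdr_max & abs(table$log2fc) > lfc_min
  table$direction <- ifelse(!table$selected, "none",
                            ifelse(table$log2fc > 0, "up", "down"))
  table
}
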