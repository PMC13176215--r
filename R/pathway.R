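#' One-sided Fisher / hypergeometric over-representation test
#'
#' Tests whether the overlap between a query gene set and a pathway term is
#' larger than expected under random draws from the universe. The p-value
#' is the hypergeometric upper tail \eqn{P(X \ge k)} with parameters
#' (universe N, term size K, query size n). Query and term genes outside
#' the universe are dropped (with a warning for the query).
#'
#' @param query Character vector of query genes (e.g. selected DEGs).
#' @param term_set Character vector of pathway member genes.
#' @param universe Character vector: the measured gene background.
#' @return List with `k` (overlap), `K`, `n`, `N`, `p_raw`, and `overlap`
#'   (the member genes).
#' @export
fisher_ora <- function(query, term_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe must be non-empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe were dropped")
    query <- intersect(query, universe)
  }
  term_set <- intersect(unique(term_set), universe)
  overlap <- intersect(query, term_set)
  k <- length(overlap); K <- length(term_set); n <- length(query)
  N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_raw = min(p, 1), overlap = overlap)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [fisher_ora()] for every term (after restricting terms to the
#' universe and filtering by size), adjusts p-values across the collection
#' with Benjamini-Hochberg, and flags significance at `fdr < fdr_max`.
#'
#' @inheritParams fisher_ora
#' @param collection Named list of gene sets.
#' @param fdr_max Significance threshold on the adjusted p-value.
#' @param min_size,max_size Term-size bounds (after intersection with the
#'   universe) applied before testing.
#' @return Data frame with one row per tested term: term, k, K, n, N,
#'   p_raw, fdr, significant, overlap (comma-separated members).
#' @export
enrich_collection <- function(query, collection, universe, fdr_max = 0.05,
                              min_size = 3, max_size = 500) {
  universe <- unique(universe)
  sizes <- vapply(collection, function(s) length(intersect(s, universe)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  collection <- collection[keep]
  if (length(collection) == 0) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      fdr = numeric(0), significant = logical(0),
                      overlap = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(collection), function(term) {
    r <- suppressWarnings(fisher_ora(query, collection[[term]], universe))
    data.frame(term = term, k = r$k, K = r$K, n = r$n, N = r$N,
               p_raw = r$p_raw, overlap = paste(r$overlap, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p_raw)
  out$significant <- out$fdr < fdr_max
  out <- out[, c("term", "k", "K", "n", "N", "p_raw", "fdr", "significant", "overlap")]
  out[order(out$p_raw, out$term), ]
}

#' Directional enrichment for up- and down-regulated gene sets
#'
#' Runs [enrich_collection()] independently for the up- and down-regulated
#' query sets, which must be disjoint. Because the query size enters the
#' hypergeometric parameters, directional results are not a partition of
#' the pooled analysis.
#'
#' @param up_set,down_set Disjoint character vectors of genes.
#' @inheritParams enrich_collection
#' @return List with elements `up` and `down`, each an ORA table (empty
#'   input set yields an empty table).
#' @export
directional_enrichment <- function(up_set, down_set, collection, universe,
                                   fdr_max = 0.05, min_size = 3, max_size = 500) {
  if (length(intersect(up_set, down_set)) > 0) {
    stop("up and down gene sets must be disjoint")
  }
  run <- function(q) {
    if (length(q) == 0) {
      return(enrich_collection(character(0), list(), universe))
    }
    enrich_collection(q, collection, universe, fdr_max, min_size, max_size)
  }
  list(up = run(up_set), down = run(down_set))
}

#' Attribution-weighted pathway score
#'
#' The mean attribution importance (mean |SHAP|) of a pathway's member
#' genes within the model's feature set — pathways whose members actually
#' drive the classifier score highly even when their enrichment p-value is
#' unremarkable, and vice versa.
#'
#' @param term_set Character vector of pathway member genes.
#' @param importance Importance table ([global_importance()]).
#' @param feature_set The model's feature genes (selected DEGs).
#' @return List with `shap_score` (0 when no member is a feature) and
#'   `n_contributing_genes`.
#' @export
shap_weighted_score <- function(term_set, importance, feature_set) {
  contributing <- intersect(intersect(term_set, feature_set), importance$gene)
  if (length(contributing) == 0) {
    return(list(shap_score = 0, n_contributing_genes = 0L))
  }
  imp <- stats::setNames(importance$mean_abs_shap, importance$gene)
  list(shap_score = mean(imp[contributing]),
       n_contributing_genes = length(contributing))
}

#' Attribution-weighted scores for a whole collection
#'
#' @inheritParams shap_weighted_score
#' @param collection Named list of gene sets.
#' @return Data frame with term, shap_score, n_contributing_genes, sorted
#'   by descending score.
#' @export
pathway_shap_scores <- function(collection, importance, feature_set) {
  rows <- lapply(names(collection), function(term) {
    r <- shap_weighted_score(collection[[term]], importance, feature_set)
    data.frame(term = term, shap_score = r$shap_score,
               n_contributing_genes = r$n_contributing_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$shap_score, out$term), ]
}
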