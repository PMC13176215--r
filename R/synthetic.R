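#' Specify a synthetic multi-dataset cartilage cohort
#'
#' Bundles every knob of the synthetic-data generator into a validated spec.
#' The generative model is additive on the log2 scale: for gene \eqn{g} and
#' sample \eqn{s} in dataset (batch) \eqn{b},
#' \deqn{y_{gs} = \mu_g + grade(s)\,d_g\,\beta\,[g \in DEG]
#'              + strain(s)\,d_g\,\tau\,[g \in mechano]
#'              + \gamma_{bg} + \delta_{bg}\,\varepsilon_{gs},}
#' with per-gene baseline \eqn{\mu_g}, planted fold change \eqn{\beta}
#' (`deg_effect`, direction \eqn{d_g = \pm 1}), strain response \eqn{\tau}
#' (`strain_effect`), additive batch shift \eqn{\gamma_{bg} \sim N(0,
#' batch\_shift\_sd^2)}, multiplicative batch dispersion \eqn{\delta_{bg} =
#' \exp(N(0, batch\_scale\_sd^2))}, and noise \eqn{\varepsilon_{gs} \sim
#' N(0, \sigma_g^2)}. This is exactly the additive + multiplicative
#' location/scale form assumed by parametric empirical-Bayes batch
#' correction, so the corrector is exercised under its own model.
#'
#' Degradation grades default to 0 (healthy), 0.4 (early-stage, meniscectomy
#' -like) and 1 (advanced OA); the binary training class is `grade >= 0.5`,
#' so early-grade samples are labelled non-OA at train time and are expected
#' to land mid-spectrum at predict time.
#'
#' @param n_genes Number of genes.
#' @param n_datasets Number of datasets (= batches).
#' @param samples_per_condition Named integer vector: samples per condition
#'   *per dataset*. Names must match `names(condition_grades)`.
#' @param condition_grades Named numeric vector of degradation grades in
#'   `[0, 1]` for each condition.
#' @param baseline_mean_range Range (log2 units) for per-gene baselines.
#' @param baseline_sd_range Range for per-gene noise SDs; default
#'   `noise_sd * c(0.8, 1.2)` gives mild gene-level heteroscedasticity.
#' @param batch_shift_sd SD (log2 units) of the additive batch effect.
#' @param batch_scale_sd SD of the log multiplicative batch effect.
#' @param n_deg_up,n_deg_down Planted up-/down-regulated gene counts.
#' @param deg_effect Planted |log2 fold change| at full grade (log2 units).
#' @param n_mechano Number of planted DEGs that also respond to strain.
#' @param strain_effect Expression shift (log2 units) added to
#'   mechano-responsive genes in strained samples, in the gene's DEG
#'   direction.
#' @param noise_sd Reference noise SD (log2 units).
#' @param seed Integer seed; all generator output is a pure function of the
#'   spec including the seed.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [simulate_strain_cohort()],
#'   [simulate_null_cohort()], [simulate_gene_sets()]
#' @export
cohort_spec <- function(n_genes = 2000,
                        n_datasets = 3,
                        samples_per_condition = c(healthy = 14, early = 6, advanced = 20),
                        condition_grades = c(healthy = 0, early = 0.4, advanced = 1),
                        baseline_mean_range = c(4, 10),
                        baseline_sd_range = NULL,
                        batch_shift_sd = 2,
                        batch_scale_sd = 0.15,
                        n_deg_up = 74,
                        n_deg_down = 19,
                        deg_effect = 1.0,
                        n_mechano = 16,
                        strain_effect = 2.0,
                        noise_sd = 0.5,
                        seed = 1L) {
  if (is.null(baseline_sd_range)) baseline_sd_range <- noise_sd * c(0.8, 1.2)
  spec <- list(
    n_genes = as.integer(n_genes), n_datasets = as.integer(n_datasets),
    samples_per_condition = samples_per_condition,
    condition_grades = condition_grades,
    baseline_mean_range = baseline_mean_range,
    baseline_sd_range = baseline_sd_range,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    n_deg_up = as.integer(n_deg_up), n_deg_down = as.integer(n_deg_down),
    deg_effect = deg_effect, n_mechano = as.integer(n_mechano),
    strain_effect = strain_effect, noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  counts <- c(
    n_genes = spec$n_genes, n_datasets = spec$n_datasets,
    n_deg_up = spec$n_deg_up, n_deg_down = spec$n_deg_down,
    n_mechano = spec$n_mechano, spec$samples_per_condition
  )
  if (any(counts < 0)) {
    stop("cohort_spec invariant violated: all counts must be >= 0 (",
         paste(names(counts)[counts < 0], collapse = ", "), ")")
  }
  if (spec$n_deg_up + spec$n_deg_down > spec$n_genes) {
    stop("cohort_spec invariant violated: n_deg_up + n_deg_down <= n_genes")
  }
  if (spec$n_mechano > spec$n_deg_up + spec$n_deg_down) {
    stop("cohort_spec invariant violated: n_mechano <= n_deg_up + n_deg_down")
  }
  if (!setequal(names(spec$samples_per_condition), names(spec$condition_grades))) {
    stop("cohort_spec invariant violated: samples_per_condition and ",
         "condition_grades must name the same conditions")
  }
  if (any(spec$condition_grades < 0 | spec$condition_grades > 1)) {
    stop("cohort_spec invariant violated: grades lie in [0, 1]")
  }
  invisible(spec)
}

# Gene-level parameters shared by every cohort drawn from one spec.
# Drawn from a seed offset so cohort-level draws cannot collide with them.
.gene_params <- function(spec) {
  set.seed(spec$seed)
  genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
  mu <- stats::runif(spec$n_genes, spec$baseline_mean_range[1], spec$baseline_mean_range[2])
  sd_g <- stats::runif(spec$n_genes, spec$baseline_sd_range[1], spec$baseline_sd_range[2])
  n_deg <- spec$n_deg_up + spec$n_deg_down
  deg_idx <- if (n_deg > 0) sample.int(spec$n_genes, n_deg) else integer(0)
  direction <- integer(spec$n_genes)
  direction[deg_idx[seq_len(spec$n_deg_up)]] <- 1L
  if (spec$n_deg_down > 0) {
    direction[deg_idx[spec$n_deg_up + seq_len(spec$n_deg_down)]] <- -1L
  }
  mechano_idx <- if (spec$n_mechano > 0) sample(deg_idx, spec$n_mechano) else integer(0)
  list(genes = genes, mu = mu, sd = sd_g, deg_idx = deg_idx,
       direction = direction, mechano_idx = sort(mechano_idx))
}

.simulate_samples <- function(spec, gp, meta, seed) {
  set.seed(seed)
  n <- nrow(meta)
  p <- spec$n_genes
  batches <- unique(meta$batch)
  gamma <- matrix(stats::rnorm(length(batches) * p, 0, spec$batch_shift_sd),
                  nrow = p, dimnames = list(gp$genes, batches))
  delta <- matrix(exp(stats::rnorm(length(batches) * p, 0, spec$batch_scale_sd)),
                  nrow = p, dimnames = list(gp$genes, batches))
  eps <- matrix(stats::rnorm(p * n, 0, gp$sd), nrow = p)
  deg_shift <- gp$direction * spec$deg_effect
  mech <- numeric(p)
  mech[gp$mechano_idx] <- gp$direction[gp$mechano_idx] * spec$strain_effect
  vals <- gp$mu +
    outer(deg_shift, meta$grade) +
    outer(mech, as.numeric(meta$strain)) +
    gamma[, meta$batch, drop = FALSE] +
    delta[, meta$batch, drop = FALSE] * eps
  dimnames(vals) <- list(gp$genes, meta$sample_id)
  vals
}

.ground_truth <- function(spec, gp, meta) {
  deg <- data.frame(
    gene = gp$genes[gp$deg_idx],
    direction = ifelse(gp$direction[gp$deg_idx] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  deg <- deg[order(deg$gene), , drop = FALSE]
  rownames(deg) <- NULL
  list(
    deg_genes = deg,
    mechano_genes = gp$genes[gp$mechano_idx],
    grade_per_sample = stats::setNames(meta$grade, meta$sample_id),
    batch_params = list(shift_sd = spec$batch_shift_sd, scale_sd = spec$batch_scale_sd)
  )
}

#' Simulate a multi-dataset expression cohort with known ground truth
#'
#' Draws `n_datasets` batches, each containing the per-condition sample
#' counts of the spec, under the generative model documented in
#' [cohort_spec()]. Returns the log2 expression matrix (genes x samples),
#' the sample metadata, and the planted ground truth.
#'
#' @param spec A [cohort_spec()].
#' @param role Cohort role recorded in the metadata (e.g. "training").
#' @param sample_seed Seed for the sample-level draws (batch effects,
#'   noise). Gene-level ground truth (baselines, planted DEG and mechano
#'   genes) depends only on `spec$seed`, so cohorts generated from the same
#'   spec with different `sample_seed`s are independent samples of the
#'   *same* population — the right construction for held-out validation
#'   cohorts.
#' @return A list with elements `expr` (matrix, genes x samples), `meta`
#'   (data.frame with columns sample_id, batch, condition, grade, class,
#'   strain, role) and `truth` (list: `deg_genes` data.frame with gene and
#'   direction, `mechano_genes`, `grade_per_sample`, `batch_params`).
#' @examples
#' sc <- simulate_cohort(cohort_spec(n_genes = 50, seed = 7))
#' dim(sc$expr)
#' table(sc$meta$condition, sc$meta$batch)
#' @export
simulate_cohort <- function(spec, role = "training",
                            sample_seed = spec$seed + 1L) {
  validate_cohort_spec(spec)
  gp <- .gene_params(spec)
  conds <- names(spec$samples_per_condition)
  meta <- do.call(rbind, lapply(seq_len(spec$n_datasets), function(b) {
    do.call(rbind, lapply(conds, function(cond) {
      n <- spec$samples_per_condition[[cond]]
      if (n == 0) return(NULL)
      data.frame(
        batch = sprintf("dataset%02d", b), condition = cond,
        grade = spec$condition_grades[[cond]],
        idx = seq_len(n), stringsAsFactors = FALSE
      )
    }))
  }))
  meta$sample_id <- sprintf("%s_%s_%02d", meta$batch, meta$condition, meta$idx)
  meta$idx <- NULL
  meta$class <- as.integer(meta$grade >= 0.5)
  meta$strain <- FALSE
  meta$role <- role
  meta <- meta[, c("sample_id", "batch", "condition", "grade", "class", "strain", "role")]
  rownames(meta) <- NULL
  expr <- .simulate_samples(spec, gp, meta, seed = sample_seed)
  list(expr = expr, meta = meta, truth = .ground_truth(spec, gp, meta))
}

#' Simulate a strain-vs-control mechanotransduction mini-cohort
#'
#' A single-dataset cohort mirroring an in vitro cyclic-tensile-strain
#' experiment: all samples sit at a fixed mid-range degradation grade, and
#' the strained half additionally shifts the planted mechano-responsive
#' genes by `strain_effect` in each gene's differential-expression
#' direction. Gene-level parameters (baselines, planted genes) are shared
#' with [simulate_cohort()] for the same spec, so a model trained on the
#' main cohort can be applied directly.
#'
#' @param spec A [cohort_spec()].
#' @param n_per_group Samples per arm (control / strain).
#' @param grade Degradation grade assigned to every sample.
#' @param seed Seed for this cohort's draws; defaults to `spec$seed + 2`.
#' @return Same structure as [simulate_cohort()].
#' @export
simulate_strain_cohort <- function(spec, n_per_group = 9, grade = 0.5,
                                   seed = spec$seed + 2L) {
  validate_cohort_spec(spec)
  gp <- .gene_params(spec)
  meta <- data.frame(
    sample_id = c(sprintf("strain_ctrl_%02d", seq_len(n_per_group)),
                  sprintf("strain_str_%02d", seq_len(n_per_group))),
    batch = "strain_dataset",
    condition = rep(c("control", "strain"), each = n_per_group),
    grade = grade,
    class = rep(0:1, each = n_per_group),
    strain = rep(c(FALSE, TRUE), each = n_per_group),
    role = "mechanotransduction",
    stringsAsFactors = FALSE
  )
  expr <- .simulate_samples(spec, gp, meta, seed = seed)
  list(expr = expr, meta = meta, truth = .ground_truth(spec, gp, meta))
}

#' Simulate a null cohort (no planted signal)
#'
#' Identical to [simulate_cohort()] with `deg_effect = 0` and
#' `strain_effect = 0`: class labels are carried in the metadata but are
#' independent of expression, and the returned ground truth lists no
#' differentially expressed or mechano-responsive genes.
#'
#' @inheritParams simulate_cohort
#' @return Same structure as [simulate_cohort()].
#' @export
simulate_null_cohort <- function(spec, role = "null") {
  spec$deg_effect <- 0
  spec$strain_effect <- 0
  out <- simulate_cohort(spec, role = role)
  out$truth$deg_genes <- out$truth$deg_genes[0, , drop = FALSE]
  out$truth$mechano_genes <- character(0)
  out
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Builds `n_sets` gene sets over the given universe. When
#' `enriched_fraction > 0` and the ground truth lists differentially
#' expressed genes, the first set ("PLANTED_SET") draws
#' `round(enriched_fraction * size)` of its members from the DEG list and
#' the remainder uniformly from the non-DEG universe, so its DEG overlap
#' exceeds the hypergeometric expectation; all other sets are uniform
#' draws.
#'
#' @param genes Character vector: the gene universe.
#' @param truth Ground truth from a simulate function (uses
#'   `truth$deg_genes$gene`); an empty DEG list yields all-uniform sets.
#' @param n_sets Number of sets (>= 1).
#' @param enriched_fraction Fraction of the planted set drawn from DEGs,
#'   in `[0, 1]`; 0 disables planting.
#' @param set_size_range Integer range of set sizes.
#' @param seed Integer seed.
#' @return Named list of character vectors (GMT-representable), with the
#'   planted term name in `attr(, "planted")` (NA if none).
#' @export
simulate_gene_sets <- function(genes, truth, n_sets = 50,
                               enriched_fraction = 0.8,
                               set_size_range = c(10, 40), seed = 1L) {
  if (n_sets < 1) stop("n_sets must be >= 1")
  if (enriched_fraction < 0 || enriched_fraction > 1) {
    stop("enriched_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  deg <- intersect(truth$deg_genes$gene, genes)
  size_choices <- seq(set_size_range[1], set_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), n_sets, replace = TRUE)]
  sizes <- pmin(sizes, length(genes))
  sets <- lapply(seq_len(n_sets), function(i) sample(genes, sizes[i]))
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  planted <- NA_character_
  if (enriched_fraction > 0 && length(deg) > 0) {
    size <- sizes[1]
    k <- min(round(enriched_fraction * size), length(deg))
    rest <- setdiff(genes, deg)
    sets[[1]] <- c(sample(deg, k), if (size > k) sample(rest, size - k))
    names(sets)[1] <- "PLANTED_SET"
    planted <- "PLANTED_SET"
  }
  attr(sets, "planted") <- planted
  sets
}

# ---- standard-format I/O ----------------------------------------------------

#' Read/write gene-by-sample expression matrices as TSV
#'
#' The on-disk format is a tab-separated table whose first column (`gene`)
#' holds gene symbols and whose remaining columns are samples.
#'
#' @param expr Numeric matrix, genes in rows (rownames = symbols).
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix; `write_expression_tsv`
#'   returns `path` invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read/write sample metadata as TSV
#'
#' @param meta Data frame with at least sample_id, batch, condition, class,
#'   role columns.
#' @param path File path.
#' @return `read_metadata_tsv` returns the data frame.
#' @export
write_metadata_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read/write gene-set collections in GMT format
#'
#' GMT is the standard tab-separated gene-set format: one set per line as
#' `term<TAB>description<TAB>member1<TAB>member2...`. Reading delegates to
#' [fgsea::gmtPathways()].
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
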