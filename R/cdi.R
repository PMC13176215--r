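#' Cartilage Degradation Index for new samples
#'
#' The CDI is the soft-voting ensemble's class-1 probability used directly
#' as a continuous 0-1 severity score: values near 0 indicate healthy
#' cartilage, values near 1 advanced biomechanical degradation. Each score
#' is annotated with a risk zone: `[0, 0.2]` low, `(0.2, 0.5]`
#' intermediate, `(0.5, 0.8)` elevated, `[0.8, 1]` high.
#'
#' @param model A fitted `cdi_ensemble` ([fit_ensemble()]).
#' @param X_new Sample-by-feature matrix over the model's features.
#' @param condition Optional per-sample condition labels carried into the
#'   output.
#' @return Data frame with columns sample_id, cdi, zone, condition.
#' @export
compute_cdi <- function(model, X_new, condition = NULL) {
  cdi <- predict(model, X_new, type = "ensemble")
  ids <- rownames(X_new)
  if (is.null(ids)) ids <- sprintf("sample_%03d", seq_along(cdi))
  if (is.null(condition)) condition <- NA_character_
  data.frame(
    sample_id = ids, cdi = unname(cdi), zone = cdi_zone(cdi),
    condition = condition, stringsAsFactors = FALSE
  )
}

#' Map CDI values to risk zones
#'
#' @param cdi Numeric vector of probabilities in `[0, 1]`.
#' @return Character vector: "low" for `[0, 0.2]`, "intermediate" for
#'   `(0.2, 0.5]`, "elevated" for `(0.5, 0.8)`, "high" for `[0.8, 1]`.
#' @export
cdi_zone <- function(cdi) {
  if (any(cdi < 0 | cdi > 1, na.rm = TRUE)) stop("CDI values must lie in [0, 1]")
  ifelse(cdi <= 0.2, "low",
         ifelse(cdi <= 0.5, "intermediate",
                ifelse(cdi < 0.8, "elevated", "high")))
}

#' Summarize CDI scores by condition
#'
#' @param records CDI records from [compute_cdi()].
#' @param by Grouping column (default "condition").
#' @return Data frame with condition, mean, sd (0 for singleton groups,
#'   flagged by `singleton`), and n; counts sum to the input size.
#' @export
summarize_cdi <- function(records, by = "condition") {
  groups <- split(records$cdi, records[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(
      condition = g, mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0,
      n = length(v), singleton = length(v) == 1,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
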