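#' Infer a ranked gene regulatory network
#'
#' Full inference pipeline: per-target importance scoring with each
#' selected method ([score_all_targets()]), per-method min-max
#' normalization, weighted combination, z-scoring, and ranking with
#' truncation. With `methods = c("rfr", "etr")` the SVR branch and its
#' weight are dropped (the cheaper two-method mode).
#'
#' @param expr Samples x genes expression matrix.
#' @param tfs Candidate regulators; `NULL` means every gene.
#' @param methods Subset of `c("rfr", "etr", "svr")`.
#' @param weights Named combination weights (see [combine_weighted()]).
#' @param limit Maximum number of ranked edges kept.
#' @param seed Master seed; the whole run is a pure function of its
#'   inputs and this seed.
#' @param workers Parallel workers for per-target scoring.
#' @param normalize Min-max normalize each method's matrix before
#'   combining (default `TRUE`; disable only for sensitivity analysis).
#' @param tree_cfg,svr_cfg Optional method configurations.
#' @return A list of class `grn_inference` with `edges` (ranked
#'   `data.frame`), `scores` (raw per-method matrices), `combined` and
#'   `zscored` matrices.
#' @export
infer_grn <- function(expr, tfs = NULL, methods = c("rfr", "etr", "svr"),
                      weights = c(rfr = 1, etr = 0.5, svr = 0.1),
                      limit = 100000L, seed = 1L, workers = 1L,
                      normalize = TRUE, tree_cfg = NULL, svr_cfg = NULL) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  methods <- match.arg(methods, c("rfr", "etr", "svr"), several.ok = TRUE)
  if (is.null(tfs)) tfs <- colnames(expr)
  scores <- lapply(stats::setNames(methods, methods), function(m) {
    cfg <- switch(m,
                  rfr = tree_cfg %||% tree_config("random_forest"),
                  etr = if (is.null(tree_cfg)) tree_config("extra_trees") else {
                    cfg <- tree_cfg; cfg$method <- "extra_trees"; cfg
                  },
                  svr = svr_cfg %||% svr_config())
    score_all_targets(expr, tfs, method = m, config = cfg,
                      seed = seed, workers = workers)
  })
  normalized <- if (normalize) lapply(scores, normalize_method_scores) else scores
  combined <- combine_weighted(normalized, weights)
  zscored <- zscore_scores(combined)
  edges <- rank_and_truncate(zscored, limit)
  structure(list(edges = edges, scores = scores, combined = combined,
                 zscored = zscored, methods = methods, weights = weights,
                 seed = seed),
            class = "grn_inference")
}

#' @export
print.grn_inference <- function(x, ...) {
  cat(sprintf("GRN inference (%s): %d ranked edges from %d regulators x %d targets\n",
              paste(x$methods, collapse = "+"), nrow(x$edges),
              nrow(x$combined), ncol(x$combined)))
  print(head(x$edges, 5))
  invisible(x)
}
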