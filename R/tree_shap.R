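# Convert a fitted ranger forest into the flat node arrays consumed by
# the compiled Shapley traversal. Uses ranger's convention: numeric split,
# value <= splitval goes to the left child; node ids are 0-based.
ranger_tree_arrays <- function(fit) {
  lapply(seq_len(fit$num.trees), function(k) {
    ti <- ranger::treeInfo(fit, k)
    leaf <- ti$terminal
    list(left = as.integer(ifelse(leaf, -1L, ti$leftChild)),
         right = as.integer(ifelse(leaf, -1L, ti$rightChild)),
         var = as.integer(ifelse(leaf, -1L, ti$splitvarID)),
         val = as.numeric(ifelse(leaf, 0, ti$splitval)),
         pred = as.numeric(ifelse(leaf, ti$prediction, 0)))
  })
}

#' Per-sample Shapley values for a fitted tree ensemble
#'
#' Computes interventional Shapley values of every feature for every
#' foreground row, marginalizing over a background set of rows: the value
#' of a feature coalition `S` for sample `x` and background row `b` is the
#' forest evaluated on the hybrid point taking coordinates in `S` from `x`
#' and the rest from `b`, averaged over backgrounds. The computation is
#' exact for this value function (no sampling), so the attributions
#' satisfy the additivity identity
#' `rowSums(phi) + base == predict(fit, X)` to numerical precision.
#'
#' @param fit A regression forest fitted by [ranger::ranger()].
#' @param x Foreground rows: numeric matrix, columns in the order the
#'   forest was fitted on.
#' @param background Background rows: numeric matrix with the same
#'   columns.
#' @return A list with `phi` (rows x features matrix of signed Shapley
#'   values), `base` (mean background prediction) and `pred` (forest
#'   predictions on `x`).
#' @export
forest_shap <- function(fit, x, background) {
  stopifnot(inherits(fit, "ranger"), is.matrix(x), is.matrix(background))
  vars <- fit$forest$independent.variable.names
  if (!identical(colnames(x), vars) || !identical(colnames(background), vars)) {
    stopf("column names of x/background must match the forest's feature order")
  }
  trees <- ranger_tree_arrays(fit)
  out <- cpp_forest_shap(trees, x, background)
  dimnames(out$phi) <- list(rownames(x), vars)
  out
}
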