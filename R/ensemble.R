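#' Min-max normalize an importance matrix
#'
#' Affine rescaling of the whole matrix to `[0, 1]`, making scores from
#' different methods commensurate before the weighted combination. A
#' constant matrix maps to all zeros with a warning.
#'
#' @param m Nonnegative finite numeric matrix (regulators x targets).
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
normalize_method_scores <- function(m) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m))) stopf("importance matrix contains non-finite values")
  rng <- range(m)
  if (rng[1] == rng[2]) {
    warning("constant importance matrix; normalized to all zeros", call. = FALSE)
    out <- m * 0
  } else {
    out <- (m - rng[1]) / (rng[2] - rng[1])
  }
  attr(out, "method_tag") <- attr(m, "method_tag")
  out
}

#' Combine importance matrices by a weighted average
#'
#' Elementwise weighted mean of the per-method score matrices:
#' \deqn{R = \frac{\omega_1 \phi^{(R)} + \omega_2 \phi^{(E)} + \omega_3 C^{(SV)}}
#'   {\omega_1 + \omega_2 + \omega_3}}
#' Methods absent from `scores` are dropped together with their weights,
#' so the two-method (no-SVR) mode is the same formula over the remaining
#' terms. The ranking is invariant to rescaling all weights by a positive
#' constant; the defaults `(1, 0.5, 0.1)` carry the same 10:5:1 ratio as
#' the tuned integer weights.
#'
#' @param scores Named list of aligned matrices; names are a subset of
#'   `names(weights)`.
#' @param weights Named nonnegative weights with positive sum over the
#'   present methods.
#' @return The combined matrix.
#' @export
combine_weighted <- function(scores,
                             weights = c(rfr = 1, etr = 0.5, svr = 0.1)) {
  stopifnot(is.list(scores), length(scores) >= 1, !is.null(names(scores)))
  if (!all(names(scores) %in% names(weights))) {
    stopf("no weight given for method(s): %s",
          paste(setdiff(names(scores), names(weights)), collapse = ", "))
  }
  w <- weights[names(scores)]
  if (any(w < 0) || sum(w) <= 0) stopf("weights must be nonnegative with positive sum")
  ref <- dimnames(scores[[1]])
  for (m in scores) {
    if (!identical(dim(m), dim(scores[[1]])) || !identical(dimnames(m), ref)) {
      stopf("importance matrices are not aligned (differing dimensions or orderings)")
    }
  }
  out <- Reduce(`+`, Map(function(m, wi) m * wi, scores, w)) / sum(w)
  attr(out, "method_tag") <- paste(names(scores), collapse = "+")
  out
}

#' Z-score the combined edge scores
#'
#' Standardizes the vector of all candidate (regulator, target !=
#' regulator) entries to mean 0 and population standard deviation 1,
#' giving the final scores an interpretable scale; self-pairs are
#' excluded from the statistics and left unscored (`NA`). A strictly
#' monotone transform, so the edge ranking is unchanged.
#'
#' @param m Combined importance matrix (regulators x targets).
#' @return Matrix of z-scores with `NA` at self-pairs.
#' @export
zscore_scores <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  self <- outer(rownames(m), colnames(m), `==`)
  vals <- m[!self]
  if (length(unique(vals)) < 2) {
    stopf("fewer than 2 distinct edge scores; z-scoring impossible")
  }
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  if (sigma == 0) stopf("zero variance in edge scores; no ranking possible")
  out <- (m - mu) / sigma
  out[self] <- NA_real_
  attr(out, "method_tag") <- attr(m, "method_tag")
  out
}

#' Rank all candidate edges and truncate
#'
#' Flattens the score matrix into directed (regulator, target) pairs,
#' sorts by score descending with ties broken by lexical
#' (regulator, target) order, and truncates to `limit` edges (default
#' 100 000, the DREAM submission cap). Self-pairs and unscored (`NA`)
#' entries are excluded.
#'
#' @param m Score matrix (regulators x targets).
#' @param limit Maximum number of edges returned.
#' @return A `data.frame` with columns `regulator`, `target`, `score`.
#' @export
rank_and_truncate <- function(m, limit = 100000L) {
  stopifnot(is.matrix(m), limit >= 1)
  reg <- rownames(m)[row(m)]
  tgt <- colnames(m)[col(m)]
  keep <- reg != tgt & is.finite(as.vector(m))
  edges <- data.frame(regulator = reg[keep], target = tgt[keep],
                      score = as.vector(m)[keep], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$regulator, edges$target), ]
  rownames(edges) <- NULL
  head(edges, limit)
}

#' Grid search for ensemble weights on a scored dataset
#'
#' Utility for re-tuning the combination weights against a gold standard:
#' evaluates every weight triple on a grid and returns the one maximizing
#' the chosen metric. Operates on any supplied normalized score matrices.
#'
#' @param scores Named list of normalized importance matrices.
#' @param gold Gold standard (see [read_gold_standard()]).
#' @param tfs Regulator identifiers.
#' @param genes All gene identifiers.
#' @param grid Numeric vector of candidate weight values per method.
#' @param metric `"aupr"` or `"auroc"`.
#' @return List with `weights` (best triple) and `value` (metric).
#' @export
grid_search_weights <- function(scores, gold, tfs, genes,
                                grid = c(0, 1, 2, 5, 10),
                                metric = c("aupr", "auroc")) {
  metric <- match.arg(metric)
  combos <- expand.grid(rep(list(grid), length(scores)))
  names(combos) <- names(scores)
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    w <- unlist(combos[i, , drop = TRUE])
    if (sum(w) <= 0) next
    combined <- combine_weighted(scores, w)
    edges <- rank_and_truncate(combined)
    ev <- evaluate_predictions(edges, gold, tfs, genes)
    val <- ev[[metric]]
    if (is.null(best) || val > best$value) {
      best <- list(weights = w, value = val)
    }
  }
  best
}
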