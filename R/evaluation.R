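#' Label ranked predictions against a gold standard
#'
#' Labels each predicted edge 1 if it is a gold-standard positive and 0
#' otherwise, and counts positives and negatives over the full prediction
#' universe: all directed (TF, gene) pairs with TF != gene. Pairs absent
#' from the gold-standard file are negatives; positives never predicted
#' still count toward the totals, so the maximum achievable recall of a
#' truncated list can be below 1.
#'
#' @param predictions Ranked edge `data.frame` (`regulator`, `target`,
#'   `score`, non-increasing).
#' @param gold Gold standard `data.frame` from [read_gold_standard()].
#' @param tfs Regulator identifiers (the only allowed edge sources).
#' @param genes All gene identifiers.
#' @return A list with `scores`, `labels` (in prediction order),
#'   `n_positives`, `n_negatives` (universe totals) and `n_predicted`.
#' @export
label_edges <- function(predictions, gold, tfs, genes) {
  validate_ranked_edges(predictions)
  stopifnot(length(tfs) >= 1, length(genes) >= 1, all(tfs %in% genes))
  bad_reg <- setdiff(predictions$regulator, tfs)
  if (length(bad_reg) > 0) {
    stopf("predicted regulator '%s' is not in the TF universe", bad_reg[1])
  }
  bad_tgt <- setdiff(predictions$target, genes)
  if (length(bad_tgt) > 0) {
    stopf("predicted target '%s' is not in the gene universe", bad_tgt[1])
  }
  pos <- gold[gold$label == 1L, , drop = FALSE]
  bad_pos <- !(pos$regulator %in% tfs & pos$target %in% genes)
  if (any(bad_pos)) {
    stopf("gold-standard positive %s -> %s lies outside the TF x gene universe",
          pos$regulator[which(bad_pos)[1]], pos$target[which(bad_pos)[1]])
  }
  n_universe <- length(tfs) * length(genes) - length(intersect(tfs, genes))
  pos_key <- paste(pos$regulator, pos$target, sep = "\t")
  pred_key <- paste(predictions$regulator, predictions$target, sep = "\t")
  labels <- as.integer(pred_key %in% pos_key)
  n_pos <- length(unique(pos_key))
  list(scores = predictions$score, labels = labels,
       n_positives = n_pos, n_negatives = n_universe - n_pos,
       n_predicted = length(labels))
}

# Tied-score groups of a descending prediction list: cumulative true and
# false positives at the end of each group.
tie_groups <- function(scores, labels) {
  ends <- cumsum(rle(scores)$lengths)  # scores are non-increasing
  cum_tp <- cumsum(labels)[ends]
  list(cum_tp = cum_tp, cum_fp = ends - cum_tp, cum_n = ends)
}

#' Area under the ROC curve of a labeled ranking
#'
#' Trapezoidal area under the ROC curve over the full prediction
#' universe. Tied scores step jointly (equivalent to averaging over all
#' orderings of the tie), and edges absent from the prediction list form
#' one tied block below all predictions; the result equals the
#' Mann-Whitney concordant-pair statistic.
#'
#' @param labeled Output of [label_edges()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labeled) {
  p <- labeled$n_positives
  n <- labeled$n_negatives
  if (p < 1 || n < 1) {
    stopf("AUROC undefined: need at least one positive and one negative (have %d, %d)", p, n)
  }
  l <- labeled$n_predicted
  tp_pred <- sum(labeled$labels)
  u_pos <- p - tp_pred
  u <- (p + n) - l
  # ranks counted from the bottom; the unpredicted block is tied at the
  # bottom with average rank (u + 1) / 2
  pred_ranks <- u + rank(labeled$scores, ties.method = "average")
  sum_rank_pos <- u_pos * (u + 1) / 2 + sum(pred_ranks[labeled$labels == 1L])
  (sum_rank_pos - p * (p + 1) / 2) / (p * n)
}

#' Area under the precision-recall curve of a labeled ranking
#'
#' Average-precision step sum over the ranked list,
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} evaluated at the end of each
#' tied-score group, with recall denominated by all gold positives in the
#' universe: positives never retrieved leave the terminal recall below 1
#' and contribute no area. No interpolation is applied.
#'
#' @param labeled Output of [label_edges()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(labeled) {
  p <- labeled$n_positives
  if (p < 1) stopf("AUPR undefined: no positives in the universe")
  if (labeled$n_predicted == 0) return(0)
  g <- tie_groups(labeled$scores, labeled$labels)
  recall <- g$cum_tp / p
  precision <- g$cum_tp / g$cum_n
  sum(diff(c(0, recall)) * precision)
}

#' True/false positives among the top-k predictions
#'
#' @param labeled Output of [label_edges()].
#' @param k Cutoff; counts run over the first `min(k, length)` entries.
#' @return Named integer vector `c(tp, fp)`.
#' @export
topk_confusion <- function(labeled, k) {
  stopifnot(k >= 1)
  lab <- head(labeled$labels, k)
  c(tp = sum(lab), fp = length(lab) - sum(lab))
}

#' Evaluate ranked predictions against a gold standard
#'
#' Computes AUROC, AUPR, top-k counts and the ROC / PR curve points of a
#' ranked edge list under the DREAM-style convention: the universe is all
#' directed (TF, gene != TF) pairs, unlisted pairs are negatives, and
#' unpredicted edges rank below all predictions.
#'
#' @inheritParams label_edges
#' @param top_k Cutoff for the confusion counts (default 100).
#' @return An object of class `grn_evaluation`: a list with `auroc`,
#'   `aupr`, `n_positives`, `n_negatives`, `top_k`, `topk_tp`, `topk_fp`,
#'   and curve points `roc_points` (`fpr`, `tpr`) and `pr_points`
#'   (`recall`, `precision`).
#' @export
evaluate_predictions <- function(predictions, gold, tfs, genes, top_k = 100L) {
  labeled <- label_edges(predictions, gold, tfs, genes)
  p <- labeled$n_positives
  n <- labeled$n_negatives
  roc <- data.frame(fpr = 0, tpr = 0)
  pr <- data.frame(recall = 0, precision = 1)
  if (labeled$n_predicted > 0) {
    g <- tie_groups(labeled$scores, labeled$labels)
    roc <- rbind(roc, data.frame(fpr = g$cum_fp / n, tpr = g$cum_tp / p))
    pr <- rbind(pr, data.frame(recall = g$cum_tp / p,
                               precision = g$cum_tp / g$cum_n))
  }
  if ((p + n) > labeled$n_predicted) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  }
  tk <- topk_confusion(labeled, top_k)
  structure(list(auroc = auroc(labeled), aupr = aupr(labeled),
                 n_positives = p, n_negatives = n,
                 n_predicted = labeled$n_predicted,
                 top_k = as.integer(top_k),
                 topk_tp = unname(tk["tp"]), topk_fp = unname(tk["fp"]),
                 roc_points = roc, pr_points = pr),
            class = "grn_evaluation")
}

#' @export
print.grn_evaluation <- function(x, ...) {
  cat(sprintf("GRN evaluation: %d predictions over %d positives / %d negatives\n",
              x$n_predicted, x$n_positives, x$n_negatives))
  cat(sprintf("  AUROC: %.4f\n  AUPR:  %.4f (positive prevalence %.4f)\n",
              x$auroc, x$aupr, x$n_positives / (x$n_positives + x$n_negatives)))
  cat(sprintf("  top-%d: %d true / %d false positives\n",
              x$top_k, x$topk_tp, x$topk_fp))
  invisible(x)
}
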