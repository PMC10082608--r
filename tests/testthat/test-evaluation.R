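pred_df <- function(reg, tgt, score) {
  data.frame(regulator = reg, target = tgt, score = score,
             stringsAsFactors = FALSE)
}

gold_df <- function(reg, tgt, label = 1L) {
  data.frame(regulator = reg, target = tgt, label = as.integer(label),
             stringsAsFactors = FALSE)
}

test_that("label_edges counts over the full TF x gene universe", {
  genes <- c("G1", "G2", "G3")
  lab <- label_edges(pred_df("G1", "G2", 0.9), gold_df("G1", "G2"),
                     tfs = "G1", genes = genes)
  expect_identical(lab$labels, 1L)
  expect_identical(lab$n_positives, 1L)
  expect_identical(lab$n_negatives, 1L)  # universe = G1->G2, G1->G3

  # unpredicted positive still counts toward the totals
  lab2 <- label_edges(pred_df("G1", "G2", 0.9), gold_df("G1", "G3"),
                      tfs = "G1", genes = genes)
  expect_identical(lab2$labels, 0L)
  expect_identical(lab2$n_positives, 1L)

  expect_error(label_edges(pred_df("G9", "G2", 1), gold_df("G1", "G2"),
                           "G1", genes), "G9")
  expect_error(label_edges(pred_df("G1", "G9", 1), gold_df("G1", "G2"),
                           "G1", genes), "G9")
  expect_error(label_edges(pred_df("G1", "G2", 1), gold_df("G2", "G3"),
                           "G1", genes), "outside")
})

test_that("AUROC handles perfect, tied and interleaved rankings", {
  genes <- paste0("G", 1:5)
  tfs <- "G1"
  universe_preds <- function(scores) {
    pred_df(rep("G1", 4), paste0("G", 2:5), scores)
  }
  gold <- gold_df(c("G1", "G1"), c("G2", "G3"))

  perfect <- label_edges(universe_preds(c(4, 3, 2, 1)), gold, tfs, genes)
  expect_equal(auroc(perfect), 1.0)

  tied <- label_edges(universe_preds(c(1, 1, 1, 1)), gold, tfs, genes)
  expect_equal(auroc(tied), 0.5)

  inter <- label_edges(pred_df(rep("G1", 4), c("G2", "G4", "G3", "G5"),
                               c(4, 3, 2, 1)), gold, tfs, genes)
  expect_equal(auroc(inter), 0.75)

  reversed <- label_edges(universe_preds(c(1, 2, 3, 4))[4:1, ], gold,
                          tfs, genes)
  expect_equal(auroc(reversed), 1 - auroc(perfect))
})

test_that("AUROC places unpredicted edges in one tied bottom block", {
  genes <- paste0("G", 1:5)
  gold <- gold_df(c("G1", "G1"), c("G2", "G3"))
  # only one (negative) edge predicted; both positives unpredicted, tied
  # with the remaining negative: per-positive concordance 0.25
  lab <- label_edges(pred_df("G1", "G4", 1), gold, "G1", genes)
  expect_equal(auroc(lab), 0.25)
})

test_that("AUPR follows the average-precision step sum", {
  genes <- paste0("G", 1:5)
  tfs <- "G1"
  gold <- gold_df(c("G1", "G1"), c("G2", "G3"))

  top2 <- label_edges(pred_df(rep("G1", 2), c("G2", "G3"), c(2, 1)),
                      gold, tfs, genes)
  expect_equal(aupr(top2), 1.0)

  inter <- label_edges(pred_df(rep("G1", 4), c("G2", "G4", "G3", "G5"),
                               c(4, 3, 2, 1)), gold, tfs, genes)
  expect_equal(aupr(inter), 0.5 * 1 + 0.5 * (2 / 3))

  miss <- label_edges(pred_df("G1", "G4", 1), gold, tfs, genes)
  expect_equal(aupr(miss), 0)
})

test_that("metrics require both classes", {
  genes <- c("G1", "G2")
  lab <- label_edges(pred_df("G1", "G2", 1), gold_df("G1", "G2"),
                     "G1", genes)
  expect_error(auroc(lab), "at least one positive and one negative")
})

test_that("top-k confusion counts the leading entries", {
  lab <- list(labels = c(1L, 0L, 1L), scores = c(3, 2, 1))
  expect_identical(topk_confusion(lab, 2), c(tp = 1L, fp = 1L))
  expect_identical(topk_confusion(lab, 10), c(tp = 2L, fp = 1L))
  expect_identical(topk_confusion(list(labels = c(1L, 1L)), 2),
                   c(tp = 2L, fp = 0L))
})

test_that("metrics agree with brute-force oracles on random instances", {
  for (seed in 1:10) {
    inst <- random_eval_instance(seed)
    lab <- label_edges(inst$predictions, inst$gold, inst$tfs, inst$genes)
    expect_lt(abs(auroc(lab) - brute_auroc(inst)), 1e-10)
    expect_lt(abs(aupr(lab) - brute_aupr(inst)), 1e-10)
  }
})

test_that("metrics are invariant under monotone score transforms", {
  inst <- random_eval_instance(99)
  lab <- label_edges(inst$predictions, inst$gold, inst$tfs, inst$genes)
  warped <- inst$predictions
  warped$score <- exp(2 * warped$score)
  lab_w <- label_edges(warped, inst$gold, inst$tfs, inst$genes)
  expect_equal(auroc(lab), auroc(lab_w))
  expect_equal(aupr(lab), aupr(lab_w))
})

test_that("evaluate_predictions returns canonical curves and counts", {
  genes <- paste0("G", 1:4)
  gold <- gold_df(c("G1", "G1"), c("G2", "G3"))
  preds <- pred_df(rep("G1", 2), c("G2", "G4"), c(2, 1))
  ev <- evaluate_predictions(preds, gold, "G1", genes, top_k = 1)
  expect_s3_class(ev, "grn_evaluation")
  expect_identical(ev$topk_tp, 1L)
  expect_identical(ev$topk_fp, 0L)
  expect_equal(ev$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(tail(ev$roc_points, 1), use.names = FALSE), c(1, 1))
  expect_equal(ev$pr_points[1, ], data.frame(recall = 0, precision = 1))
  expect_true(all(ev$roc_points >= 0 & ev$roc_points <= 1))
  expect_true(all(ev$pr_points >= 0 & ev$pr_points <= 1))
  expect_output(print(ev), "AUROC")
})
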