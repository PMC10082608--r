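# Shared helpers for the test suite.

tmp_write <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

# Random expression matrix with named gene columns.
rand_expr <- function(n, ids, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * length(ids)), n, length(ids),
         dimnames = list(NULL, ids))
}

# Hand-built network for simulator unit tests.
manual_network <- function(gene_ids, tf_ids, edges) {
  structure(list(gene_ids = gene_ids, tf_ids = tf_ids, edges = edges),
            class = "synthetic_network")
}

# Build a random labeled-ranking instance over a small TF x gene universe:
# a random subset of pairs is predicted with scores containing ties, and a
# random subset of the universe is gold-positive. Returns everything both
# metric implementations need.
random_eval_instance <- function(seed) {
  set.seed(seed)
  tfs <- paste0("T", 1:sample(2:4, 1))
  genes <- c(tfs, paste0("G", seq_len(sample(3:10, 1))))
  universe <- expand.grid(regulator = tfs, target = genes,
                          stringsAsFactors = FALSE)
  universe <- universe[universe$regulator != universe$target, ]
  n_u <- nrow(universe)
  n_pred <- sample(0:min(n_u, 50), 1)
  pred_idx <- sample(n_u, n_pred)
  scores <- round(runif(n_pred), 1)  # deliberately produces ties
  ord <- order(-scores)
  predictions <- data.frame(regulator = universe$regulator[pred_idx][ord],
                            target = universe$target[pred_idx][ord],
                            score = scores[ord], stringsAsFactors = FALSE)
  pos_idx <- sample(n_u, max(1, sample.int(n_u, 1) %/% 2))
  gold <- data.frame(regulator = universe$regulator[pos_idx],
                     target = universe$target[pos_idx],
                     label = 1L, stringsAsFactors = FALSE)
  list(predictions = predictions, gold = gold, tfs = tfs, genes = genes,
       universe = universe, pos_idx = sort(pos_idx),
       pred_idx = pred_idx[ord])
}

# Brute-force AUROC: mean over all (positive, negative) universe pairs of
# concordance, ties counting one half. Unpredicted pairs share one score
# strictly below all predicted ones.
brute_auroc <- function(inst) {
  n_u <- nrow(inst$universe)
  full <- rep(-Inf, n_u)
  full[inst$pred_idx] <- inst$predictions$score
  is_pos <- seq_len(n_u) %in% inst$pos_idx
  sp <- full[is_pos]
  sn <- full[!is_pos]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# Brute-force AUPR: walk distinct predicted score values in descending
# order, accumulate (delta recall) x precision at each tied group's end,
# recall denominated by all universe positives.
brute_aupr <- function(inst) {
  labels <- as.integer(inst$pred_idx %in% inst$pos_idx)
  p_total <- length(inst$pos_idx)
  if (nrow(inst$predictions) == 0) return(0)
  area <- 0
  prev_recall <- 0
  seen <- 0
  for (s in unique(inst$predictions$score)) {
    grp <- inst$predictions$score == s
    seen <- seen + sum(grp)
    tp <- sum(labels[inst$predictions$score >= s])
    recall <- tp / p_total
    precision <- tp / seen
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
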