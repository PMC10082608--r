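#' Configuration for the synthetic network and expression simulator
#'
#' The generator emulates multifactorial steady-state expression data: a
#' sparse directed acyclic regulatory network in which each regulated gene
#' is a noisy linear function of its regulators. Defaults describe a small
#' benchmark instance with clearly recoverable structure.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factors; the first `n_tfs` genes.
#' @param n_samples Number of steady-state samples.
#' @param edge_density Probability that each eligible TF -> downstream-gene
#'   pair carries an edge.
#' @param effect_scale Scale of regulatory weights; each weight's magnitude
#'   is uniform on `[0.5, 1.5] * effect_scale`, with random sign.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   regulated genes (unregulated genes are standard normal).
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 20, n_tfs = 5, n_samples = 200,
                             edge_density = 0.3, effect_scale = 1,
                             noise_sd = 0.1, seed = 1L) {
  if (n_genes < 1) stopf("n_genes must be positive")
  if (n_tfs < 1 || n_tfs > n_genes) stopf("n_tfs must be in [1, n_genes]")
  if (edge_density < 0 || edge_density > 1) stopf("edge_density must be in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (effect_scale <= 0) stopf("effect_scale must be positive")
  if (n_samples < 1) stopf("n_samples must be positive")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples),
                 edge_density = edge_density, effect_scale = effect_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a random sparse regulatory network
#'
#' Genes are `G1 ... Gn`; the first `n_tfs` are transcription factors and
#' the only allowed edge sources. Each eligible pair (TF `u`, gene `v`)
#' with `index(u) < index(v)` receives an edge independently with
#' probability `edge_density`; the index ordering makes the graph acyclic
#' by construction. Weights are drawn uniformly from
#' `[0.5, 1.5] * effect_scale` with random sign.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_network` with elements `gene_ids`,
#'   `tf_ids` and `edges` (a `data.frame` of `regulator`, `target`,
#'   `weight`).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gene_ids <- sprintf("G%d", seq_len(config$n_genes))
  tf_ids <- gene_ids[seq_len(config$n_tfs)]
  u <- rep(seq_len(config$n_tfs), each = config$n_genes)
  v <- rep(seq_len(config$n_genes), times = config$n_tfs)
  keep <- u < v
  u <- u[keep]; v <- v[keep]
  edges <- with_rng(hash_seed(config$seed, "network"), {
    present <- runif(length(u)) < config$edge_density
    uu <- u[present]; vv <- v[present]
    mag <- runif(length(uu), 0.5, 1.5) * config$effect_scale
    sign <- ifelse(runif(length(uu)) < 0.5, -1, 1)
    data.frame(regulator = gene_ids[uu], target = gene_ids[vv],
               weight = sign * mag, stringsAsFactors = FALSE)
  })
  structure(list(gene_ids = gene_ids, tf_ids = tf_ids, edges = edges),
            class = "synthetic_network")
}

#' Simulate steady-state expression from a synthetic network
#'
#' Genes are processed in index order (a topological order of the DAG):
#' an unregulated gene is i.i.d. standard normal across samples, a
#' regulated gene is the weighted sum of its regulators' simulated values
#' plus i.i.d. Gaussian noise with standard deviation `noise_sd`.
#'
#' @param network A [generate_network()] result.
#' @param config The matching [synthetic_config()].
#' @return A samples x genes numeric matrix with gene identifiers as
#'   column names.
#' @export
simulate_expression <- function(network, config) {
  stopifnot(inherits(network, "synthetic_network"),
            inherits(config, "synthetic_config"))
  n <- config$n_samples
  g <- length(network$gene_ids)
  x <- matrix(0, n, g, dimnames = list(NULL, network$gene_ids))
  with_rng(hash_seed(config$seed, "expression"), {
    for (j in seq_len(g)) {
      gene <- network$gene_ids[j]
      parents <- network$edges[network$edges$target == gene, , drop = FALSE]
      if (nrow(parents) == 0) {
        x[, j] <- rnorm(n)
      } else {
        signal <- x[, parents$regulator, drop = FALSE] %*% parents$weight
        x[, j] <- drop(signal) + rnorm(n, sd = config$noise_sd)
      }
    }
  })
  x
}

#' Write a self-contained fixture set
#'
#' Writes the expression matrix, TF list, and gold standard (all generated
#' edges labeled 1; absent pairs are implied negatives) in the formats
#' accepted by [read_expression()], [read_tf_list()] and
#' [read_gold_standard()].
#'
#' @param network A [generate_network()] result.
#' @param expression The matching [simulate_expression()] matrix.
#' @param directory Output directory, created if missing.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_fixture_set <- function(network, expression, directory) {
  stopifnot(inherits(network, "synthetic_network"), is.matrix(expression))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- list(expression = file.path(directory, "expression.tsv"),
                tf_list = file.path(directory, "tf_list.txt"),
                gold_standard = file.path(directory, "gold_standard.tsv"))
  header <- paste(colnames(expression), collapse = "\t")
  rows <- apply(expression, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(header, rows), paths$expression)
  writeLines(network$tf_ids, paths$tf_list)
  if (nrow(network$edges) > 0) {
    writeLines(sprintf("%s\t%s\t1", network$edges$regulator, network$edges$target),
               paths$gold_standard)
  } else {
    writeLines(character(0), paths$gold_standard)
  }
  invisible(paths)
}
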