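test_that("generate_network honors density and eligibility", {
  cfg0 <- synthetic_config(n_genes = 6, n_tfs = 2, edge_density = 0, seed = 3)
  expect_identical(nrow(generate_network(cfg0)$edges), 0L)

  cfg1 <- synthetic_config(n_genes = 4, n_tfs = 2, edge_density = 1, seed = 3)
  net <- generate_network(cfg1)
  expect_identical(nrow(net$edges), 5L)  # G1->G2,G3,G4; G2->G3,G4
  key <- paste(net$edges$regulator, net$edges$target)
  expect_setequal(key, c("G1 G2", "G1 G3", "G1 G4", "G2 G3", "G2 G4"))
  expect_true(all(abs(net$edges$weight) >= 0.5 & abs(net$edges$weight) <= 1.5))
})

test_that("generator output is a pure function of the config", {
  cfg <- synthetic_config(seed = 11)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1, n2)
  expect_identical(simulate_expression(n1, cfg), simulate_expression(n2, cfg))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(n_tfs = 0), "n_tfs")
  expect_error(synthetic_config(n_tfs = 30, n_genes = 20), "n_tfs")
  expect_error(synthetic_config(edge_density = 1.2), "edge_density")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
  expect_error(synthetic_config(effect_scale = 0), "effect_scale")
})

test_that("simulate_expression follows the linear-Gaussian model", {
  edge <- data.frame(regulator = "G1", target = "G2", weight = 1,
                     stringsAsFactors = FALSE)
  net <- manual_network(c("G1", "G2"), "G1", edge)

  noiseless <- synthetic_config(n_genes = 2, n_tfs = 1, n_samples = 50,
                                noise_sd = 0, seed = 5)
  x0 <- simulate_expression(net, noiseless)
  expect_equal(x0[, "G2"], x0[, "G1"])

  noisy <- synthetic_config(n_genes = 2, n_tfs = 1, n_samples = 200,
                            noise_sd = 0.1, seed = 5)
  x1 <- simulate_expression(net, noisy)
  expect_gt(cor(x1[, "G1"], x1[, "G2"]), 0.9)
})

test_that("unlinked genes are essentially uncorrelated", {
  cfg <- synthetic_config(n_genes = 6, n_tfs = 2, n_samples = 200,
                          edge_density = 0, seed = 9)
  x <- simulate_expression(generate_network(cfg), cfg)
  cm <- cor(x)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.3)
})

test_that("linked pairs carry recoverable signal", {
  # Fraction of (linked, unlinked) TF-gene pair comparisons in which the
  # linked pair has the larger absolute correlation. Confounding chains
  # (two genes sharing an upstream TF) make some unlinked pairs strongly
  # correlated, so the fraction is high but not 1.
  hits <- vapply(1:10, function(s) {
    cfg <- synthetic_config(seed = s)
    net <- generate_network(cfg)
    x <- simulate_expression(net, cfg)
    cm <- abs(cor(x))
    linked <- cm[cbind(net$edges$regulator, net$edges$target)]
    pairs <- expand.grid(r = net$tf_ids, t = net$gene_ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$r != pairs$t, ]
    unlinked <- !paste(pairs$r, pairs$t) %in%
      paste(net$edges$regulator, net$edges$target)
    mean(outer(linked, cm[cbind(pairs$r, pairs$t)][unlinked], `>`))
  }, numeric(1))
  expect_true(all(hits > 0.7))
  expect_gt(mean(hits), 0.8)
})

test_that("fixture sets round-trip through the readers", {
  cfg <- synthetic_config(n_genes = 8, n_tfs = 3, n_samples = 20, seed = 7)
  net <- generate_network(cfg)
  x <- simulate_expression(net, cfg)
  dir <- file.path(tempdir(), "fixture-roundtrip")
  paths <- write_fixture_set(net, x, dir)
  back <- read_expression(paths$expression)
  expect_identical(dim(back), dim(x))
  expect_equal(unname(back), unname(x), tolerance = 0)
  expect_identical(read_tf_list(paths$tf_list), net$tf_ids)
  gold <- read_gold_standard(paths$gold_standard)
  expect_identical(nrow(gold), nrow(net$edges))
  expect_true(all(gold$label == 1L))
  expect_setequal(paste(gold$regulator, gold$target),
                  paste(net$edges$regulator, net$edges$target))
})

test_that("an empty network writes an empty gold standard", {
  cfg <- synthetic_config(n_genes = 4, n_tfs = 2, n_samples = 5,
                          edge_density = 0, seed = 1)
  net <- generate_network(cfg)
  x <- simulate_expression(net, cfg)
  dir <- file.path(tempdir(), "fixture-empty")
  paths <- write_fixture_set(net, x, dir)
  expect_identical(nrow(read_gold_standard(paths$gold_standard)), 0L)
})
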