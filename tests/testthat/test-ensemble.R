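mk <- function(v, ids = paste0("G", 1:3)) {
  matrix(v, length(ids), length(ids), dimnames = list(ids, ids))
}

test_that("min-max normalization maps to [0, 1]", {
  m <- mk(c(0, 5, 10, 0, 5, 10, 0, 5, 10))
  expect_equal(sort(unique(as.vector(normalize_method_scores(m)))),
               c(0, 0.5, 1))
  expect_warning(z <- normalize_method_scores(mk(rep(3, 9))), "constant")
  expect_true(all(z == 0))
  canonical <- mk(seq(0, 1, length.out = 9))
  expect_equal(normalize_method_scores(canonical), canonical,
               ignore_attr = TRUE)
  expect_error(normalize_method_scores(mk(c(rep(1, 8), NA))), "non-finite")
})

test_that("the weighted combination follows the stated arithmetic", {
  b_equal <- list(rfr = mk(1), etr = mk(1), svr = mk(1))
  expect_true(all(combine_weighted(b_equal) == 1))

  b_first <- list(rfr = mk(1), etr = mk(0), svr = mk(0))
  expect_true(all(combine_weighted(b_first) == 0.625))

  misaligned <- list(rfr = mk(1), etr = mk(1)[c(2, 1, 3), ])
  expect_error(combine_weighted(misaligned), "aligned")
  expect_error(combine_weighted(list(xxx = mk(1))), "no weight")
  expect_error(combine_weighted(b_equal, c(rfr = 0, etr = 0, svr = 0)),
               "positive sum")
})

test_that("two-method mode equals the three-method formula with zero SVR weight", {
  set.seed(1)
  b <- list(rfr = mk(runif(9)), etr = mk(runif(9)), svr = mk(runif(9)))
  two <- combine_weighted(b[c("rfr", "etr")])
  three_w0 <- combine_weighted(b, c(rfr = 1, etr = 0.5, svr = 0))
  expect_equal(unclass(two), unclass(three_w0), ignore_attr = TRUE)
})

test_that("the ranking is invariant to rescaling all weights", {
  set.seed(2)
  b <- list(rfr = mk(runif(9)), etr = mk(runif(9)), svr = mk(runif(9)))
  r1 <- rank_and_truncate(combine_weighted(b, c(rfr = 1, etr = 0.5, svr = 0.1)))
  r10 <- rank_and_truncate(combine_weighted(b, c(rfr = 10, etr = 5, svr = 1)))
  expect_identical(r1[c("regulator", "target")], r10[c("regulator", "target")])
})

test_that("raising one score never lowers that edge's rank", {
  set.seed(3)
  b <- list(rfr = mk(runif(9)), etr = mk(runif(9)), svr = mk(runif(9)))
  edges <- rank_and_truncate(combine_weighted(b))
  pos_before <- which(edges$regulator == "G1" & edges$target == "G2")
  b$rfr["G1", "G2"] <- b$rfr["G1", "G2"] + 0.5
  bumped <- rank_and_truncate(combine_weighted(b))
  pos_after <- which(bumped$regulator == "G1" & bumped$target == "G2")
  expect_lte(pos_after, pos_before)
})

test_that("z-scoring standardizes off-diagonal entries and keeps the ranking", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("R1", paste0("G", 1:3)))
  z <- zscore_scores(m)
  expect_equal(as.vector(z), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-6)

  set.seed(4)
  big <- mk(runif(9))
  zb <- zscore_scores(big)
  off <- zb[!outer(rownames(zb), colnames(zb), `==`)]
  expect_lt(abs(mean(off)), 1e-10)
  expect_lt(abs(sqrt(mean((off - mean(off))^2)) - 1), 1e-10)
  expect_true(all(is.na(diag(zb))))
  expect_identical(rank_and_truncate(big)[c("regulator", "target")],
                   rank_and_truncate(zb)[c("regulator", "target")])

  expect_error(zscore_scores(mk(rep(2, 9))), "distinct")
})

test_that("ranking sorts descending with lexical tie-break and truncates", {
  ids <- c("G1", "G2")
  genes <- c("G1", "G2", "G3")
  m <- matrix(c(0.9, 0.7, 0.5, 0.7, 0.7, 0.1), 2, 3,
              dimnames = list(ids, genes))
  # non-self scores: G1->G2 0.5, G1->G3 0.7, G2->G1 0.7, G2->G3 0.1
  r <- rank_and_truncate(m)
  expect_identical(nrow(r), 4L)
  expect_identical(paste(r$regulator, r$target),
                   c("G1 G3", "G2 G1", "G1 G2", "G2 G3"))
  expect_true(all(diff(r$score) <= 0))
  top1 <- rank_and_truncate(m, limit = 1)
  expect_identical(nrow(top1), 1L)
  expect_identical(paste(top1$regulator, top1$target), "G1 G3")
})

test_that("NA entries (self-pairs after z-scoring) are dropped from the ranking", {
  m <- mk(1:9 / 10)
  z <- zscore_scores(m)
  r <- rank_and_truncate(z)
  expect_identical(nrow(r), 6L)
  expect_false(any(r$regulator == r$target))
})
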