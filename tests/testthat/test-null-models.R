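fx <- toy_fixtures()

test_that("rewiring preserves degrees and in-strength on every sample", {
  cn <- rand_connectome(12, 0.4, seed = 5, k_extra = 4)
  for (s in 1:50) {
    r <- rewire_preserving(cn, seed = 7000 + s)
    expect_identical(rowSums(r$A), rowSums(cn$A))
    expect_identical(colSums(r$A), colSums(cn$A))
    expect_equal(colSums(r$W), colSums(cn$W), tolerance = 1e-12)
    expect_identical(r$k_in_ext, cn$k_in_ext)
    expect_true(all(diag(r$A) == 0))
  }
})

test_that("a complete graph admits no swap and is returned unchanged", {
  expect_warning(r <- rewire_preserving(fx$K4), "no swap")
  expect_identical(r$W, fx$K4$W)
})

test_that("the two-edge graph has exactly one swap, with weights following targets", {
  # 1->2 (w=5), 3->4 (w=7): the only admissible swap yields 1->4, 3->2,
  # and both orders of drawing the edge pair produce it, so a single
  # attempted swap always lands in the swapped state
  W <- matrix(0, 4, 4); W[1, 2] <- 5; W[3, 4] <- 7
  cn <- connectome(W)
  for (s in 1:10) {
    r <- rewire_preserving(cn, n_swaps = 1, seed = s)
    expect_equal(which(r$A > 0), which(outer(1:4, 1:4, function(i, j)
      (i == 1 & j == 4) | (i == 3 & j == 2)) > 0))
    # weights stay with their target endpoints: the edge into 4 keeps w=7
    expect_equal(unname(r$W[1, 4]), 7)
    expect_equal(unname(r$W[3, 2]), 5)
    expect_identical(colSums(r$W), colSums(cn$W))
    # a second swap undoes the first: the state space has exactly two states
    r2 <- rewire_preserving(cn, n_swaps = 2, seed = s)
    expect_identical(r2$W, cn$W)
  }
})

test_that("weight shuffling conserves topology and the weight multiset", {
  cn <- rand_connectome(10, 0.4, seed = 6)
  for (s in 1:50) {
    sh <- shuffle_weights(cn, seed = 8000 + s)
    expect_identical(sh$A, cn$A)
    expect_identical(sort(sh$W[sh$A > 0]), sort(cn$W[cn$A > 0]))
  }
  # single-edge graph: only one permutation exists
  W1 <- matrix(0, 3, 3); W1[1, 2] <- 2.5
  expect_identical(shuffle_weights(connectome(W1), seed = 1)$W,
                   connectome(W1)$W)
})

test_that("weight shuffles are uniform over permutations of a 3-edge graph", {
  W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 2; W[3, 1] <- 3
  cn <- connectome(W)
  n_draw <- 10000
  keys <- withr::with_seed(99, {
    vapply(seq_len(n_draw), function(i) {
      paste(shuffle_weights(cn)$W[cn$A > 0], collapse = "-")
    }, character(1))
  })
  freq <- table(keys)
  expect_length(freq, 6)
  # each of the 6 permutations at 1/6 within 3 binomial standard deviations
  p <- 1 / 6
  sd3 <- 3 * sqrt(p * (1 - p) / n_draw)
  expect_true(all(abs(freq / n_draw - p) < sd3))
})

test_that("metric normalization against nulls behaves at the boundaries", {
  cn <- rand_connectome(8, 0.5, seed = 11)
  # zero-swap ensemble: every null equals the original
  ens0 <- null_ensemble(cn, metrics = list(C = function(z) clustering_weighted(z)$network_value),
                        kind = "rewire", n_samples = 20, swap_multiplier = 0,
                        seed = 1)
  nm <- normalized_metric(clustering_weighted(cn)$network_value, ens0, "C")
  expect_equal(nm$norm, 1)
  expect_equal(nm$p, 1)

  # observation above every null sample reports p = 0 (bounded by 1/n below)
  ens <- null_ensemble(cn, metrics = list(C = function(z) clustering_weighted(z)$network_value),
                       kind = "shuffle", n_samples = 50, seed = 2)
  nm2 <- normalized_metric(max(ens$values[, "C"]) + 10, ens, "C")
  expect_equal(nm2$p, 0)
  nm2c <- normalized_metric(max(ens$values[, "C"]) + 10, ens, "C", correction = TRUE)
  expect_equal(nm2c$p, 1 / 51)
})

test_that("group permutation test matches exhaustive enumeration", {
  a <- c(10, 11, 12); b <- c(1, 2, 3)
  # exact two-sided p over all 20 label assignments
  pooled <- c(a, b)
  combos <- utils::combn(6, 3)
  obs <- mean(a) - mean(b)
  exact <- mean(apply(combos, 2, function(ia) {
    abs(mean(pooled[ia]) - mean(pooled[-ia])) >= abs(obs) - 1e-12
  }))
  pt <- permutation_test_groups(a, b, n_perm = 4000, seed = 3)
  expect_lt(abs(pt$p - exact), 0.02)

  # symmetry: swapping the groups flips the sign, not the p-value
  pt_swap <- permutation_test_groups(b, a, n_perm = 4000, seed = 3)
  expect_equal(pt_swap$p, pt$p)
  expect_equal(pt_swap$statistic, -pt$statistic)

  # identical groups are never significant
  pt_id <- permutation_test_groups(c(1, 2, 3), c(1, 2, 3), n_perm = 500, seed = 4)
  expect_gt(pt_id$p, 0.5)
})

test_that("permutation p-values are calibrated under exchangeability", {
  ps <- withr::with_seed(17, {
    vapply(1:60, function(i) {
      x <- stats::rnorm(12)
      permutation_test_groups(x[1:6], x[7:12], n_perm = 200)$p
    }, numeric(1))
  })
  # roughly uniform: about half the p-values below 0.5, few below 0.05
  expect_gt(mean(ps > 0.2), 0.5)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("BH correction reproduces the step-up procedure", {
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  out <- fdr_bh(c(0.001, NA, 0.5))
  expect_true(is.na(out$adjusted[2]))
  expect_true(out$reject[1])
})
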