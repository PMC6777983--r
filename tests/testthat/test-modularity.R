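fx <- toy_fixtures()

two_cliques <- function() {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1
  diag(A) <- 0
  connectome(A)
}

test_that("module detection separates disconnected cliques and maximises Q", {
  cn <- two_cliques()
  p <- detect_modules(cn, n_restarts = 10, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(unname(p$membership[1:4]), rep(p$membership[[1]], 4))
  expect_equal(unname(p$membership[5:8]), rep(p$membership[[5]], 4))
  # reported Q equals the brute-force double-sum of the returned partition
  expect_equal(p$Q, oracle_modularity(cn$A, p$membership), tolerance = 1e-12)
  # rescoring the detected partition reproduces its Q
  expect_equal(score_partition(cn, p), p$Q, tolerance = 1e-12)
})

test_that("partition scoring matches the brute-force double sum", {
  expect_equal(score_partition(fx$TOY7, rep(1, 7)), 0, tolerance = 1e-12)
  singletons <- seq_len(7)
  q_single <- score_partition(fx$TOY7, singletons)
  expect_lt(q_single, 0)
  expect_equal(q_single, oracle_modularity(fx$TOY7$A, singletons), tolerance = 1e-12)
  for (s in 1:10) {
    cn <- rand_connectome(7, 0.4, seed = 300 + s)
    mem <- withr::with_seed(s, sample(1:3, 7, replace = TRUE))
    expect_equal(score_partition(cn, mem), oracle_modularity(cn$A, mem),
                 tolerance = 1e-12)
    expect_equal(score_partition(cn, mem, weighted = TRUE),
                 oracle_modularity(cn$W, mem), tolerance = 1e-12)
    # label-permutation invariance
    relab <- c(3, 1, 2)[mem]
    expect_equal(score_partition(cn, relab), score_partition(cn, mem))
  }
})

test_that("binary detection ignores the weight placement", {
  cn <- rand_connectome(10, 0.35, seed = 42)
  sh <- shuffle_weights(cn, seed = 43)
  p1 <- detect_modules(cn, weighted = FALSE, n_restarts = 5, seed = 7)
  p2 <- detect_modules(sh, weighted = FALSE, n_restarts = 5, seed = 7)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$Q, p2$Q)
})

test_that("detection is deterministic given a seed and beats the trivial partition", {
  cn <- generate_connectome(synth_spec(n_nodes = 20), seed = 9)
  pa <- detect_modules(cn, weighted = TRUE, n_restarts = 10, seed = 5)
  pb <- detect_modules(cn, weighted = TRUE, n_restarts = 10, seed = 5)
  expect_identical(pa$membership, pb$membership)
  expect_gte(pa$Q, 0)
})

test_that("planted two-module structure is recovered", {
  agree <- vapply(1:5, function(s) {
    spec <- synth_spec(n_nodes = 20, density = 0.5, p_intra = 0.9,
                       p_inter = 0.1, hub_fraction = 0)
    cn <- generate_connectome(spec, seed = 100 + s)
    plant <- unname(cn$meta$modules)
    p <- detect_modules(cn, n_restarts = 10, seed = s)
    rand_index(p$membership, plant)$rand
  }, numeric(1))
  expect_true(all(agree >= 0.95))
})

test_that("Rand index agrees with the pair-counting oracle and is label-invariant", {
  m1 <- c(1, 1, 2, 2); m2 <- c(1, 2, 2, 2)
  expect_equal(rand_index(m1, m2)$rand, oracle_rand_index(m1, m2))
  expect_equal(rand_index(m1, m1)$rand, 1)
  expect_equal(rand_index(m1, c(2, 2, 1, 1))$rand, 1)  # pure relabelling
  for (s in 1:10) {
    ms <- withr::with_seed(600 + s, list(sample(1:3, 8, replace = TRUE),
                                         sample(1:4, 8, replace = TRUE)))
    expect_equal(rand_index(ms[[1]], ms[[2]])$rand,
                 oracle_rand_index(ms[[1]], ms[[2]]), tolerance = 1e-12)
  }
  expect_error(rand_index(m1, c(1, 2)), "different node sets")
})

test_that("the Rand permutation null detects genuine agreement", {
  cn <- generate_connectome(synth_spec(n_nodes = 20, p_intra = 0.9, p_inter = 0.1,
                                       hub_fraction = 0), seed = 3)
  p <- detect_modules(cn, n_restarts = 10, seed = 4)
  ri <- rand_index(p$membership, unname(cn$meta$modules), n_perm = 500, seed = 5)
  expect_lt(ri$p, 0.05)
})

test_that("edge classification partitions edges into intra and inter", {
  all_in_one <- classify_edges_by_module(fx$TOY7, rep(1, 7))
  expect_true(all(all_in_one$class == "intra"))
  singles <- classify_edges_by_module(fx$TOY7, 1:7)
  expect_true(all(singles$class == "inter"))
  planted <- classify_edges_by_module(fx$TOY7, unname(fx$TOY7$meta$modules))
  # counting oracle on the fixture edge list
  expect_equal(sum(planted$class == "inter"), 5)
  expect_equal(sum(planted$class == "intra"), 12)
  expect_equal(nrow(planted), sum(fx$TOY7$A))
})
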