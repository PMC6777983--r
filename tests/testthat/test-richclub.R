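fx <- toy_fixtures()

test_that("binary coefficient matches density limits and the subset oracle", {
  K4 <- connectome(1 - diag(4), k_in_ext = c(5, 4, 3, 3))
  expect_equal(phi_binary(K4, 2), 1)          # club of the two top nodes
  expect_equal(phi_binary(K4, 0), 1)          # whole complete graph
  # threshold below every in-degree: club is the whole network -> density
  expect_equal(phi_binary(fx$TOY7, 0), network_density(fx$TOY7))
  # club smaller than two nodes is undefined
  expect_true(is.na(phi_binary(fx$TOY7, max(fx$TOY7$k_in_ext))))
  for (k in 0:6) {
    expect_equal(phi_binary(fx$TOY7, k), oracle_phi_binary(fx$TOY7, k),
                 tolerance = 1e-12)
    expect_equal(phi_weighted(fx$TOY7, k), oracle_phi_weighted(fx$TOY7, k),
                 tolerance = 1e-12)
  }
})

test_that("weighted coefficient handles ties and the maximal case", {
  # uniform weights: every weight ties, so the ratio is exactly 1 whenever
  # the club has any internal edge
  cnu <- connectome(fx$TOY7$A, k_in_ext = fx$TOY7$k_in_ext)
  for (k in 0:5) {
    phi <- phi_weighted(cnu, k)
    if (!is.na(phi) && phi > 0) expect_equal(phi, 1)
  }
  # club edges carrying the globally largest weights give exactly 1
  W <- matrix(0, 5, 5)
  W[1, 2] <- 10; W[2, 1] <- 9                # the hub pair, strongest edges
  W[3, 4] <- 1; W[4, 5] <- 2; W[5, 3] <- 0.5
  cn <- connectome(W, k_in_ext = c(9, 8, 1, 1, 1))
  expect_equal(phi_weighted(cn, 5), 1)
})

test_that("rich-club coefficients respect their analytic bounds", {
  for (s in 1:20) {
    cn <- rand_connectome(8, 0.5, seed = 1200 + s, k_extra = 5)
    for (k in unique(cn$k_in_ext)) {
      pb <- phi_binary(cn, k - 1)
      pw <- phi_weighted(cn, k - 1)
      if (!is.na(pb)) { expect_gte(pb, 0); expect_lte(pb, 1) }
      if (!is.na(pw)) { expect_gte(pw, 0); expect_lte(pw, 1 + 1e-12) }
    }
  }
})

test_that("adding an edge inside the club never decreases the binary coefficient", {
  for (s in 1:10) {
    cn <- rand_connectome(8, 0.4, seed = 1500 + s, k_extra = 4)
    k <- sort(cn$k_in_ext, decreasing = TRUE)[3]
    cl <- which(cn$k_in_ext > k - 1)
    if (length(cl) < 2) next
    before <- phi_binary(cn, k - 1)
    open <- which(cn$A[cl, cl] == 0 & diag(length(cl)) == 0, arr.ind = TRUE)
    if (nrow(open) == 0) next
    W2 <- cn$W
    W2[cl[open[1, 1]], cl[open[1, 2]]] <- 1
    cn2 <- connectome(W2, k_in_ext = pmax(cn$k_in_ext, colSums(W2 > 0)))
    # guard: the insertion must not change club membership
    if (!identical(which(cn2$k_in_ext > k - 1), cl)) next
    expect_gte(phi_binary(cn2, k - 1), before)
  }
})

test_that("identity ensemble normalises the curve to one", {
  cn <- rand_connectome(10, 0.5, seed = 77, k_extra = 5)
  rc <- rich_club_curve(cn, "binary", n_null = 20, swap_multiplier = 0, seed = 1)
  ok <- !is.na(rc$curve$phi)
  expect_equal(rc$curve$phi_norm[ok], rep(1, sum(ok)))
  expect_equal(rc$curve$p_raw[ok], rep(1, sum(ok)))
})

test_that("a planted strong core is flagged and a null spec is not", {
  core_spec <- synth_spec(n_nodes = 24, density = 0.4, n_modules = 1,
                          hub_fraction = 0.2, hub_p = 0.95, hub_weight_mult = 3,
                          extra_sources = 40)
  cn <- generate_connectome(core_spec, seed = 21)
  # hubs must actually rank top by external in-degree for the curve to see them
  rc <- rich_club_curve(cn, "weighted", n_null = 200, seed = 22)
  sig <- !is.na(rc$curve$p_fdr) & rc$curve$p_fdr < 0.05 & rc$curve$phi_norm > 1
  expect_true(any(sig))

  null_spec <- synth_spec(n_nodes = 24, density = 0.4, n_modules = 1,
                          hub_fraction = 0, extra_sources = 40)
  cn0 <- generate_connectome(null_spec, seed = 23)
  rc0 <- rich_club_curve(cn0, "weighted", n_null = 200, seed = 24)
  sig0 <- !is.na(rc0$curve$p_fdr) & rc0$curve$p_fdr < 0.05
  expect_false(any(sig0))
})

test_that("hub selection takes the top in-degree fraction with deterministic ties", {
  cn29 <- generate_connectome(synth_spec(), seed = 2)
  hubs <- suppressMessages(select_hubs(cn29, 0.2))
  expect_length(hubs$hubs, 6)   # ceiling(0.2 * 29)
  expect_equal(sort(cn29$k_in_ext[hubs$hubs], decreasing = TRUE)[6],
               sort(cn29$k_in_ext, decreasing = TRUE)[6])

  # all-equal in-degrees: the single hub is decided by label order
  cn5 <- connectome(fx$RING5$W, k_in_ext = rep(3, 5))
  expect_message(h5 <- select_hubs(cn5, 0.2), "tie")
  expect_identical(h5$hubs, "R01")

  # rich/feeder/local partition the edge set exactly
  h7 <- select_hubs(fx$TOY7, 0.3)
  expect_equal(nrow(h7$edges), sum(fx$TOY7$A))
  is_hub <- fx$TOY7$labels %in% h7$hubs
  names(is_hub) <- fx$TOY7$labels
  for (r in seq_len(nrow(h7$edges))) {
    ends <- is_hub[h7$edges$from[r]] + is_hub[h7$edges$to[r]]
    expect_equal(h7$edges$class[r], c("local", "feeder", "rich")[ends + 1])
  }
})

test_that("class strength contrasts recover constructed ratios", {
  # uniform weights: all ratios 1 and nothing significant
  cnu <- connectome(fx$TOY7$A, k_in_ext = fx$TOY7$k_in_ext)
  hu <- select_hubs(cnu, 0.3)
  ctr <- class_strength_contrasts(cnu, hu, n_perm = 200, seed = 5)
  expect_equal(ctr$ratio, rep(1, nrow(ctr)))
  expect_true(all(ctr$p_raw > 0.9))

  # rich weights doubled: the rich/feeder and rich/local ratios are 2
  W <- fx$TOY7$A * 1
  h <- select_hubs(fx$TOY7, 0.3)
  hub_idx <- fx$TOY7$labels %in% h$hubs
  W[hub_idx, hub_idx] <- W[hub_idx, hub_idx] * 2
  cn2 <- connectome(W, k_in_ext = fx$TOY7$k_in_ext)
  h2 <- select_hubs(cn2, 0.3)
  ctr2 <- class_strength_contrasts(cn2, h2, n_perm = 200, seed = 6)
  expect_equal(ctr2$ratio[ctr2$class_a == "rich" & ctr2$class_b == "feeder"], 2)
  expect_equal(ctr2$ratio[ctr2$class_a == "rich" & ctr2$class_b == "local"], 2)
  expect_equal(ctr2$ratio[ctr2$class_a == "feeder" & ctr2$class_b == "local"], 1)

  # module split adds intra/inter scopes (partition chosen so every class
  # occurs in both scopes)
  ctr3 <- class_strength_contrasts(fx$TOY7, select_hubs(fx$TOY7, 0.3),
                                   partition = c(1, 2, 1, 1, 2, 2, 2),
                                   n_perm = 100, seed = 7)
  expect_setequal(unique(ctr3$scope), c("all", "intra", "inter"))
  expect_equal(nrow(ctr3), 9)
  # an empty class within a scope is a hard error, not a silent NA
  expect_error(
    class_strength_contrasts(fx$TOY7, select_hubs(fx$TOY7, 0.3),
                             partition = unname(fx$TOY7$meta$modules),
                             n_perm = 50, seed = 8),
    "empty connection class")
})
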