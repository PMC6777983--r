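fx <- toy_fixtures()

short_cfg <- function(...) kuramoto_config(lambda_grid = 0.05, t_total = 60,
                                           transient = 20, n_runs = 1, ...)

test_that("uncoupled oscillators follow the closed-form linear solution", {
  cfg <- kuramoto_config(lambda_grid = 0, t_total = 30, transient = 0,
                         dt = 0.05, sample_dt = 0.5, n_runs = 1)
  om <- c(0.1, 0.4, 0.9); th0 <- c(-1, 0, 2)
  ph <- simulate_kuramoto(fx$RING5$A[1:3, 1:3], 0, cfg, omega = om, theta0 = th0)
  tt <- attr(ph, "times")
  exact <- matrix(th0, length(tt), 3, byrow = TRUE) + outer(tt, om)
  expect_lt(max(abs(ph - exact)), 1e-10)
})

test_that("two coupled oscillators lock exactly below the analytic threshold", {
  # phase difference obeys d' = dw - 2 lambda sin(d): fixed point iff |dw| <= 2 lambda
  lambda <- 0.5
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  cfg <- kuramoto_config(lambda_grid = lambda, t_total = 400, transient = 300,
                         n_runs = 1)
  drift <- function(dw) {
    ph <- simulate_kuramoto(M, lambda, cfg, omega = c(0.5 + dw / 2, 0.5 - dw / 2),
                            theta0 = c(0.3, -0.2))
    d <- ph[, 1] - ph[, 2]
    max(d) - min(d)   # near zero when locked, grows without bound otherwise
  }
  expect_lt(drift(0.9 * 2 * lambda), 0.05)
  expect_gt(drift(1.1 * 2 * lambda), 1)
})

test_that("order parameters hit their degenerate values exactly", {
  # identical constant phases: full synchrony
  ph_sync <- matrix(1.2, 10, 4)
  op <- order_parameters(ph_sync)
  expect_equal(op$r, 1)
  expect_equal(op$r_link, 1)
  expect_equal(op$C, matrix(1, 4, 4))

  # four static phases at quadrature: complete cancellation
  ph_quad <- matrix(c(0, pi / 2, pi, 3 * pi / 2), 10, 4, byrow = TRUE)
  expect_equal(order_parameters(ph_quad)$r, 0, tolerance = 1e-12)

  # a pair drifting at constant frequency difference over whole cycles
  tt <- seq(0, 2 * pi, length.out = 201)[-201]
  ph_drift <- cbind(tt, rep(0, 200))
  op_d <- order_parameters(ph_drift)
  oracle_c12 <- Mod(sum(exp(1i * (ph_drift[, 1] - ph_drift[, 2])))) / 200
  expect_equal(op_d$C[1, 2], oracle_c12, tolerance = 1e-12)
  expect_lt(op_d$C[1, 2], 1e-10)
})

test_that("order parameters are invariant to a global phase shift", {
  cfg <- short_cfg()
  ph <- simulate_kuramoto(fx$TOY7$A, 0.05, cfg, seed = 5)
  op1 <- order_parameters(ph)
  op2 <- order_parameters(ph + 1.234)
  expect_equal(op1$r, op2$r, tolerance = 1e-12)
  expect_equal(op1$C, op2$C, tolerance = 1e-12)
})

test_that("RK4 converges at fourth order under step halving", {
  # a drifting (unlocked) 3-node cycle: discretisation errors accumulate
  # instead of being contracted onto a phase-locked attractor
  M <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  om <- c(0.1, 0.9, 1.7); th0 <- c(0, 1, -1)
  final <- function(dt) {
    cfg <- kuramoto_config(lambda_grid = 0.3, t_total = 40, transient = 0,
                           dt = dt, sample_dt = 40, n_runs = 1)
    simulate_kuramoto(M, 0.3, cfg, omega = om, theta0 = th0)[1, ]
  }
  e1 <- max(abs(final(0.4) - final(0.2)))
  e2 <- max(abs(final(0.2) - final(0.1)))
  e3 <- max(abs(final(0.1) - final(0.05)))
  expect_gte(log2(e1 / e2), 3.8)
  expect_gte(log2(e2 / e3), 3.8)
})

test_that("weighted coupling rescales total strength to the edge count", {
  # uniform weights reduce to the adjacency
  cnu <- connectome(fx$TOY7$A * 0.37, k_in_ext = fx$TOY7$k_in_ext)
  expect_equal(weighted_coupling(cnu), cnu$A, ignore_attr = TRUE)
  # any weights: total equals the edge count
  expect_equal(sum(weighted_coupling(fx$TOY7)), sum(fx$TOY7$A))
  # TOY7 scalar-rescale oracle
  expect_equal(weighted_coupling(fx$TOY7),
               fx$TOY7$W * sum(fx$TOY7$A) / sum(fx$TOY7$W))
  expect_equal(weighted_coupling(fx$TOY7, mode = "binary"), fx$TOY7$A)
})

test_that("filtered synchrony keeps the r_link fraction of strongest pairs", {
  C <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3, 3)
  expect_equal(sum(filtered_sync(C, 1)), 6)            # all off-diagonal kept
  expect_equal(sum(filtered_sync(C, 0)), 0)
  F2 <- filtered_sync(C, 1 / 3)                         # top 2 of 6 entries
  expect_equal(sum(F2), 2)
  expect_equal(F2[1, 2] + F2[2, 1], 2)                  # the two .9 entries
  expect_true(all(diag(F2) == 0))
})

test_that("synchrony grows with coupling and the sweep table is well-formed", {
  cn <- generate_connectome(synth_spec(n_nodes = 12, density = 0.5,
                                       extra_sources = 10), seed = 81)
  cfg <- kuramoto_config(lambda_grid = c(0, 0.1), t_total = 200,
                         transient = 100, n_runs = 20)
  part <- detect_modules(cn, n_restarts = 5, seed = 82)
  hubs <- suppressMessages(select_hubs(cn))
  sw <- kuramoto_sweep(cn, "weighted", cfg, partition = part, hubs = hubs,
                       seed = 83)
  expect_gt(sw$table$r[2], sw$table$r[1])
  expect_gt(sw$table$r_link[2], sw$table$r_link[1])
  # lambda = 0: no coupling, little pairwise synchrony, ratios near 1
  expect_lt(sw$table$r_link[1], 0.2)
  expect_equal(sw$table$dyn_mod[1], 1, tolerance = 0.25)
  for (li in 1:2) {
    C <- sw$C_mean[[li]]
    expect_true(all(C >= -1e-12 & C <= 1 + 1e-12))
    expect_equal(C, t(C), tolerance = 1e-12)
    expect_true(all(sw$F_mean[[li]] >= 0 & sw$F_mean[[li]] <= 1))
  }
})

test_that("shuffled mode with uniform weights is distributed like weighted mode", {
  # with all weights equal, shuffling is a no-op, so the per-run r values
  # must come from the same distribution
  cnu <- connectome(fx$TOY7$A, k_in_ext = fx$TOY7$k_in_ext)
  cfg <- kuramoto_config(lambda_grid = 0.05, t_total = 150, transient = 50,
                         n_runs = 100)
  sw_w <- kuramoto_sweep(cnu, "weighted", cfg, seed = 91)
  sw_s <- kuramoto_sweep(cnu, "weight_shuffled", cfg, seed = 92)
  ks <- suppressWarnings(stats::ks.test(sw_w$per_run[[1]][, "r"],
                                        sw_s$per_run[[1]][, "r"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted disconnected modules synchronise internally first", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  cn <- connectome(A)
  cfg <- kuramoto_config(lambda_grid = 0.15, t_total = 200, transient = 100,
                         n_runs = 10)
  sw <- kuramoto_sweep(cn, "binary", cfg,
                       partition = rep(1:2, each = 4), seed = 95)
  expect_gt(sw$table$dyn_mod[1], 1.5)
})

test_that("divergent integration is reported with the step size", {
  # coupling at overflow scale drives the state non-finite within a step
  cfg <- kuramoto_config(lambda_grid = 1, t_total = 2, transient = 0,
                         dt = 0.5, sample_dt = 0.5, n_runs = 1)
  M <- matrix(1e300, 2, 2); diag(M) <- 0
  expect_error(simulate_kuramoto(M, 1e10, cfg, omega = c(0, 1), theta0 = c(0, 3)),
               "dt")
})
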