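# Brute-force / independent oracles used throughout the suite. Every oracle
# deliberately uses a different algorithm (plain loops, exhaustive
# enumeration, or igraph) than the package implementation it checks.

rand_connectome <- function(n, p = 0.5, seed = NULL, weighted = TRUE,
                            k_extra = 0) {
  gen <- function() {
    repeat {
      A <- matrix(stats::runif(n * n) < p, n, n) * 1
      diag(A) <- 0
      if (sum(A) >= 2) break
    }
    W <- if (weighted) A * matrix(stats::runif(n * n, 0.5, 3), n, n) else A
    k_ext <- colSums(A) + if (k_extra > 0) sample.int(k_extra + 1, n, replace = TRUE) - 1 else 0
    connectome(W, k_in_ext = k_ext)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Fagiolo directed clustering by explicit ordered-triple loops.
oracle_clustering <- function(A, W) {
  n <- nrow(A)
  Wc <- W^(1/3)
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- vapply(1:n, function(i) sum(A[i, ] * A[, i]), numeric(1))
  C <- numeric(n)
  for (i in 1:n) {
    t_i <- 0
    for (j in 1:n) for (h in 1:n) {
      if (j == i || h == i || j == h) next
      t_i <- t_i + (Wc[i, j] + Wc[j, i]) * (Wc[i, h] + Wc[h, i]) *
        (Wc[j, h] + Wc[h, j])
    }
    t_i <- t_i / 2
    den <- d_tot[i] * (d_tot[i] - 1) - 2 * d_bi[i]
    C[i] <- if (den > 0) t_i / den else 0
  }
  C
}

# All-pairs (cost, hops) by Bellman-Ford-style relaxation over edges with
# lexicographic (cost, hops) ordering — independent of the package's
# Floyd-Warshall.
oracle_paths_bf <- function(cost) {
  n <- nrow(cost)
  edges <- which(is.finite(cost) & row(cost) != col(cost), arr.ind = TRUE)
  D <- matrix(Inf, n, n); H <- matrix(Inf, n, n)
  diag(D) <- 0; diag(H) <- 0
  for (s in 1:n) {
    for (pass in 1:(2 * n)) {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        u <- edges[e, 1]; v <- edges[e, 2]
        if (!is.finite(D[s, u])) next
        nd <- D[s, u] + cost[u, v]; nh <- H[s, u] + 1
        if (nd < D[s, v] - 1e-12 ||
            (abs(nd - D[s, v]) <= 1e-12 && nh < H[s, v])) {
          D[s, v] <- nd; H[s, v] <- nh; changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  list(D = D, H = H)
}

oracle_phi_binary <- function(cn, k) {
  cl <- which(cn$k_in_ext > k)
  if (length(cl) < 2) return(NA_real_)
  e <- 0
  for (i in cl) for (j in cl) if (i != j && cn$A[i, j] > 0) e <- e + 1
  e / (length(cl) * (length(cl) - 1))
}

oracle_phi_weighted <- function(cn, k) {
  cl <- which(cn$k_in_ext > k)
  if (length(cl) < 2) return(NA_real_)
  e <- 0; wsum <- 0
  for (i in cl) for (j in cl) if (i != j && cn$A[i, j] > 0) {
    e <- e + 1; wsum <- wsum + cn$W[i, j]
  }
  if (e == 0) return(0)
  allw <- sort(cn$W[cn$A > 0], decreasing = TRUE)
  wsum / sum(allw[1:e])
}

oracle_modularity <- function(M, mem) {
  n <- nrow(M); m <- sum(M)
  k_out <- rowSums(M); k_in <- colSums(M)
  q <- 0
  for (i in 1:n) for (j in 1:n) {
    if (mem[i] == mem[j]) q <- q + M[i, j] / m - k_out[i] * k_in[j] / m^2
  }
  unname(q)
}

oracle_rand_index <- function(m1, m2) {
  n <- length(m1)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((m1[i] == m1[j]) == (m2[i] == m2[j])) agree <- agree + 1
  }
  agree / total
}

oracle_pareto <- function(pts, mode) {
  n <- nrow(pts)
  nd <- rep(TRUE, n)
  sgn <- if (mode == "max_smallworld") c(1, -1) else c(-1, 1)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    ge <- sgn[1] * pts[j, 1] >= sgn[1] * pts[i, 1] &&
      sgn[2] * pts[j, 2] >= sgn[2] * pts[i, 2]
    gt <- sgn[1] * pts[j, 1] > sgn[1] * pts[i, 1] ||
      sgn[2] * pts[j, 2] > sgn[2] * pts[i, 2]
    if (ge && gt) { nd[i] <- FALSE; break }
  }
  nd
}

# igraph as an independent all-pairs shortest-path oracle on a cost matrix
igraph_distances <- function(cost) {
  el <- which(is.finite(cost) & row(cost) != col(cost), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  if (igraph::vcount(g) < nrow(cost))
    g <- igraph::add_vertices(g, nrow(cost) - igraph::vcount(g))
  igraph::distances(g, mode = "out", weights = cost[el])
}
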