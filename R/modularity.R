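# Directed (weighted) modularity: Leicht-Newman spectral bisection with
# Kernighan-Lin style fine-tuning, Q scoring, Rand-index agreement, and
# intra/intermodular edge classification.

# Symmetrised directed modularity matrix S = B + t(B),
# B_ij = W_ij - k_out_i * k_in_j / m.  Q(partition) = sum_g S[g,g] / (2 m).
modularity_matrix <- function(c, weighted) {
  M <- if (weighted) c$W else c$A
  m <- sum(M)
  if (m <= 0) stopf("graph has no edges")
  B <- M - outer(rowSums(M), colSums(M)) / m
  list(S = B + t(B), m = m)
}

canonical_membership <- function(mem) {
  match(mem, unique(mem))
}

# Kernighan-Lin style fine-tuning of a bisection sign vector s on the
# group modularity matrix Bg (Newman 2006 fine-tuning): repeated passes in
# which every vertex is moved once, greedily, keeping the best intermediate
# state, until a full pass yields no improvement.
kl_refine <- function(Bg, s) {
  f <- as.numeric(t(s) %*% Bg %*% s)
  repeat {
    moved <- rep(FALSE, length(s))
    s_run <- s; f_run <- f
    Bgs <- as.numeric(Bg %*% s_run)
    best_f <- f; best_s <- s
    for (step in seq_along(s)) {
      gains <- -4 * s_run * Bgs + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      f_run <- f_run + gains[i]
      Bgs <- Bgs - 2 * s_run[i] * Bg[, i]
      s_run[i] <- -s_run[i]
      moved[i] <- TRUE
      if (f_run > best_f + 1e-12) { best_f <- f_run; best_s <- s_run }
    }
    if (best_f > f + 1e-12) { f <- best_f; s <- best_s } else break
  }
  list(s = s, f = f)
}

bisect_group <- function(S, group, n_restarts) {
  Sg <- S[group, group, drop = FALSE]
  Bg <- Sg - diag(rowSums(Sg), nrow = length(group))
  ev <- eigen(Bg, symmetric = TRUE)
  s0 <- ifelse(ev$vectors[, 1] >= 0, 1, -1)
  best <- kl_refine(Bg, s0)
  if (n_restarts > 1) {
    for (r in seq_len(n_restarts - 1)) {
      s_init <- sample(c(-1, 1), length(group), replace = TRUE)
      cand <- kl_refine(Bg, s_init)
      if (cand$f > best$f + 1e-12) best <- cand
    }
  }
  best
}

#' Detect modules by directed modularity maximisation
#'
#' Maximises the directed (optionally weighted) modularity
#' `Q = (1/m) * sum_ij (M_ij - k_out_i k_in_j / m) * delta(c_i, c_j)`
#' by Leicht-Newman spectral bisection on the symmetrised modularity matrix,
#' with Kernighan-Lin style fine-tuning of every split, applied recursively
#' until no split increases Q. Each bisection is restarted `n_restarts` times
#' from random sign vectors (plus the spectral start) and the best Q is kept;
#' ties are broken towards the lexicographically smallest canonical
#' assignment, so the result is deterministic given the seed.
#'
#' @param c a [connectome] with at least 1 edge.
#' @param weighted use connection strengths (`TRUE`) or the binary adjacency?
#' @param n_restarts random restarts per bisection (default 100).
#' @param seed optional integer seed.
#' @return An object of class `partition`: `membership` (named, contiguous
#'   ids from 1), `Q`, `weighted`, `n_modules`, `n_restarts`, `seed`.
#' @export
detect_modules <- function(c, weighted = FALSE, n_restarts = 100, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  mm <- modularity_matrix(c, weighted)
  with_seed_opt(seed, {
    mem <- rep(1L, c$n)
    queue <- list(seq_len(c$n))
    next_id <- 2L
    while (length(queue) > 0) {
      group <- queue[[1]]; queue <- queue[-1]
      if (length(group) < 2) next
      best <- bisect_group(mm$S, group, n_restarts)
      dQ <- best$f / (4 * mm$m)
      if (dQ > 1e-10 && length(unique(best$s)) == 2) {
        g1 <- group[best$s > 0]; g2 <- group[best$s < 0]
        mem[g2] <- next_id; next_id <- next_id + 1L
        queue <- c(queue, list(g1), list(g2))
      }
    }
    mem <- canonical_membership(mem)
    names(mem) <- c$labels
    structure(list(membership = mem,
                   Q = score_partition(c, mem, weighted = weighted),
                   weighted = weighted, n_modules = max(mem),
                   n_restarts = n_restarts, seed = seed),
              class = "partition")
  })
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d modules, Q = %.4f (%s)\n",
              x$n_modules, x$Q, if (x$weighted) "weighted" else "binary"))
  print(table(module = x$membership))
  invisible(x)
}

as_membership <- function(partition, n) {
  mem <- if (inherits(partition, "partition")) partition$membership else partition
  mem <- as.integer(mem)
  if (length(mem) != n) stopf("partition must assign all %d nodes", n)
  if (anyNA(mem)) stopf("unassigned node in partition")
  mem
}

#' Score the directed (weighted) modularity of a given partition
#'
#' @param c a [connectome].
#' @param partition a `partition` object or an integer membership vector.
#' @param weighted score on strengths or on the binary adjacency?
#' @return The modularity Q of the assignment.
#' @export
score_partition <- function(c, partition, weighted = FALSE) {
  stopifnot(inherits(c, "connectome"))
  mem <- as_membership(partition, c$n)
  M <- if (weighted) c$W else c$A
  m <- sum(M)
  if (m <= 0) stopf("graph has no edges")
  k_out <- rowSums(M); k_in <- colSums(M)
  same <- outer(mem, mem, "==")
  sum((M - outer(k_out, k_in) / m)[same]) / m
}

#' Rand index between two partitions, with a permutation null
#'
#' The (unadjusted) Rand index is the fraction of unordered node pairs on
#' which two partitions agree — both grouped together or both apart. The
#' permutation p-value shuffles one membership vector across nodes `n_perm`
#' times and reports the proportion of permutations whose Rand index is at
#' least the observed one.
#'
#' @param p1,p2 `partition` objects or membership vectors over the same nodes.
#' @param n_perm number of permutations (0 skips the test; study default
#'   10,000).
#' @param seed optional integer seed.
#' @return List with `rand` and `p` (`NA` when `n_perm = 0`).
#' @export
rand_index <- function(p1, p2, n_perm = 0, seed = NULL) {
  m1 <- if (inherits(p1, "partition")) p1$membership else as.integer(p1)
  m2 <- if (inherits(p2, "partition")) p2$membership else as.integer(p2)
  if (length(m1) != length(m2)) stopf("partitions cover different node sets")
  rand1 <- function(a, b) {
    n <- length(a)
    tab <- table(a, b)
    npairs <- choose(n, 2)
    (npairs + 2 * sum(choose(tab, 2)) -
        sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2))) / npairs
  }
  obs <- rand1(m1, m2)
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed_opt(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        if (rand1(m1, sample(m2)) >= obs - 1e-12) hits <- hits + 1L
      }
      hits / n_perm
    })
  }
  list(rand = obs, p = p)
}

#' Classify directed edges as intra- or intermodular
#'
#' @param c a [connectome].
#' @param partition a `partition` or membership vector.
#' @return A data frame with one row per directed edge: `from`, `to`,
#'   `weight`, and `class` (`"intra"` or `"inter"`).
#' @export
classify_edges_by_module <- function(c, partition) {
  stopifnot(inherits(c, "connectome"))
  mem <- as_membership(partition, c$n)
  idx <- which(c$A > 0)
  from <- as.integer((idx - 1) %% c$n + 1)
  to <- as.integer((idx - 1) %/% c$n + 1)
  data.frame(
    from = c$labels[from], to = c$labels[to], weight = c$W[idx],
    class = ifelse(mem[from] == mem[to], "intra", "inter"),
    stringsAsFactors = FALSE
  )
}
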