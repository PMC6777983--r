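# Randomised reference ensembles and the associated statistics:
# degree- and in-strength-preserving rewiring, weight shuffling, normalized
# metrics with empirical p-values, permutation tests and FDR control.

#' Degree- and in-strength-preserving rewiring
#'
#' Randomises the topology by repeated double-edge swaps: two directed edges
#' `a -> b` and `c -> d` are replaced by `a -> d` and `c -> b`. Swaps creating
#' self-loops or duplicate edges are rejected. Each weight stays attached to
#' its *target* slot (the weight that entered `d` still enters `d` via the new
#' edge), so the in-strength of every node is preserved exactly, and in- and
#' out-degrees are preserved by construction. The external in-degree
#' `k_in_ext` is carried over unchanged: it derives from the full source set,
#' which subgraph rewiring does not touch.
#'
#' @param c a [connectome] with at least 2 edges.
#' @param n_swaps number of attempted swaps; default 10 x edge count.
#' @param seed optional integer seed (the caller's RNG stream is untouched
#'   when given).
#' @return A rewired [connectome].
#' @export
rewire_preserving <- function(c, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  with_seed_opt(seed, {
    n <- c$n
    idx <- which(c$A > 0)
    E <- length(idx)
    if (E < 2) stopf("rewiring needs at least 2 edges")
    if (E == n * (n - 1)) {
      warning("complete graph admits no swap; returning an unmodified copy",
              call. = FALSE)
      return(c)
    }
    if (is.null(n_swaps)) n_swaps <- 10L * E
    from <- as.integer((idx - 1) %% n + 1)
    to <- as.integer((idx - 1) %/% n + 1)
    w <- c$W[idx]
    Alog <- c$A > 0
    for (s in seq_len(n_swaps)) {
      e <- sample.int(E, 2L)
      a <- from[e[1L]]; b <- to[e[1L]]
      cc <- from[e[2L]]; d <- to[e[2L]]
      if (a == cc || a == d || cc == b || b == d) next
      if (Alog[a, d] || Alog[cc, b]) next
      Alog[a, b] <- FALSE; Alog[cc, d] <- FALSE
      Alog[a, d] <- TRUE;  Alog[cc, b] <- TRUE
      # weights follow their target slot: w(c->d) now enters d via a->d
      to[e[1L]] <- d; to[e[2L]] <- b
      wtmp <- w[e[1L]]; w[e[1L]] <- w[e[2L]]; w[e[2L]] <- wtmp
    }
    Wnew <- matrix(0, n, n)
    Wnew[cbind(from, to)] <- w
    connectome(Wnew, labels = c$labels, lobe = c$lobe, k_in_ext = c$k_in_ext,
               meta = c$meta)
  })
}

#' Shuffle connection strengths over a fixed topology
#'
#' Redistributes the observed weights uniformly at random over the existing
#' edges: the adjacency and the weight multiset are conserved, only the
#' assignment of strengths to connections changes.
#'
#' @param c a [connectome] with at least 1 edge.
#' @param seed optional integer seed.
#' @return A weight-shuffled [connectome].
#' @export
shuffle_weights <- function(c, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  with_seed_opt(seed, {
    idx <- which(c$A > 0)
    if (length(idx) < 1) stopf("needs at least 1 edge")
    Wnew <- c$W
    Wnew[idx] <- c$W[idx][sample.int(length(idx))]
    connectome(Wnew, labels = c$labels, lobe = c$lobe, k_in_ext = c$k_in_ext,
               meta = c$meta)
  })
}

#' Build a null ensemble of randomised networks
#'
#' Draws `n_samples` randomised versions of a connectome — either
#' degree/in-strength-preserving rewirings (`kind = "rewire"`) or weight
#' shuffles over the fixed topology (`kind = "shuffle"`) — and evaluates the
#' supplied scalar metrics on each sample. Only the metric values are kept;
#' pass `keep_samples = TRUE` to retain the randomised networks themselves.
#'
#' @param c a [connectome].
#' @param metrics named list of functions `connectome -> scalar`.
#' @param kind `"rewire"` or `"shuffle"`.
#' @param n_samples ensemble size (the study default is 10,000; tests use
#'   hundreds).
#' @param swap_multiplier attempted swaps per edge for `"rewire"`.
#' @param keep_samples retain the list of randomised connectomes?
#' @param seed optional integer seed.
#' @return An object of class `null_ensemble` with the value matrix
#'   (`n_samples` x metrics), per-metric means and standard deviations.
#' @export
null_ensemble <- function(c, metrics, kind = c("rewire", "shuffle"),
                          n_samples = 1000, swap_multiplier = 10,
                          keep_samples = FALSE, seed = NULL) {
  stopifnot(inherits(c, "connectome"), is.list(metrics), length(metrics) > 0)
  kind <- match.arg(kind)
  if (is.null(names(metrics)) || any(names(metrics) == ""))
    stopf("metrics must be a *named* list of functions")
  with_seed_opt(seed, {
    E <- sum(c$A)
    vals <- matrix(NA_real_, n_samples, length(metrics),
                   dimnames = list(NULL, names(metrics)))
    samples <- if (keep_samples) vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      cs <- if (kind == "rewire") {
        rewire_preserving(c, n_swaps = swap_multiplier * E)
      } else {
        shuffle_weights(c)
      }
      if (keep_samples) samples[[s]] <- cs
      vals[s, ] <- vapply(metrics, function(f) as.numeric(f(cs)), numeric(1))
    }
    structure(list(kind = kind, n_samples = n_samples, values = vals,
                   mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
                   samples = samples, seed = seed),
              class = "null_ensemble")
  })
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble (%s), %d samples\n", x$kind, x$n_samples))
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Normalise an observed metric against a null ensemble
#'
#' Computes the ratio of the observed metric to its null-ensemble mean and the
#' empirical p-value: the proportion of null samples at least as extreme as
#' the observation in the observed direction (null values >= observed when the
#' observation lies above the null mean, <= otherwise). With
#' `correction = TRUE` the small-sample `(x + 1) / (n + 1)` estimate is used.
#'
#' @param observed observed scalar metric value.
#' @param ensemble a [null_ensemble] built for the same connectome.
#' @param metric name of the metric column in the ensemble.
#' @param correction apply the +1 small-sample correction?
#' @return List with `norm`, `p`, `null_mean`, `null_sd`.
#' @export
normalized_metric <- function(observed, ensemble, metric, correction = FALSE) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!metric %in% colnames(ensemble$values)) stopf("no metric '%s' in ensemble", metric)
  nullv <- ensemble$values[, metric]
  mu <- mean(nullv)
  if (mu == 0) stopf("null mean is zero; normalization undefined")
  extreme <- if (observed >= mu) sum(nullv >= observed) else sum(nullv <= observed)
  p <- if (correction) (extreme + 1) / (length(nullv) + 1) else extreme / length(nullv)
  list(norm = observed / mu, p = p, null_mean = mu, null_sd = stats::sd(nullv))
}

#' Two-group permutation test on the difference of means
#'
#' Pools the two samples, permutes the group labels `n_perm` times, and
#' reports the two-sided p-value: the proportion of permutations whose
#' absolute mean difference is at least the observed one.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param n_perm number of random label permutations (study default 10,000).
#' @param seed optional integer seed.
#' @return List with `statistic` (mean(a) - mean(b)) and `p`.
#' @export
permutation_test_groups <- function(a, b, n_perm = 10000, seed = NULL) {
  if (length(a) < 1 || length(b) < 1) stopf("both groups must be nonempty")
  if (n_perm < 1) stopf("n_perm must be at least 1")
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a); ntot <- length(pooled)
  with_seed_opt(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      ia <- sample.int(ntot, na)
      stat <- mean(pooled[ia]) - mean(pooled[-ia])
      if (abs(stat) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    list(statistic = obs, p = hits / n_perm)
  })
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust]) and the rejection mask at
#' level `q`. `NA` p-values (e.g. undefined rich-club thresholds) propagate as
#' `NA` without entering the correction.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param q FDR level for the rejection mask.
#' @return List with `adjusted` and logical `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stopf("p-values must lie in [0, 1]")
  adjusted <- rep(NA_real_, length(pvals))
  adjusted[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}
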