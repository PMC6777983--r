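# Evolutionary two-objective Pareto exploration of the
# (normalized clustering, normalized path length) plane: the small-world
# morphospace, explored under three mutation regimes.

#' Pareto front of a two-objective point set
#'
#' Identifies the nondominated points among `(C_norm, L_norm)` pairs. Under
#' `mode = "max_smallworld"` a point dominates another when its clustering is
#' at least as high and its path length at least as low, with at least one
#' strict inequality; `"min_smallworld"` reverses both orientations.
#' Duplicated points never dominate each other, so all copies stay on the
#' front.
#'
#' @param points numeric matrix or data frame with columns `C_norm`, `L_norm`
#'   (or any two columns in that order).
#' @param mode `"max_smallworld"` (max C, min L) or `"min_smallworld"`.
#' @return Logical vector marking the nondominated points.
#' @export
pareto_front <- function(points, mode = c("max_smallworld", "min_smallworld")) {
  mode <- match.arg(mode)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 1) stopf("need at least one point")
  # orient both objectives so larger is better
  u <- if (mode == "max_smallworld") pts[, 1] else -pts[, 1]
  v <- if (mode == "max_smallworld") -pts[, 2] else pts[, 2]
  n <- nrow(pts)
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dominated <- any((u >= u[i] & v >= v[i]) & (u > u[i] | v > v[i]))
    nd[i] <- !dominated
  }
  nd
}

# Area of the region dominated by a front, measured against a fixed reference
# corner that is at least as bad as every point (both objectives oriented so
# larger is better). Standard 2-D staircase sweep.
hypervolume <- function(points, mode, ref) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (mode == "max_smallworld") {
    u <- ref[2] - pts[, 2]   # path-length gain
    v <- pts[, 1] - ref[1]   # clustering gain
  } else {
    u <- pts[, 2] - ref[2]
    v <- ref[1] - pts[, 1]
  }
  u <- pmax(u, 0); v <- pmax(v, 0)
  ord <- order(-u, -v)
  best_v <- 0; hv <- 0
  for (i in ord) {
    if (v[i] > best_v) {
      hv <- hv + u[i] * (v[i] - best_v)
      best_v <- v[i]
    }
  }
  hv
}

#' Mutate a network under a morphospace regime
#'
#' Adjusts four network edges, the unit of variation in the evolutionary
#' sampler, under the regime's conservation law:
#' * `binary_swap` — two double-edge swaps preserving in- and out-degrees
#'   (weights equal the adjacency);
#' * `weighted_swap_instrength` — two double-edge swaps with weights attached
#'   to their target slots, preserving degrees and in-strength;
#' * `weight_only_swap` — two exchanges of the weights of random edge pairs,
#'   preserving the binary topology and the weight multiset.
#'
#' @param c a [connectome].
#' @param regime mutation regime (see above).
#' @param n_swaps number of elementary swaps (default 2, i.e. four edges).
#' @param seed optional integer seed.
#' @return The mutated [connectome].
#' @export
mutate_network <- function(c, regime = c("binary_swap", "weighted_swap_instrength",
                                         "weight_only_swap"),
                           n_swaps = 2, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  regime <- match.arg(regime)
  with_seed_opt(seed, {
    if (regime == "weight_only_swap") {
      idx <- which(c$A > 0)
      if (length(idx) < 2) return(c)
      Wnew <- c$W
      for (s in seq_len(n_swaps)) {
        e <- sample(idx, 2L)
        tmp <- Wnew[e[1]]; Wnew[e[1]] <- Wnew[e[2]]; Wnew[e[2]] <- tmp
      }
      return(connectome(Wnew, labels = c$labels, lobe = c$lobe,
                        k_in_ext = c$k_in_ext, meta = c$meta))
    }
    out <- c
    for (s in seq_len(n_swaps)) {
      # one accepted double-edge swap (bounded retries; dense graphs may
      # admit none, in which case the network is returned unchanged)
      for (try in 1:50) {
        cand <- suppressWarnings(rewire_preserving(out, n_swaps = 1))
        if (!identical(cand$A, out$A)) { out <- cand; break }
        if (sum(out$A) == out$n * (out$n - 1)) break
      }
    }
    if (regime == "binary_swap") out <- as_binary(out)
    out
  })
}

#' Evolve a population of networks towards a small-world Pareto front
#'
#' Runs the evolutionary morphospace sampler: a population of networks,
#' initialised with copies of the original connectome, is iteratively scored
#' on normalized clustering and normalized characteristic path length, its
#' Pareto front identified, and every dominated network replaced by a mutated
#' copy of a randomly chosen front member (front members persist unmutated).
#' Objectives are normalized against *fixed* reference constants — the mean
#' clustering and path length of a rewired null ensemble of the original
#' network — computed once per run (or supplied via `refs`).
#'
#' Binary regimes score binary clustering/path length; weighted regimes score
#' the weighted versions.
#'
#' @param c the original [connectome].
#' @param regime mutation regime, as in [mutate_network].
#' @param mode objective orientation, as in [pareto_front].
#' @param pop_size population size (study default 500; scaled-down analyses
#'   use 50).
#' @param n_iter iterations (study default 1,000; scaled-down 100).
#' @param refs optional list `(C_ref, L_ref)` of normalization constants.
#' @param n_null ensemble size used to compute `refs` when absent.
#' @param seed optional integer seed.
#' @return An object of class `morphospace_run`: final population objectives
#'   (`objectives` with `on_front` flag), per-iteration `trace` (front size,
#'   objective extremes, dominated hypervolume), `fronts` (per-iteration front
#'   point sets), `refs`, and the run settings.
#' @export
evolve_morphospace <- function(c, regime = c("binary_swap", "weighted_swap_instrength",
                                             "weight_only_swap"),
                               mode = c("max_smallworld", "min_smallworld"),
                               pop_size = 500, n_iter = 1000, refs = NULL,
                               n_null = 200, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  regime <- match.arg(regime)
  mode <- match.arg(mode)
  weighted <- regime != "binary_swap"
  base <- if (weighted) c else as_binary(c)
  objective_fun <- function(cn) {
    C <- if (weighted) clustering_weighted(cn)$network_value else
      clustering_binary(cn)$network_value
    L <- if (weighted) path_length_weighted(cn)$cost$network_value else
      path_length_binary(cn)$network_value
    c(C, L)
  }
  with_seed_opt(seed, {
    if (is.null(refs)) {
      ens <- null_ensemble(base, metrics = list(C = function(x) objective_fun(x)[1],
                                                L = function(x) objective_fun(x)[2]),
                           kind = "rewire", n_samples = n_null)
      refs <- list(C_ref = unname(ens$mean["C"]), L_ref = unname(ens$mean["L"]))
    }
    score <- function(cn) {
      o <- objective_fun(cn)
      c(C_norm = o[1] / refs$C_ref, L_norm = o[2] / refs$L_ref)
    }
    pop <- replicate(pop_size, base, simplify = FALSE)
    obj <- matrix(rep(suppressMessages(score(base)), each = pop_size),
                  pop_size, 2, dimnames = list(NULL, c("C_norm", "L_norm")))
    fronts <- vector("list", n_iter)
    trace <- vector("list", n_iter)
    if (n_iter > 0) for (it in seq_len(n_iter)) {
      nd <- pareto_front(obj, mode)
      front_idx <- which(nd)
      for (i in which(!nd)) {
        parent <- front_idx[sample.int(length(front_idx), 1L)]
        child <- mutate_network(pop[[parent]], regime)
        pop[[i]] <- child
        obj[i, ] <- suppressMessages(score(child))
      }
      nd_after <- pareto_front(obj, mode)
      fronts[[it]] <- obj[nd_after, , drop = FALSE]
      trace[[it]] <- data.frame(
        iteration = it, front_size = sum(nd_after),
        C_norm_min = min(obj[, 1]), C_norm_max = max(obj[, 1]),
        L_norm_min = min(obj[, 2]), L_norm_max = max(obj[, 2])
      )
    }
    final_front <- pareto_front(obj, mode)
    structure(list(
      regime = regime, mode = mode, pop_size = pop_size, n_iter = n_iter,
      refs = refs, population = pop,
      objectives = data.frame(member = seq_len(pop_size), obj,
                              on_front = final_front),
      trace = if (n_iter > 0) do.call(rbind, trace) else
        data.frame(iteration = integer(), front_size = integer(),
                   C_norm_min = numeric(), C_norm_max = numeric(),
                   L_norm_min = numeric(), L_norm_max = numeric()),
      fronts = fronts, seed = seed
    ), class = "morphospace_run")
  })
}

#' @export
print.morphospace_run <- function(x, ...) {
  cat(sprintf("Morphospace run: regime %s, mode %s, pop %d, %d iterations\n",
              x$regime, x$mode, x$pop_size, x$n_iter))
  cat(sprintf("  C_norm in [%.3f, %.3f], L_norm in [%.3f, %.3f]; final front %d members\n",
              min(x$objectives$C_norm), max(x$objectives$C_norm),
              min(x$objectives$L_norm), max(x$objectives$L_norm),
              sum(x$objectives$on_front)))
  invisible(x)
}
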