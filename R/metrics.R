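# Directed clustering and shortest-path measures, binary and weighted.

metric_vector <- function(name, per_node, network_value, aggregation, extra = list()) {
  structure(list(name = name, per_node = per_node,
                 network_value = network_value, aggregation = aggregation,
                 extra = extra),
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("%s: network value %.6g (%s over %d nodes)\n",
              x$name, x$network_value, x$aggregation, length(x$per_node)))
  invisible(x)
}

# Fagiolo directed clustering shared kernel. Wc is the elementwise cube root
# of the weight matrix (equal to A in the binary case).
fagiolo_clustering <- function(A, Wc, variant) {
  d_out <- rowSums(A); d_in <- colSums(A)
  d_tot <- d_in + d_out
  d_bi <- diag(A %*% A)
  num <- switch(variant,
    total     = diag((Wc + t(Wc)) %*% (Wc + t(Wc)) %*% (Wc + t(Wc))) / 2,
    cycle     = diag(Wc %*% Wc %*% Wc),
    middleman = diag(Wc %*% t(Wc) %*% Wc),
    `in`      = diag(t(Wc) %*% Wc %*% Wc),
    out       = diag(Wc %*% Wc %*% t(Wc))
  )
  den <- switch(variant,
    total     = d_tot * (d_tot - 1) - 2 * d_bi,
    cycle     = d_in * d_out - d_bi,
    middleman = d_in * d_out - d_bi,
    `in`      = d_in * (d_in - 1),
    out       = d_out * (d_out - 1)
  )
  ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
}

#' Directed binary clustering coefficient
#'
#' Per-node directed clustering after Fagiolo, evaluated on the binary
#' adjacency: the fraction of directed triangles through a node among those
#' its in/out neighbourhood admits. The default `"total"` variant counts all
#' directed triangle motifs; the other variants restrict to cycles, middleman,
#' inward or outward triangles. Nodes whose neighbourhood admits no triangle
#' (total degree < 2) score 0 and are included in the network mean.
#'
#' @param c a [connectome] with at least 3 nodes.
#' @param variant triangle motif class, one of `"total"` (default), `"cycle"`,
#'   `"middleman"`, `"in"`, `"out"`.
#' @return A `metric_vector` with per-node values and the network mean.
#' @export
clustering_binary <- function(c, variant = c("total", "cycle", "middleman", "in", "out")) {
  stopifnot(inherits(c, "connectome"))
  if (c$n < 3) stopf("clustering needs at least 3 nodes")
  variant <- match.arg(variant)
  v <- fagiolo_clustering(c$A, c$A, variant)
  names(v) <- c$labels
  metric_vector(paste0("clustering_binary_", variant), v, mean(v), "mean")
}

#' Directed weighted clustering coefficient
#'
#' Fagiolo's weighted directed clustering: triangle intensities are geometric
#' means of the raw weights (cube-root products), with the same degree-based
#' normalisation as the binary variant. Weights are *not* rescaled by the
#' maximum weight, so for weights above 1 the coefficient can exceed 1; with
#' all weights equal to 1 it reduces exactly to [clustering_binary].
#'
#' @inheritParams clustering_binary
#' @return A `metric_vector`.
#' @export
clustering_weighted <- function(c, variant = c("total", "cycle", "middleman", "in", "out")) {
  stopifnot(inherits(c, "connectome"))
  if (c$n < 3) stopf("clustering needs at least 3 nodes")
  variant <- match.arg(variant)
  v <- fagiolo_clustering(c$A, c$W^(1/3), variant)
  names(v) <- c$labels
  metric_vector(paste0("clustering_weighted_", variant), v, mean(v), "mean")
}

# All-pairs shortest paths minimising (cost, hops) lexicographically:
# Floyd-Warshall over the pair (D, H). Ties in cost (within 1e-12) are broken
# towards fewer hops, making the step length deterministic.
pair_shortest_paths <- function(cost) {
  n <- nrow(cost)
  D <- cost
  H <- ifelse(is.finite(cost), 1, Inf)
  diag(D) <- 0; diag(H) <- 0
  tol <- 1e-12
  for (k in seq_len(n)) {
    cand <- outer(D[, k], D[k, ], "+")
    candH <- outer(H[, k], H[k, ], "+")
    fin <- is.finite(cand)
    eq <- fin & is.finite(D) & abs(cand - D) <= tol
    better <- (fin & cand < D - tol) | (eq & candH < H)
    D[better] <- cand[better]
    H[better] <- candH[better]
  }
  list(D = D, H = H)
}

path_network_mean <- function(M, what) {
  v <- off_diag(M)
  unreachable <- sum(!is.finite(v))
  if (unreachable > 0)
    message(sprintf("%d unreachable ordered pairs excluded from the %s mean",
                    unreachable, what))
  mean(v[is.finite(v)])
}

#' Binary characteristic path length
#'
#' All-pairs directed hop distance; the network value is the mean over all
#' ordered pairs of distinct nodes. Unreachable pairs are excluded from the
#' mean with a message. Per-node values are the mean outgoing distance from
#' each node.
#'
#' @param c a [connectome] with at least 2 nodes.
#' @return A `metric_vector`; the full distance matrix is in `$extra$D`.
#' @export
path_length_binary <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (c$n < 2) stopf("path length needs at least 2 nodes")
  cost <- ifelse(c$A > 0, 1, Inf)
  sp <- pair_shortest_paths(cost)
  per_node <- vapply(seq_len(c$n), function(i) {
    d <- sp$D[i, -i]; mean(d[is.finite(d)])
  }, numeric(1))
  names(per_node) <- c$labels
  metric_vector("path_length_binary", per_node,
                path_network_mean(sp$D, "binary path length"),
                "mean over ordered pairs", extra = list(D = sp$D))
}

#' Weighted characteristic path length and step length
#'
#' Weighted shortest paths minimise total traversal cost with the cost of an
#' edge taken as the inverse of its connection strength. Returns both the
#' characteristic path length (mean minimal cost over ordered pairs) and the
#' characteristic *step* length: the mean number of discrete hops those
#' cost-minimal paths use, a measure of the binary efficiency of weighted
#' routes. Among equal-cost paths the one with fewest hops is counted.
#'
#' @param c a [connectome]; every supported edge must have strictly positive
#'   weight.
#' @return A list with `metric_vector`s `cost` and `steps`; distance and hop
#'   matrices are in `cost$extra$D` and `steps$extra$H`.
#' @export
path_length_weighted <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (c$n < 2) stopf("path length needs at least 2 nodes")
  if (any(c$W[c$A > 0] <= 0)) stopf("zero-weight edge on the support")
  cost <- ifelse(c$A > 0, 1 / c$W, Inf)
  sp <- pair_shortest_paths(cost)
  per_cost <- vapply(seq_len(c$n), function(i) {
    d <- sp$D[i, -i]; mean(d[is.finite(d)])
  }, numeric(1))
  per_steps <- vapply(seq_len(c$n), function(i) {
    h <- sp$H[i, -i]; mean(h[is.finite(h)])
  }, numeric(1))
  names(per_cost) <- names(per_steps) <- c$labels
  list(
    cost = metric_vector("path_length_weighted", per_cost,
                         path_network_mean(sp$D, "weighted path length"),
                         "mean over ordered pairs", extra = list(D = sp$D)),
    steps = metric_vector("step_length_weighted", per_steps,
                          path_network_mean(sp$H, "weighted step length"),
                          "mean over ordered pairs", extra = list(H = sp$H))
  )
}
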