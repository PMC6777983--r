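# Synthetic connectome generation emulating the statistical structure of
# dense retrograde tract-tracing data, plus tiny fixed fixtures whose metric
# values are oracle-computable.

#' Specification of a synthetic connectome
#'
#' The defaults describe the study conditions this package targets: 29
#' regions at 66% directed density; log-normally distributed raw connection
#' counts (log-transformed to weights); two planted modules whose intra- and
#' intermodular connection probabilities (0.82 and 0.50) match the realized
#' intra/intermodular densities of the dense tract-tracing network the
#' generator emulates; a hub core (top 20% of nodes) with near-complete
#' mutual connectivity and boosted weights; and an external in-degree built
#' from 62 additional unobserved source regions. An optional exponential
#' distance rule (EDR) attenuates weights with spatial distance.
#'
#' @param n_nodes number of regions.
#' @param density target directed connection density.
#' @param n_modules number of planted modules (1 = no modular structure).
#' @param p_intra,p_inter intra-/intermodular connection probabilities before
#'   rescaling to the target density.
#' @param weight_mu,weight_sigma log-normal parameters (natural-log scale) of
#'   the raw labelled-neuron-like counts.
#' @param log_base base of the count-to-weight log transform.
#' @param hub_fraction fraction of nodes forming the planted rich core
#'   (0 disables the core).
#' @param hub_p connection probability among core nodes.
#' @param hub_weight_mult multiplicative weight boost of core-core edges.
#' @param hub_k_boost multiplier on the external attachment probability of
#'   core nodes, so the planted core ranks top by external in-degree the way
#'   empirical hub regions do.
#' @param extra_sources number of unobserved source regions contributing to
#'   the external in-degree.
#' @param edr_lambda optional EDR decay length (in unit-cube distance units);
#'   `NULL` disables the distance rule.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_nodes = 29, density = 0.66,
                       n_modules = 2, p_intra = 0.82, p_inter = 0.50,
                       weight_mu = 3, weight_sigma = 2, log_base = 10,
                       hub_fraction = 0.2, hub_p = 0.95, hub_weight_mult = 2,
                       hub_k_boost = 1.3, extra_sources = 62,
                       edr_lambda = NULL) {
  if (density <= 0 || density > 1) stopf("density must lie in (0, 1]")
  for (p in c(p_intra, p_inter, hub_p))
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  if (n_modules < 1) stopf("need at least one module")
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic connectome
#'
#' Draws a directed graph with the structure described by a [synth_spec]:
#' edges are sampled with module-dependent probabilities rescaled so the
#' expected density matches the target; the hub core is wired at `hub_p` and
#' its internal weights multiplied by `hub_weight_mult`; raw counts are
#' log-normal, floored to integers of at least 1, and log-transformed into
#' weights; the external in-degree adds a `Binomial(extra_sources, density)`
#' top-up to the realized internal in-degree; and, when `edr_lambda` is set,
#' weights decay as `exp(-d / edr_lambda)` with inter-node distance for
#' positions uniform in the unit cube. Fully reproducible given a seed.
#'
#' @param spec a [synth_spec].
#' @param seed optional integer seed.
#' @return A [connectome]; planted module assignments, hub labels and (with
#'   EDR) positions are stored in `$meta`.
#' @export
generate_connectome <- function(spec = synth_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed_opt(seed, {
    n <- spec$n_nodes
    labels <- sprintf("R%02d", seq_len(n))
    mem <- rep(seq_len(spec$n_modules), length.out = n)
    mem <- sort(mem)
    # module-dependent edge probabilities, rescaled to hit the target density
    same <- outer(mem, mem, "==")
    diag(same) <- NA
    P <- ifelse(same, spec$p_intra, spec$p_inter)
    if (spec$n_modules == 1) P[!is.na(same)] <- spec$density
    expected <- mean(P, na.rm = TRUE)
    P <- pmin(P * spec$density / expected, 1)
    n_hub <- if (spec$hub_fraction > 0) ceiling(spec$hub_fraction * n) else 0L
    hub_idx <- seq_len(n_hub)   # planted core: first nodes of module 1
    if (n_hub >= 2) {
      P[hub_idx, hub_idx] <- spec$hub_p
      # rebalance the non-core cells so the overall expected density stays
      # on target despite the dense core block
      core <- matrix(FALSE, n, n); core[hub_idx, hub_idx] <- TRUE
      noncore <- !core & !is.na(same)
      want <- spec$density * n * (n - 1) - spec$hub_p * n_hub * (n_hub - 1)
      have <- sum(P[noncore])
      if (have > 0 && want > 0) P[noncore] <- pmin(P[noncore] * want / have, 1)
    }
    diag(P) <- 0
    A <- matrix(stats::runif(n * n) < P, n, n) * 1
    diag(A) <- 0
    # log-normal labelled-neuron-like counts on the sampled edges
    idx <- which(A > 0)
    counts <- pmax(1, floor(stats::rlnorm(length(idx), spec$weight_mu,
                                          spec$weight_sigma)))
    W <- matrix(0, n, n)
    W[idx] <- log_weight(counts, base = spec$log_base)
    if (n_hub >= 2) {
      core <- matrix(FALSE, n, n)
      core[hub_idx, hub_idx] <- TRUE
      W[core & A > 0] <- W[core & A > 0] * spec$hub_weight_mult
    }
    positions <- NULL
    if (!is.null(spec$edr_lambda)) {
      positions <- matrix(stats::runif(3 * n), n, 3)
      D <- as.matrix(stats::dist(positions))
      W <- W * exp(-D / spec$edr_lambda)
    }
    k_int <- colSums(A > 0)
    p_ext <- rep(spec$density, n)
    p_ext[hub_idx] <- min(1, spec$density * spec$hub_k_boost)
    k_ext <- k_int + stats::rbinom(n, spec$extra_sources, p_ext)
    connectome(W, labels = labels, k_in_ext = k_ext,
               meta = list(spec = spec, modules = stats::setNames(mem, labels),
                           hubs = labels[hub_idx], positions = positions,
                           seed = seed))
  })
}

#' Fixed toy fixtures with oracle-computable metrics
#'
#' A versioned set of tiny networks used throughout the test suite:
#' * `TOY4` — a 4-region tracing experiment ([raw_tracing]) with 7 nonzero
#'   integer count pathways, for weight-transform checks;
#' * `TOY7` — a 7-node weighted connectome with two planted modules
#'   (`{R1..R4}`, `{R5..R7}`), a 2-hub core (`R1`, `R2`) and a fixed external
#'   in-degree vector, for every graph-metric check;
#' * `K4` — the complete directed graph on 4 nodes (unit weights);
#' * `RING5` — a directed 5-cycle (unit weights).
#'
#' @return Named list with elements `TOY4`, `TOY7`, `K4`, `RING5`.
#' @export
toy_fixtures <- function() {
  counts4 <- matrix(0, 4, 4, dimnames = list(paste0("T", 1:4), paste0("T", 1:4)))
  counts4[1, 2] <- 9;  counts4[2, 1] <- 99; counts4[1, 3] <- 4
  counts4[3, 4] <- 1;  counts4[4, 1] <- 19; counts4[2, 3] <- 50
  counts4[4, 2] <- 3
  toy4 <- raw_tracing(counts4)

  lab7 <- paste0("R", 1:7)
  e7 <- rbind(
    c(1, 2, 5.0), c(2, 1, 4.0), c(1, 3, 2.0), c(3, 1, 1.5),
    c(2, 3, 3.0), c(3, 4, 1.0), c(4, 1, 2.5), c(2, 4, 0.5),
    c(5, 6, 2.0), c(6, 7, 1.2), c(7, 5, 0.8), c(6, 5, 2.2),
    c(1, 5, 3.5), c(5, 2, 1.8), c(4, 6, 0.6), c(7, 2, 0.9), c(2, 7, 1.1)
  )
  W7 <- matrix(0, 7, 7, dimnames = list(lab7, lab7))
  W7[e7[, 1:2]] <- e7[, 3]
  toy7 <- connectome(W7, labels = lab7,
                     k_in_ext = c(6, 6, 4, 3, 4, 3, 3),
                     meta = list(modules = stats::setNames(c(1, 1, 1, 1, 2, 2, 2), lab7),
                                 hubs = c("R1", "R2")))

  ring <- matrix(0, 5, 5)
  ring[cbind(1:5, c(2:5, 1))] <- 1
  list(TOY4 = toy4, TOY7 = toy7, K4 = connectome(1 - diag(4)),
       RING5 = connectome(ring))
}
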