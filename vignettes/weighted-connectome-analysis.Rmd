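---
title: "Weighted and binary analysis of directed connectomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted and binary analysis of directed connectomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strengthnet)
```

This vignette documents the models, estimators and numerical choices behind
`strengthnet`. The package asks one scientific question of a directed,
weighted connectome: *what does the placement of connection strengths add to
the organisation already present in the binary wiring diagram?* It answers it
by computing each topological measure twice — on the adjacency and on the
weights — and referring both to tailored null ensembles.

## Data model

A `connectome` is a directed graph over labelled regions in a fixed
orientation: `W[i, j]` is the strength of the projection *from* region `i`
*into* region `j` (rows are sources, columns targets; all readers normalise
to this orientation). The adjacency `A` is the support of `W`; self-loops are
stripped on ingest because retrograde tracing reports intrinsic labels on the
diagonal that are not network edges.

Each node also carries an **external in-degree** `k_in_ext`, the number of
distinct source regions projecting into it counted over the *full* parcellated
source set, not only the injected subgraph. In edge-complete tract-tracing
designs the injected regions are a subset of the atlas (29 of 91 in the
dataset this package targets), and the incoming-projection counts from all
atlas regions are known even though the subgraph only contains the injected
ones. Rich-club analysis ranks nodes on this quantity, which is why it is a
first-class field rather than a derived one; it must dominate the
within-subgraph in-degree, and the constructor enforces that.

Two weight transforms are provided. Labelled-neuron counts are log-normally
distributed over many orders of magnitude, so the default weight is
`w = log10(p + 1)`; zero counts map to zero weights so the support is
untouched. The base of the logarithm is not fixed by convention, so it is a
parameter (`base`), with base 10 the package default. The alternative FLNe
weighting (extrinsic fraction of labelled neurons) divides each injection
column by its total extrinsic label count, compensating for variable tracer
uptake; it can be combined with the log transform.

## Graph measures

**Clustering.** Directed clustering follows Fagiolo's formulation: for node
`i`, triangle intensity is summed over all directed triangle motifs through
`i`, with each triangle scored by the geometric mean of its weights
(cube-root products), and normalised by the motif count the node's in-, out-
and bilateral degrees admit. Two choices deserve emphasis:

* weights enter *raw* — there is no division by the maximum weight. With
  log-count weights above 1 the coefficient can therefore exceed 1 (weighted
  network means of 3–4 are typical for this data class); with all weights
  equal to 1 it reduces exactly to the binary coefficient, which the tests
  assert.
* nodes whose neighbourhood admits no triangle (total degree below 2) score 0
  and are *included* in the network mean.

The `"total"` motif class is the default (the literature rarely specifies the
variant); `cycle`, `middleman`, `in` and `out` variants are available for
sensitivity analysis.

**Path and step length.** Weighted shortest paths minimise summed traversal
cost with edge cost `1/w` (strong projections are cheap to use). The network
measure `L^w` is the mean minimal cost over ordered pairs. The **step
length** `Lstep^w` is the mean number of hops those cost-minimal routes use —
a measure of how binary-efficient the weighted routing is. Among equal-cost
routes the package deterministically counts the one with fewest hops
(tie tolerance `1e-12`); this makes step length well defined and
reproducible. Both are computed by a Floyd–Warshall recursion over the pair
(cost, hops) ordered lexicographically. Unreachable ordered pairs are
excluded from means with a message; at the ~66% density this package targets
the graph is strongly connected and the exclusion only matters for sparse
synthetic edge cases.

## Null models

Two ensembles calibrate every observation:

* **Degree- and in-strength-preserving rewiring** (`rewire_preserving`):
  repeated double-edge swaps `a→b, c→d  ⇒  a→d, c→b`, rejecting self-loops
  and duplicates. Each weight stays attached to its *target* slot — the
  weight that entered `d` still enters `d` — so every node's in-strength is
  conserved exactly, alongside in- and out-degree. Out-strength is *not*
  conserved (only the named quantities are). The default randomisation
  attempts 10 swaps per edge (`swap_multiplier`); the number of accepted
  swaps is lower at high density because many proposals are rejected.
  `k_in_ext` is carried over unchanged since it derives from the untouched
  full source set — this keeps club membership fixed across the ensemble and
  makes rich-club coefficients comparable between original and nulls.
* **Weight shuffling** (`shuffle_weights`): a uniform random permutation of
  the weights over the fixed edge support. It isolates the contribution of
  strength *placement* from that of topology and of the strength
  distribution itself.

Empirical p-values are the plain proportion of null samples at least as
extreme as the observation in the observed direction; the small-sample
`(x+1)/(n+1)` estimate is available behind `correction = TRUE`. Group
comparisons (intra- vs intermodular strength, connection-class strengths,
per-coupling sweep statistics) use two-sided random-label permutation tests
on the difference of means, and families of tests are corrected by
Benjamini–Hochberg FDR (`stats::p.adjust`). Ensemble sizes default to the
10,000 of full-scale analyses; the test-suite and the bundled acceptance
analysis run hundreds, which is enough for the effect sizes they assert.

## Modularity

Directed modularity `Q = (1/m) Σ_ij (M_ij − k_i^out k_j^in / m) δ(c_i, c_j)`
is maximised by Leicht–Newman spectral bisection on the symmetrised
modularity matrix `B + Bᵀ`, each split refined by Kernighan–Lin-style
fine-tuning (every node moved once per pass, greedily, keeping the best
intermediate state), applied recursively until no split increases `Q` by more
than `1e-10`. Each bisection restarts from the spectral sign vector plus
`n_restarts − 1` random sign vectors, keeping the best refined result; given
a seed the procedure is fully deterministic. Because spectral optimisation is
a heuristic, equal-`Q` solutions with different memberships exist; downstream
comparisons therefore use `Q`, module counts and the Rand index rather than
exact memberships. The Rand index is deliberately unadjusted — its
permutation null (shuffling one membership across nodes) supplies the chance
calibration that the adjusted variant would build in analytically.

## Rich club

For a threshold `k`, the club is the set of nodes with `k_in_ext > k`. The
binary coefficient is the club's internal connection density; the weighted
coefficient divides the club's internal weight by the sum of the equally many
globally strongest weights, so it is bounded by 1 and equals 1 when the club
monopolises the strongest connections. Thresholds whose club has fewer than
two members yield `NA`, which propagates (never silently zero). Curves are
normalised by the rewired ensemble's mean coefficient at each `k`, given
per-`k` empirical p-values, and FDR-corrected across the grid. The same
rewired ensemble serves both flavors; a weight-shuffled reference for the
weighted flavor is computable through `null_ensemble` if wanted.

Hub selection takes the top 20% of nodes by `k_in_ext` (ties at the boundary
broken by label order, with a message), and connections are classed as
*rich* (hub→hub), *feeder* (exactly one hub endpoint) or *local*. Mean
strengths of the classes are contrasted by permutation tests, overall and
split into intra-/intermodular scopes; an empty class in a scope is an error
at the function level, and the pipeline falls back to the overall contrast
with a logged message when a small network produces one.

## Morphospace

The evolutionary sampler explores which (normalized clustering, normalized
path length) combinations networks with the same conservation laws can reach.
A population (default 500, scaled analyses 50) starts as copies of the
original network. Each iteration: score all members, find the Pareto front
under the active orientation (`max_smallworld`: high `C_norm`, low `L_norm`;
`min_smallworld` reversed), replace every dominated member by a mutated copy
of a uniformly chosen front member. Front members persist unmutated
(elitism), which makes the dominated hypervolume non-decreasing — an
invariant the tests assert. A mutation adjusts four edges: two double-edge
swaps under the regime's conservation law (binary degrees; degrees plus
in-strength), or two weight-pair exchanges for the fixed-topology regime.

Normalisation constants are computed **once**, from a rewired null ensemble
of the original network, and reused for every candidate: per-candidate null
ensembles would be computationally prohibitive, and a single normalisation
keeps the two axes interpretable as one fixed scale. The two objective
orientations are run separately (fronts from one orientation are not reused
by the other). `n_iter = 0` degenerates to a population of identical
originals, which pins the normalization constants in tests.

## Functional dynamics

Regions are Kuramoto phase oscillators,
`dθ_i/dt = ω_i + λ Σ_j M_ji sin(θ_j − θ_i)` — note `M_ji`: *incoming*
projections drive a node, matching the source×target orientation. Weighted
coupling rescales `W` so its total equals the edge count, making `λ`
comparable across binary, weighted and weight-shuffled runs. Intrinsic
frequencies are uniform on `[0, 1]` and initial phases uniform on `[−π, π]`,
fresh per realisation.

Integration is classic fixed-step RK4 over `T = 700` model time units with
statistics collected after a transient `τ = 300`. The step `dt = 0.05` and
observation spacing `sample_dt = 0.5` are package choices (the time step of
record is not part of the model definition); the test suite measures the
convergence order by step-halving (≥ 3.8 on a drifting configuration) and the
λ = 0 closed form to `1e-10`, which justifies the default step. Because the
absolute synchrony level at a given `λ` shifts with such conventions,
cross-implementation comparisons of the sweep should be qualitative — the
location of the synchronisation transition and the ordering of ratios — not
numeric equality.

Per realisation the package computes the global order parameter `r` (time
average of the population phase-vector modulus), the pairwise synchrony
matrix `C_ij = |⟨e^{i(θ_i−θ_j)}⟩_t|`, its off-diagonal mean `r_link`, and the
filtered matrix `F` that keeps the `round(N(N−1)·r_link)` largest entries of
`C` (per-run `r_link`, ties at the cutoff broken by index order with a
message). Averaging `F` over realisations estimates each pair's
synchronisation probability. Module and rich-club structure enter as
synchrony ratios: intra/intermodular mean synchrony ("dynamical modularity")
and hub–hub versus other-pair synchrony, also split by intra-/intermodular
pair sets. Sweeps store per-run statistics so that two sweeps (e.g. weighted
vs weight-shuffled) can be compared per coupling value by permutation tests
with FDR across the grid.

Realisations within a sweep are integrated in one batched pass (a
block-diagonal sparse coupling operator, or a single dense operator when all
realisations share the coupling matrix); the batch is numerically identical
to run-by-run integration, which a test asserts to machine precision.

## Synthetic data: what it emulates, and what it does not

`synth_spec()` defaults describe the study conditions the package targets:
29 regions at 66% directed density; log-normal raw counts (`meanlog 3`,
`sdlog 2`, floored to integers ≥ 1) log10-transformed to weights; two planted
modules whose intra/inter connection probabilities (0.82 / 0.50) mirror the
realized intra- and intermodular densities reported for the empirical
network; a planted hub core (top 20% of nodes) wired at probability 0.95
with weights boosted ×2 and an external attachment rate boosted ×1.3 so the
core ranks top by external in-degree the way empirical hubs do; and an
external in-degree built from 62 unobserved source regions via a
`Binomial(62, density)` top-up. An optional exponential distance rule
multiplies weights by `exp(−d/λ_d)` for positions in the unit cube,
emulating the exponential weight–distance relation of real cortical
networks; it attenuates weights, not edge presence.

Two features of real data are deliberately *not* emulated: weights are drawn
independently of the module structure (no intramodular strength excess), and
there is no regional geometry or nomenclature. Consequently, passing tests on
synthetic data demonstrate that the estimators recover *planted* structure
and stay calibrated on unstructured nulls — they do not by themselves
establish any empirical claim about real connectomes, and
weighted-versus-shuffled contrasts on synthetic data are expected to be
near-neutral at the module level.

## Degenerate inputs and numerical conventions

* Complete graphs admit no rewiring swap: a copy is returned with a warning.
* Clubs smaller than two nodes give `NA` coefficients, excluded from FDR.
* Equal-cost path ties: fewest hops, tolerance `1e-12`.
* Hub-selection and filtered-synchrony ties: label/index order, with a
  message.
* All stochastic functions take an explicit `seed` and leave the caller's
  RNG stream untouched; the pipeline derives per-stage sub-seeds from one
  master seed, making whole bundles byte-reproducible.

## Problem sizes of the bundled analyses

The package's own acceptance analysis (`scripts/acceptance.R`) runs the full
stack on the synthetic study-condition network with 300-sample null
ensembles, 1,000-permutation tests, a 30-member/40-iteration morphospace and
a 5-coupling × 20-realisation Kuramoto sweep; the test suite uses 100–1,000
null samples and 20–100 realisations. These sizes were chosen so the whole
analysis reruns in about a minute while keeping Monte-Carlo error an order of
magnitude below the asserted effects; full-scale studies would use the
10,000-sample defaults noted above.

## Known limitations

* Modularity memberships are heuristic optima; only `Q`, module counts and
  Rand agreement are stable comparison targets.
* The weighted clustering convention (raw weights, cube-root products) is one
  of several in circulation; values are only comparable under the same
  convention and log base.
* The Kuramoto model treats all regions as identical oscillators and always
  reaches global synchrony at strong coupling; no delays or regional
  heterogeneity are modelled.
* Out-strength is not preserved by the rewiring null; conclusions about
  out-strength-driven quantities should use a dedicated ensemble.
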