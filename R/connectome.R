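#' Construct a directed weighted connectome
#'
#' A `connectome` holds a directed weighted graph over labelled brain regions
#' in a fixed orientation: rows are source regions, columns are target regions,
#' so `W[i, j] > 0` means a directed projection from region `i` into region
#' `j`. The binary adjacency `A` is the support of `W`. Each node additionally
#' carries an *external in-degree* `k_in_ext`: the number of distinct source
#' regions projecting into it counted over an extended source set (in
#' retrograde tract-tracing data, all parcellated regions, not only the
#' injected subset). Rich-club analysis ranks nodes by this quantity.
#'
#' Self-loops are stripped on ingest with a warning; tract-tracing matrices
#' report intrinsic labels on the diagonal which are not network edges.
#'
#' @param W numeric matrix of non-negative weights (rows = source,
#'   columns = target). A 0/1 matrix yields a binary connectome.
#' @param labels character vector of region names; defaults to existing
#'   dimnames or `"R01"`, `"R02"`, ...
#' @param lobe optional character vector tagging each region with a lobe.
#' @param k_in_ext optional integer vector of external in-degrees; defaults to
#'   the within-graph in-degree. Must dominate the within-graph in-degree
#'   elementwise.
#' @param meta free-form provenance list.
#' @return An object of class `connectome` with fields `n`, `labels`, `lobe`,
#'   `A`, `W`, `k_in_ext`, `meta`.
#' @examples
#' W <- matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE)
#' cn <- connectome(W)
#' cn$A
#' @export
connectome <- function(W, labels = NULL, lobe = NULL, k_in_ext = NULL,
                       meta = list()) {
  W <- as.matrix(W)
  if (!is.numeric(W)) stopf("W must be a numeric matrix")
  if (nrow(W) != ncol(W)) stopf("W must be square (got %d x %d)", nrow(W), ncol(W))
  if (anyNA(W)) stopf("W contains missing values")
  if (any(W < 0)) stopf("weights must be non-negative")
  n <- nrow(W)
  if (is.null(labels)) {
    labels <- rownames(W) %||% sprintf("R%02d", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stopf("need %d labels, got %d", n, length(labels))
  if (anyDuplicated(labels)) stopf("duplicate region labels")
  if (any(diag(W) != 0)) {
    warning("self-loops removed from the diagonal", call. = FALSE)
    diag(W) <- 0
  }
  dimnames(W) <- list(labels, labels)
  A <- (W > 0) * 1
  dimnames(A) <- dimnames(W)
  k_int <- as.integer(colSums(A))
  if (is.null(k_in_ext)) {
    k_in_ext <- k_int
  } else {
    k_in_ext <- as.integer(k_in_ext)
    if (length(k_in_ext) != n) stopf("k_in_ext must have length %d", n)
    if (any(k_in_ext < 0)) stopf("k_in_ext must be non-negative")
    if (any(k_in_ext < k_int)) {
      stopf("k_in_ext must dominate the within-graph in-degree (violated at %s)",
            paste(labels[k_in_ext < k_int], collapse = ", "))
    }
  }
  names(k_in_ext) <- labels
  if (!is.null(lobe)) {
    lobe <- as.character(lobe)
    if (length(lobe) != n) stopf("lobe must have length %d", n)
    names(lobe) <- labels
  }
  structure(
    list(n = n, labels = labels, lobe = lobe, A = A, W = W,
         k_in_ext = k_in_ext, meta = meta),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  e <- sum(x$A)
  cat(sprintf("Directed connectome: %d regions, %d edges (density %.3f)\n",
              x$n, e, network_density(x)))
  cat(sprintf("  weights in [%.3g, %.3g]; external in-degree in [%d, %d]\n",
              min(x$W[x$A > 0] %||% 0), max(x$W), min(x$k_in_ext), max(x$k_in_ext)))
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  cat(sprintf("Regions: %s%s\n", paste(utils::head(object$labels, 8), collapse = ", "),
              if (object$n > 8) ", ..." else ""))
  print(object)
  invisible(object)
}

#' Drop weights, keeping the binary topology
#'
#' @param c a [connectome].
#' @return A `connectome` whose `W` equals its adjacency `A`.
#' @export
as_binary <- function(c) {
  connectome(c$A, labels = c$labels, lobe = c$lobe, k_in_ext = c$k_in_ext,
             meta = c$meta)
}

#' Bundle a raw retrograde tract-tracing experiment
#'
#' Holds the labeled-neuron count matrix of a retrograde tracing study:
#' `counts[i, j]` is the number of neurons in source region `i` labelled by an
#' injection into target region `j`. The source set may exceed the injected
#' (target) set. `neurons_ext[j]` is the total number of reported labelled
#' neurons extrinsic to target `j` — the denominator of the extrinsic fraction
#' of labelled neurons (FLNe).
#'
#' @param counts non-negative numeric matrix, sources x targets.
#' @param sources,targets region identifiers; default to dimnames.
#' @param neurons_ext per-target totals of extrinsic labelled neurons; defaults
#'   to the column sums over extrinsic sources.
#' @return An object of class `raw_tracing`.
#' @export
raw_tracing <- function(counts, sources = NULL, targets = NULL,
                        neurons_ext = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative and complete")
  sources <- as.character(sources %||% rownames(counts) %||%
                            sprintf("S%02d", seq_len(nrow(counts))))
  targets <- as.character(targets %||% colnames(counts) %||%
                            sprintf("R%02d", seq_len(ncol(counts))))
  if (length(sources) != nrow(counts) || length(targets) != ncol(counts))
    stopf("sources/targets must match the counts dimensions")
  if (anyDuplicated(sources) || anyDuplicated(targets))
    stopf("duplicate region identifiers")
  dimnames(counts) <- list(sources, targets)
  extrinsic_sum <- vapply(seq_along(targets), function(j) {
    sum(counts[sources != targets[j], j])
  }, numeric(1))
  if (is.null(neurons_ext)) {
    neurons_ext <- extrinsic_sum
  } else {
    neurons_ext <- as.numeric(neurons_ext)
    if (length(neurons_ext) != length(targets))
      stopf("neurons_ext must have one entry per target")
    if (any(neurons_ext + 1e-9 < extrinsic_sum))
      stopf("neurons_ext must be at least the extrinsic column sum")
  }
  names(neurons_ext) <- targets
  structure(list(sources = sources, targets = targets, counts = counts,
                 neurons_ext = neurons_ext),
            class = "raw_tracing")
}

#' @export
print.raw_tracing <- function(x, ...) {
  cat(sprintf("Retrograde tracing data: %d sources x %d targets, %d nonzero pathways\n",
              length(x$sources), length(x$targets), sum(x$counts > 0)))
  invisible(x)
}

#' Log-transform labelled-neuron counts into connection weights
#'
#' Computes `w = log(p + 1)` elementwise in the configured base, the standard
#' variance-stabilising transform for log-normally distributed labelled-neuron
#' counts. Zero counts map to zero weights, so the connection support is
#' preserved exactly.
#'
#' @param counts non-negative numeric matrix (or vector).
#' @param base logarithm base; default 10.
#' @return Matrix of the same shape with `log(counts + 1, base)`.
#' @examples
#' log_weight(matrix(c(0, 9, 99, 0), 2, 2))
#' @export
log_weight <- function(counts, base = 10) {
  if (anyNA(counts) || any(counts < 0)) stopf("counts must be non-negative")
  log(counts + 1, base = base)
}

#' Extrinsic fraction of labelled neurons (FLNe)
#'
#' Normalises each injection column of a tracing count matrix by the total
#' number of labelled neurons extrinsic to the injected region, compensating
#' for variable tracer uptake across injections.
#'
#' @param raw a [raw_tracing] object.
#' @param log apply [log_weight] to the FLNe values afterwards?
#' @param base log base used when `log = TRUE`.
#' @return Sources x targets matrix of FLNe values.
#' @export
flne_weight <- function(raw, log = FALSE, base = 10) {
  stopifnot(inherits(raw, "raw_tracing"))
  denom <- raw$neurons_ext
  bad <- denom <= 0 & colSums(raw$counts) > 0
  if (any(bad))
    stopf("zero extrinsic-neuron denominator for target(s) with labels: %s",
          paste(raw$targets[bad], collapse = ", "))
  flne <- sweep(raw$counts, 2, ifelse(denom > 0, denom, 1), "/")
  if (log) flne <- log_weight(flne, base = base)
  flne
}

#' Edge-complete subgraph of injected regions
#'
#' Restricts a tracing experiment to the injected (target) regions, for which
#' all possible directed connections were experimentally probed, and returns
#' the corresponding [connectome]. The external in-degree `k_in_ext[j]` counts
#' the distinct source regions over the *full* source set with a nonzero
#' pathway into `j`, excluding `j` itself.
#'
#' @param raw a [raw_tracing] object whose targets are a subset of its sources.
#' @param weighting one of `"log_counts"` (default, `log(p+1)`), `"flne"`,
#'   `"flne_log"`, or `"counts"` (raw counts).
#' @param base log base for the log weightings.
#' @param lobe optional per-target lobe tags.
#' @return A [connectome] over the target regions.
#' @export
edge_complete_subgraph <- function(raw,
                                   weighting = c("log_counts", "flne",
                                                 "flne_log", "counts"),
                                   base = 10, lobe = NULL) {
  stopifnot(inherits(raw, "raw_tracing"))
  weighting <- match.arg(weighting)
  missing_t <- setdiff(raw$targets, raw$sources)
  if (length(missing_t) > 0)
    stopf("target(s) not present among sources: %s", paste(missing_t, collapse = ", "))
  Wfull <- switch(weighting,
    counts    = raw$counts,
    log_counts = log_weight(raw$counts, base = base),
    flne      = flne_weight(raw),
    flne_log  = flne_weight(raw, log = TRUE, base = base)
  )
  sub <- Wfull[raw$targets, raw$targets, drop = FALSE]
  diag(sub) <- 0
  k_ext <- vapply(seq_along(raw$targets), function(j) {
    col <- raw$counts[, raw$targets[j]]
    sum(col > 0 & raw$sources != raw$targets[j])
  }, numeric(1))
  connectome(sub, labels = raw$targets, lobe = lobe, k_in_ext = k_ext,
             meta = list(weighting = weighting, log_base = base,
                         n_sources = length(raw$sources)))
}

#' Directed connection density
#'
#' @param c a [connectome] with at least 2 nodes.
#' @return Fraction of the `n * (n - 1)` possible directed connections present.
#' @export
network_density <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (c$n < 2) stopf("density needs at least 2 nodes")
  sum(c$A) / (c$n * (c$n - 1))
}
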