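# Rich-club analysis over the external in-degree: binary and weighted
# coefficients, normalization against rewired ensembles with FDR across the
# threshold grid, hub selection, and connection-class strength contrasts.

club_members <- function(c, k) which(c$k_in_ext > k)

#' Binary rich-club coefficient
#'
#' For threshold `k`, the club is the set of nodes whose external in-degree
#' exceeds `k`; the coefficient is the density of directed connections among
#' them: `phi(k) = E_club / (N_club * (N_club - 1))`. Undefined (`NA`) when
#' the club has fewer than 2 nodes.
#'
#' @param c a [connectome].
#' @param k in-degree threshold (club = nodes with `k_in_ext > k`).
#' @return The coefficient, or `NA` for clubs smaller than 2 nodes.
#' @export
phi_binary <- function(c, k) {
  stopifnot(inherits(c, "connectome"), k >= 0)
  cl <- club_members(c, k)
  if (length(cl) < 2) return(NA_real_)
  sum(c$A[cl, cl]) / (length(cl) * (length(cl) - 1))
}

#' Weighted rich-club coefficient
#'
#' The ratio of the total weight of connections inside the club to the sum of
#' the same number of globally strongest connection weights:
#' `phi_w(k) = W_club / sum(top E_club ranked weights)`. Always in `[0, 1]`;
#' equals 1 when the club's connections are the strongest in the network.
#'
#' @inheritParams phi_binary
#' @export
phi_weighted <- function(c, k) {
  stopifnot(inherits(c, "connectome"), k >= 0)
  cl <- club_members(c, k)
  if (length(cl) < 2) return(NA_real_)
  E <- sum(c$A[cl, cl])
  if (E == 0) return(0)
  w_sorted <- sort(c$W[c$A > 0], decreasing = TRUE)
  sum(c$W[cl, cl]) / sum(w_sorted[seq_len(E)])
}

# Fast whole-curve evaluation for one network, shared with the ensemble loop.
# Clubs over k_in_ext are nested, so the curve needs only the distinct club
# sizes: cumulative edge/weight counts over nodes sorted by k_in_ext.
rc_curve_values <- function(A, W, ord, club_size, weighted) {
  n <- length(ord)
  As <- A[ord, ord, drop = FALSE]
  add_e <- vapply(seq_len(n), function(m) {
    if (m == 1) return(0)
    sum(As[m, seq_len(m - 1)]) + sum(As[seq_len(m - 1), m])
  }, numeric(1))
  E_m <- cumsum(add_e)
  if (!weighted) {
    phi <- ifelse(club_size >= 2,
                  E_m[pmax(club_size, 1)] / (club_size * (club_size - 1)), NA_real_)
    return(phi)
  }
  Ws <- W[ord, ord, drop = FALSE]
  add_w <- vapply(seq_len(n), function(m) {
    if (m == 1) return(0)
    sum(Ws[m, seq_len(m - 1)]) + sum(Ws[seq_len(m - 1), m])
  }, numeric(1))
  W_m <- cumsum(add_w)
  w_cum <- cumsum(sort(W[A > 0], decreasing = TRUE))
  vapply(seq_along(club_size), function(i) {
    m <- club_size[i]
    if (m < 2) return(NA_real_)
    E <- E_m[m]
    if (E == 0) return(0)
    W_m[m] / w_cum[E]
  }, numeric(1))
}

#' Rich-club curve with null normalization and FDR across thresholds
#'
#' Computes the binary or weighted rich-club coefficient over a grid of
#' external in-degree thresholds, normalises it by the mean coefficient of an
#' ensemble of degree- and in-strength-preserving rewired networks (which
#' share `k_in_ext`, so club membership is identical across the ensemble), and
#' assigns each threshold an empirical p-value — the proportion of randomised
#' networks whose coefficient is at least the observed one — corrected across
#' the grid by the Benjamini-Hochberg procedure.
#'
#' @param c a [connectome].
#' @param flavor `"binary"` or `"weighted"`.
#' @param n_null rewired ensemble size (study default 10,000).
#' @param k_grid integer thresholds; default all values from
#'   `min(k_in_ext)` to `max(k_in_ext)`.
#' @param q FDR level.
#' @param swap_multiplier attempted swaps per edge in the rewiring.
#' @param seed optional integer seed.
#' @return An object of class `rich_club_curve` wrapping a data frame with
#'   columns `k`, `n_club`, `phi`, `phi_rand_mean`, `phi_norm`, `p_raw`,
#'   `p_fdr`.
#' @export
rich_club_curve <- function(c, flavor = c("binary", "weighted"),
                            n_null = 1000, k_grid = NULL, q = 0.05,
                            swap_multiplier = 10, seed = NULL) {
  stopifnot(inherits(c, "connectome"))
  flavor <- match.arg(flavor)
  weighted <- flavor == "weighted"
  if (is.null(k_grid)) k_grid <- seq(min(c$k_in_ext), max(c$k_in_ext))
  if (length(k_grid) == 0) stopf("empty threshold grid")
  ord <- order(-c$k_in_ext, c$labels)
  k_sorted <- c$k_in_ext[ord]
  club_size <- vapply(k_grid, function(k) sum(k_sorted > k), integer(1))
  phi_obs <- rc_curve_values(c$A, c$W, ord, club_size, weighted)
  with_seed_opt(seed, {
    E <- sum(c$A)
    phi_null <- matrix(NA_real_, n_null, length(k_grid))
    for (s in seq_len(n_null)) {
      cs <- rewire_preserving(c, n_swaps = swap_multiplier * E)
      phi_null[s, ] <- rc_curve_values(cs$A, cs$W, ord, club_size, weighted)
    }
    phi_rand_mean <- colMeans(phi_null)
    p_raw <- vapply(seq_along(k_grid), function(i) {
      if (is.na(phi_obs[i])) return(NA_real_)
      mean(phi_null[, i] >= phi_obs[i] - 1e-12)
    }, numeric(1))
    p_fdr <- fdr_bh(p_raw, q = q)$adjusted
    curve <- data.frame(
      k = k_grid, n_club = club_size, phi = phi_obs,
      phi_rand_mean = phi_rand_mean,
      phi_norm = ifelse(phi_rand_mean > 0, phi_obs / phi_rand_mean, NA_real_),
      p_raw = p_raw, p_fdr = p_fdr
    )
    structure(list(curve = curve, flavor = flavor, n_null = n_null,
                   seed = seed),
              class = "rich_club_curve")
  })
}

#' @export
print.rich_club_curve <- function(x, ...) {
  sig <- x$curve$k[!is.na(x$curve$p_fdr) & x$curve$p_fdr < 0.05]
  cat(sprintf("Rich-club curve (%s), %d thresholds, %d nulls\n",
              x$flavor, nrow(x$curve), x$n_null))
  if (length(sig) > 0) {
    cat(sprintf("  phi_norm > chance (FDR < 0.05) for k in [%d, %d]\n",
                min(sig), max(sig)))
  } else {
    cat("  no thresholds significant at FDR < 0.05\n")
  }
  invisible(x)
}

#' Select rich-club hubs and classify connections
#'
#' Takes the top fraction of nodes by external in-degree as the rich club
#' (the study default is the top 20%) and labels every directed connection as
#' `"rich"` (both endpoints hubs), `"feeder"` (exactly one endpoint a hub), or
#' `"local"` (neither). Ties at the selection boundary are broken by label
#' order, with a message.
#'
#' @param c a [connectome].
#' @param fraction hub fraction in (0, 1); `ceiling(fraction * n)` hubs.
#' @return An object of class `hub_partition`: `hubs` (labels), `is_hub`,
#'   and `edges` (data frame `from`, `to`, `weight`, `class`).
#' @export
select_hubs <- function(c, fraction = 0.2) {
  stopifnot(inherits(c, "connectome"))
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  n_hub <- ceiling(fraction * c$n)
  ord <- order(-c$k_in_ext, c$labels)
  if (n_hub < c$n && c$k_in_ext[ord[n_hub]] == c$k_in_ext[ord[n_hub + 1]])
    message("tie at the hub-selection boundary broken by label order")
  hubs_idx <- ord[seq_len(n_hub)]
  is_hub <- seq_len(c$n) %in% hubs_idx
  idx <- which(c$A > 0)
  from <- as.integer((idx - 1) %% c$n + 1)
  to <- as.integer((idx - 1) %/% c$n + 1)
  n_ends <- is_hub[from] + is_hub[to]
  edges <- data.frame(
    from = c$labels[from], to = c$labels[to], weight = c$W[idx],
    class = c("local", "feeder", "rich")[n_ends + 1],
    stringsAsFactors = FALSE
  )
  structure(list(hubs = c$labels[hubs_idx], is_hub = is_hub, edges = edges,
                 fraction = fraction),
            class = "hub_partition")
}

#' @export
print.hub_partition <- function(x, ...) {
  cat(sprintf("Rich club: %d hubs (%s)\n", length(x$hubs),
              paste(x$hubs, collapse = ", ")))
  print(table(class = x$edges$class))
  invisible(x)
}

#' Connection-class strength contrasts with permutation tests
#'
#' Compares the mean connection strength of rich, feeder and local connection
#' classes — overall and, when a module partition is supplied, separately for
#' intra- and intermodular connections — by random-group-assignment
#' permutation tests, FDR-corrected across all comparisons.
#'
#' @param c a [connectome].
#' @param hubp a `hub_partition` from [select_hubs].
#' @param partition optional `partition` (modules from the binary analysis).
#' @param n_perm permutations per comparison (study default 10,000).
#' @param q FDR level.
#' @param seed optional integer seed.
#' @return Data frame with one row per comparison: `scope`, `class_a`,
#'   `class_b`, `mean_a`, `mean_b`, `ratio`, `p_raw`, `p_fdr`.
#' @export
class_strength_contrasts <- function(c, hubp, partition = NULL,
                                     n_perm = 10000, q = 0.05, seed = NULL) {
  stopifnot(inherits(c, "connectome"), inherits(hubp, "hub_partition"))
  edges <- hubp$edges
  scopes <- list(all = rep(TRUE, nrow(edges)))
  if (!is.null(partition)) {
    mem <- as_membership(partition, c$n)
    names(mem) <- c$labels
    intra <- mem[edges$from] == mem[edges$to]
    scopes$intra <- intra
    scopes$inter <- !intra
  }
  pairs <- list(c("rich", "feeder"), c("rich", "local"), c("feeder", "local"))
  with_seed_opt(seed, {
    rows <- list()
    for (scope in names(scopes)) {
      sel <- scopes[[scope]]
      for (pr in pairs) {
        wa <- edges$weight[sel & edges$class == pr[1]]
        wb <- edges$weight[sel & edges$class == pr[2]]
        if (length(wa) == 0 || length(wb) == 0) {
          stopf("empty connection class '%s' in scope '%s'",
                pr[which(c(length(wa), length(wb)) == 0)[1]], scope)
        }
        pt <- permutation_test_groups(wa, wb, n_perm = n_perm)
        rows[[length(rows) + 1]] <- data.frame(
          scope = scope, class_a = pr[1], class_b = pr[2],
          mean_a = mean(wa), mean_b = mean(wb),
          ratio = mean(wa) / mean(wb), p_raw = pt$p,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    out$p_fdr <- fdr_bh(out$p_raw, q = q)$adjusted
    out
  })
}
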