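#' Cluster-forming t threshold
#'
#' Two-tailed Student-t critical value at level `alpha` with `df` degrees of
#' freedom: the percent point (quantile) function evaluated at
#' `1 - alpha/2`. With `alpha = 0.05` and 12 degrees of freedom (13
#' participants per group, one-sample contrasts) this is 2.1788, reported as
#' 2.17 when truncated to two decimals.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom, `>= 1`.
#' @param truncate Truncate (round toward zero) to two decimals, matching
#'   conventional reporting.
#' @return Critical t value.
#' @examples
#' t_threshold(0.05, 12)
#' t_threshold(0.05, 12, truncate = TRUE)
#' @export
t_threshold <- function(alpha = 0.05, df, truncate = FALSE) {
  check_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar_number(df, "df", lower = 1)
  out <- qt(1 - alpha / 2, df)
  if (truncate) out <- trunc(out * 100) / 100
  out
}

# Adjacency edge list for a 1-D (contiguity) or 2-D (4-connectivity,
# column-major) domain.
domain_edges <- function(dims) {
  p <- prod(dims)
  if (length(dims) == 1) {
    e <- if (p < 2) matrix(integer(0), ncol = 2) else {
      cbind(seq_len(p - 1L), seq.int(2L, p))
    }
    attr(e, "one_d") <- TRUE
    return(e)
  }
  nr <- dims[1]; nc <- dims[2]
  idx <- matrix(seq_len(p), nr, nc)
  vert <- cbind(as.vector(idx[-nr, , drop = FALSE]),
                as.vector(idx[-1, , drop = FALSE]))
  horiz <- cbind(as.vector(idx[, -nc, drop = FALSE]),
                 as.vector(idx[, -1, drop = FALSE]))
  rbind(vert, horiz)
}

# Connected components of the suprathreshold cells. Returns a list of
# integer index vectors (one per cluster); `mask` is logical over the
# flattened domain.
mask_components <- function(mask, edges) {
  verts <- which(mask)
  if (length(verts) == 0) return(list())
  if (isTRUE(attr(edges, "one_d"))) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    return(lapply(keep, function(k) seq.int(starts[k], ends[k])))
  }
  sel <- mask[edges[, 1]] & mask[edges[, 2]]
  if (!any(sel)) return(as.list(verts))
  remap <- integer(length(mask))
  remap[verts] <- seq_along(verts)
  e <- edges[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(remap[e[, 1]], remap[e[, 2]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(verts) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  split(verts, comp)
}

# Largest positive and largest-magnitude negative cluster mass of a t map.
max_cluster_masses <- function(tv, threshold, edges) {
  pos <- 0; neg <- 0
  mask <- tv > threshold
  if (any(mask)) {
    cl <- mask_components(mask, edges)
    pos <- max(vapply(cl, function(i) sum(tv[i]), numeric(1)))
  }
  mask <- tv < -threshold
  if (any(mask)) {
    cl <- mask_components(mask, edges)
    neg <- max(vapply(cl, function(i) -sum(tv[i]), numeric(1)))
  }
  c(pos = pos, neg = neg)
}

# Observed clusters of both signs with their index sets and masses.
observed_clusters <- function(tv, threshold, edges) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tv > threshold else tv < -threshold
    if (!any(mask)) next
    for (cl in mask_components(mask, edges)) {
      out[[length(out) + 1L]] <- list(sign = sgn, cells = cl,
                                      mass = sum(tv[cl]))
    }
  }
  out
}

# Span columns (time / frequency extents) for a cluster's cells.
cluster_spans <- function(cells, dims, axes) {
  if (length(dims) == 1) {
    tibble(time_min = axes$time[min(cells)], time_max = axes$time[max(cells)])
  } else {
    fi <- (cells - 1L) %% dims[1] + 1L
    ti <- (cells - 1L) %/% dims[1] + 1L
    tibble(freq_min = axes$freq[min(fi)], freq_max = axes$freq[max(fi)],
           time_min = axes$time[min(ti)], time_max = axes$time[max(ti)])
  }
}

# Shared input checking/flattening for the permutation tests: a list of
# equally-dimensioned vectors/matrices -> n x p matrix plus domain dims.
stack_maps <- function(maps) {
  if (length(maps) == 0) abort("No input maps.")
  d0 <- dim(maps[[1]])
  dims <- if (is.null(d0)) length(maps[[1]]) else d0
  X <- t(vapply(maps, function(m) {
    dm <- if (is.null(dim(m))) length(m) else dim(m)
    if (!identical(as.integer(dm), as.integer(dims))) {
      abort("All maps must share the same domain dimensions.")
    }
    as.numeric(m)
  }, numeric(prod(dims))))
  list(X = X, dims = as.integer(dims))
}

finish_cluster_result <- function(tv, dims, threshold, edges, null_pos,
                                  null_neg, n_eff, exact, axes, n_perm) {
  obs <- observed_clusters(tv, threshold, edges)
  if (length(obs) == 0) {
    clusters <- tibble(cluster = integer(0), sign = character(0),
                       mass = numeric(0), n_cells = integer(0),
                       p = numeric(0))
  } else {
    # two-tailed max-statistic null: largest absolute cluster mass per
    # permutation, over both sign classes
    null_max <- pmax(null_pos, null_neg)
    clusters <- purrr::imap_dfr(obs, function(cl, i) {
      # tolerance so the identity permutation's recomputed mass ties with
      # the observed mass despite floating-point round-off
      tol <- 1e-8 * max(1, abs(cl$mass))
      p <- (1 + sum(null_max >= abs(cl$mass) - tol)) / (1 + n_eff)
      row <- tibble(cluster = i,
                    sign = if (cl$sign > 0) "positive" else "negative",
                    mass = cl$mass, n_cells = length(cl$cells), p = p)
      if (!is.null(axes)) row <- dplyr::bind_cols(row, cluster_spans(cl$cells, dims, axes))
      row
    })
    clusters <- dplyr::arrange(clusters, .data$p, dplyr::desc(abs(.data$mass)))
    clusters$cluster <- seq_len(nrow(clusters))
  }
  structure(
    list(clusters = clusters,
         cells = lapply(obs, `[[`, "cells"),
         t_map = array(tv, dim = dims),
         dims = dims, threshold = threshold,
         n_perm = n_perm, n_effective = n_eff, exact = exact,
         axes = axes),
    class = "ses_cluster_result"
  )
}

#' One-sample cluster-based permutation test
#'
#' Tests per-participant contrast maps against zero. A pointwise one-sample
#' t statistic is thresholded (strictly, `|t| > threshold`); suprathreshold
#' cells are grouped into contiguous clusters (1-D contiguity for series,
#' 4-connectivity for frequency x time maps) separately for positive and
#' negative t; cluster mass is the sum of t within a cluster. The null
#' distribution of the maximum cluster mass per sign is built by randomly
#' flipping the sign of whole participant maps; when `2^n <= n_perm` all
#' sign patterns are enumerated and the p-values are exact. p-values use
#' the `(1 + exceedances) / (1 + permutations)` convention, so `p > 0`
#' always.
#'
#' @param maps List of per-participant maps (equal-dimension numeric
#'   vectors or matrices; matrices are frequency x time).
#' @param threshold Cluster-forming t threshold; default
#'   `t_threshold(alpha, n - 1)`.
#' @param alpha Level used for the default threshold.
#' @param n_perm Number of random sign flips (or cap triggering exact
#'   enumeration).
#' @param seed Seed for the random flips.
#' @param enumerate `NULL` (default) enumerates all sign patterns whenever
#'   `2^n <= n_perm`; `TRUE` forces enumeration; `FALSE` forces random
#'   flips.
#' @param exclude Optional logical map (same dimensions) of cells excluded
#'   from clustering, e.g. wavelet edge samples.
#' @param axes Optional `list(time = ..., freq = ...)` axis values used to
#'   report cluster spans.
#' @return A `ses_cluster_result`: tibble of clusters (`mass`, `p`, spans),
#'   the t map, the threshold, and the permutation metadata.
#' @export
one_sample_cluster_perm <- function(maps, threshold = NULL, alpha = 0.05,
                                    n_perm = 1024, seed = 1L,
                                    enumerate = NULL,
                                    exclude = NULL, axes = NULL) {
  s <- stack_maps(maps)
  X <- s$X
  n <- nrow(X)
  if (n < 2) abort("Need at least 2 participants.")
  if (is.null(threshold)) threshold <- t_threshold(alpha, n - 1)
  p_cells <- ncol(X)
  t_of <- function(m, ss) {
    v <- (ss - n * m^2) / (n - 1)
    tv <- m / sqrt(pmax(v, 0) / n)
    tv[!is.finite(tv)] <- 0
    tv
  }
  ss <- colSums(X^2)
  tv <- t_of(colMeans(X), ss)
  if (!is.null(exclude)) tv[as.logical(as.vector(exclude))] <- 0
  edges <- domain_edges(s$dims)
  exact <- if (is.null(enumerate)) 2^n <= n_perm else isTRUE(enumerate)
  S <- if (exact) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           nrow = n_perm))
  }
  n_eff <- nrow(S)
  M <- (S %*% X) / n
  null_pos <- numeric(n_eff)
  null_neg <- numeric(n_eff)
  for (i in seq_len(n_eff)) {
    tvi <- t_of(M[i, ], ss)
    if (!is.null(exclude)) tvi[as.logical(as.vector(exclude))] <- 0
    mm <- max_cluster_masses(tvi, threshold, edges)
    null_pos[i] <- mm["pos"]
    null_neg[i] <- mm["neg"]
  }
  finish_cluster_result(tv, s$dims, threshold, edges, null_pos, null_neg,
                        n_eff, exact, axes, n_perm)
}

#' Two-sample cluster-based permutation test
#'
#' Independent-samples pointwise t statistics (pooled variance) between two
#' groups of participant maps, clustered as in
#' [one_sample_cluster_perm()]. The null is built by shuffling group
#' labels; when the number of distinct label assignments is at most
#' `n_perm`, all assignments are enumerated and p-values are exact.
#'
#' @param maps_a,maps_b Lists of per-participant maps for the two groups.
#' @param threshold Cluster-forming t threshold; default
#'   `t_threshold(alpha, df)` with per-group degrees of freedom
#'   `min(nA, nB) - 1` (`df_mode = "per_group"`) or pooled
#'   `nA + nB - 2` (`df_mode = "pooled"`).
#' @param alpha Level used for the default threshold.
#' @param df_mode Degrees-of-freedom convention for the default threshold.
#' @param n_perm Number of label shuffles (or cap triggering exact
#'   enumeration).
#' @param seed Seed for the shuffles.
#' @param enumerate As in [one_sample_cluster_perm()] but for label
#'   assignments.
#' @param exclude,axes As in [one_sample_cluster_perm()].
#' @return A `ses_cluster_result`.
#' @export
two_sample_cluster_perm <- function(maps_a, maps_b, threshold = NULL,
                                    alpha = 0.05,
                                    df_mode = c("per_group", "pooled"),
                                    n_perm = 1024, seed = 1L,
                                    enumerate = NULL,
                                    exclude = NULL, axes = NULL) {
  df_mode <- match.arg(df_mode)
  sa <- stack_maps(maps_a)
  sb <- stack_maps(maps_b)
  if (!identical(sa$dims, sb$dims)) abort("Groups must share the domain.")
  na <- nrow(sa$X); nb <- nrow(sb$X)
  if (na < 2 || nb < 2) abort("Need at least 2 participants per group.")
  if (is.null(threshold)) {
    df <- if (df_mode == "per_group") min(na, nb) - 1 else na + nb - 2
    threshold <- t_threshold(alpha, df)
  }
  X <- rbind(sa$X, sb$X)
  n <- na + nb
  ssx <- colSums(X^2)
  tot <- colSums(X)
  x2 <- X^2
  t_of <- function(ind) {
    # ind: logical membership of group A
    suma <- colSums(X[ind, , drop = FALSE])
    sqa <- colSums(x2[ind, , drop = FALSE])
    ma <- suma / na
    mb <- (tot - suma) / nb
    ssa <- sqa - na * ma^2
    ssb <- (ssx - sqa) - nb * mb^2
    sp2 <- (ssa + ssb) / (na + nb - 2)
    tv <- (ma - mb) / sqrt(pmax(sp2, 0) * (1 / na + 1 / nb))
    tv[!is.finite(tv)] <- 0
    tv
  }
  obs_ind <- c(rep(TRUE, na), rep(FALSE, nb))
  tv <- t_of(obs_ind)
  if (!is.null(exclude)) tv[as.logical(as.vector(exclude))] <- 0
  edges <- domain_edges(sa$dims)
  n_part <- choose(n, na)
  exact <- if (is.null(enumerate)) n_part <= n_perm else isTRUE(enumerate)
  assignments <- if (exact) {
    utils::combn(n, na, simplify = FALSE)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n, na), simplify = FALSE))
  }
  n_eff <- length(assignments)
  null_pos <- numeric(n_eff)
  null_neg <- numeric(n_eff)
  for (i in seq_len(n_eff)) {
    ind <- logical(n)
    ind[assignments[[i]]] <- TRUE
    tvi <- t_of(ind)
    if (!is.null(exclude)) tvi[as.logical(as.vector(exclude))] <- 0
    mm <- max_cluster_masses(tvi, threshold, edges)
    null_pos[i] <- mm["pos"]
    null_neg[i] <- mm["neg"]
  }
  finish_cluster_result(tv, sa$dims, threshold, edges, null_pos, null_neg,
                        n_eff, exact, axes, n_perm)
}
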