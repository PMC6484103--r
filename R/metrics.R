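# Network observables. Only non-removed ("functional") edges are traversable;
# an affected link participates with its decayed strength, so its path weight
# 1/eps grows as the strength decays.

#' Fraction of nodes in the largest strongly connected component
#'
#' The LSCC is the largest node set with a directed path between every
#' ordered pair; its fractional size f is the order parameter of the
#' breakdown transition. A network with no functional edges has LSCC size 1
#' (every node a singleton), so f = 1/N.
#'
#' @param network A `decay_network`.
#' @return f in `[1/N, 1]`.
#' @examples
#' net <- decay_network(3, c(1, 2, 3), c(2, 3, 1))
#' lscc_fraction(net) # 1: a directed cycle is strongly connected
#' @export
lscc_fraction <- function(network) {
  stopifnot(inherits(network, "decay_network"))
  e <- network$edges
  functional <- e$state != STATE_REMOVED
  if (!any(functional)) return(1 / network$n_nodes)
  g <- igraph::graph_from_edgelist(
    cbind(e$from[functional], e$to[functional]), directed = TRUE)
  # graph_from_edgelist sizes the graph by the largest mentioned node id;
  # isolated higher-numbered nodes only matter through n_nodes in the ratio
  max(igraph::components(g, mode = "strong")$csize) / network$n_nodes
}

#' Minimum path weights between all node pairs
#'
#' The weight of a link is the inverse of its current coupling strength
#' (resistance to transmission); the weight of a path is the sum of its link
#' weights; `w[i, j]` is the minimum over all directed paths from i to j
#' (Dijkstra), `Inf` where no functional path exists, with the diagonal
#' excluded (set to `NA`).
#'
#' @param network A `decay_network`.
#' @param sources Optional integer vector of source nodes (rows of the
#'   returned matrix); default all nodes.
#' @return A `length(sources) x n_nodes` matrix of minimum path weights.
#' @export
path_weights <- function(network, sources = NULL) {
  stopifnot(inherits(network, "decay_network"))
  g <- as_igraph(network, functional_only = TRUE, weights = "resistance")
  v <- if (is.null(sources)) igraph::V(g) else sources
  w <- igraph::distances(g, v = v, mode = "out",
                         weights = igraph::E(g)$weight, algorithm = "dijkstra")
  idx <- if (is.null(sources)) seq_len(network$n_nodes) else as.integer(sources)
  w[cbind(seq_along(idx), idx)] <- NA_real_
  w
}

#' Weighted global efficiency
#'
#' Mean over all ordered node pairs (i, j), i != j, of `1 / w[i, j]`, the
#' best-path efficiency, where `w` is the minimum path weight over link
#' weights `1/eps`. Pairs with no functional path contribute 0, so global
#' efficiency falls to 0 as the network disintegrates.
#'
#' @param network A `decay_network` with at least 2 nodes.
#' @param n_sources Number of source nodes used to estimate the pair average
#'   on large networks; `NULL` (default) is exact up to 2000 nodes and
#'   samples 500 sources above (seeded by network size, so repeated calls on
#'   equal-sized networks use the same sources). Set `n_sources = Inf` to
#'   force the exact computation.
#' @return Global efficiency, a non-negative real (1 for a complete digraph
#'   at full strength).
#' @examples
#' tri <- decay_network(3, c(1, 2, 3), c(2, 3, 1))
#' global_efficiency(tri) # (3 * 1 + 3 * 0.5) / 6 = 0.75
#' @export
global_efficiency <- function(network, n_sources = NULL) {
  stopifnot(inherits(network, "decay_network"))
  if (network$n_nodes < 2L) {
    abort("Global efficiency needs at least 2 nodes.",
          class = "neurodecay_parameter_error")
  }
  w <- path_weights(network, sources = sample_sources(network, n_sources))
  eff <- 1 / w
  eff[!is.finite(w)] <- 0
  # mean over ordered pairs: each row has n_nodes - 1 valid targets
  sum(eff, na.rm = TRUE) / (nrow(w) * (network$n_nodes - 1))
}

sample_sources <- function(network, n_sources) {
  n <- network$n_nodes
  if (is.null(n_sources)) n_sources <- if (n <= 2000L) Inf else 500L
  if (!is.finite(n_sources) || n_sources >= n) return(NULL)
  withr::with_seed(n, sample.int(n, n_sources))
}

#' Histogram of best-path efficiencies
#'
#' Bins the best-path efficiency `1/w[i, j]` of every reachable ordered pair.
#' Bins are half-open `[lo, hi)` with the final bin closed. A healthy network
#' has a very large count of high-efficiency paths (structural plasticity:
#' many alternative routes); decay collapses the histogram toward few,
#' low-efficiency paths.
#'
#' @param network A `decay_network`.
#' @param bin_edges Increasing numeric vector of bin edges within `[0, 1]`;
#'   default 0 to 1 in steps of 0.05.
#' @param n_sources As in [global_efficiency()]; when sources are sampled,
#'   counts are scaled by `n/n_sources` to estimate the full-pair counts.
#' @return An `efficiency_histogram` tibble: `bin_lo`, `bin_hi`, `count`.
#' @export
efficiency_histogram <- function(network, bin_edges = seq(0, 1, by = 0.05),
                                 n_sources = NULL) {
  stopifnot(inherits(network, "decay_network"))
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.",
          class = "neurodecay_parameter_error")
  }
  src <- sample_sources(network, n_sources)
  w <- path_weights(network, sources = src)
  eff <- 1 / w[is.finite(w) & !is.na(w)]
  idx <- findInterval(eff, bin_edges, rightmost.closed = TRUE)
  idx <- idx[idx >= 1L & idx < length(bin_edges)]
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  scale <- if (is.null(src)) 1 else network$n_nodes / length(src)
  out <- tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    count = counts * scale
  )
  structure(out, n_pairs_reachable = length(eff) * scale,
            class = c("efficiency_histogram", class(tibble())))
}

#' Average clustering coefficient
#'
#' Mean local clustering coefficient over all nodes, computed on the
#' undirected projection of the functional edges; nodes of projected degree
#' below 2 contribute 0.
#'
#' @param network A `decay_network`.
#' @return Average clustering in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  stopifnot(inherits(network, "decay_network"))
  g <- as_igraph(network, functional_only = TRUE, weights = "none")
  u <- igraph::as_undirected(g, mode = "collapse")
  igraph::transitivity(u, type = "localaverage", isolates = "zero")
}

#' Average shortest path length
#'
#' Mean minimum path weight over reachable ordered pairs (i, j), i != j,
#' with link weights `1/eps`. With identical unit strengths this equals the
#' mean hop distance. Optionally restricted to pairs inside the LSCC.
#'
#' @param network A `decay_network`.
#' @param n_sources As in [global_efficiency()].
#' @param scope `"reachable"` (default): average over all reachable ordered
#'   pairs; `"lscc"`: average over ordered pairs within the largest strongly
#'   connected component.
#' @return Mean path length (positive), or `NA` if no ordered pair is
#'   reachable.
#' @export
average_path_length <- function(network, n_sources = NULL,
                                scope = c("reachable", "lscc")) {
  stopifnot(inherits(network, "decay_network"))
  scope <- match.arg(scope)
  if (scope == "lscc") {
    g <- as_igraph(network, functional_only = TRUE, weights = "resistance")
    comp <- igraph::components(g, mode = "strong")
    members <- which(comp$membership == which.max(comp$csize))
    if (length(members) < 2L) return(NA_real_)
    sub <- igraph::induced_subgraph(g, members)
    w <- igraph::distances(sub, mode = "out", weights = igraph::E(sub)$weight)
    diag(w) <- NA_real_
    return(mean(w, na.rm = TRUE))
  }
  w <- path_weights(network, sources = sample_sources(network, n_sources))
  vals <- w[is.finite(w) & !is.na(w)]
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Total coupling strength
#'
#' Sum of the current coupling strengths of all functional (non-removed)
#' links; the model quantity directly comparable to average spine density.
#'
#' @param network A `decay_network`.
#' @return Non-negative real.
#' @export
total_strength <- function(network) {
  stopifnot(inherits(network, "decay_network"))
  e <- network$edges
  sum(e$eps[e$state != STATE_REMOVED])
}
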