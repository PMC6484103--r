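# Directed weighted network container and generators.
#
# Edges carry an initial coupling strength eps0 in (0, 1], a current strength
# eps in [0, eps0], and a decay state: 0 = healthy, 1 = affected (decaying),
# 2 = removed (strength at or below eps0 / e, non-functional).

STATE_HEALTHY <- 0L
STATE_AFFECTED <- 1L
STATE_REMOVED <- 2L

state_labels <- c("healthy", "affected", "removed")

#' Construct a directed weighted network
#'
#' Low-level constructor for the network container used throughout the
#' package: `n_nodes` neurons and a set of directed links, each carrying an
#' initial coupling strength in `(0, 1]`. Fresh networks start with every
#' link healthy (current strength equal to the initial strength).
#'
#' @param n_nodes Number of nodes (positive integer).
#' @param from,to Integer vectors of tail and head node indices (1-based).
#' @param eps0 Initial coupling strengths in `(0, 1]`; recycled if length 1.
#' @param node_names Optional character vector of node labels, length
#'   `n_nodes`.
#'
#' @return A `decay_network` object: a list with `n_nodes`, an `edges` tibble
#'   (`from`, `to`, `eps0`, `eps`, `affected_at`, `state`) and the current
#'   simulation day `t`.
#' @export
decay_network <- function(n_nodes, from, to, eps0 = 1, node_names = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L) {
    abort("`n_nodes` must be a single positive integer.", class = "neurodecay_parameter_error")
  }
  from <- as.integer(from)
  to <- as.integer(to)
  if (length(from) != length(to)) {
    abort("`from` and `to` must have equal length.", class = "neurodecay_parameter_error")
  }
  eps0 <- rep_len(as.double(eps0), length(from))
  if (length(from) > 0L) {
    if (anyNA(from) || anyNA(to) || any(from < 1L) || any(to < 1L) ||
        any(from > n_nodes) || any(to > n_nodes)) {
      abort("Edge endpoints must lie in 1..n_nodes.", class = "neurodecay_parameter_error")
    }
    if (any(from == to)) {
      abort("Self-loops are not allowed.", class = "neurodecay_validation_error")
    }
    if (anyDuplicated(edge_key(from, to, n_nodes))) {
      abort("Duplicate edges are not allowed.", class = "neurodecay_validation_error")
    }
    if (any(!is.finite(eps0)) || any(eps0 <= 0) || any(eps0 > 1)) {
      abort("Initial strengths must lie in (0, 1].", class = "neurodecay_validation_error")
    }
  }
  structure(
    list(
      n_nodes = n_nodes,
      edges = tibble(
        from = from, to = to, eps0 = eps0, eps = eps0,
        affected_at = rep(NA_real_, length(from)),
        state = rep(STATE_HEALTHY, length(from))
      ),
      node_names = node_names,
      t = 0
    ),
    class = "decay_network"
  )
}

# unique numeric key per ordered pair; safe for n up to ~3e7
edge_key <- function(from, to, n) as.double(from) * (n + 1) + as.double(to)

#' @export
print.decay_network <- function(x, ...) {
  e <- x$edges
  n_func <- sum(e$state != STATE_REMOVED)
  cat(sprintf(
    "<decay_network> %d nodes, %d edges (%d functional) at day %s\n",
    x$n_nodes, nrow(e), n_func, format(x$t)
  ))
  counts <- tabulate(e$state + 1L, nbins = 3L)
  cat(sprintf(
    "  healthy: %d  affected: %d  removed: %d  total strength: %.4g\n",
    counts[1], counts[2], counts[3], sum(e$eps[e$state != STATE_REMOVED])
  ))
  invisible(x)
}

#' Edge table of a network
#'
#' @param network A `decay_network`.
#' @return A tibble with one row per edge: `from`, `to`, `eps0` (initial
#'   strength), `eps` (current strength), `affected_at` (day the link was
#'   affected, `NA` while healthy) and `state` (factor: healthy, affected,
#'   removed).
#' @export
edges <- function(network) {
  stopifnot(inherits(network, "decay_network"))
  dplyr::mutate(network$edges,
    state = factor(state_labels[.data$state + 1L], levels = state_labels)
  )
}

#' @export
as_tibble.decay_network <- function(x, ...) edges(x)

#' Convert to an igraph graph
#'
#' @param network A `decay_network`.
#' @param functional_only Drop removed edges (default `TRUE`).
#' @param weights One of `"none"`, `"strength"` (current coupling strength
#'   eps) or `"resistance"` (link weight 1/eps, the path-weight convention).
#' @return An igraph directed graph with `n_nodes` vertices.
#' @export
as_igraph <- function(network, functional_only = TRUE,
                      weights = c("none", "strength", "resistance")) {
  stopifnot(inherits(network, "decay_network"))
  weights <- match.arg(weights)
  e <- network$edges
  if (functional_only) e <- e[e$state != STATE_REMOVED, ]
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = TRUE)
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(g, rbind(e$from, e$to))
  }
  if (weights == "strength") igraph::E(g)$weight <- e$eps
  if (weights == "resistance") {
    if (any(e$eps <= 0)) {
      abort("Functional edge with non-positive strength.", class = "neurodecay_state_error")
    }
    igraph::E(g)$weight <- 1 / e$eps
  }
  g
}

# Frozen default rewiring probability for the directed small-world generator,
# calibrated once with calibrate_rewire_prob(1e4, 10, target_cc = 0.4, seed = 11):
# gives average clustering ~0.40 and mean path length ~5.3 at N = 1e4, k_out = 10.
DEFAULT_REWIRE_PROB <- 0.1758

#' Default calibrated rewiring probability
#'
#' The frozen output of [calibrate_rewire_prob()] at n = 1e4, k_out = 10,
#' target clustering 0.4.
#' @return A double.
#' @export
default_rewire_prob <- function() DEFAULT_REWIRE_PROB

#' Generate a directed small-world network
#'
#' Directed Watts-Strogatz construction: each node i sends links to its
#' `k_out` clockwise ring neighbours i+1, ..., i+k_out; each link's head is
#' then rewired, independently with probability `rewire_prob`, to a uniformly
#' chosen node (self-loops and duplicate edges are rejected and redrawn).
#' The edge count is exactly `n * k_out`. At the calibrated default
#' `rewire_prob` the n = 1e4, k_out = 10 network has average clustering
#' near 0.4 and mean shortest-path length near 5.5, the regime reported for
#' brain networks.
#'
#' @param n Number of nodes; must exceed `2 * k_out`.
#' @param k_out Out-degree of the initial ring lattice.
#' @param rewire_prob Head-rewiring probability in `[0, 1]`; default is the
#'   frozen calibrated value (see [calibrate_rewire_prob()]).
#' @param seed Optional integer seed for reproducible generation.
#' @return A fresh `decay_network` with unit initial strengths (use
#'   [assign_weights()] for non-uniform initial strengths).
#' @examples
#' net <- generate_small_world(100, 5, seed = 1)
#' nrow(edges(net)) # exactly 500
#' @export
generate_small_world <- function(n, k_out, rewire_prob = DEFAULT_REWIRE_PROB,
                                 seed = NULL) {
  n <- as.integer(n)
  k_out <- as.integer(k_out)
  if (is.na(n) || is.na(k_out) || k_out < 1L || n <= 2L * k_out) {
    abort("Require n > 2 * k_out and k_out >= 1.", class = "neurodecay_parameter_error")
  }
  if (!is.numeric(rewire_prob) || length(rewire_prob) != 1L ||
      is.na(rewire_prob) || rewire_prob < 0 || rewire_prob > 1) {
    abort("`rewire_prob` must be in [0, 1].", class = "neurodecay_parameter_error")
  }
  with_optional_seed(seed, {
    from <- rep(seq_len(n), each = k_out)
    to <- ((from - 1L + rep(seq_len(k_out), n)) %% n) + 1L
    rw <- which(runif(n * k_out) < rewire_prob)
    if (length(rw) > 0L) {
      keep <- setdiff(seq_along(from), rw)
      to[rw] <- sample.int(n, length(rw), replace = TRUE)
      # redraw rewired heads until no self-loop or duplicate edge remains;
      # kept lattice edges take precedence in duplicate detection
      repeat {
        keys <- edge_key(from, to, n)
        dup <- logical(length(from))
        dup[c(keep, rw)] <- duplicated(keys[c(keep, rw)])
        bad <- rw[to[rw] == from[rw] | dup[rw]]
        if (length(bad) == 0L) break
        to[bad] <- sample.int(n, length(bad), replace = TRUE)
      }
    }
    decay_network(n, from, to, eps0 = 1)
  })
}

#' Calibrate the small-world rewiring probability
#'
#' Bisection on the (monotonically decreasing) average clustering coefficient
#' of the generated network as a function of the rewiring probability, so the
#' fresh network matches a target clustering. Used once to fix the package's
#' default rewiring probability (target 0.4 at n = 1e4, k_out = 10).
#'
#' @param n,k_out Network size and out-degree used during calibration.
#' @param target_cc Target average clustering coefficient.
#' @param tol Absolute tolerance on the achieved clustering.
#' @param max_iter Maximum bisection iterations.
#' @param seed Integer seed (one network is generated per probe).
#' @return The calibrated rewiring probability (double).
#' @export
calibrate_rewire_prob <- function(n = 1e4, k_out = 10, target_cc = 0.4,
                                  tol = 0.005, max_iter = 25, seed = 1) {
  cc_at <- function(p, s) {
    clustering_coefficient(generate_small_world(n, k_out, p, seed = s))
  }
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cc <- cc_at(mid, seed + i)
    if (abs(cc - target_cc) < tol) return(mid)
    if (cc > target_cc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Specify the distribution of initial coupling strengths
#'
#' Three families are supported: `identical` (every link at full strength 1,
#' the healthy-reference convention), truncated `normal` with the stated mean
#' and standard deviation (values redrawn until they fall in (0, 1]), and
#' `lognormal` with `mu`/`sigma` the parameters of the underlying normal,
#' rescaled into (0, 1) by division by the realised maximum.
#'
#' @param kind One of `"identical"`, `"normal"`, `"lognormal"`.
#' @param mu,sigma Location and scale; ignored for `"identical"`.
#' @return A `weight_spec` list.
#' @examples
#' weight_spec("normal", mu = 0.7, sigma = 0.2)
#' @export
weight_spec <- function(kind = c("identical", "normal", "lognormal"),
                        mu = NULL, sigma = NULL) {
  kind <- match.arg(kind)
  if (kind != "identical") {
    if (!is.numeric(mu) || !is.numeric(sigma) || sigma < 0) {
      abort("`mu` and `sigma` (>= 0) are required for non-identical weights.",
            class = "neurodecay_parameter_error")
    }
    if (kind == "normal") {
      mass <- stats::pnorm(1, mu, sigma) - stats::pnorm(0, mu, sigma)
      if (sigma > 0 && mass < 1e-12) {
        abort("Normal weight spec has vanishing mass in (0, 1].",
              class = "neurodecay_parameter_error")
      }
      if (sigma == 0 && (mu <= 0 || mu > 1)) {
        abort("Degenerate normal weight spec must have mu in (0, 1].",
              class = "neurodecay_parameter_error")
      }
    }
  }
  structure(list(kind = kind, mu = mu, sigma = sigma), class = "weight_spec")
}

#' Assign initial coupling strengths
#'
#' Draws an initial strength for every edge according to a [weight_spec()]
#' and resets the network to a fresh (all-healthy) state.
#'
#' @param network A `decay_network`.
#' @param spec A [weight_spec()].
#' @param seed Optional integer seed.
#' @return The network with new `eps0` (and `eps = eps0`, all edges healthy).
#' @export
assign_weights <- function(network, spec, seed = NULL) {
  stopifnot(inherits(network, "decay_network"), inherits(spec, "weight_spec"))
  m <- nrow(network$edges)
  if (m < 1L) abort("Network has no edges.", class = "neurodecay_parameter_error")
  w <- with_optional_seed(seed, draw_weights(spec, m))
  network$edges$eps0 <- w
  network$edges$eps <- w
  network$edges$affected_at <- NA_real_
  network$edges$state <- rep(STATE_HEALTHY, m)
  network$t <- 0
  network
}

draw_weights <- function(spec, m) {
  switch(spec$kind,
    identical = rep(1, m),
    normal = {
      if (spec$sigma == 0) return(rep(spec$mu, m))
      w <- rnorm(m, spec$mu, spec$sigma)
      bad <- which(w <= 0 | w > 1)
      while (length(bad) > 0L) {
        w[bad] <- rnorm(length(bad), spec$mu, spec$sigma)
        bad <- bad[w[bad] <= 0 | w[bad] > 1]
      }
      w
    },
    lognormal = {
      w <- rlnorm(m, meanlog = spec$mu, sdlog = spec$sigma)
      w / max(w) * (1 - 1e-9)
    }
  )
}

#' Generate a dense connectome-like fixture network
#'
#' Synthetic stand-in for a mesoscopic whole-brain connectome (region-level
#' parcellation): a directed, weighted, very dense graph with strong
#' geometric locality, hence clustering well above the uniform-random
#' expectation and short paths. Nodes are placed on a ring and the `m`
#' ordered pairs are sampled without replacement with probability decaying
#' exponentially in ring distance (plus a small uniform floor providing
#' long-range shortcuts). Defaults elsewhere in the package use
#' n = 360, m = 43516, the density of region-level human connectomes.
#'
#' @param n Number of nodes.
#' @param m Number of directed edges; at most `n * (n - 1)`.
#' @param spec A [weight_spec()] for the initial strengths (default
#'   log-normal, the heavy-tailed shape typical of interaction strengths).
#' @param seed Optional integer seed.
#' @param locality Multiplier on the density-implied ring-distance scale of
#'   the connection kernel (1 = the halfwidth `m/(2n)` that matches the
#'   requested density).
#' @return A fresh `decay_network`.
#' @export
generate_connectome_fixture <- function(n = 360, m = 43516,
                                        spec = weight_spec("lognormal", mu = 0, sigma = 1),
                                        seed = NULL, locality = 1) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 2L || is.na(m) || m < 1L || m > n * (n - 1L)) {
    abort("Require 1 <= m <= n * (n - 1).", class = "neurodecay_parameter_error")
  }
  with_optional_seed(seed, {
    # sample unordered pairs under a ring-distance kernel and connect them
    # reciprocally: local cliques give the high clustering of real
    # parcellation networks, the uniform floor provides long-range shortcuts
    idx <- which(upper.tri(matrix(0L, n, n)))
    pi_ <- ((idx - 1L) %% n) + 1L
    pj_ <- ((idx - 1L) %/% n) + 1L
    d <- abs(pi_ - pj_)
    d <- pmin(d, n - d)
    # sharp kernel at the density-implied halfwidth: near-saturated local
    # neighbourhoods (high clustering) with a uniform floor of shortcuts
    halfwidth <- locality * max(1, m / (2 * n))
    kern <- exp(-(d / halfwidth)^6) + 0.002
    n_pairs <- m %/% 2L
    pick <- sample.int(length(idx), n_pairs, replace = FALSE, prob = kern)
    from <- c(pi_[pick], pj_[pick])
    to <- c(pj_[pick], pi_[pick])
    if (m %% 2L == 1L) {
      rest <- setdiff(seq_along(idx), pick)
      extra <- rest[sample.int(length(rest), 1L)]
      from <- c(from, pi_[extra])
      to <- c(to, pj_[extra])
    }
    net <- decay_network(n, from, to, eps0 = 1)
    assign_weights(net, spec)
  })
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) force(code)
  else withr::with_seed(as.integer(seed), code)
}
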