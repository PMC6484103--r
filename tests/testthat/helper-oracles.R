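# Brute-force oracles and tiny network builders, independent of the package's
# igraph-backed code paths.

# ---- builders ----------------------------------------------------------

net_cycle <- function(n, eps0 = 1) {
  decay_network(n, seq_len(n), c(seq_len(n)[-1], 1L), eps0 = eps0)
}

net_complete <- function(n) {
  from <- rep(seq_len(n), each = n - 1L)
  to <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)))
  decay_network(n, from, to)
}

# uniformly random simple directed graph with m edges, weights in (0, 1]
net_random <- function(n, m, seed, unit_weights = FALSE) {
  withr::with_seed(seed, {
    pairs <- which(matrix(TRUE, n, n) & !diag(n) > 0)
    all_from <- ((pairs - 1L) %% n) + 1L
    all_to <- ((pairs - 1L) %/% n) + 1L
    pick <- sample.int(length(pairs), m)
    w <- if (unit_weights) 1 else runif(m, 0.05, 1)
    decay_network(n, all_from[pick], all_to[pick], eps0 = w)
  })
}

adjacency_of <- function(net, weighted = FALSE) {
  n <- net$n_nodes
  e <- net$edges
  keep <- e$state != 2L
  a <- matrix(if (weighted) Inf else FALSE, n, n)
  if (weighted) {
    a[cbind(e$from[keep], e$to[keep])] <- 1 / e$eps[keep]
  } else {
    a[cbind(e$from[keep], e$to[keep])] <- TRUE
  }
  a
}

# ---- oracles -----------------------------------------------------------

# all-pairs minimum path weights by Floyd-Warshall on link weights 1/eps
oracle_path_weights <- function(net) {
  d <- adjacency_of(net, weighted = TRUE)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  diag(d) <- NA_real_
  d
}

# largest-SCC fraction from the reachability closure (boolean matrix powers)
oracle_lscc_fraction <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  reach <- a | diag(n) > 0
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  comp_sizes <- integer(0)
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(mutual[i, ])
    seen[members] <- TRUE
    comp_sizes <- c(comp_sizes, length(members))
  }
  max(comp_sizes) / n
}

oracle_global_efficiency <- function(net) {
  w <- oracle_path_weights(net)
  eff <- 1 / w
  eff[!is.finite(w)] <- 0
  sum(eff, na.rm = TRUE) / (nrow(w) * (nrow(w) - 1))
}

# average local clustering by O(n^3) triangle counting on the undirected
# projection of functional edges
oracle_clustering <- function(net) {
  a <- adjacency_of(net)
  u <- a | t(a)
  n <- nrow(u)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(u[i, ])
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (x in nb) for (y in nb) if (x < y && u[x, y]) links <- links + 1
    local[i] <- 2 * links / (k * (k - 1))
  }
  mean(local)
}

# day grid on which an edge affected at t_a is removed: strength first at or
# below eps0/e
oracle_removal_day <- function(t_a, tau, dt = 1) {
  t <- t_a
  repeat {
    t <- t + dt
    if (exp(-(t - t_a) / tau) <= exp(-1)) return(t)
  }
}
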