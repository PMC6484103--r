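# Network observables against enumeration and brute-force oracles.

test_that("LSCC fraction matches hand-computable cases", {
  expect_equal(lscc_fraction(net_complete(6)), 1)
  # disjoint 5-cycle and 3-cycle on 8 nodes
  two_cycles <- decay_network(8, c(1, 2, 3, 4, 5, 6, 7, 8),
                              c(2, 3, 4, 5, 1, 7, 8, 6))
  expect_equal(lscc_fraction(two_cycles), 0.625)
  expect_equal(oracle_lscc_fraction(two_cycles), 0.625)
  # a DAG has only singleton SCCs
  dag <- decay_network(5, c(1, 1, 2, 3), c(2, 3, 4, 4))
  expect_equal(lscc_fraction(dag), 1 / 5)
})

test_that("path weights follow the additive minimum-weight rule", {
  pair <- decay_network(2, c(1, 2), c(2, 1))
  w <- path_weights(pair)
  expect_equal(w[1, 2], 1)
  expect_equal(w[2, 1], 1)
  tri <- net_cycle(3)
  w3 <- path_weights(tri)
  expect_equal(w3[1, 2], 1)
  expect_equal(w3[1, 3], 2)
  chain <- decay_network(3, c(1, 2), c(2, 3), eps0 = c(0.5, 0.25))
  expect_equal(path_weights(chain)[1, 3], 2 + 4)
  expect_true(is.infinite(path_weights(chain)[3, 1]))
})

test_that("global efficiency and path length match enumerated small cases", {
  pair <- decay_network(2, c(1, 2), c(2, 1))
  expect_equal(global_efficiency(pair), 1)
  tri <- net_cycle(3)
  expect_equal(global_efficiency(tri), (3 * 1 + 3 * 0.5) / 6)
  expect_equal(average_path_length(tri), mean(c(1, 1, 1, 2, 2, 2)))
  expect_equal(average_path_length(net_complete(5)), 1)
  # no functional edges: efficiency zero, path length undefined
  dead <- net_cycle(4)
  dead$edges$state <- rep(2L, 4)
  expect_equal(global_efficiency(dead), 0)
  expect_true(is.na(average_path_length(dead)))
  expect_error(global_efficiency(decay_network(1, integer(0), integer(0))),
               class = "neurodecay_parameter_error")
})

test_that("LSCC, efficiency and path weights agree with brute-force oracles", {
  for (i in 1:200) {
    n <- sample(5:40, 1)
    m <- sample(n:min(3 * n, n * (n - 1)), 1)
    net <- net_random(n, m, seed = i)
    # knock out a random subset to exercise the functional-edge filter
    withr::with_seed(i, {
      out <- sample(c(TRUE, FALSE), m, replace = TRUE, prob = c(0.2, 0.8))
    })
    net$edges$state[out] <- 2L
    expect_equal(lscc_fraction(net), oracle_lscc_fraction(net), tolerance = 1e-10)
    expect_equal(global_efficiency(net), oracle_global_efficiency(net),
                 tolerance = 1e-10)
    w <- path_weights(net)
    wo <- oracle_path_weights(net)
    w[!is.finite(w)] <- -1; wo[!is.finite(wo)] <- -1
    expect_equal(w, wo, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("clustering matches triangle-counting oracle and known graphs", {
  # undirected-complete triangle: all 6 directed edges
  expect_equal(clustering_coefficient(net_complete(3)), 1)
  star <- decay_network(5, c(1, 1, 1, 1), c(2, 3, 4, 5))
  expect_equal(clustering_coefficient(star), 0)
  net <- net_random(50, 400, seed = 77)
  expect_equal(clustering_coefficient(net), oracle_clustering(net),
               tolerance = 1e-12)
})

test_that("global efficiency is relabeling-invariant and scales linearly with strengths", {
  net <- net_random(25, 80, seed = 3)
  ge <- global_efficiency(net)
  perm <- withr::with_seed(4, sample.int(25))
  relabeled <- decay_network(25, perm[net$edges$from], perm[net$edges$to],
                             eps0 = net$edges$eps0)
  expect_equal(global_efficiency(relabeled), ge, tolerance = 1e-12)
  for (c_scale in c(0.25, 0.8)) {
    scaled <- net
    scaled$edges$eps0 <- net$edges$eps0 * c_scale
    scaled$edges$eps <- net$edges$eps * c_scale
    expect_equal(global_efficiency(scaled), ge * c_scale, tolerance = 1e-12)
    expect_equal(path_weights(scaled), path_weights(net) / c_scale,
                 tolerance = 1e-12)
  }
})

test_that("unit-strength path length equals mean hop distance", {
  net <- net_random(40, 200, seed = 9, unit_weights = TRUE)
  g <- as_igraph(net)
  hops <- igraph::distances(g, mode = "out")
  diag(hops) <- NA
  expect_equal(average_path_length(net),
               mean(hops[is.finite(hops) & !is.na(hops)]))
})

test_that("efficiency histogram bins reachable pairs with half-open bins", {
  tri <- net_cycle(3)
  h <- efficiency_histogram(tri, bin_edges = c(0, 0.5, 1))
  # efficiencies: three pairs at 1, three at 0.5; 0.5 falls in [0.5, 1]
  expect_equal(h$count, c(0, 6))
  expect_equal(sum(h$count), attr(h, "n_pairs_reachable"))
  dead <- net_cycle(4)
  dead$edges$state <- rep(2L, 4)
  expect_true(all(efficiency_histogram(dead)$count == 0))
  net <- net_random(30, 120, seed = 12)
  h2 <- efficiency_histogram(net)
  w <- path_weights(net)
  expect_equal(sum(h2$count), sum(is.finite(w) & !is.na(w)))
  expect_error(efficiency_histogram(tri, bin_edges = c(0.5, 0.2)),
               class = "neurodecay_parameter_error")
})

test_that("total strength sums functional strengths and tracks closed-form decay", {
  net <- net_cycle(12)
  expect_equal(total_strength(net), 12)
  tr <- run_decay(net, decay_params(p0 = 1, p1 = 0, tau = 25, horizon = 60,
                                    removal_fraction = 0, seed = 2))
  expect_equal(tr$total_strength, 12 * exp(-tr$t / 25), tolerance = 1e-12)
  gone <- net_cycle(12)
  gone$edges$state <- rep(2L, 12)
  expect_equal(total_strength(gone), 0)
})

test_that("LSCC-scoped path length is computable and at least the direct-link minimum", {
  net <- net_random(30, 150, seed = 21)
  apl_lscc <- average_path_length(net, scope = "lscc")
  expect_gte(apl_lscc, min(1 / net$edges$eps))
})
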