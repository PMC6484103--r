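# The affection / decay / removal process.

test_that("an affected link is removed exactly tau days after affection", {
  for (tau in c(20, 25, 30, 35, 40)) {
    net <- net_cycle(8)
    params <- decay_params(p0 = 1, p1 = 0, tau = tau, horizon = tau + 5)
    tr <- withr::with_seed(1, run_decay(net, params))
    expect_identical(tr$n_removed[tr$t == tau - 1], 0L)
    expect_identical(tr$n_removed[tr$t == tau], 8L)
    expect_equal(oracle_removal_day(0, tau), tau)
  }
})

test_that("certain affection hits every edge in one step", {
  net <- net_cycle(10)
  net <- withr::with_seed(1, decay_step(net, 0, decay_params(p0 = 1, p1 = 0)))
  expect_true(all(net$edges$state == 1L))
  expect_true(all(net$edges$affected_at == 0))
  expect_identical(attr(net, "events")$n_newly_affected, 10L)
})

test_that("newly affected counts match the binomial expectation", {
  h <- 2000L
  net <- generate_small_world(500, 4, seed = 5)
  params <- decay_params(p0 = 0.01, p1 = 1e-4)
  t <- 50
  p <- params$p0 + params$p1 * t
  counts <- withr::with_seed(99, vapply(seq_len(200), function(i) {
    attr(decay_step(net, t, params), "events")$n_newly_affected
  }, integer(1)))
  se_mean <- sqrt(h * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - h * p), 3 * se_mean)
})

test_that("with removal disabled total strength decays by the closed form", {
  net <- net_cycle(40)
  params <- decay_params(p0 = 1, p1 = 0, tau = 30, horizon = 100,
                         removal_fraction = 0, seed = 3)
  tr <- run_decay(net, params)
  expect_equal(tr$total_strength, 40 * exp(-tr$t / 30), tolerance = 1e-12)
})

test_that("without affection the trace is constant", {
  net <- generate_small_world(100, 4, seed = 6)
  tr <- run_decay(net, decay_params(p0 = 0, p1 = 0, horizon = 30, seed = 1),
                  metrics = "global_efficiency")
  expect_true(all(tr$f_lscc == tr$f_lscc[1]))
  expect_true(all(tr$total_strength == tr$total_strength[1]))
  ge <- tr$global_efficiency[!is.na(tr$global_efficiency)]
  expect_true(all(ge == ge[1]))
  expect_true(all(tr$n_removed == 0L))
})

test_that("f, global efficiency and total strength are non-increasing in time", {
  net <- generate_small_world(300, 5, seed = 7)
  tr <- run_decay(net, decay_params(tau = 25, horizon = 160, seed = 8,
                                    metric_cadence = 5),
                  metrics = "global_efficiency")
  expect_true(all(diff(tr$f_lscc) <= 1e-12))
  expect_true(all(diff(tr$total_strength) <= 1e-9))
  ge <- tr$global_efficiency[!is.na(tr$global_efficiency)]
  expect_true(all(diff(ge) <= 1e-9))
  expect_true(all(tr$n_healthy + tr$n_affected + tr$n_removed == 1500L))
})

test_that("edge states only ever move forward (healthy -> affected -> removed)", {
  net <- net_cycle(30)
  params <- decay_params(p0 = 0.05, p1 = 1e-3, tau = 20)
  prev <- net$edges$state
  withr::with_seed(11, {
    for (t in 0:80) {
      net <- decay_step(net, t, params)
      expect_true(all(net$edges$state >= prev))
      prev <- net$edges$state
    }
  })
  expect_true(all(net$edges$state == 2L))
})

test_that("ever-affected fraction follows the cumulative affection probability", {
  n_edges <- 500L
  t_check <- 40
  params <- decay_params(p0 = 0.01, p1 = 1e-4, tau = 30, horizon = t_check)
  p_ever <- 1 - prod(1 - pmin(1, params$p0 + params$p1 * (0:t_check)))
  fracs <- vapply(seq_len(50), function(i) {
    net <- net_cycle(n_edges)
    p <- params; p$seed <- 2000 + i
    tr <- run_decay(net, p)
    1 - tr$n_healthy[nrow(tr)] / n_edges
  }, numeric(1))
  se <- sqrt(p_ever * (1 - p_ever) / (n_edges * 50))
  expect_lt(abs(mean(fracs) - p_ever), 3 * se)
})

test_that("ensembles are reproducible and a single realization equals its run", {
  params <- decay_params(tau = 30, horizon = 50)
  e1 <- run_ensemble(80, 3, params, n_realizations = 1, base_seed = 5)
  expect_equal(as.data.frame(e1$mean[names(e1$traces[[1]])]),
               as.data.frame(e1$traces[[1]]))
  e2 <- run_ensemble(80, 3, params, n_realizations = 3, base_seed = 5)
  e3 <- run_ensemble(80, 3, params, n_realizations = 3, base_seed = 5)
  expect_identical(e2$mean, e3$mean)
  expect_false(identical(e2$traces[[1]]$f_lscc, e2$traces[[2]]$f_lscc) &&
               identical(e2$traces[[1]]$total_strength, e2$traces[[2]]$total_strength))
})

test_that("tau calibration inverts the exponential decay", {
  for (tau0 in c(5, 21, 60)) {
    expect_equal(calibrate_tau(exp(-1), tau0), tau0, tolerance = 1e-12)
  }
  expect_equal(calibrate_tau(0.5, 21), 21 / log(2), tolerance = 1e-12)
  expect_gt(calibrate_tau(0.5, 21), 20)
  expect_lt(calibrate_tau(0.5, 21), 40)
  expect_error(calibrate_tau(1.2, 21), class = "neurodecay_parameter_error")
  expect_error(calibrate_tau(0.5, -1), class = "neurodecay_parameter_error")
})

test_that("negative time and bad parameters are rejected", {
  net <- net_cycle(5)
  expect_error(decay_step(net, -1, decay_params()),
               class = "neurodecay_parameter_error")
  expect_error(decay_params(p0 = 2), class = "neurodecay_parameter_error")
  expect_error(decay_params(tau = 0), class = "neurodecay_parameter_error")
  expect_error(decay_params(horizon = 0.5, dt = 1),
               class = "neurodecay_parameter_error")
})
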