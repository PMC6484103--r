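# The degeneration process: per-day stochastic affection of links, exponential
# strength decay with timescale tau, removal at 1/e of the initial strength.

#' Decay process parameters
#'
#' The per-day probability that a healthy link is affected is
#' `p(t) = min(1, p0 + p1 * t)`. An affected link's strength decays as
#' `eps0 * exp(-(t - t_a) / tau)` from its affection day `t_a`, and the link
#' is removed (non-functional) once the strength is at or below
#' `removal_fraction * eps0` (default `1/e`, so removal falls exactly at
#' `t_a + tau`).
#'
#' @param p0 Initial per-day affection probability (default 0.01, the
#'   mouse-culture scenario).
#' @param p1 Per-day increment of the affection probability (default 1e-4);
#'   nets out loss and repair, with loss dominating.
#' @param tau Decay timescale in days (default 30; the 50%-spine-loss-in-3-
#'   weeks observation calibrates tau to the 20-40 day range, see
#'   [calibrate_tau()]).
#' @param dt Time step in days (default 1; one step is one day).
#' @param horizon Last simulated day.
#' @param seed Optional integer seed used by [run_decay()].
#' @param metric_cadence Days between evaluations of the expensive metrics
#'   (weighted shortest paths, clustering) in [run_decay()]; cheap quantities
#'   (LSCC fraction, strengths, state counts) are recorded every step.
#' @param removal_fraction Fraction of the initial strength at which a link
#'   is removed; `0` disables removal (links decay but stay functional).
#' @return A `decay_params` list.
#' @examples
#' decay_params(p0 = 0.01, p1 = 1e-4, tau = 30, horizon = 200)
#' @export
decay_params <- function(p0 = 0.01, p1 = 1e-4, tau = 30, dt = 1,
                         horizon = 250, seed = NULL, metric_cadence = 5,
                         removal_fraction = exp(-1)) {
  if (!is.numeric(p0) || p0 < 0 || p0 > 1) {
    abort("`p0` must be a probability in [0, 1].", class = "neurodecay_parameter_error")
  }
  if (!is.numeric(p1) || p1 < 0) {
    abort("`p1` must be non-negative.", class = "neurodecay_parameter_error")
  }
  if (!is.numeric(tau) || tau <= 0) {
    abort("`tau` must be positive.", class = "neurodecay_parameter_error")
  }
  if (!is.numeric(dt) || dt <= 0 || !is.numeric(horizon) || horizon < dt) {
    abort("Require dt > 0 and horizon >= dt.", class = "neurodecay_parameter_error")
  }
  if (!is.numeric(metric_cadence) || metric_cadence < 1) {
    abort("`metric_cadence` must be a positive number of days.",
          class = "neurodecay_parameter_error")
  }
  if (!is.numeric(removal_fraction) || removal_fraction < 0 || removal_fraction >= 1) {
    abort("`removal_fraction` must be in [0, 1).", class = "neurodecay_parameter_error")
  }
  structure(
    list(p0 = p0, p1 = p1, tau = tau, dt = dt, horizon = horizon,
         seed = seed, metric_cadence = metric_cadence,
         removal_fraction = removal_fraction),
    class = "decay_params"
  )
}

#' Advance the decay process by one step
#'
#' At day `t`, every healthy link independently becomes affected with
#' probability `min(1, p0 + p1 * t)`; every affected link's current strength
#' is set to `eps0 * exp(-(t - t_a) / tau)`; links whose strength has fallen
#' to `removal_fraction * eps0` (default `1/e`) or below become removed.
#' Uses the current R random number stream (seed handling is done by the
#' callers, [run_decay()] and [run_ensemble()]).
#'
#' @param network A `decay_network`.
#' @param t Current day (non-negative).
#' @param params A [decay_params()].
#' @return The updated network (with `$t` set to `t`); the event summary of
#'   the step is attached as attribute `"events"` (`n_newly_affected`,
#'   `n_newly_removed`).
#' @export
decay_step <- function(network, t, params) {
  stopifnot(inherits(network, "decay_network"), inherits(params, "decay_params"))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    abort("`t` must be a single non-negative day.", class = "neurodecay_parameter_error")
  }
  e <- network$edges
  state <- e$state
  healthy <- state == STATE_HEALTHY
  p <- min(1, params$p0 + params$p1 * t)
  hit <- healthy & (runif(nrow(e)) < p)
  e$affected_at[hit] <- t
  state[hit] <- STATE_AFFECTED
  affected <- state == STATE_AFFECTED
  # recompute from eps0 and elapsed time (no cumulative multiplication drift)
  e$eps[affected] <- e$eps0[affected] *
    exp(-(t - e$affected_at[affected]) / params$tau)
  removed_now <- affected &
    params$removal_fraction > 0 &
    e$eps <= e$eps0 * params$removal_fraction
  state[removed_now] <- STATE_REMOVED
  e$state <- state
  network$edges <- e
  network$t <- t
  attr(network, "events") <- list(
    n_newly_affected = sum(hit),
    n_newly_removed = sum(removed_now)
  )
  network
}

#' Run the decay process on a network
#'
#' Iterates [decay_step()] from day 0 to the horizon, recording a time series
#' of network observables. The LSCC fraction, total coupling strength and
#' edge-state counts are recorded every step; weighted global efficiency,
#' clustering and mean path length (when requested via `metrics`) every
#' `metric_cadence` days. The run stops early only when no functional edge
#' remains, after which every recorded quantity is constant.
#'
#' @param network A fresh or partially decayed `decay_network`.
#' @param params A [decay_params()]; `params$seed`, when set, makes the run
#'   reproducible.
#' @param metrics Character vector of additional per-cadence metrics among
#'   `"global_efficiency"`, `"clustering"`, `"path_length"`.
#' @param n_sources Number of sampled source nodes for the weighted
#'   shortest-path metrics on large networks; `NULL` (default) computes them
#'   exactly for networks up to 2000 nodes and samples 500 sources above.
#' @return A `decay_trace`: a tibble with columns `t`, `f_lscc`,
#'   `total_strength`, `n_healthy`, `n_affected`, `n_removed` and, where
#'   requested, `global_efficiency`, `clustering`, `path_length` (`NA`
#'   off-cadence). Attributes: `n_nodes`, `params`.
#' @examples
#' net <- generate_small_world(200, 5, seed = 1)
#' tr <- run_decay(net, decay_params(tau = 30, horizon = 60, seed = 2))
#' head(tr)
#' @export
run_decay <- function(network, params, metrics = character(), n_sources = NULL) {
  stopifnot(inherits(network, "decay_network"), inherits(params, "decay_params"))
  bad <- setdiff(metrics, c("global_efficiency", "clustering", "path_length"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown metrics: ", paste(bad, collapse = ", ")),
          class = "neurodecay_parameter_error")
  }
  with_optional_seed(params$seed, {
    days <- seq(0, params$horizon, by = params$dt)
    n_rec <- length(days)
    rec <- list(
      t = days,
      f_lscc = rep(NA_real_, n_rec),
      global_efficiency = rep(NA_real_, n_rec),
      total_strength = rep(NA_real_, n_rec),
      clustering = rep(NA_real_, n_rec),
      path_length = rep(NA_real_, n_rec),
      n_healthy = rep(NA_integer_, n_rec),
      n_affected = rep(NA_integer_, n_rec),
      n_removed = rep(NA_integer_, n_rec)
    )
    last <- n_rec
    for (i in seq_len(n_rec)) {
      t <- days[i]
      network <- decay_step(network, t, params)
      st <- network$edges$state
      functional <- st != STATE_REMOVED
      rec$n_healthy[i] <- sum(st == STATE_HEALTHY)
      rec$n_affected[i] <- sum(st == STATE_AFFECTED)
      rec$n_removed[i] <- sum(st == STATE_REMOVED)
      rec$total_strength[i] <- sum(network$edges$eps[functional])
      rec$f_lscc[i] <- lscc_fraction(network)
      on_cadence <- (t %% params$metric_cadence) == 0 || i == n_rec
      if (on_cadence && length(metrics) > 0L) {
        if ("global_efficiency" %in% metrics) {
          rec$global_efficiency[i] <- global_efficiency(network, n_sources = n_sources)
        }
        if ("clustering" %in% metrics) {
          rec$clustering[i] <- clustering_coefficient(network)
        }
        if ("path_length" %in% metrics) {
          rec$path_length[i] <- average_path_length(network, n_sources = n_sources)
        }
      }
      if (!any(functional)) { last <- i; break }
    }
    keep_cols <- c("t", "f_lscc",
                   intersect(c("global_efficiency"), metrics),
                   "total_strength",
                   intersect(c("clustering", "path_length"), metrics),
                   "n_healthy", "n_affected", "n_removed")
    out <- as_tibble(rec[keep_cols])[seq_len(last), ]
    new_decay_trace(out, n_nodes = network$n_nodes, params = params)
  })
}

new_decay_trace <- function(x, n_nodes, params) {
  structure(x,
    n_nodes = n_nodes, params = params,
    class = c("decay_trace", class(tibble())))
}

#' Number of nodes recorded with a trace or ensemble
#' @param x A `decay_trace` or `decay_ensemble`.
#' @return Integer node count.
#' @export
n_nodes <- function(x) {
  n <- attr(x, "n_nodes")
  if (is.null(n) && inherits(x, "decay_ensemble")) n <- x$n_nodes
  n
}

#' Run an ensemble of decay realizations
#'
#' Repeats the generate-then-decay experiment over independently seeded
#' realizations and averages the recorded metrics pointwise on the common
#' day grid. Realization seeds are derived reproducibly from `base_seed`.
#' Traces that stopped early (no functional edges left) are padded with
#' their exact constant continuation before averaging.
#'
#' @param n,k_out,rewire_prob Small-world generator arguments (see
#'   [generate_small_world()]); ignored when `network` is supplied.
#' @param params A [decay_params()] (its `seed` field is ignored here).
#' @param n_realizations Number of realizations (such curves are
#'   conventionally averaged over ~100 realizations; fewer suffice at large N).
#' @param base_seed Integer seed from which per-realization network and
#'   decay seeds are derived.
#' @param w_spec A [weight_spec()] for initial strengths.
#' @param network Optional fixed `decay_network` used for every realization
#'   (only the decay process then varies), e.g. a connectome.
#' @param metrics,n_sources Passed to [run_decay()].
#' @return A `decay_ensemble` object: list with `mean` (tibble of pointwise
#'   means, plus `f_lscc_sd`), `traces` (list of `decay_trace`), `n_nodes`,
#'   `n_realizations`, `params`.
#' @export
run_ensemble <- function(n, k_out, params, n_realizations,
                         base_seed = 1, rewire_prob = DEFAULT_REWIRE_PROB,
                         w_spec = weight_spec("identical"),
                         network = NULL, metrics = character(),
                         n_sources = NULL) {
  if (!is.numeric(n_realizations) || n_realizations < 1) {
    abort("`n_realizations` must be >= 1.", class = "neurodecay_parameter_error")
  }
  seeds <- derive_seeds(base_seed, n_realizations)
  traces <- purrr::map(seq_len(n_realizations), function(i) {
    net <- if (is.null(network)) {
      w_net <- generate_small_world(n, k_out, rewire_prob, seed = seeds$network[i])
      if (w_spec$kind == "identical") w_net
      else assign_weights(w_net, w_spec, seed = seeds$weights[i])
    } else {
      network
    }
    p <- params
    p$seed <- seeds$decay[i]
    run_decay(net, p, metrics = metrics, n_sources = n_sources)
  })
  nn <- if (is.null(network)) as.integer(n) else network$n_nodes
  mean_tr <- average_traces(traces, nn)
  structure(
    list(mean = mean_tr, traces = traces, n_nodes = nn,
         n_realizations = n_realizations, params = params,
         base_seed = base_seed),
    class = "decay_ensemble"
  )
}

# Reproducible per-realization seeds: three independent streams drawn from a
# generator seeded with base_seed; values stay below 2^31.
derive_seeds <- function(base_seed, n) {
  withr::with_seed(as.integer(base_seed), {
    list(
      network = sample.int(.Machine$integer.max - 1L, n),
      weights = sample.int(.Machine$integer.max - 1L, n),
      decay = sample.int(.Machine$integer.max - 1L, n)
    )
  })
}

average_traces <- function(traces, n_nodes) {
  grid <- traces[[which.max(purrr::map_int(traces, nrow))]]$t
  cols <- setdiff(names(traces[[1]]), "t")
  padded <- purrr::map(traces, function(tr) {
    extra <- length(grid) - nrow(tr)
    if (extra <= 0L) return(tr)
    pad <- tr[rep(nrow(tr), extra), ]
    pad$t <- grid[(nrow(tr) + 1):length(grid)]
    # after full removal the continuation is exactly constant
    dplyr::bind_rows(tr, pad)
  })
  out <- tibble(t = grid)
  for (cl in cols) {
    m <- vapply(padded, function(tr) tr[[cl]], numeric(length(grid)))
    m <- matrix(m, nrow = length(grid))
    out[[cl]] <- rowMeans(m)
  }
  fmat <- matrix(vapply(padded, function(tr) tr$f_lscc, numeric(length(grid))),
                 nrow = length(grid))
  out$f_lscc_sd <- apply(fmat, 1, stats::sd)
  new_decay_trace(out, n_nodes = n_nodes, params = attr(traces[[1]], "params"))
}

#' @export
print.decay_ensemble <- function(x, ...) {
  cat(sprintf(
    "<decay_ensemble> %d realizations, %d nodes, %d recorded days\n",
    x$n_realizations, x$n_nodes, nrow(x$mean)
  ))
  print(head(x$mean, 5))
  invisible(x)
}

#' Calibrate the decay timescale from an observed strength loss
#'
#' Inverts `exp(-duration / tau) = remaining_fraction`: the timescale that
#' makes a single affected link retain `remaining_fraction` of its strength
#' after `duration` days. The experimental anchor — spine density halved in
#' three weeks — gives `calibrate_tau(0.5, 21)` = 21/ln 2 of about 30.3 days,
#' inside the 20-40 day range used for the mouse scenario.
#'
#' @param remaining_fraction Fraction of initial strength remaining, in (0, 1).
#' @param duration Elapsed time in days (positive).
#' @return The timescale tau in days.
#' @examples
#' calibrate_tau(0.5, 21) # ~30.3 days
#' @export
calibrate_tau <- function(remaining_fraction, duration) {
  if (!is.numeric(remaining_fraction) || remaining_fraction <= 0 ||
      remaining_fraction >= 1) {
    abort("`remaining_fraction` must lie in (0, 1).",
          class = "neurodecay_parameter_error")
  }
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive.", class = "neurodecay_parameter_error")
  }
  -duration / log(remaining_fraction)
}
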