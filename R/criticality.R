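# Critical breakdown time: near the transition the LSCC fraction follows a
# power law f = a * (Tc - T)^beta for T < Tc. Tc and beta are chosen on a
# grid by maximising the R^2 of the through-origin linear regression of f on
# (Tc - T)^beta over a window of near-critical points, and the per-size Tc
# estimates are extrapolated to infinite network size against 1/N.

#' First day the LSCC fraction falls to a threshold
#'
#' The critical time is defined operationally as the day beyond which the
#' LSCC ceases to exist; the default threshold `2/N` (component reduced to at
#' most two nodes) marks complete breakdown.
#'
#' @param trace A `decay_trace` (or any data frame with `t` and `f_lscc`).
#' @param threshold Breakdown threshold in (0, 1); default `2/N` using the
#'   trace's recorded node count.
#' @return First day with `f_lscc <= threshold`, or `NA` if never reached.
#' @export
breakdown_day <- function(trace, threshold = NULL) {
  if (inherits(trace, "decay_ensemble")) trace <- trace$mean
  f <- trace$f_lscc
  if (is.null(f)) abort("`trace` must have an `f_lscc` column.",
                        class = "neurodecay_parameter_error")
  if (is.null(threshold)) {
    nn <- n_nodes(trace)
    if (is.null(nn)) abort("Supply `threshold` for traces without a node count.",
                           class = "neurodecay_parameter_error")
    threshold <- 2 / nn
  }
  hit <- which(f <= threshold)
  if (length(hit) == 0L) return(NA_real_)
  trace$t[hit[1]]
}

#' Fit the critical time and scaling exponent
#'
#' Grid search over candidate critical times and exponents: for each
#' `(Tc, beta)` the trace points inside the near-critical window (by default
#' `0.01 <= f <= 0.3`) with `T < Tc` are regressed through the origin,
#' `f = a * (Tc - T)^beta`, and the candidate with maximum R^2 is selected.
#' A multiplicative prefactor `a` is fitted because a pure power law cannot
#' match the scale of f; R^2 is computed against the window mean and clamped
#' to `[0, 1]`.
#'
#' @param trace A `decay_trace` or ensemble-mean trace (fits are meant
#'   for ensemble means, not single noisy runs).
#' @param tc_grid Candidate critical days; default integer days from 30 days
#'   before to 10 days after the observed breakdown day.
#' @param beta_grid Candidate exponents; 1 (the mean-field percolation value)
#'   is always included.
#' @param window Length-2 numeric `(f_min, f_max)` selecting the
#'   near-critical points used in the fit.
#' @param min_points Minimum number of usable points (default 5).
#' @return A `critical_fit`: list with `tc`, `beta`, `prefactor`,
#'   `r_squared`, `n_nodes`, `window`, `n_points` and the full `grid` of
#'   candidates. Methods: [tidy()], [glance()].
#' @examples
#' tr <- tibble::tibble(t = 0:129, f_lscc = pmax(0.002 * (130 - 0:129), 0))
#' fit <- fit_tc(tr, tc_grid = 120:140)
#' fit$tc   # 130
#' fit$beta # 1
#' @export
fit_tc <- function(trace, tc_grid = NULL, beta_grid = c(0.5, 1, 1.5, 2),
                   window = c(0.01, 0.3), min_points = 5) {
  if (inherits(trace, "decay_ensemble")) trace <- trace$mean
  f <- trace$f_lscc
  t <- trace$t
  if (is.null(f) || is.null(t)) {
    abort("`trace` must have `t` and `f_lscc` columns.",
          class = "neurodecay_parameter_error")
  }
  beta_grid <- sort(unique(c(1, beta_grid)))
  nn <- n_nodes(trace)
  if (is.null(tc_grid)) {
    bd <- breakdown_day(trace,
                        threshold = if (is.null(nn)) min(f, na.rm = TRUE) else NULL)
    if (!is.na(bd) && min(f, na.rm = TRUE) > window[2]) bd <- NA
    if (is.na(bd)) {
      abort("Trace never breaks down; cannot locate the transition.",
            class = "neurodecay_no_transition_error")
    }
    tc_grid <- seq(max(1, floor(bd) - 30), floor(bd) + 10)
  }
  if (length(tc_grid) == 0L || length(beta_grid) == 0L) {
    abort("Grids must be non-empty.", class = "neurodecay_parameter_error")
  }
  if (!any(f <= window[1], na.rm = TRUE)) {
    abort("Trace never breaks down; cannot locate the transition.",
          class = "neurodecay_no_transition_error")
  }
  in_window <- !is.na(f) & f >= window[1] & f <= window[2]
  grid <- tidyr::expand_grid(tc = tc_grid, beta = beta_grid)
  fits <- purrr::pmap(grid, function(tc, beta) {
    use <- in_window & t < tc
    if (sum(use) < min_points) {
      return(list(prefactor = NA_real_, r_squared = -Inf, n_points = sum(use)))
    }
    x <- (tc - t[use])^beta
    y <- f[use]
    a <- sum(x * y) / sum(x * x)
    rss <- sum((y - a * x)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else as.numeric(rss == 0)
    list(prefactor = a, r_squared = r2, n_points = sum(use))
  })
  grid$prefactor <- purrr::map_dbl(fits, "prefactor")
  grid$r_squared <- purrr::map_dbl(fits, "r_squared")
  grid$n_points <- purrr::map_int(fits, ~ as.integer(.x$n_points))
  if (all(!is.finite(grid$r_squared))) {
    abort("Fewer than `min_points` usable points in the fit window.",
          class = "neurodecay_insufficient_data_error")
  }
  best <- which.max(grid$r_squared)
  structure(
    list(
      tc = grid$tc[best], beta = grid$beta[best],
      prefactor = grid$prefactor[best],
      r_squared = grid$r_squared[best],
      n_points = grid$n_points[best],
      window = window, n_nodes = nn,
      grid = dplyr::mutate(grid, r_squared = pmax(.data$r_squared, 0))
    ),
    class = "critical_fit"
  )
}

#' @export
print.critical_fit <- function(x, ...) {
  cat(sprintf(
    "<critical_fit> Tc = %s days, beta = %s, prefactor = %.4g, R^2 = %.4f (%d points%s)\n",
    format(x$tc), format(x$beta), x$prefactor, x$r_squared, x$n_points,
    if (!is.null(x$n_nodes)) sprintf(", N = %d", x$n_nodes) else ""
  ))
  invisible(x)
}

#' @rdname fit_tc
#' @param x A `critical_fit`.
#' @param ... Unused.
#' @export
tidy.critical_fit <- function(x, ...) {
  tibble(
    term = c("tc", "beta", "prefactor"),
    estimate = c(x$tc, x$beta, x$prefactor)
  )
}

#' @rdname fit_tc
#' @export
glance.critical_fit <- function(x, ...) {
  tibble(
    tc = x$tc, beta = x$beta, r.squared = x$r_squared,
    nobs = x$n_points, n_nodes = x$n_nodes %||% NA_integer_
  )
}

#' Finite-size extrapolation of the critical time
#'
#' Ordinary least squares of the per-size critical times on `1/N`; the
#' intercept is the critical time in the infinite-size limit.
#'
#' @param fits A list of `critical_fit` objects at (>= 3) distinct network
#'   sizes, or a data frame with columns `n_nodes` and `tc`.
#' @return A `finite_size_fit`: list with `tc_infinity` (intercept), `slope`,
#'   `r_squared` and the per-size `fits` tibble. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(n_nodes = c(500, 1000, 2000, 5000),
#'                     tc = 150 - 1000 / n_nodes)
#' extrapolate_tc(d)$tc_infinity # 150
#' @export
extrapolate_tc <- function(fits) {
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    purrr::map_dfr(fits, function(f) {
      tibble(n_nodes = f$n_nodes, tc = f$tc, beta = f$beta,
             r_squared = f$r_squared)
    })
  }
  if (is.null(tab$n_nodes) || is.null(tab$tc)) {
    abort("Need `n_nodes` and `tc` for extrapolation.",
          class = "neurodecay_parameter_error")
  }
  if (length(unique(tab$n_nodes)) < 3L) {
    abort("Extrapolation needs fits at >= 3 distinct network sizes.",
          class = "neurodecay_insufficient_data_error")
  }
  m <- lm(tc ~ inv_n, data = tibble(tc = tab$tc, inv_n = 1 / tab$n_nodes))
  structure(
    list(
      tc_infinity = unname(coef(m)[1]),
      slope = unname(coef(m)[2]),
      r_squared = suppressWarnings(summary(m)$r.squared),
      fits = tab, model = m
    ),
    class = "finite_size_fit"
  )
}

#' @export
print.finite_size_fit <- function(x, ...) {
  cat(sprintf(
    "<finite_size_fit> Tc(N -> Inf) = %.2f days (slope %.4g vs 1/N, R^2 = %.4f, %d sizes)\n",
    x$tc_infinity, x$slope, x$r_squared, nrow(x$fits)
  ))
  invisible(x)
}

#' @rdname extrapolate_tc
#' @param x A `finite_size_fit`.
#' @param ... Unused.
#' @export
tidy.finite_size_fit <- function(x, ...) x$fits

#' @rdname extrapolate_tc
#' @export
glance.finite_size_fit <- function(x, ...) {
  tibble(tc_infinity = x$tc_infinity, slope = x$slope,
         r.squared = x$r_squared, n_sizes = nrow(x$fits))
}
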