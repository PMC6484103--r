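# ggplot2 views of traces, ensembles, histograms and fits.

#' Plot a simulation trace
#'
#' Faceted time series of the recorded observables (LSCC fraction, total
#' strength and any requested cadence metrics).
#'
#' @param object A `decay_trace`.
#' @param metrics Columns to show; default every recorded metric column.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_trace <- function(object,
                                 metrics = c("f_lscc", "global_efficiency",
                                             "total_strength", "clustering",
                                             "path_length"), ...) {
  present <- intersect(metrics, names(object))
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "t", dplyr::all_of(present)),
    -"t", names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL,
                  title = "Network degeneration trace") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble-mean LSCC trajectory
#'
#' Ensemble mean with a +/- 1 sd ribbon for the LSCC fraction.
#'
#' @param object A `decay_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_ensemble <- function(object, ...) {
  m <- object$mean
  ggplot2::ggplot(m, ggplot2::aes(x = .data$t, y = .data$f_lscc)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(0, .data$f_lscc - .data$f_lscc_sd),
      ymax = pmin(1, .data$f_lscc + .data$f_lscc_sd)), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "LSCC fraction f",
                  title = sprintf("Ensemble mean over %d realizations (N = %d)",
                                  object$n_realizations, object$n_nodes)) +
    ggplot2::theme_minimal()
}

#' Plot a best-path efficiency histogram
#'
#' @param object An `efficiency_histogram`.
#' @param ... Unused.
#' @return A ggplot (log10 count scale).
#' @export
autoplot.efficiency_histogram <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), .data$count > 0)
  ggplot2::ggplot(d, ggplot2::aes(
    x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count)) +
    ggplot2::geom_col(width = min(object$bin_hi - object$bin_lo)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "best-path efficiency 1/w", y = "ordered pairs",
                  title = "Counts of maximum-efficiency paths") +
    ggplot2::theme_minimal()
}

#' Plot the finite-size extrapolation
#'
#' Per-size critical times against 1/N with the fitted line; the intercept is
#' the infinite-size critical time.
#'
#' @param object A `finite_size_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.finite_size_fit <- function(object, ...) {
  d <- dplyr::mutate(object$fits, inv_n = 1 / .data$n_nodes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_n, y = .data$tc)) +
    ggplot2::geom_abline(intercept = object$tc_infinity, slope = object$slope,
                         linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::expand_limits(x = 0) +
    ggplot2::labs(x = "1 / N", y = "critical time Tc (days)",
                  title = sprintf("Tc extrapolates to %.1f days at 1/N -> 0",
                                  object$tc_infinity)) +
    ggplot2::theme_minimal()
}
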