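#' Plot a simulation result
#'
#' Two-panel base-graphics summary of a run: the population mean plastic
#' weight (with a +/- 1 sd band) and the population mean energy ratio against
#' time, with the set point marked.
#'
#' @param x A `simulation_result`.
#' @param set_point Set point drawn as a reference line (default from the
#'   run's modulation parameters).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.simulation_result <- function(x, set_point = x$config$mod$set_point_c,
                                   ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$time, s$w_mean, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "mean plastic weight", ...)
  graphics::polygon(c(s$time, rev(s$time)),
                    c(pmin(1, s$w_mean + s$w_sd),
                      rev(pmax(0, s$w_mean - s$w_sd))),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(s$time, s$w_mean)
  graphics::plot(s$time, s$alpha_mean, type = "l", ylim = c(0, 1),
                 xlab = "time (s)", ylab = "mean energy ratio", ...)
  graphics::abline(h = set_point, lty = 2)
  invisible(x)
}

#' Plot the degree-weight relation of a network experiment
#'
#' Scatter of synaptic in-degree against mean afferent plastic weight for the
#' sampled neurons of [run_network_experiment()], annotated with the Pearson
#' correlation.
#'
#' @param experiment The list returned by [run_network_experiment()].
#' @param ... Passed to [plot()].
#' @return Invisibly, the `degree_weight` data.frame.
#' @export
plot_degree_weight <- function(experiment, ...) {
  dw <- experiment$degree_weight
  graphics::plot(dw$in_degree, dw$mean_afferent_weight,
                 xlab = "synaptic in-degree",
                 ylab = "mean afferent plastic weight", ...)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("r = %.3f", experiment$degree_weight_cor))
  invisible(dw)
}
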