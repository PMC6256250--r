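#' Simulation run configuration
#'
#' @param dt Time step (ms). Defaults to 0.1 ms for single-neuron work; network
#'   simulations typically use 0.5 ms.
#' @param duration Simulated time (s). Should be at least the energy window
#'   whenever an energy-ratio readout is wanted.
#' @param seed Integer seed; a single seed reproduces the whole run.
#' @param constraints_enabled Logical: apply the energy gate (`TRUE`) or run
#'   classical STDP (`FALSE`).
#' @param plasticity_enabled Logical: set `FALSE` to freeze all weights (used
#'   for rate calibration).
#' @param sample_every Recording interval for weight/ratio summaries (s).
#' @param steady_frac Fraction of the run after which steady-state accumulators
#'   start (default 0.8: the final 20%).
#' @param bin_width Sliding-window bin width (ms); `dt` must divide it.
#' @param max_spikes Cap on individually stored spike events (counts are always
#'   complete). 0 disables event storage.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, duration = 200, seed = 1L,
                              constraints_enabled = TRUE,
                              plasticity_enabled = TRUE,
                              sample_every = 1, steady_frac = 0.8,
                              bin_width = 1, max_spikes = 2e6) {
  if (dt <= 0) stop("simulation_config: dt must be > 0")
  if (duration <= 0) stop("simulation_config: duration must be > 0")
  spb <- bin_width / dt
  if (abs(spb - round(spb)) > 1e-9)
    stop("simulation_config: dt must divide bin_width")
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 constraints_enabled = isTRUE(constraints_enabled),
                 plasticity_enabled = isTRUE(plasticity_enabled),
                 sample_every = sample_every, steady_frac = steady_frac,
                 bin_width = bin_width, max_spikes = as.integer(max_spikes)),
            class = "simulation_config")
}

#' Run an energy-constrained spiking network simulation
#'
#' Clock-driven co-simulation of LIF dynamics, per-neuron energy traces and
#' (optionally energy-gated) STDP over a fixed wiring diagram. External drive
#' is Poisson by default; plastic external synapses (the single-neuron
#' preparation) are simulated source-by-source, fixed external bundles are
#' sampled in aggregate (exact compound-Poisson superposition). A
#' pregenerated stimulus schedule can be supplied for deterministic runs.
#'
#' @param topology A `synapse_table` from [build_network()] or
#'   [single_neuron_table()].
#' @param lif [lif_params()].
#' @param energy [energy_constants()].
#' @param stdp [stdp_params()].
#' @param mod [modulation_params()].
#' @param stimulus_rate External source rate (Hz).
#' @param sim [simulation_config()].
#' @param stimulus_schedule Optional data.frame with columns `time_s` (sorted)
#'   and `source` (global external-source index); overrides Poisson drive.
#' @param ext_sampling `"auto"` (default), `"explicit"` or `"aggregate"`.
#'   Plastic externals are always explicit.
#' @return A `simulation_result` list: `series` (data.frame of sampled time,
#'   w_mean, w_sd, alpha_mean, alpha_sd, alpha_defined, rate), `weights`
#'   (final internal edge weights), `ext_weights`, `spikes` (data.frame,
#'   possibly truncated; `spikes_complete` says whether), per-neuron
#'   `spike_count`, `steady_spike_count`, `alpha_steady`, `alpha_final`,
#'   `w_trans_final`, `w_integ_final`, plus `summary` computed by
#'   [steady_summary()].
#' @export
run_simulation <- function(topology, lif = lif_params(),
                           energy = energy_constants(),
                           stdp = stdp_params(), mod = modulation_params(),
                           stimulus_rate = 10, sim = simulation_config(),
                           stimulus_schedule = NULL,
                           ext_sampling = c("auto", "explicit", "aggregate")) {
  ext_sampling <- match.arg(ext_sampling)
  stopifnot(inherits(topology, "synapse_table"))
  n <- attr(topology, "n_neurons")
  n_exc <- attr(topology, "n_excitatory")
  ext <- attr(topology, "external_weights")
  if (is.null(ext)) ext <- rep(list(numeric(0)), n)
  ext_plastic <- isTRUE(attr(topology, "external_plastic"))
  ext_w <- unlist(ext, use.names = FALSE)
  ext_target <- rep(seq_len(n), lengths(ext))

  if (!is.null(stimulus_schedule)) {
    stopifnot(all(c("time_s", "source") %in% names(stimulus_schedule)))
    o <- order(stimulus_schedule$time_s)
    sched_t <- stimulus_schedule$time_s[o]
    sched_s <- as.integer(stimulus_schedule$source[o])
    ext_mode <- 3L
  } else if (length(ext_w) == 0 || stimulus_rate == 0) {
    ext_mode <- 0L
    sched_t <- numeric(0); sched_s <- integer(0)
  } else if (ext_plastic || ext_sampling == "explicit") {
    ext_mode <- 1L
    sched_t <- numeric(0); sched_s <- integer(0)
  } else {
    ext_mode <- 2L
    sched_t <- numeric(0); sched_s <- integer(0)
  }
  agg_count <- vapply(ext, length, numeric(1))
  agg_mean <- vapply(ext, function(x) if (length(x)) mean(x) else 0, numeric(1))
  agg_var <- vapply(ext, function(x) if (length(x) > 1) stats::var(x) else 0,
                    numeric(1))

  set.seed(sim$seed)
  res <- .simulate_cpp(
    n, n_exc,
    as.integer(topology$pre), as.integer(topology$post),
    as.numeric(topology$weight), as.logical(topology$plastic),
    as.numeric(ext_w), as.integer(ext_target), ext_plastic,
    ext_mode, stimulus_rate, sched_t, sched_s,
    agg_count, agg_mean, agg_var,
    sim$dt / 1000, sim$duration, sim$sample_every, sim$steady_frac,
    lif$tau_m / 1000, lif$v_rest, lif$v_threshold, lif$v_reset,
    lif$t_refractory / 1000, lif$efficacy,
    energy$e_single_trans, energy$e_single_integ,
    energy$tau_trans / 1000, energy$tau_integ / 1000,
    energy$window, sim$bin_width / 1000,
    stdp$a_plus, stdp$a_minus, stdp$tau_plus / 1000, stdp$tau_minus / 1000,
    stdp$weight_dependent,
    mod$lambda_gain, mod$set_point_c,
    sim$constraints_enabled, sim$plasticity_enabled,
    sim$max_spikes)

  series <- data.frame(time = res$time, w_mean = res$w_mean, w_sd = res$w_sd,
                       alpha_mean = res$alpha_mean, alpha_sd = res$alpha_sd,
                       alpha_defined = res$alpha_defined, rate = res$rate)
  out <- list(series = series,
              weights = res$weights,
              ext_weights = res$ext_weights,
              spikes = data.frame(neuron = res$spike_neuron,
                                  time = res$spike_time),
              spikes_complete = res$spikes_complete,
              spike_count = res$spike_count,
              steady_spike_count = res$steady_spike_count,
              alpha_steady = res$alpha_steady,
              alpha_final = res$alpha_final,
              w_trans_final = res$w_trans_final,
              w_integ_final = res$w_integ_final,
              potentials = res$potentials,
              topology = topology,
              config = list(lif = lif, energy = energy, stdp = stdp,
                            mod = mod, stimulus_rate = stimulus_rate,
                            sim = sim))
  class(out) <- "simulation_result"
  out$summary <- steady_summary(out)
  out
}

#' Steady-state summary of a simulation
#'
#' Averages the recorded series over the steady-state region (samples with
#' `time >= steady_frac * duration`) and collects per-neuron steady firing
#' rates and energy ratios.
#'
#' @param result A `simulation_result`.
#' @return A list: `w_mean` (time-averaged mean plastic weight), `w_sd`
#'   (final-sample weight sd), `alpha_mean` (time-averaged population mean
#'   ratio; `NA` if never defined), `rate_mean` (population mean steady firing
#'   rate, Hz), `rates` (per neuron), `alpha_steady` (per neuron), `duration`,
#'   `steady_window`.
#' @export
steady_summary <- function(result) {
  cfg <- result$config$sim
  t0 <- cfg$steady_frac * cfg$duration
  s <- result$series
  keep <- s$time >= t0 & s$time > 0
  steady_len <- cfg$duration - t0
  rates <- result$steady_spike_count / steady_len
  list(w_mean = mean(s$w_mean[keep]),
       w_sd = s$w_sd[nrow(s)],
       alpha_mean = if (all(is.na(s$alpha_mean[keep]))) NA_real_
                    else mean(s$alpha_mean[keep], na.rm = TRUE),
       rate_mean = mean(rates),
       rates = rates,
       alpha_steady = result$alpha_steady,
       duration = cfg$duration,
       steady_window = steady_len)
}

#' @export
print.simulation_result <- function(x, ...) {
  s <- x$summary
  cat("<simulation_result>\n")
  cat(sprintf("  neurons: %d  internal edges: %d  external synapses: %d\n",
              attr(x$topology, "n_neurons"), nrow(x$topology),
              length(x$ext_weights)))
  cat(sprintf("  duration: %g s  constraints: %s\n",
              x$config$sim$duration,
              if (x$config$sim$constraints_enabled) "on" else "off"))
  cat(sprintf("  steady mean plastic weight: %.4f\n", s$w_mean))
  cat(sprintf("  steady mean energy ratio:   %s\n",
              if (is.na(s$alpha_mean)) "undefined"
              else sprintf("%.4f", s$alpha_mean)))
  cat(sprintf("  steady mean firing rate:    %.3f Hz\n", s$rate_mean))
  invisible(x)
}
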