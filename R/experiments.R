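#' Empirical f-I curve of one LIF neuron under Poisson bombardment
#'
#' Simulates a single neuron driven by `m` independent Poisson trains at `f`
#' Hz through a common weight `w` (plasticity off) and returns the empirical
#' output rate. Used to calibrate the synaptic efficacy scale.
#'
#' @param params A [lif_params()] object.
#' @param m Number of afferent trains.
#' @param f Train rate (Hz).
#' @param w Common synaptic weight in [0,1].
#' @param duration Simulated time (s).
#' @param seed Integer seed.
#' @param dt Step (ms).
#' @return A list: `rate` (Hz), `n_spikes`, `wide_ci` (TRUE when fewer than
#'   100 spikes were observed, i.e. the estimate has a wide confidence
#'   interval).
#' @export
fi_curve <- function(params = lif_params(), m = 2000, f = 10, w = 0.5,
                     duration = 50, seed = 1L, dt = 0.1) {
  if (w == 0 || f == 0 || m == 0)
    return(list(rate = 0, n_spikes = 0L, wide_ci = TRUE))
  tab <- single_neuron_table(m = m, seed = seed)
  attr(tab, "external_weights") <- list(rep(w, m))
  attr(tab, "external_plastic") <- FALSE
  sim <- simulation_config(dt = dt, duration = duration, seed = seed,
                           constraints_enabled = FALSE,
                           plasticity_enabled = FALSE,
                           sample_every = duration, max_spikes = 0)
  res <- run_simulation(tab, lif = params, stimulus_rate = f, sim = sim)
  n_sp <- res$spike_count[1]
  list(rate = n_sp / duration, n_spikes = n_sp, wide_ci = n_sp < 100)
}

#' Calibrate the synaptic efficacy scale
#'
#' Finds the efficacy (mV per unit-weight spike) at which a neuron receiving
#' `m` Poisson trains at `f` Hz through weight `w_target` fires at
#' `rate_target` Hz, by bisection on the simulated rate. Two named operating
#' points are provided. `"control"` (the default, used to freeze
#' [default_efficacy()]): at the initial mean weight 0.5 the neuron follows
#' the stimulus rate (`rate_target = f`), which keeps the standard
#' preparations active. `"balance"`: the LIF curve meets the energy-balance
#' line `nu = (1-c)/c * m * f * w * E_trans / E_integ` at `w = 0.758` (about
#' 1.73 Hz with the default energy constants); under that calibration the
#' uniform-[0,1] initial condition is deeply subthreshold.
#'
#' @param target `"control"` or `"balance"`; sets `w_target`/`rate_target`
#'   unless they are given explicitly.
#' @param m,f Operating point (afferent count, train rate in Hz).
#' @param w_target Common weight at the operating point (`NULL`: from
#'   `target`).
#' @param rate_target Target output rate in Hz (`NULL`: from `target`; for
#'   `"balance"` computed from `energy`).
#' @param energy [energy_constants()] used for the balance rate.
#' @param lif [lif_params()] (its efficacy field is ignored).
#' @param lower,upper Bisection bracket (mV).
#' @param duration Per-evaluation simulated time (s).
#' @param iterations Bisection iterations.
#' @param seed Integer seed.
#' @return A list: `efficacy` (mV), `rate_achieved`, `rate_target`.
#' @export
calibrate_efficacy <- function(target = c("control", "balance"),
                               m = 2000, f = 10, w_target = NULL,
                               rate_target = NULL,
                               energy = energy_constants(),
                               lif = lif_params(),
                               lower = 0.02, upper = 0.12,
                               duration = 60, iterations = 18, seed = 42L) {
  target <- match.arg(target)
  if (is.null(w_target)) w_target <- if (target == "control") 0.5 else 0.758
  if (is.null(rate_target)) {
    if (target == "control") {
      rate_target <- f
    } else {
      cc <- energy$set_point_c
      rate_target <- (1 - cc) / cc * m * f * w_target *
        energy$e_single_trans / energy$e_single_integ
    }
  }
  rate_at <- function(eps) {
    p <- lif
    p$efficacy <- eps
    fi_curve(p, m = m, f = f, w = w_target, duration = duration,
             seed = seed)$rate
  }
  lo <- lower; hi <- upper
  if (rate_at(lo) > rate_target) stop("calibrate_efficacy: lower bound too high")
  if (rate_at(hi) < rate_target) stop("calibrate_efficacy: upper bound too low")
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < rate_target) lo <- mid else hi <- mid
  }
  eps <- (lo + hi) / 2
  list(efficacy = eps, rate_achieved = rate_at(eps), rate_target = rate_target)
}

#' Single-neuron plasticity experiment
#'
#' One LIF neuron with `m` plastic synapses (initial weights uniform on
#' [0,1]) driven by independent Poisson trains, run to steady state with or
#' without the energy constraint.
#'
#' @param m Number of synapses.
#' @param f Stimulus rate (Hz).
#' @param constraints Logical: energy gate on or off.
#' @param seed Integer seed (controls initial weights and stimulus).
#' @param duration Simulated time (s).
#' @param dt Step (ms).
#' @param lif,energy,stdp,mod Parameter objects.
#' @return A list: `w_mean`, `w_sd`, `alpha_mean`, `rate` (steady-state
#'   values), `weights` (final), `weight_histogram`
#'   ([summarize_weights()] output), `series`, `result` (the full
#'   `simulation_result`).
#' @export
run_single_neuron_experiment <- function(m = 2000, f = 10, constraints = TRUE,
                                         seed = 1L, duration = 200, dt = 0.1,
                                         lif = lif_params(),
                                         energy = energy_constants(),
                                         stdp = stdp_params(),
                                         mod = modulation_params()) {
  if (m < 1) stop("run_single_neuron_experiment: m must be >= 1")
  if (duration < energy$window)
    stop("run_single_neuron_experiment: duration shorter than the energy window")
  tab <- single_neuron_table(m = m, seed = seed)
  sim <- simulation_config(dt = dt, duration = duration, seed = seed + 1L,
                           constraints_enabled = constraints,
                           sample_every = 1, max_spikes = 0)
  res <- run_simulation(tab, lif = lif, energy = energy, stdp = stdp,
                        mod = mod, stimulus_rate = f, sim = sim)
  s <- res$summary
  list(m = m, f = f, constraints = constraints,
       w_mean = s$w_mean, w_sd = s$w_sd,
       alpha_mean = s$alpha_mean, rate = s$rate_mean,
       weights = res$ext_weights,
       weight_histogram = summarize_weights(res$ext_weights),
       series = res$series, result = res)
}

#' Recurrent network plasticity experiment
#'
#' Builds the Dale-constrained recurrent network, drives every neuron with an
#' external Poisson bundle, and runs to steady state with or without the
#' energy constraint. Also reports the per-neuron relation between synaptic
#' in-degree and mean afferent plastic weight, the signature read-out of the
#' energy constraint at network level.
#'
#' @param n_excitatory,n_inhibitory Network composition (default 500/125).
#' @param constraints Logical: energy gate on or off.
#' @param seed Integer seed.
#' @param duration Simulated time (s).
#' @param dt Step (ms).
#' @param f External rate (Hz).
#' @param n_sample_neurons Number of excitatory neurons sampled for the
#'   degree-weight correlation (default 50).
#' @param net_config Optional [network_config()] overriding the defaults.
#' @param lif,energy,stdp,mod Parameter objects.
#' @return A list: `w_mean`, `w_sd`, `alpha_mean`, `rate`, `weights` (final
#'   plastic weights), `degree_weight` (data.frame neuron/in_degree/
#'   mean_afferent_weight for the sampled neurons), `degree_weight_cor`
#'   (Pearson), `series`, `result`.
#' @export
run_network_experiment <- function(n_excitatory = 500, n_inhibitory = 125,
                                   constraints = TRUE, seed = 1L,
                                   duration = 300, dt = 0.5, f = 10,
                                   n_sample_neurons = 50,
                                   net_config = NULL,
                                   lif = lif_params(),
                                   energy = energy_constants(),
                                   stdp = stdp_params(),
                                   mod = modulation_params()) {
  if (n_excitatory < 1 || n_inhibitory < 1)
    stop("run_network_experiment: need at least one neuron of each type")
  if (is.null(net_config))
    net_config <- network_config(n_excitatory = n_excitatory,
                                 n_inhibitory = n_inhibitory, seed = seed)
  net <- build_network(net_config)
  sim <- simulation_config(dt = dt, duration = duration, seed = seed + 1L,
                           constraints_enabled = constraints,
                           sample_every = 1, max_spikes = 0)
  res <- run_simulation(net, lif = lif, energy = energy, stdp = stdp,
                        mod = mod, stimulus_rate = f, sim = sim)
  s <- res$summary

  # degree vs mean afferent plastic weight over sampled excitatory neurons
  nE <- attr(net, "n_excitatory")
  plastic <- net$plastic
  post <- net$post
  wfin <- res$weights
  set.seed(seed + 2L)
  cand <- which(tabulate(post[plastic], nbins = nE) > 0)
  take <- sample(cand, min(n_sample_neurons, length(cand)))
  dw <- data.frame(
    neuron = take,
    in_degree = vapply(take, function(j) sum(post == j), numeric(1)),
    mean_afferent_weight = vapply(take, function(j)
      mean(wfin[plastic & post == j]), numeric(1)))
  dwc <- if (nrow(dw) > 2 && stats::sd(dw$in_degree) > 0 &&
             stats::sd(dw$mean_afferent_weight) > 0)
    stats::cor(dw$in_degree, dw$mean_afferent_weight) else NA_real_

  list(n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
       constraints = constraints,
       w_mean = s$w_mean, w_sd = s$w_sd,
       alpha_mean = s$alpha_mean, rate = s$rate_mean,
       weights = wfin[plastic],
       degree_weight = dw, degree_weight_cor = dwc,
       series = res$series, result = res)
}

#' Sweep the number of synapses of a single neuron
#'
#' Repeats the single-neuron experiment over a grid of synapse counts and
#' collects the steady-state energy ratio, mean weight, and firing rate.
#'
#' @param m_values Grid of synapse counts.
#' @param constraints Logical.
#' @param seed Integer seed.
#' @param duration Per-run simulated time (s).
#' @param ... Passed to [run_single_neuron_experiment()].
#' @return A `sweep_result` data.frame with one row per `m`: columns `m`,
#'   `alpha_mean`, `w_mean`, `rate`.
#' @export
sweep_synapse_count <- function(m_values = c(500, 1000, 2000, 4000),
                                constraints = TRUE, seed = 1L,
                                duration = 120, ...) {
  rows <- lapply(seq_along(m_values), function(i) {
    r <- run_single_neuron_experiment(m = m_values[i], constraints = constraints,
                                      seed = seed + i, duration = duration, ...)
    data.frame(m = m_values[i], alpha_mean = r$alpha_mean,
               w_mean = r$w_mean, rate = r$rate)
  })
  out <- do.call(rbind, rows)
  attr(out, "constraints") <- constraints
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Sweep the network size at fixed 4:1 composition
#'
#' @param sizes Total neuron counts (each split 4:1 into E:I).
#' @param constraints Logical.
#' @param seed Integer seed.
#' @param duration Per-run simulated time (s).
#' @param ... Passed to [run_network_experiment()].
#' @return A `sweep_result` data.frame: columns `n`, `avg_degree`,
#'   `alpha_mean`, `w_mean`, `rate`.
#' @export
sweep_network_size <- function(sizes = c(25, 50, 100), constraints = TRUE,
                               seed = 1L, duration = 120, ...) {
  rows <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    if (n < 5) stop("sweep_network_size: each size must be >= 5")
    nE <- round(n * 0.8); nI <- n - nE
    r <- run_network_experiment(n_excitatory = nE, n_inhibitory = nI,
                                constraints = constraints, seed = seed + i,
                                duration = duration, ...)
    data.frame(n = n,
               avg_degree = average_degree(r$result$topology),
               alpha_mean = r$alpha_mean, w_mean = r$w_mean, rate = r$rate)
  })
  out <- do.call(rbind, rows)
  attr(out, "constraints") <- constraints
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Energy-balance diagnostic of a sweep
#'
#' At the stationary energy balance the signaling capacity of a cell (or
#' network) is proportional to its energy ratio: `m * wbar` for a single
#' neuron, `<k> * N * wbar` for a network. This diagnostic computes the
#' capacity-to-ratio quotient per sweep point and its coefficient of
#' variation; under the constraint the quotient should be nearly constant
#' across the sweep.
#'
#' @param sweep A `sweep_result` from [sweep_synapse_count()] (columns `m`,
#'   `w_mean`, `alpha_mean`) or [sweep_network_size()] (columns `n`,
#'   `avg_degree`, `w_mean`, `alpha_mean`).
#' @return A list: `products` (capacity per point), `quotients`
#'   (capacity/alpha), `cv` (sd/mean of the quotients; 0 for a single point).
#' @export
balance_diagnostic <- function(sweep) {
  stopifnot(inherits(sweep, "data.frame"))
  capacity <- if ("m" %in% names(sweep)) {
    sweep$m * sweep$w_mean
  } else {
    sweep$avg_degree * sweep$n * sweep$w_mean
  }
  q <- capacity / sweep$alpha_mean
  cv <- if (length(q) > 1) stats::sd(q) / mean(q) else 0
  list(products = capacity, quotients = q, cv = cv)
}

#' Summary statistics and normality check of a weight set
#'
#' Mean, standard deviation, histogram over [0,1], and a chi-square
#' goodness-of-fit of the weights against a normal distribution with matched
#' mean and standard deviation (tail-open bins, adjacent bins pooled until
#' every expected count is at least 5; degrees of freedom reduced by the two
#' estimated moments).
#'
#' @param weights Numeric vector (>= 2 values).
#' @param bins Number of histogram bins over [0,1] (default 40).
#' @return A list: `mean`, `sd`, `histogram` (counts), `breaks`, `chisq`
#'   (statistic), `df`, `p_value` (normality not rejected when `p_value` >=
#'   the chosen level).
#' @export
summarize_weights <- function(weights, bins = 40) {
  if (length(weights) < 2) stop("summarize_weights: need at least 2 weights")
  m <- mean(weights)
  s <- stats::sd(weights)
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- tabulate(findInterval(weights, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  if (s == 0) {
    return(list(mean = m, sd = 0, histogram = counts, breaks = breaks,
                chisq = Inf, df = NA_integer_, p_value = 0))
  }
  # expected counts under N(m, s), open tails absorbed into the edge bins
  p <- diff(stats::pnorm(breaks, m, s))
  p[1] <- stats::pnorm(breaks[2], m, s)
  p[bins] <- 1 - stats::pnorm(breaks[bins], m, s)
  expected <- p / sum(p) * length(weights)
  # pool adjacent bins until all expected >= 5
  obs <- counts; expd <- expected
  i <- 1L
  while (i <= length(expd)) {
    if (expd[i] < 5 && length(expd) > 1L) {
      j <- if (i < length(expd)) i + 1L else i - 1L
      expd[j] <- expd[j] + expd[i]
      obs[j] <- obs[j] + obs[i]
      expd <- expd[-i]; obs <- obs[-i]
      if (j > i) next else i <- i - 1L
    } else i <- i + 1L
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- max(1L, length(expd) - 1L - 2L)
  list(mean = m, sd = s, histogram = counts, breaks = breaks,
       chisq = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
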