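#' LIF neuron parameters
#'
#' Parameters of the leaky integrate-and-fire point neuron used for every cell
#' in the network. Synaptic input is delta-current: each arriving presynaptic
#' spike deflects the membrane by `efficacy * weight` millivolts (negative for
#' inhibitory afferents).
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param v_threshold Spike threshold (mV). Must exceed `v_rest`.
#' @param v_reset Post-spike reset potential (mV). Must not exceed `v_rest`.
#' @param t_refractory Absolute refractory period (ms).
#' @param efficacy Synaptic efficacy scale: membrane deflection (mV) produced
#'   by one presynaptic spike through a synapse of weight 1. The default is the
#'   value produced by [calibrate_efficacy()] for the standard single-neuron
#'   operating point (2000 afferents at 10 Hz); see that function.
#'
#' @return An object of class `lif_params` (a validated named list).
#' @examples
#' p <- lif_params()
#' p$tau_m
#' @export
lif_params <- function(tau_m = 20, v_rest = -65, v_threshold = -50,
                       v_reset = -65, t_refractory = 2,
                       efficacy = default_efficacy()) {
  p <- list(tau_m = tau_m, v_rest = v_rest, v_threshold = v_threshold,
            v_reset = v_reset, t_refractory = t_refractory,
            efficacy = efficacy)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("lif_params: `", nm, "` must be a finite numeric scalar")
  }
  if (tau_m <= 0) stop("lif_params: tau_m must be > 0")
  if (t_refractory < 0) stop("lif_params: t_refractory must be >= 0")
  if (v_threshold <= v_rest) stop("lif_params: v_threshold must exceed v_rest")
  if (v_reset > v_rest) stop("lif_params: v_reset must not exceed v_rest")
  if (efficacy < 0) stop("lif_params: efficacy must be >= 0")
  structure(p, class = "lif_params")
}

#' Default synaptic efficacy scale
#'
#' The efficacy (mV of membrane deflection per unit-weight presynaptic spike)
#' frozen from [calibrate_efficacy()] at the rate-following operating point:
#' a neuron receiving 2000 independent Poisson trains at 10 Hz through the
#' initial mean weight 0.5 fires at the stimulus rate (10 Hz). This keeps the
#' standard preparations active and well mixed from their uniform-[0,1]
#' initial weights. The alternative balance-point calibration (LIF curve
#' intersecting the energy-balance line at `wbar ~ 0.758`, about 1.73 Hz;
#' efficacy 0.04546 mV) is available through
#' `calibrate_efficacy(target = "balance")`; it places the initial condition
#' far below threshold, so the standard preparations stay silent under it.
#'
#' @return Numeric scalar (mV).
#' @export
default_efficacy <- function() 0.07352

#' Energy accounting constants
#'
#' ATP costs and kernel/window constants of the per-neuron energy budget.
#' Each action potential arriving at a synapse of weight `w` deposits
#' `e_single_trans * w` ATP of transmission energy on the receiving neuron,
#' spread over time by an alpha kernel of time constant `tau_trans`; each
#' action potential the neuron emits deposits `e_single_integ` ATP of
#' integration energy spread by a kernel of time constant `tau_integ`. The
#' controlled variable is the ratio of windowed transmission energy to total
#' windowed signaling energy, with homeostatic set point `set_point_c`.
#'
#' @param e_single_trans ATP per arriving action potential at unit weight
#'   (default 4.1e4 = 0.25 vesicles/AP x 1.64e5 ATP/vesicle).
#' @param e_single_integ ATP per emitted action potential (default 1.2e8).
#' @param tau_trans Transmission energy kernel time constant (ms).
#' @param tau_integ Integration energy kernel time constant (ms).
#' @param window Sliding window for the energy ratio (s).
#' @param set_point_c Energy-balance set point in (0,1).
#'
#' @return An object of class `energy_constants`.
#' @examples
#' energy_constants()$set_point_c
#' @export
energy_constants <- function(e_single_trans = 4.1e4, e_single_integ = 1.2e8,
                             tau_trans = 20, tau_integ = 100,
                             window = 5, set_point_c = 0.75) {
  p <- list(e_single_trans = e_single_trans, e_single_integ = e_single_integ,
            tau_trans = tau_trans, tau_integ = tau_integ,
            window = window, set_point_c = set_point_c)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("energy_constants: `", nm, "` must be a positive numeric scalar")
  }
  if (set_point_c >= 1) stop("energy_constants: set_point_c must lie in (0,1)")
  structure(p, class = "energy_constants")
}

#' STDP window parameters
#'
#' Exponential pair-based STDP window. Pairing is nearest-spike: the timing
#' difference is `dt = t_post - t_pre` computed from the latest spike of each
#' side. By default the update is weight-dependent (soft bounds): potentiation
#' is scaled by `(1 - w)` and depression by `w`, which keeps weights in (0,1)
#' without clipping and yields a unimodal, approximately normal stationary
#' weight distribution under balanced amplitudes.
#'
#' @param a_plus Potentiation amplitude (dimensionless).
#' @param a_minus Depression amplitude (dimensionless).
#' @param tau_plus Potentiation window time constant (ms).
#' @param tau_minus Depression window time constant (ms).
#' @param weight_dependent Logical; if `TRUE` (default) use soft-bound
#'   weight-dependent updates, otherwise additive updates clipped to [0,1].
#'
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.01, a_minus = 0.01,
                        tau_plus = 20, tau_minus = 20,
                        weight_dependent = TRUE) {
  if (a_plus < 0 || a_minus < 0) stop("stdp_params: amplitudes must be >= 0")
  if (tau_plus <= 0 || tau_minus <= 0) stop("stdp_params: time constants must be > 0")
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 tau_plus = tau_plus, tau_minus = tau_minus,
                 weight_dependent = isTRUE(weight_dependent)),
            class = "stdp_params")
}

#' Energy modulation parameters
#'
#' Constants of the sigmoidal gate `f(alpha) = 2 / (1 + exp(lambda *
#' sign(dt) * (alpha - c)))` that multiplies every STDP increment. At
#' `alpha = c` the gate is 1 and the rule reduces to classical STDP; when
#' transmission over-consumes (`alpha > c`) potentiation is suppressed and
#' depression amplified, and vice versa.
#'
#' @param lambda_gain Gain of the gate (dimensionless, > 0; default 300).
#' @param set_point_c Set point in (0,1) (default 0.75). Must equal the
#'   `set_point_c` of [energy_constants()] in a simulation.
#'
#' @return An object of class `modulation_params`.
#' @export
modulation_params <- function(lambda_gain = 300, set_point_c = 0.75) {
  if (!is.numeric(lambda_gain) || lambda_gain <= 0)
    stop("modulation_params: lambda_gain must be > 0")
  if (!is.numeric(set_point_c) || set_point_c <= 0 || set_point_c >= 1)
    stop("modulation_params: set_point_c must lie in (0,1)")
  structure(list(lambda_gain = lambda_gain, set_point_c = set_point_c),
            class = "modulation_params")
}

#' Single LIF integration step (reference implementation)
#'
#' Advances one neuron by `dt` using the exact exponential-Euler update:
#' the potential decays toward rest with time constant `tau_m`, then the
#' summed synaptic drive of the step is added as an instantaneous deflection.
#' A spike is emitted when the potential reaches threshold outside the
#' refractory period. This scalar R version defines the semantics that the
#' compiled engine reproduces; it is used directly for small analyses and in
#' tests.
#'
#' @param state List with `potential` (mV), `refractory_remaining` (ms),
#'   `last_spike_time` (s or NA).
#' @param params A [lif_params()] object.
#' @param drive Summed membrane deflection from spikes arriving this step (mV,
#'   already weighted and signed).
#' @param dt Time step (ms).
#' @param t Current time (s), used to stamp `last_spike_time`.
#'
#' @return List with elements `state` (updated) and `spike` (logical).
#' @export
lif_step <- function(state, params, drive, dt, t = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("lif_step: dt must be a positive scalar")
  if (!is.finite(drive)) stop("lif_step: drive must be finite")
  v <- params$v_rest + (state$potential - params$v_rest) * exp(-dt / params$tau_m)
  refr <- max(0, state$refractory_remaining - dt)
  spike <- FALSE
  if (state$refractory_remaining > 0) {
    # spikes cannot depolarize a refractory membrane
    v <- params$v_reset
  } else {
    v <- v + drive
    if (v >= params$v_threshold) {
      spike <- TRUE
      v <- params$v_reset
      refr <- params$t_refractory
      state$last_spike_time <- t
    }
  }
  state$potential <- v
  state$refractory_remaining <- refr
  list(state = state, spike = spike)
}

#' Create a fresh neuron state
#'
#' @param params A [lif_params()] object.
#' @param is_excitatory Logical flag.
#' @return A list with `potential`, `refractory_remaining`, `last_spike_time`,
#'   `is_excitatory`.
#' @export
neuron_state <- function(params = lif_params(), is_excitatory = TRUE) {
  list(potential = params$v_rest, refractory_remaining = 0,
       last_spike_time = NA_real_, is_excitatory = isTRUE(is_excitatory))
}
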