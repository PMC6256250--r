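#' Alpha kernel for energy dissipation
#'
#' The normalized alpha function `phi(t) = (t - t0) / tau^2 * exp(-(t - t0)/tau)`
#' that spreads the ATP cost of a single spike event over time. Its integral
#' from `t0` to infinity is exactly 1 for any `tau`, so multiplying it by a
#' per-event ATP mass conserves that mass; its peak is at `t - t0 = tau` with
#' value `1/(tau * e)`.
#'
#' @param t Evaluation time(s) (s). Vectorized.
#' @param t0 Event time (s).
#' @param tau Kernel time constant (s).
#' @return Kernel value(s) (1/s); 0 for `t < t0` (causality).
#' @examples
#' alpha_kernel(0.02, 0, 0.02) # peak, = 1/(0.02*e)
#' stats::integrate(alpha_kernel, 0, 2, t0 = 0, tau = 0.02)$value
#' @export
alpha_kernel <- function(t, t0, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("alpha_kernel: tau must be a positive scalar")
  s <- t - t0
  out <- ifelse(s < 0, 0, s / tau^2 * exp(-s / tau))
  out
}

#' Brute-force energy trace from a spike list
#'
#' Evaluates an energy trace `E(t) = sum_k mass_k * phi(t; t_k, tau)` by direct
#' summation over all stored spike events. This is the defining form of the
#' per-neuron transmission and integration energy traces; the simulation
#' engine evaluates the same quantity through an O(1)-per-step two-variable
#' recursion, and the two must agree to floating-point accuracy.
#'
#' @param times Evaluation times (s), numeric vector.
#' @param spike_times Event times (s).
#' @param masses Per-event ATP masses (same length as `spike_times`, or a
#'   scalar recycled).
#' @param tau Kernel time constant (s).
#' @return Numeric vector of trace values (ATP/s) at `times`.
#' @export
energy_trace_bruteforce <- function(times, spike_times, masses, tau) {
  masses <- rep_len(masses, length(spike_times))
  vapply(times, function(t) {
    keep <- spike_times <= t
    sum(masses[keep] * alpha_kernel(t, spike_times[keep], tau))
  }, numeric(1))
}

#' Exact one-step recursion for an alpha-kernel trace
#'
#' The alpha-kernel sum solves a second-order linear ODE, so the trace can be
#' advanced exactly with two state variables: `E` (the trace itself) and `G`
#' (the sum of `mass * exp(-(t - t_k)/tau)`). Over a step `dt`:
#' `E <- exp(-dt/tau) * (E + G * dt / tau^2)`, `G <- exp(-dt/tau) * G`;
#' an event of mass `m` at the current time adds `m` to `G` and nothing to `E`.
#' Exposed for testing; the compiled engine uses the same update.
#'
#' @param state List with numeric `E` and `G`.
#' @param dt Step (s).
#' @param tau Kernel time constant (s).
#' @param impulse_mass ATP mass of an event occurring at the *start* of the
#'   step (0 if none).
#' @return Updated state list.
#' @export
alpha_trace_step <- function(state, dt, tau, impulse_mass = 0) {
  g <- state$G + impulse_mass
  d <- exp(-dt / tau)
  list(E = d * (state$E + g * dt / tau^2), G = d * g)
}

#' Windowed energy ratio
#'
#' The homeostatic controlled variable: `alpha = W_trans / (W_trans +
#' W_integ)` where the `W` are energies integrated over the trailing window.
#' Undefined (returns `NA`) when the denominator is zero, i.e. before any
#' signaling energy has been spent.
#'
#' @param w_trans Windowed transmission energy (ATP, >= 0).
#' @param w_integ Windowed integration energy (ATP, >= 0).
#' @return The ratio in [0,1], or `NA_real_` when undefined.
#' @examples
#' windowed_ratio(3, 1) # 0.75
#' windowed_ratio(0, 0) # NA
#' @export
windowed_ratio <- function(w_trans, w_integ) {
  if (any(w_trans < 0) || any(w_integ < 0))
    stop("windowed_ratio: energies must be non-negative")
  denom <- w_trans + w_integ
  ifelse(denom > 0, w_trans / denom, NA_real_)
}
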