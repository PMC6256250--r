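#' STDP timing window
#'
#' The classical exponential pair-based STDP kernel evaluated at a timing
#' difference `dt = t_post - t_pre` (seconds): potentiation
#' `+a_plus * exp(-dt/tau_plus)` for `dt > 0`, depression
#' `-a_minus * exp(dt/tau_minus)` for `dt < 0`, and 0 at exact coincidence
#' (the modulated rule divides by `|dt|`, so `dt = 0` carries no update).
#'
#' @param delta_t Timing difference(s) `t_post - t_pre` in seconds. Vectorized.
#' @param params An [stdp_params()] object.
#' @return Weight change(s) before energy modulation and weight dependence.
#' @examples
#' stdp_H(0.010, stdp_params()) # ~ +0.0060653
#' @export
stdp_H <- function(delta_t, params = stdp_params()) {
  tp <- params$tau_plus / 1000   # ms -> s
  tm <- params$tau_minus / 1000
  ifelse(delta_t > 0,  params$a_plus * exp(-delta_t / tp),
  ifelse(delta_t < 0, -params$a_minus * exp(delta_t / tm), 0))
}

#' Energy modulation factor
#'
#' The metabolic gate `f(alpha) = 2 / (1 + exp(lambda * sign(dt) * (alpha -
#' c)))`, a value in (0,2) multiplying each STDP increment. `f = 1` when
#' `alpha = c` (classical STDP recovered), when `alpha` is undefined (no
#' signaling energy yet), or at `dt = 0`. For potentiation (`dt > 0`) the gate
#' decreases with `alpha`; for depression it increases, so the pair always
#' satisfies `f(alpha, +) + f(alpha, -) = 2`.
#'
#' @param alpha Windowed energy ratio in [0,1], or `NA` when undefined.
#'   Vectorized over `alpha`.
#' @param delta_t Timing difference (s); only its sign matters.
#' @param params A [modulation_params()] object.
#' @return Modulation factor(s) in (0,2).
#' @examples
#' energy_modulation(0.75, 0.01) # exactly 1 at the set point
#' @export
energy_modulation <- function(alpha, delta_t, params = modulation_params()) {
  s <- sign(delta_t)
  out <- 2 / (1 + exp(params$lambda_gain * s * (alpha - params$set_point_c)))
  out[is.na(alpha)] <- 1
  if (any(s == 0)) out[rep_len(s == 0, length(out))] <- 1
  out
}

#' Apply one modulated STDP update to an edge
#'
#' Computes `dw = f(alpha_post, dt) * H(dt)`, applies the soft-bound weight
#' dependence when the STDP parameters request it (potentiation scaled by
#' `1 - w`, depression by `w`), and clips the result to [0,1]. Only plastic
#' edges may be updated.
#'
#' @param table A `synapse_table`.
#' @param edge Row index of the edge to update.
#' @param alpha_post Windowed energy ratio of the postsynaptic neuron (`NA`
#'   when undefined).
#' @param delta_t Timing difference `t_post - t_pre` (s).
#' @param stdp An [stdp_params()] object.
#' @param mod A [modulation_params()] object.
#' @return The table with the edge weight updated.
#' @export
apply_weight_update <- function(table, edge, alpha_post, delta_t,
                                stdp = stdp_params(),
                                mod = modulation_params()) {
  if (!isTRUE(table$plastic[edge]))
    stop("apply_weight_update: edge is not plastic")
  w <- table$weight[edge]
  dw <- energy_modulation(alpha_post, delta_t, mod) * stdp_H(delta_t, stdp)
  if (stdp$weight_dependent)
    dw <- if (delta_t > 0) dw * (1 - w) else dw * w
  table$weight[edge] <- min(1, max(0, w + dw))
  table
}
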