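#' Pure-STDP reference simulator (R implementation)
#'
#' A deliberately simple, loop-based R simulator of the same LIF + STDP
#' system with the energy gate hard-wired to 1 (classical STDP). It follows
#' the same update conventions as the compiled engine (documented in
#' [run_simulation()]): internal deliveries from the previous step first, then
#' scheduled external arrivals, energy-trace advance, then the LIF sweep with
#' emission-time potentiation; a spike's integration-energy impulse enters the
#' trace at the following step. It accepts only a pregenerated stimulus
#' schedule, so a run is fully deterministic; it exists as an independent
#' cross-check that the compiled engine with modulation forced off reproduces
#' classical STDP trajectories exactly, and is only intended for small
#' instances.
#'
#' @inheritParams run_simulation
#' @return A list with `weights`, `ext_weights`, `spikes` (data.frame
#'   neuron/time), `potentials` (final membrane potentials), and `series`
#'   containing sampled mean plastic weight.
#' @export
reference_pure_stdp <- function(topology, lif = lif_params(),
                                energy = energy_constants(),
                                stdp = stdp_params(),
                                stimulus_schedule = NULL,
                                sim = simulation_config()) {
  stopifnot(inherits(topology, "synapse_table"))
  n <- attr(topology, "n_neurons")
  n_exc <- attr(topology, "n_excitatory")
  ext <- attr(topology, "external_weights")
  if (is.null(ext)) ext <- rep(list(numeric(0)), n)
  ext_plastic <- isTRUE(attr(topology, "external_plastic"))
  wx <- unlist(ext, use.names = FALSE)
  ext_target <- rep(seq_len(n), lengths(ext))

  dt <- sim$dt / 1000
  n_steps <- round(sim$duration / dt)
  leak <- exp(-dt / (lif$tau_m / 1000))
  ref_steps <- round(lif$t_refractory / 1000 / dt)
  eff <- lif$efficacy
  tau_t <- energy$tau_trans / 1000
  tau_i <- energy$tau_integ / 1000
  dec_t <- exp(-dt / tau_t); cf_t <- dt / (tau_t * tau_t)
  dec_i <- exp(-dt / tau_i); cf_i <- dt / (tau_i * tau_i)
  spb <- round(sim$bin_width / 1000 / dt)
  n_bins <- round(energy$window / (sim$bin_width / 1000))
  tp <- stdp$tau_plus / 1000; tm <- stdp$tau_minus / 1000

  w <- topology$weight
  epre <- topology$pre; epost <- topology$post; eplast <- topology$plastic
  out_edges <- lapply(seq_len(n), function(j) which(epre == j))
  pin_edges <- lapply(seq_len(n), function(j) which(epost == j & eplast))
  xin_syn <- lapply(seq_len(n), function(j) which(ext_target == j))

  v <- rep(lif$v_rest, n); refr <- integer(n)
  Et <- Gt <- Ei <- Gi <- numeric(n)
  ring_t <- matrix(0, n, n_bins); ring_i <- matrix(0, n, n_bins)
  acc_t <- acc_i <- Wt <- Wi <- numeric(n)
  ring_ptr <- 1L
  last_post <- rep(-1, n); last_pre <- rep(-1, nrow(topology))
  last_pre_x <- rep(-1, length(wx))
  fired_prev <- integer(0)
  sp_n <- integer(0); sp_t <- numeric(0)
  imp_i <- numeric(n)  # emission impulses carried into the next step

  if (is.null(stimulus_schedule))
    stimulus_schedule <- data.frame(time_s = numeric(0), source = integer(0))
  o <- order(stimulus_schedule$time_s)
  sched_t <- stimulus_schedule$time_s[o]
  sched_s <- as.integer(stimulus_schedule$source[o])
  cur <- 1L

  sample_steps <- max(1L, round(sim$sample_every / dt))
  rec_t <- numeric(0); rec_w <- numeric(0)

  for (step in seq_len(n_steps) - 1L) {
    t_now <- step * dt
    t_emit <- (step + 1L) * dt
    drive <- numeric(n)
    imp_t <- numeric(n)

    for (fi in fired_prev) {
      pre_exc <- fi <= n_exc
      for (e in out_edges[[fi]]) {
        j <- epost[e]
        drive[j] <- drive[j] + (if (pre_exc) eff else -eff) * w[e]
        imp_t[j] <- imp_t[j] + energy$e_single_trans * w[e]
        if (sim$plasticity_enabled && eplast[e]) {
          if (last_post[j] >= 0) {
            dtt <- last_post[j] - t_now
            if (dtt < 0) {
              dw <- stdp$a_minus * exp(dtt / tm)
              if (stdp$weight_dependent) dw <- dw * w[e]
              w[e] <- w[e] - dw
              if (w[e] < 0) w[e] <- 0
            }
          }
          last_pre[e] <- t_now
        }
      }
    }
    fired_prev <- integer(0)

    while (cur <= length(sched_t) && sched_t[cur] < t_now + dt) {
      s <- sched_s[cur]
      j <- ext_target[s]
      drive[j] <- drive[j] + eff * wx[s]
      imp_t[j] <- imp_t[j] + energy$e_single_trans * wx[s]
      if (sim$plasticity_enabled && ext_plastic) {
        if (last_post[j] >= 0) {
          dtt <- last_post[j] - t_now
          if (dtt < 0) {
            dw <- stdp$a_minus * exp(dtt / tm)
            if (stdp$weight_dependent) dw <- dw * wx[s]
            wx[s] <- wx[s] - dw
            if (wx[s] < 0) wx[s] <- 0
          }
        }
        last_pre_x[s] <- t_now
      }
      cur <- cur + 1L
    }

    gt <- Gt + imp_t
    Et <- dec_t * (Et + gt * cf_t); Gt <- dec_t * gt
    gi <- Gi + imp_i
    Ei <- dec_i * (Ei + gi * cf_i); Gi <- dec_i * gi
    imp_i <- numeric(n)
    at <- Et * dt; ai <- Ei * dt
    acc_t <- acc_t + at; acc_i <- acc_i + ai
    Wt <- Wt + at; Wi <- Wi + ai
    if ((step + 1L) %% spb == 0L) {
      Wt <- Wt - ring_t[, ring_ptr]
      Wi <- Wi - ring_i[, ring_ptr]
      Wt[Wt < 0] <- 0; Wi[Wi < 0] <- 0
      ring_t[, ring_ptr] <- acc_t; ring_i[, ring_ptr] <- acc_i
      acc_t <- numeric(n); acc_i <- numeric(n)
      ring_ptr <- ring_ptr %% n_bins + 1L
    }

    for (j in seq_len(n)) {
      if (refr[j] > 0L) {
        refr[j] <- refr[j] - 1L
        v[j] <- lif$v_reset
        next
      }
      vj <- lif$v_rest + (v[j] - lif$v_rest) * leak + drive[j]
      if (vj >= lif$v_threshold) {
        v[j] <- lif$v_reset
        refr[j] <- ref_steps
        fired_prev <- c(fired_prev, j)
        imp_i[j] <- imp_i[j] + energy$e_single_integ
        sp_n <- c(sp_n, j); sp_t <- c(sp_t, t_emit)
        if (sim$plasticity_enabled) {
          for (e in pin_edges[[j]]) {
            if (last_pre[e] >= 0) {
              dtt <- t_emit - last_pre[e]
              if (dtt > 0) {
                dw <- stdp$a_plus * exp(-dtt / tp)
                if (stdp$weight_dependent) dw <- dw * (1 - w[e])
                w[e] <- w[e] + dw
                if (w[e] > 1) w[e] <- 1
              }
            }
          }
          if (ext_plastic) {
            for (s in xin_syn[[j]]) {
              if (last_pre_x[s] >= 0) {
                dtt <- t_emit - last_pre_x[s]
                if (dtt > 0) {
                  dw <- stdp$a_plus * exp(-dtt / tp)
                  if (stdp$weight_dependent) dw <- dw * (1 - wx[s])
                  wx[s] <- wx[s] + dw
                  if (wx[s] > 1) wx[s] <- 1
                }
              }
            }
          }
        }
        last_post[j] <- t_emit
      } else {
        v[j] <- vj
      }
    }

    if ((step + 1L) %% sample_steps == 0L) {
      rec_t <- c(rec_t, t_emit)
      rec_w <- c(rec_w, mean(c(w[eplast], if (ext_plastic) wx)))
    }
  }

  list(weights = w, ext_weights = wx,
       spikes = data.frame(neuron = sp_n, time = sp_t),
       potentials = v,
       series = data.frame(time = rec_t, w_mean = rec_w))
}
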