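test_that("a network with zero weights and no stimulus stays quiescent", {
  net <- tiny_network(nE = 4, nI = 1, n_ext = 2, seed = 6)
  net$weight[] <- 0
  ext0 <- lapply(attr(net, "external_weights"), function(x) x * 0)
  attr(net, "external_weights") <- ext0
  sim <- simulation_config(dt = 0.5, duration = 6, seed = 3, sample_every = 1)
  res <- run_simulation(net, sim = sim)
  expect_equal(sum(res$spike_count), 0)
  expect_true(all(res$w_trans_final == 0))
  expect_true(all(res$w_integ_final == 0))
  expect_true(all(res$weights == 0))
  expect_true(all(res$potentials == lif_params()$v_rest))
})

test_that("identical seed and configuration reproduce the run exactly", {
  tab <- single_neuron_table(m = 300, seed = 4)
  p <- lif_params(efficacy = 1.2)  # scaled so 300 afferents drive spiking
  sim <- simulation_config(dt = 0.5, duration = 12, seed = 17, sample_every = 1)
  a <- run_simulation(tab, lif = p, sim = sim)
  b <- run_simulation(tab, lif = p, sim = sim)
  expect_gt(nrow(a$spikes), 0)
  expect_identical(a$series, b$series)
  expect_identical(a$ext_weights, b$ext_weights)
  expect_identical(a$spikes, b$spikes)
  # a different seed changes the stimulus realization
  sim2 <- simulation_config(dt = 0.5, duration = 12, seed = 18, sample_every = 1)
  expect_false(identical(run_simulation(tab, lif = p, sim = sim2)$spikes,
                         a$spikes))
})

test_that("with modulation off the engine matches the pure-STDP reference bit for bit", {
  # recurrent network case
  net <- tiny_network(nE = 6, nI = 2, n_ext = 4, seed = 3)
  sched <- random_schedule(n_src = 8 * 4, n_events = 5000, duration = 12,
                           seed = 77)
  p <- excitable_lif(6)
  sim <- simulation_config(dt = 0.5, duration = 12, seed = 2,
                           constraints_enabled = FALSE, sample_every = 1)
  eng <- run_simulation(net, lif = p, sim = sim, stimulus_schedule = sched)
  ref <- reference_pure_stdp(net, lif = p, stimulus_schedule = sched, sim = sim)
  expect_gt(nrow(eng$spikes), 10)          # the comparison actually bites
  expect_identical(eng$spikes$time, ref$spikes$time)
  expect_identical(eng$spikes$neuron, ref$spikes$neuron)
  expect_identical(eng$weights, ref$weights)
  expect_identical(eng$potentials, ref$potentials)

  # single neuron with plastic external synapses
  tab <- single_neuron_table(m = 20, seed = 5)
  sched1 <- random_schedule(n_src = 20, n_events = 1200, duration = 8, seed = 6)
  p1 <- excitable_lif(8)
  sim1 <- simulation_config(dt = 1, duration = 8, seed = 9,
                            constraints_enabled = FALSE, sample_every = 1)
  eng1 <- run_simulation(tab, lif = p1, sim = sim1, stimulus_schedule = sched1)
  ref1 <- reference_pure_stdp(tab, lif = p1, stimulus_schedule = sched1,
                              sim = sim1)
  expect_gt(nrow(eng1$spikes), 5)
  expect_identical(eng1$ext_weights, ref1$ext_weights)
  expect_identical(eng1$spikes$time, ref1$spikes$time)
  expect_identical(eng1$potentials, ref1$potentials)
})

test_that("halving the step changes the steady mean weight by less than 2%", {
  tab <- single_neuron_table(m = 500, seed = 8)
  w1 <- run_simulation(tab, sim = simulation_config(
    dt = 0.2, duration = 40, seed = 5, constraints_enabled = FALSE,
    sample_every = 1))$summary$w_mean
  w2 <- run_simulation(tab, sim = simulation_config(
    dt = 0.1, duration = 40, seed = 5, constraints_enabled = FALSE,
    sample_every = 1))$summary$w_mean
  expect_lt(abs(w1 - w2) / w2, 0.02)
})

test_that("non-finite neuron state fails fast with a step index", {
  tab <- single_neuron_table(m = 10, seed = 1)
  p <- lif_params()
  p$efficacy <- NaN
  sim <- simulation_config(dt = 0.5, duration = 3, seed = 2, sample_every = 1)
  expect_error(run_simulation(tab, lif = p, sim = sim), "non-finite")
})

test_that("plastic weights stay inside [0,1] throughout a constrained run", {
  tab <- single_neuron_table(m = 400, seed = 10)
  sim <- simulation_config(dt = 0.5, duration = 30, seed = 11, sample_every = 0.5)
  res <- run_simulation(tab, sim = sim)
  expect_true(all(res$ext_weights >= 0 & res$ext_weights <= 1))
  expect_true(all(res$series$w_mean >= 0 & res$series$w_mean <= 1))
  a <- res$series$alpha_mean
  expect_true(all(is.na(a) | (a >= 0 & a <= 1)))
})
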