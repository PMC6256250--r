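test_that("alpha kernel is causal, unit-mass, and peaks at tau", {
  expect_equal(alpha_kernel(0, 0, 0.02), 0)
  expect_equal(alpha_kernel(-1, 0, 0.02), 0)
  for (tau in c(0.02, 0.1)) {
    mass <- stats::integrate(alpha_kernel, 0, 100 * tau, t0 = 0, tau = tau,
                             rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
  # numeric maximization oracle: peak at t0 + tau with value 1/(tau*e)
  opt <- stats::optimize(alpha_kernel, c(0, 1), t0 = 0, tau = 0.02,
                         maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, 0.02, tolerance = 1e-6)
  expect_equal(opt$objective, 1 / (0.02 * exp(1)), tolerance = 1e-9)
  expect_equal(alpha_kernel(0.02, 0, 0.02), 18.39397, tolerance = 1e-6)
})

test_that("the two-variable recursion equals the brute-force kernel sum", {
  set.seed(42)
  tau <- 0.02
  spikes <- sort(runif(10, 0, 0.5))
  masses <- runif(10, 0.5, 2)
  dt <- 1e-3
  grid <- seq(dt, 1, by = dt)
  # recursion stepped over the grid, impulses injected at their grid step
  st <- list(E = 0, G = 0)
  spike_step <- round(spikes / dt)
  rec <- numeric(length(grid))
  for (k in seq_along(grid)) {
    m <- sum(masses[spike_step == k - 1])
    st <- alpha_trace_step(st, dt, tau, impulse_mass = m)
    rec[k] <- st$E
  }
  brute <- energy_trace_bruteforce(grid, spike_step * dt, masses, tau)
  expect_lt(max(abs(rec - brute)) / max(brute), 1e-9)
})

test_that("per-event energy masses are conserved by the engine traces", {
  # one scheduled arrival at weight 1; window spans the whole run so the
  # windowed integral equals the total energy deposited (minus the tail)
  tab <- single_neuron_table(m = 1, seed = 1)
  attr(tab, "external_weights") <- list(1)
  attr(tab, "external_plastic") <- FALSE
  en <- energy_constants()
  sched <- data.frame(time_s = 0.05, source = 1)
  sim <- simulation_config(dt = 0.1, duration = 1, seed = 1, sample_every = 1,
                           constraints_enabled = FALSE,
                           plasticity_enabled = FALSE)
  en_long <- energy_constants(window = 1)
  res <- run_simulation(tab, lif = lif_params(efficacy = 0), energy = en_long,
                        sim = sim, stimulus_schedule = sched)
  expect_equal(res$w_trans_final, en$e_single_trans, tolerance = 1e-3)
  expect_equal(res$w_integ_final, 0)

  # two simultaneous arrivals at weight 0.5 equal one arrival at weight 1
  tab2 <- single_neuron_table(m = 2, seed = 1)
  attr(tab2, "external_weights") <- list(c(0.5, 0.5))
  attr(tab2, "external_plastic") <- FALSE
  sched2 <- data.frame(time_s = c(0.05, 0.05), source = c(1, 2))
  res2 <- run_simulation(tab2, lif = lif_params(efficacy = 0),
                         energy = en_long, sim = sim,
                         stimulus_schedule = sched2)
  expect_identical(res2$w_trans_final, res$w_trans_final)

  # n emitted spikes integrate to n times the integration mass
  p <- lif_params(efficacy = 30)
  tab3 <- single_neuron_table(m = 1, seed = 1)
  attr(tab3, "external_weights") <- list(1)
  attr(tab3, "external_plastic") <- FALSE
  sched3 <- data.frame(time_s = c(0.02, 0.1, 0.2), source = c(1, 1, 1))
  en3 <- energy_constants(window = 2)
  sim3 <- simulation_config(dt = 0.1, duration = 2, seed = 1, sample_every = 1,
                            constraints_enabled = FALSE,
                            plasticity_enabled = FALSE)
  res3 <- run_simulation(tab3, lif = p, energy = en3, sim = sim3,
                         stimulus_schedule = sched3)
  expect_equal(sum(res3$spike_count), 3)
  expect_equal(res3$w_integ_final, 3 * en$e_single_integ, tolerance = 1e-3)
})

test_that("windowed integrals expire after silence", {
  tab <- single_neuron_table(m = 1, seed = 1)
  attr(tab, "external_weights") <- list(1)
  attr(tab, "external_plastic") <- FALSE
  en <- energy_constants(window = 0.5)
  sched <- data.frame(time_s = 0.01, source = 1)
  sim <- simulation_config(dt = 0.1, duration = 2, seed = 1, sample_every = 1,
                           constraints_enabled = FALSE,
                           plasticity_enabled = FALSE)
  res <- run_simulation(tab, lif = lif_params(efficacy = 0), energy = en,
                        sim = sim, stimulus_schedule = sched)
  # by t = 2 the arrival (t = 0.01) left the trailing 0.5 s window long ago
  expect_lt(res$w_trans_final / energy_constants()$e_single_trans, 1e-6)
})

test_that("windowed_ratio follows its defining arithmetic", {
  expect_equal(windowed_ratio(3, 1), 0.75)
  expect_true(is.na(windowed_ratio(0, 0)))
  expect_equal(windowed_ratio(0, 5), 0)
  expect_error(windowed_ratio(-1, 1), "non-negative")
})
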