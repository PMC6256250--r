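test_that("summarize_weights matches hand arithmetic on a printed toy list", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  s <- summarize_weights(x, bins = 10)
  expect_equal(s$mean, 0.3)
  expect_equal(s$sd, sqrt(sum((x - 0.3)^2) / 4))
  expect_equal(sum(s$histogram), 5)
  expect_error(summarize_weights(0.5), "at least 2")
  # a constant list has zero spread and cannot look normal
  s0 <- summarize_weights(rep(0.4, 100))
  expect_equal(s0$sd, 0)
  expect_equal(s0$p_value, 0)
})

test_that("the normality chi-square is calibrated on true normal samples", {
  hits <- vapply(1:30, function(s) {
    set.seed(s)
    w <- pmin(1, pmax(0, rnorm(10000, 0.5, 0.05)))
    summarize_weights(w)$p_value >= 0.05
  }, logical(1))
  # fails to reject in at least ~90% of seeds
  expect_gte(mean(hits), 0.85)
  # and clearly rejects a uniform sample
  set.seed(1)
  expect_lt(summarize_weights(runif(10000))$p_value, 0.01)
})

test_that("balance_diagnostic computes capacity-to-ratio quotients", {
  one <- structure(data.frame(m = 2000, w_mean = 0.75, alpha_mean = 0.75,
                              rate = 1.7),
                   class = c("sweep_result", "data.frame"))
  bd <- balance_diagnostic(one)
  expect_equal(bd$cv, 0)
  expect_equal(bd$products, 1500)
  expect_equal(bd$quotients, 2000)
  two <- structure(data.frame(n = c(25, 50), avg_degree = c(10, 20),
                              w_mean = c(0.5, 0.25), alpha_mean = c(0.5, 0.5)),
                   class = c("sweep_result", "data.frame"))
  bd2 <- balance_diagnostic(two)
  expect_equal(bd2$products, c(125, 250))
  expect_gt(bd2$cv, 0)
})

test_that("configuration validation applies defaults and rejects bad input", {
  cfg <- validate_config()
  expect_equal(cfg$energy$e_single_trans, 4.1e4)
  expect_equal(cfg$energy$e_single_integ, 1.2e8)
  expect_equal(cfg$energy$set_point_c, 0.75)
  expect_equal(cfg$energy$window, 5)
  expect_equal(cfg$energy$tau_trans, 20)
  expect_equal(cfg$energy$tau_integ, 100)
  expect_equal(cfg$modulation$lambda_gain, 300)
  expect_equal(cfg$stimulus$rate, 10)
  expect_equal(cfg$network$n_excitatory, 500L)
  expect_equal(cfg$network$n_inhibitory, 125L)

  expect_error(validate_config(list(modulation = list(lambda_gain = -1))),
               "lambda")
  expect_error(validate_config(list(bogus = list(a = 1))), "unknown section")
  expect_error(validate_config(list(energy = list(nope = 1))), "unknown key")
  # several violations are reported together
  err <- tryCatch(validate_config(list(modulation = list(lambda_gain = -1),
                                       energy = list(nope = 1))),
                  error = conditionMessage)
  expect_match(err, "lambda")
  expect_match(err, "nope")
})

test_that("configurations round-trip through YAML", {
  cfg <- validate_config(list(stimulus = list(rate = 12),
                              network = list(n_excitatory = 8L,
                                             n_inhibitory = 2L)))
  path <- tempfile(fileext = ".yaml")
  save_config(cfg, path)
  back <- load_config(path)
  expect_equal(back, cfg)
  unlink(path)
})

test_that("single-neuron experiment returns a coherent steady summary", {
  r <- run_single_neuron_experiment(m = 300, f = 10, constraints = FALSE,
                                    seed = 3, duration = 20, dt = 0.5)
  expect_true(r$w_mean > 0 && r$w_mean < 1)
  expect_length(r$weights, 300)
  expect_true(all(r$weights >= 0 & r$weights <= 1))
  expect_gte(r$rate, 0)
  expect_error(run_single_neuron_experiment(m = 100, duration = 2),
               "window")
})
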