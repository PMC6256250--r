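test_that("STDP window has the classical exponential form", {
  p <- stdp_params()
  expect_equal(stdp_H(0.010, p), 0.01 * exp(-0.5), tolerance = 1e-12)
  expect_equal(stdp_H(0.010, p), 0.0060653, tolerance = 1e-4)
  expect_equal(stdp_H(-0.010, p), -0.0060653, tolerance = 1e-4)
  expect_equal(stdp_H(0, p), 0)
  expect_lt(abs(stdp_H(1, p)), 1e-20)
  expect_lt(abs(stdp_H(-1, p)), 1e-20)
  # vectorized and sign-correct
  expect_true(all(stdp_H(seq(0.001, 0.1, by = 0.001), p) > 0))
  expect_true(all(stdp_H(-seq(0.001, 0.1, by = 0.001), p) < 0))
})

test_that("energy gate is 1 at the set point and pairs sum to 2", {
  mp <- modulation_params()
  expect_equal(energy_modulation(0.75, 0.01, mp), 1)
  expect_equal(energy_modulation(0.75, -0.01, mp), 1)
  expect_equal(energy_modulation(NA, 0.01, mp), 1)
  expect_equal(energy_modulation(0.9, 0, mp), 1)
  # potentiation fully suppressed when transmission over-consumes
  expect_lt(energy_modulation(1, 0.01, mp), 1e-30)
  # algebraic identity f(a,+) + f(a,-) = 2, checked on a dense grid
  grid <- seq(0.001, 0.999, by = 0.001)
  s <- energy_modulation(grid, 0.01, mp) + energy_modulation(grid, -0.01, mp)
  expect_equal(s, rep(2, length(grid)), tolerance = 1e-12)
  # range and monotonicity; the open bounds 0 and 2 are only approached at
  # double-precision saturation of the exponential far from the set point
  fp <- energy_modulation(grid, 0.01, mp)
  fm <- energy_modulation(grid, -0.01, mp)
  expect_true(all(fp >= 0 & fp <= 2 & fm >= 0 & fm <= 2))
  mid <- seq(0.71, 0.79, by = 0.001)
  fpm <- energy_modulation(mid, 0.01, mp)
  fmm <- energy_modulation(mid, -0.01, mp)
  expect_true(all(fpm > 0 & fpm < 2 & fmm > 0 & fmm < 2))
  expect_true(all(diff(fp) <= 0))
  expect_true(all(diff(fm) >= 0))
  expect_error(modulation_params(lambda_gain = -1), "lambda")
})

test_that("apply_weight_update reduces to pure STDP at the set point and clips", {
  net <- tiny_network(nE = 3, nI = 1, seed = 2)
  e <- which(net$plastic)[1]
  stdp_add <- stdp_params(weight_dependent = FALSE)
  # alpha = c: increment is exactly the raw window value
  w0 <- net$weight[e]
  upd <- apply_weight_update(net, e, alpha_post = 0.75, delta_t = 0.01,
                             stdp = stdp_add)
  expect_equal(upd$weight[e] - w0, stdp_H(0.01, stdp_add), tolerance = 1e-12)
  # clipping at the upper bound
  net$weight[e] <- 1
  upd <- apply_weight_update(net, e, alpha_post = 0.5, delta_t = 0.005,
                             stdp = stdp_add)
  expect_equal(upd$weight[e], 1)
  # soft-bound form cannot leave [0,1] either
  net$weight[e] <- 0.99
  upd <- apply_weight_update(net, e, alpha_post = 0.2, delta_t = 0.002)
  expect_lte(upd$weight[e], 1)
  # non-plastic edges refuse updates
  ne <- which(!net$plastic)[1]
  expect_error(apply_weight_update(net, ne, 0.75, 0.01), "plastic")
})

test_that("over-consuming transmission yields less total potentiation", {
  net <- tiny_network(nE = 3, nI = 1, seed = 2)
  e <- which(net$plastic)[1]
  run_pairings <- function(alpha) {
    tab <- net
    tab$weight[e] <- 0.3
    for (k in 1:50)
      tab <- apply_weight_update(tab, e, alpha_post = alpha, delta_t = 0.01)
    tab$weight[e]
  }
  w_balanced <- run_pairings(0.75)
  w_over <- run_pairings(0.80)
  w_under <- run_pairings(0.70)
  expect_lt(w_over, w_balanced)
  expect_gt(w_under, w_balanced)
})
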