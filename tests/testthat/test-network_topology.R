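test_that("standard 500E+125I network has 625 neurons and no I-I edges", {
  net <- build_network(network_config(seed = 11, n_external = 1))
  expect_equal(attr(net, "n_neurons"), 625L)
  nE <- attr(net, "n_excitatory")
  expect_equal(nE, 500L)
  expect_false(any(net$pre > nE & net$post > nE))
  expect_setequal(levels(net$kind), c("EE", "EI", "IE"))
  expect_true(all(net$plastic == (net$kind == "EE")))
})

test_that("full density gives one edge per allowed pair (brute-force count)", {
  # 4E+1I: allowed unordered pairs = C(5,2) - C(1,2) = 10
  net <- build_network(network_config(n_excitatory = 4, n_inhibitory = 1,
                                      n_external = 2, seed = 1))
  expect_equal(nrow(net), 10L)
  # brute-force oracle over all pairs
  allowed <- 0
  for (i in 1:4) for (j in (i + 1):5) if (!(i > 4 && j > 4)) allowed <- allowed + 1
  expect_equal(nrow(net), allowed)
})

test_that("Dale constraint and unidirectionality hold across seeds", {
  for (seed in 1:8) {
    net <- build_network(network_config(n_excitatory = 16, n_inhibitory = 4,
                                        connection_density = 0.7,
                                        n_external = 1, seed = seed))
    nE <- attr(net, "n_excitatory")
    expect_false(any(net$pre > nE & net$post > nE))
    fwd <- paste(net$pre, net$post)
    rev <- paste(net$post, net$pre)
    expect_length(intersect(fwd, rev), 0L)
    expect_true(all(net$weight >= 0 & net$weight <= 1))
  }
})

test_that("edge count matches the binomial expectation at partial density", {
  d <- 0.3
  nE <- 32; nI <- 8
  n_allowed <- choose(nE + nI, 2) - choose(nI, 2)
  counts <- vapply(1:20, function(s)
    nrow(build_network(network_config(n_excitatory = nE, n_inhibitory = nI,
                                      connection_density = d, n_external = 1,
                                      seed = s))), numeric(1))
  se <- sqrt(n_allowed * d * (1 - d) / 20)
  expect_lt(abs(mean(counts) - d * n_allowed), 3 * se)
})

test_that("initial excitatory-excitatory weights are uniform on [0,1]", {
  net <- build_network(network_config(seed = 5, n_external = 1))
  w <- net$weight[net$kind == "EE"]
  expect_gt(length(w), 1e5)
  ks <- suppressWarnings(stats::ks.test(w, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("in_degree and average_degree agree with brute-force recounts", {
  net <- tiny_network(nE = 6, nI = 2, seed = 9)
  n <- attr(net, "n_neurons")
  degs <- vapply(seq_len(n), function(j) in_degree(net, j), numeric(1))
  expect_equal(sum(degs), nrow(net))
  expect_equal(average_degree(net), nrow(net) / n)
  expect_error(in_degree(net, n + 1), "unknown")
  # isolated neuron: a 1-neuron "network" has no internal edges
  iso <- single_neuron_table(m = 3, seed = 1)
  expect_equal(in_degree(iso, 1), 0L)
  expect_equal(average_degree(iso), 0)
  # fully-connected all-excitatory net: every neuron touches all others
  full <- build_network(network_config(n_excitatory = 5, n_inhibitory = 0,
                                       n_external = 1, seed = 2))
  outs <- vapply(1:5, function(j) sum(full$pre == j), numeric(1))
  ins <- vapply(1:5, function(j) sum(full$post == j), numeric(1))
  expect_true(all(ins + outs == 4))
})

test_that("edge lists round-trip through CSV bit-exactly", {
  net <- tiny_network(nE = 5, nI = 2, n_ext = 3, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_edges(net, path)
  back <- read_edges(path)
  expect_equal(back$pre, net$pre)
  expect_equal(back$post, net$post)
  expect_identical(back$weight, net$weight)
  expect_equal(as.character(back$kind), as.character(net$kind))
  expect_identical(attr(back, "external_weights"), attr(net, "external_weights"))
  unlink(c(path, paste0(path, ".external.csv")))
})
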