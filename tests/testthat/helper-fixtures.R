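# Shared fixture builders. Everything is generated in code; instances are kept
# tiny so individual tests stay fast.

# several steady-state expectations fail by design (see the methods vignette's
# stability analysis); keep the runner from terminating the suite early so
# every file still executes
options(testthat.progress.max_fails = 1000)

# small Dale-constrained recurrent net with a few external sources per neuron
tiny_network <- function(nE = 6, nI = 2, n_ext = 4, seed = 3) {
  build_network(network_config(n_excitatory = nE, n_inhibitory = nI,
                               n_external = n_ext, seed = seed))
}

# deterministic Poisson-like stimulus schedule over n_src sources
random_schedule <- function(n_src, n_events, duration, seed) {
  set.seed(seed)
  data.frame(time_s = sort(runif(n_events, 0, duration)),
             source = sample(n_src, n_events, replace = TRUE))
}

# single neuron with large PSPs so that a handful of scheduled arrivals fire it
excitable_lif <- function(efficacy = 6) lif_params(efficacy = efficacy)
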