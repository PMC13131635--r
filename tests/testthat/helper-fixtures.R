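# small deterministic fixtures shared across test files

tiny_net <- function(seed = 1, ...) {
  build_network(n_e = 4, n_i = 3, p_ii = 0.5, p_ie = 0.5, p_ei = 0.5,
                p_gap = 0.5, seed = seed, ...)
}

tiny_pops <- function(net, seed = 1) {
  with_seed <- thetagamma:::with_seed
  with_seed(seed, list(e = stellate_population(net$n_e, cv = 0),
                       i = pv_population(net$n_i, cv = 0)))
}

# short protocol for fast spectral tests: 8 Hz, few cycles, modest rate
short_protocol <- function(n_cycles = 6, sample_rate = 2000, seed = 1)
  synth_protocol(8, n_cycles = n_cycles, pre_ms = 250, post_ms = 250,
                 sample_rate = sample_rate, seed = seed)
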