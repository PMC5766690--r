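# small network builders used across tests

# directed pair: unit 1 receives `template` from unit 2, no reverse edge.
# Frequencies are drawn like the generator's (relative spread sigma_rel).
one_way_pair <- function(template, sigma_rel = 0.1, D = 4e-4, seed = 1L,
                         period_mean = 25) {
  cfg <- synth_config(n_units = 2L, k_in = 0L, period_mean = period_mean,
                      sigma_rel = sigma_rel, D = D, seed = seed)
  net <- generate_network(cfg)
  net$adjacency[1L, 2L] <- 1L
  net$couplings[["1|2"]] <- template
  net
}

# random interaction function with coefficients of typical magnitude `scale`
random_interaction <- function(M, scale = 1) {
  fourier_interaction(a = stats::rnorm(M, 0, scale),
                      b = stats::rnorm(M, 0, scale))
}

# drop all spikes before t0 and re-reference the window (post-transient view)
dataset_after <- function(dataset, t0) {
  spikes <- lapply(dataset$spikes, function(s) s[s >= t0] - t0)
  spike_dataset(spikes, t_start = 0, t_end = dataset$t_end - t0)
}
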