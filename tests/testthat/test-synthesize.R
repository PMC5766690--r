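test_that("coupling templates have the advertised locked states", {
  a <- coupling_template("in_phase", 0.006)
  sa <- stable_phase_differences(a)
  expect_equal(sa$root[sa$stability == "stable"], 0, tolerance = 1e-8)

  b <- coupling_template("bistable", 0.006)
  expect_equal(b$b, c(-0.0012, -0.006))
  sb <- stable_phase_differences(b)
  expect_equal(sb$root[sb$stability == "stable"], c(0, pi), tolerance = 1e-6)

  expect_error(coupling_template("in_phase", 0), "positive")
  expect_error(coupling_template("sideways", 1))
})

test_that("network generation respects in-degree, no self-edges, determinism", {
  cfg <- synth_config(n_units = 64, k_in = 8, seed = 11)
  net <- generate_network(cfg)
  expect_equal(unname(rowSums(net$adjacency)), rep(8, 64))
  expect_equal(diag(net$adjacency), rep(0L, 64))
  # coupling entries exactly at the nonzero adjacency cells
  keys <- which(net$adjacency == 1, arr.ind = TRUE)
  expect_setequal(names(net$couplings), paste0(keys[, 1], "|", keys[, 2]))

  net2 <- generate_network(cfg)
  expect_identical(net, net2)
  net3 <- generate_network(synth_config(n_units = 64, k_in = 8, seed = 12))
  expect_false(identical(net$adjacency, net3$adjacency))

  empty <- generate_network(synth_config(n_units = 5, k_in = 0))
  expect_equal(sum(empty$adjacency), 0)
  expect_length(empty$couplings, 0)
  expect_error(synth_config(n_units = 5, k_in = 5), "k_in")
})

test_that("frequencies are dispersed around the mean period and positive", {
  net <- generate_network(synth_config(n_units = 200, k_in = 0,
                                       sigma_rel = 0.1, seed = 3))
  expect_true(all(net$omega > 0))
  expect_equal(mean(net$omega), 2 * pi / 25, tolerance = 0.03)
  expect_equal(stats::sd(net$omega) / (2 * pi / 25), 0.1, tolerance = 0.25)
})

test_that("cycle counts convert to durations through the mean frequency", {
  net <- generate_network(synth_config(n_units = 4, k_in = 0, period_mean = 100,
                                       sigma_rel = 0, seed = 1))
  expect_equal(cycles_to_duration(net, 1000), 1e5)
  expect_error(cycles_to_duration(net, 0), "n_cycles")
  het <- generate_network(synth_config(n_units = 4, k_in = 0, period_mean = 100,
                                       sigma_rel = 0.2, seed = 2))
  expect_equal(cycles_to_duration(het, 10), 10 * 2 * pi / mean(het$omega))
})

test_that("noiseless uncoupled oscillators spike at their natural period", {
  cfg <- synth_config(n_units = 1, k_in = 0, period_mean = 100, sigma_rel = 0,
                      D = 0, seed = 1)
  net <- generate_network(cfg)
  h <- 0.1
  ds <- simulate_phases(net, 1000, h = h, seed = 1, phi0 = 0)
  expect_equal(ds$spikes[[1]], seq(100, 1000, by = 100), tolerance = 2 * h)

  het <- generate_network(synth_config(n_units = 5, k_in = 0, sigma_rel = 0.1,
                                       D = 0, seed = 9))
  ds2 <- simulate_phases(het, cycles_to_duration(het, 50), seed = 2)
  for (i in 1:5) {
    isi <- diff(ds2$spikes[[i]])
    expect_lt(max(abs(isi - 2 * pi / het$omega[i])), 2 * het$period_mean / 1000)
  }
})

test_that("mutually coupled identical pair locks in phase deterministically", {
  cfg <- synth_config(n_units = 2, k_in = 1, sigma_rel = 0, D = 0, seed = 1,
                      coupling = fourier_interaction(0, -0.1))
  net <- generate_network(cfg)
  ds <- simulate_phases(net, 2000, seed = 1, phi0 = c(0.5, 0),
                        return_paths = TRUE, thin = 1)
  P <- attr(ds, "paths")
  final_dphi <- P[nrow(P), 1] - P[nrow(P), 2]
  expect_lt(abs(final_dphi), 1e-3)
})

test_that("simulation is bit-deterministic given the seed", {
  net <- generate_network(synth_config(n_units = 4, k_in = 1, seed = 5))
  d1 <- simulate_phases(net, 2000, seed = 7)
  d2 <- simulate_phases(net, 2000, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_phases(net, 2000, seed = 8)
  expect_false(identical(d1$spikes, d3$spikes))
})

test_that("cycle-duration variance grows as the diffusion closed form", {
  # var(T_cycle) ~ 2 D Tbar^3 / (2 pi)^2 for small D
  for (D in c(2e-4, 8e-4)) {
    net <- generate_network(synth_config(n_units = 1, k_in = 0, sigma_rel = 0,
                                         D = D, seed = 1))
    ds <- simulate_phases(net, cycles_to_duration(net, 3000), seed = 31)
    v <- stats::var(diff(ds$spikes[[1]]))
    pred <- 2 * D * 25^3 / (2 * pi)^2
    expect_equal(v, pred, tolerance = 0.15)
  }
})

test_that("homogeneous noiseless in-phase network reaches global synchrony", {
  net <- generate_network(synth_config(n_units = 16, k_in = 4, sigma_rel = 0,
                                       D = 0, seed = 13))
  ds <- simulate_phases(net, cycles_to_duration(net, 400), seed = 14)
  late <- dataset_after(ds, cycles_to_duration(net, 300))
  coh <- coherence(late, bin_sizes = net$period_mean / 10)
  expect_gt(coh$kappa_mean, 0.999)
})

test_that("network-size scaling preset halves coupling as size doubles", {
  base <- synth_config(n_units = 64, k_in = 8, coupling_scale = 0.006)
  big <- scale_network_config(base, 2)
  expect_equal(big$n_units, 128L)
  expect_equal(big$k_in, 16L)
  expect_equal(big$coupling_scale, 0.003)
})

test_that("spike_dataset validates ordering and window", {
  expect_error(spike_dataset(list(c(3, 2, 5)), 0, 10), "increasing")
  expect_error(spike_dataset(list(c(1, 2, 50)), 0, 10), "outside")
  ds <- spike_dataset(list(c(1, 2), numeric(0), 5), 0, 10)
  expect_equal(attr(ds, "unusable"), c(2L, 3L))
})
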