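test_that("default prior has the documented shape and guards", {
  pr <- default_prior(3)
  expect_equal(pr$chi, rep(0, 3))
  expect_equal(pr$Sigma, diag(1e6, 3))
  expect_equal(pr$alpha, 1e-3)
  expect_equal(pr$beta, 1e-3)
  expect_error(default_prior(3, prior_scale = 0), "positive")
  expect_error(nig_state(0, matrix(1), alpha = -1, beta = 1), "positive")
  expect_error(nig_state(c(0, 0), matrix(1:4, 2), 1, 1), "symmetric")
})

test_that("design matrix has the documented layout", {
  mk_reg <- function(dphi) {
    structure(list(receiver = 1L,
                   senders = as.integer(seq_len(ncol(dphi)) + 1L),
                   delta = rep(1, nrow(dphi)), dphi = dphi,
                   dt = 1, T = nrow(dphi)), class = "regression_data")
  }
  reg1 <- mk_reg(matrix(stats::runif(10), ncol = 1))
  expect_equal(ncol(build_design(reg1, 1)), 3)

  reg63 <- mk_reg(matrix(stats::runif(5 * 63), ncol = 63))
  expect_equal(ncol(build_design(reg63, 5)), 631)

  regz <- mk_reg(matrix(0, nrow = 4, ncol = 2))
  F <- build_design(regz, 2)
  expect_equal(unname(F[1, ]), c(1, 1, 0, 1, 0, 1, 0, 1, 0))
  map <- attr(F, "column_map")
  expect_equal(nrow(map), 9)
  # trig columns equal cos/sin of the harmonic times the phase difference
  regr <- mk_reg(matrix(stats::runif(20, 0, 6), ncol = 2))
  Fr <- build_design(regr, 3)
  mapr <- attr(Fr, "column_map")
  for (k in 2:ncol(Fr)) {
    j <- match(mapr$sender[k], regr$senders)
    expected <- if (mapr$fun[k] == "cos") cos(mapr$harmonic[k] * regr$dphi[, j])
                else sin(mapr$harmonic[k] * regr$dphi[, j])
    expect_equal(unname(Fr[, k]), unname(expected))
  }
})

test_that("conjugate update: empty data, alpha increment, sequential = batch", {
  set.seed(10)
  Tn <- 120
  F <- cbind(1, matrix(stats::rnorm(Tn * 2), ncol = 2))
  delta <- drop(F %*% c(0.2, 0.05, -0.1)) + stats::rnorm(Tn, 0, 0.3)
  pr <- default_prior(3)

  expect_identical(nig_update(pr, F[0, , drop = FALSE], numeric(0)), pr)

  post <- nig_update(pr, F, delta)
  expect_equal(post$alpha - pr$alpha, Tn / 2)

  batch <- nig_update(pr, F, delta)
  chunks <- list(list(F = F[1:40, ], delta = delta[1:40]),
                 list(F = F[41:Tn, ], delta = delta[41:Tn]))
  seq2 <- sequential_update(pr, chunks)
  expect_equal(seq2$chi, batch$chi, tolerance = 1e-9)
  expect_equal(seq2$Sigma, batch$Sigma, tolerance = 1e-9)
  expect_equal(seq2$beta, batch$beta, tolerance = 1e-9)
  perm <- sequential_update(pr, rev(chunks))
  expect_equal(perm$chi, batch$chi, tolerance = 1e-9)
  expect_equal(perm$beta, batch$beta, tolerance = 1e-9)

  expect_error(sequential_update(pr, list(list(F = F[, 1:2], delta = delta))),
               "width")
})

test_that("posterior scale contracts as data accumulate", {
  set.seed(11)
  F <- cbind(1, stats::rnorm(400))
  delta <- drop(F %*% c(1, 0.5)) + stats::rnorm(400, 0, 0.2)
  pr <- default_prior(2)
  tr <- sum(diag(pr$Sigma))
  for (k in c(50, 100, 200, 400)) {
    post <- nig_update(pr, F[1:k, ], delta[1:k])
    expect_lte(sum(diag(post$Sigma)), tr)
    tr <- sum(diag(post$Sigma))
  }
})

test_that("closed-form posterior matches dense grid quadrature", {
  inst <- tiny_regression_instance()
  post <- nig_update(default_prior(3), inst$F, inst$delta)
  oracle <- nig_grid_oracle(inst$F, inst$delta)
  expect_equal(post$chi, unname(oracle$mean_c), tolerance = 0.01)
  var_c <- (post$beta / (post$alpha - 1)) * diag(post$Sigma)
  expect_equal(var_c, unname(oracle$var_c), tolerance = 0.01)
  es2 <- post$beta / (post$alpha - 1)
  expect_equal(es2, oracle$mean_s2, tolerance = 0.01)
  vs2 <- post$beta^2 / ((post$alpha - 1)^2 * (post$alpha - 2))
  expect_equal(vs2, oracle$var_s2, tolerance = 0.02)
})

test_that("log evidence satisfies the likelihood x prior / posterior identity", {
  inst <- tiny_regression_instance()
  pr <- default_prior(3)
  post <- nig_update(pr, inst$F, inst$delta)
  ev <- log_evidence(pr, inst$F, inst$delta)
  set.seed(12)
  for (k in 1:5) {
    coef <- post$chi + stats::rnorm(3, 0, 0.02)
    s2 <- post$beta / post$alpha * exp(stats::rnorm(1, 0, 0.3))
    ident <- nig_log_likelihood(inst$F, inst$delta, coef, s2) +
      nig_log_density(pr, coef, s2) - nig_log_density(post, coef, s2)
    expect_lt(abs(ident - ev), 1e-8)
  }
  # and the value agrees with the quadrature oracle
  oracle <- nig_grid_oracle(inst$F, inst$delta)
  expect_equal(ev, oracle$log_evidence, tolerance = 0.01)
})

test_that("irrelevant regressors lower the evidence on average", {
  set.seed(13)
  diffs <- replicate(20, {
    Tn <- 200
    x <- stats::runif(Tn, 0, 2 * pi)
    F <- cbind(1, cos(x), sin(x))
    delta <- drop(F %*% c(0.25, 0, -0.05)) + stats::rnorm(Tn, 0, 0.05)
    Fnoise <- cbind(F, cos(stats::runif(Tn, 0, 2 * pi)),
                    sin(stats::runif(Tn, 0, 2 * pi)))
    log_evidence(default_prior(3), F, delta) -
      log_evidence(default_prior(5), Fnoise, delta)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("harmonic selection is exact for a forced range and breaks ties low", {
  set.seed(14)
  reg <- structure(list(receiver = 1L, senders = 2L,
                        delta = stats::rnorm(50, 0.25, 0.01),
                        dphi = matrix(stats::runif(50, 0, 6.3)),
                        dt = 1, T = 50L), class = "regression_data")
  expect_equal(select_harmonics(reg, m_range = 3)$M, 3)
  # empty data: all candidate evidences are equal, smallest M wins
  reg0 <- structure(list(receiver = 1L, senders = 2L, delta = numeric(0),
                         dphi = matrix(numeric(0), ncol = 1),
                         dt = 1, T = 0L), class = "regression_data")
  sel0 <- select_harmonics(reg0, m_range = c(2, 4))
  expect_equal(sel0$M, 2)
  expect_equal(unname(diff(sel0$log_evidence)), 0)
})

test_that("evidence recovers the harmonic count of the generating coupling", {
  picks1 <- picks2 <- integer(0)
  for (s in 1:10) {
    net1 <- one_way_pair(coupling_template("in_phase", 0.006), seed = 40 + s)
    ds1 <- simulate_phases(net1, cycles_to_duration(net1, 1000), seed = 140 + s)
    picks1 <- c(picks1, fit_receiver(ds1, 1)$M)
    net2 <- one_way_pair(coupling_template("bistable", 0.006), seed = 40 + s)
    ds2 <- simulate_phases(net2, cycles_to_duration(net2, 1000), seed = 140 + s)
    picks2 <- c(picks2, fit_receiver(ds2, 1)$M)
  }
  expect_gte(sum(picks1 == 1), 8)
  expect_gte(sum(picks2 == 2), 8)
})

test_that("single-receiver fit recovers frequency, coupling and flags no ghosts", {
  # uncoupled noiseless pair: exact frequency, couplings consistent with zero
  net <- generate_network(synth_config(n_units = 2, k_in = 0, sigma_rel = 0.1,
                                       D = 0, seed = 15))
  ds <- simulate_phases(net, cycles_to_duration(net, 500), seed = 16)
  fit <- fit_receiver(ds, 1)
  expect_equal(fit$omega_hat, net$omega[1], tolerance = 1e-5)
  est <- fit$couplings[["2"]]
  sds <- fit$coupling_sd[["2"]]
  expect_true(all(abs(est$a) < 2 * sds$a + 1e-9))
  expect_true(all(abs(est$b) < 2 * sds$b + 1e-9))

  # one-way coupled drifting pair: first sine coefficient within posterior
  # uncertainty of the truth
  net2 <- one_way_pair(coupling_template("in_phase", 0.006), seed = 57)
  ds2 <- simulate_phases(net2, cycles_to_duration(net2, 1000), seed = 58)
  fit2 <- fit_receiver(ds2, 1)
  b1 <- fit2$couplings[["2"]]$b[1]
  sd1 <- fit2$coupling_sd[["2"]]$b[1]
  expect_lt(abs(b1 - (-0.006)), 3 * sd1 + 0.002)
  expect_lt(abs(b1 - (-0.006)) / 0.006, 0.5)
})

test_that("noise intensity estimate reflects the per-sample information", {
  # linear interpolation removes within-cycle diffusion, so the recovered
  # sigma^2 reflects cycle-level jitter: D_hat ~ D * dt / mean ISI rather
  # than D itself.  Check that scaling across several seeds.
  ratios <- sapply(1:5, function(s) {
    net <- generate_network(synth_config(n_units = 2, k_in = 0, sigma_rel = 0.1,
                                         D = 5e-4, seed = 60 + s))
    ds <- simulate_phases(net, cycles_to_duration(net, 1000), seed = 160 + s)
    fit <- fit_receiver(ds, 1)
    isi <- mean(diff(ds$spikes[[1]]))
    fit$D_hat / (5e-4 * fit$dt / isi)
  })
  expect_gt(median(ratios), 0.3)
  expect_lt(median(ratios), 1.7)
})

test_that("credible bands: collapse at level 0, Monte-Carlo coverage, narrowing", {
  net <- one_way_pair(coupling_template("in_phase", 0.006), seed = 17)
  dsf <- simulate_phases(net, cycles_to_duration(net, 1000), seed = 18)
  fit <- fit_receiver(dsf, 1)
  grid <- seq(0, 2 * pi, length.out = 33)
  band0 <- interaction_credible_band(fit, 2, grid, level = 0)
  expect_equal(band0$lo, band0$mean)
  expect_equal(band0$hi, band0$mean)

  band <- interaction_credible_band(fit, 2, grid, level = 0.95)
  # sampling oracle: draw from the posterior and measure coverage
  set.seed(19)
  post <- fit$posterior
  n_draw <- 2e4
  s2 <- 1 / stats::rgamma(n_draw, shape = post$alpha, rate = post$beta)
  L <- chol(post$Sigma)
  M <- fit$M
  js <- match(2L, fit$senders)
  cols <- 1L + (js - 1L) * 2L * M + seq_len(2L * M)
  inside <- matrix(NA, n_draw, length(grid))
  Z <- matrix(stats::rnorm(n_draw * post$P), n_draw)
  draws <- sweep(Z %*% L, 1, sqrt(s2), `*`)
  draws <- sweep(draws, 2, post$chi, `+`)
  G <- matrix(0, length(grid), post$P)
  for (m in seq_len(M)) {
    G[, cols[2 * m - 1]] <- cos(m * grid)
    G[, cols[2 * m]] <- sin(m * grid)
  }
  vals <- draws %*% t(G)
  cover <- mean(vals >= matrix(band$lo, n_draw, length(grid), byrow = TRUE) &
                vals <= matrix(band$hi, n_draw, length(grid), byrow = TRUE))
  expect_equal(cover, 0.95, tolerance = 0.015)

  # band narrows with more data (same seed, longer prefix)
  ds100 <- truncate_dataset(dsf, cycles_to_duration(net, 100))
  f100 <- fit_receiver(ds100, 1)
  b100 <- interaction_credible_band(f100, 2, grid)
  expect_lt(median(band$hi - band$lo), median(b100$hi - b100$lo))

  expect_error(interaction_credible_band(fit, 1, grid), "sender")
})
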