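test_that("delta-kernel interaction reproduces the closed form", {
  T <- 30
  tau <- seq(0, T, length.out = 257)[-257]
  Z <- prc_table(tau, sin(2 * pi * tau / T), period = T)
  k <- input_kernel("delta", weight = -0.4)
  # evaluate at phase differences aligned with the PRC grid: the periodic
  # linear interpolation is then exact and the closed form
  # Gamma(dphi) = (w/T) sin(dphi) must hold to machine-level accuracy
  dphi <- 2 * pi * tau / T
  g <- interaction_from_prc(Z, k, dphi_grid = dphi)
  expect_lt(max(abs(g$gamma - (-0.4 / T) * sin(dphi))), 1e-6)
})

test_that("constant PRC gives a constant interaction equal to z0 w A / T", {
  T <- 25
  tau <- seq(0, T, length.out = 129)[-129]
  Z <- prc_table(tau, rep(2.5, 128), period = T)
  for (k in list(input_kernel("exponential", weight = -1, tau_d = 3),
                 input_kernel("bi_exponential", weight = 0.7, tau_d = 5,
                              tau_r = 0.5),
                 input_kernel("delta", weight = -1))) {
    g <- interaction_from_prc(Z, k, dphi_grid = seq(0, 2 * pi, length.out = 17),
                              n_quad = 8192L)
    A <- phasebayes:::kernel_integral(k, T)
    expect_equal(g$gamma, rep(2.5 * k$weight * A / T, 17), tolerance = 1e-6)
  }
})

test_that("interaction is linear in the PRC and in the kernel weight", {
  T <- 25
  tau <- seq(0, T, length.out = 257)[-257]
  Z1 <- prc_table(tau, sin(2 * pi * tau / T), period = T)
  Z2 <- prc_table(tau, cos(4 * pi * tau / T) + 0.3, period = T)
  Zsum <- prc_table(tau, Z1$Z + 2 * Z2$Z, period = T)
  k <- input_kernel("exponential", weight = -1, tau_d = 4)
  grid <- seq(0, 2 * pi, length.out = 33)
  g1 <- interaction_from_prc(Z1, k, grid)$gamma
  g2 <- interaction_from_prc(Z2, k, grid)$gamma
  gs <- interaction_from_prc(Zsum, k, grid)$gamma
  expect_equal(gs, g1 + 2 * g2, tolerance = 1e-10)

  k3 <- input_kernel("exponential", weight = -3, tau_d = 4)
  g3 <- interaction_from_prc(Z1, k3, grid)$gamma
  expect_equal(g3, 3 * g1, tolerance = 1e-12)
})

test_that("quadrature error falls quadratically with the step", {
  T <- 25
  tau <- seq(0, T, length.out = 2049)[-2049]
  Z <- prc_table(tau, sin(2 * pi * tau / T) + 0.5 * sin(6 * pi * tau / T),
                 period = T)
  k <- input_kernel("exponential", weight = -1, tau_d = 2)
  grid <- seq(0.3, 6, length.out = 7)
  ref <- interaction_from_prc(Z, k, grid, n_quad = 16384L)$gamma
  e1 <- max(abs(interaction_from_prc(Z, k, grid, n_quad = 256L)$gamma - ref))
  e2 <- max(abs(interaction_from_prc(Z, k, grid, n_quad = 512L)$gamma - ref))
  expect_lt(e2, e1 / 2.5)
})

test_that("inhibitory delta kernel with nonnegative PRC yields nonpositive interaction", {
  T <- 25
  tau <- seq(0, T, length.out = 257)[-257]
  Z <- prc_table(tau, (1 - cos(2 * pi * tau / T)), period = T)  # type-I-like
  k <- input_kernel("delta", weight = -1)
  g <- interaction_from_prc(Z, k, dphi_grid = seq(0, 2 * pi, length.out = 65))
  expect_true(all(g$gamma <= 1e-12))
})

test_that("odd-part scan flags bifurcations of the stable set across periods", {
  mk <- function(T, b1) {
    tau <- seq(0, T, length.out = 257)[-257]
    # interaction with sine coefficient b1 after the delta-kernel average
    prc_table(tau, -T * b1 * sin(2 * pi * tau / T), period = T)
  }
  k <- input_kernel("delta", weight = 1)
  # same sign across periods: no bifurcation
  fam <- list(`24` = mk(24, 0.02), `28` = mk(28, 0.03), `32` = mk(32, 0.025))
  scan <- odd_part_scan(fam, k, M = 2)
  expect_false(scan$bifurcation)
  expect_equal(unname(sapply(scan$stable_sets, length)), c(1, 1, 1))
  # sine coefficient changes sign at some period: stable root moves 0 -> pi
  fam2 <- list(`24` = mk(24, 0.02), `32` = mk(32, -0.02))
  scan2 <- odd_part_scan(fam2, k, M = 2)
  expect_true(scan2$bifurcation)
  # a single period can never flag
  expect_false(odd_part_scan(fam[1], k)$bifurcation)
  expect_error(odd_part_scan(list(), k), "at least one")
})

test_that("adjoint PRC of the radial isochron clock matches the analytic solution", {
  omega <- 2 * pi / 5
  rhs <- function(t, x) {
    r2 <- sum(x^2)
    c(x[1] * (1 - r2) - omega * x[2], x[2] * (1 - r2) + omega * x[1])
  }
  jac <- function(t, x) {
    matrix(c(1 - 3 * x[1]^2 - x[2]^2, -omega - 2 * x[1] * x[2],
             omega - 2 * x[1] * x[2], 1 - x[1]^2 - 3 * x[2]^2),
           2, 2, byrow = TRUE)
  }
  prc <- adjoint_prc(rhs, jac, x0 = c(1.3, 0), guess_period = 5,
                     n_samples = 64)
  expect_equal(prc$period, 5, tolerance = 1e-6)
  # the cycle's phase-zero point is where the backward pass started; the
  # analytic PRC there is (-sin(omega t + theta0), cos(omega t + theta0))
  x0c <- prc$cycle(0)
  theta0 <- atan2(x0c[2], x0c[1])
  ana <- cbind(-sin(omega * prc$tau + theta0), cos(omega * prc$tau + theta0))
  expect_lt(max(abs(prc$Z - ana)), 5e-3)

  # normalization identity Z . f = 2 pi / T at every sample
  dots <- sapply(seq_along(prc$tau), function(i)
    sum(prc$Z[i, ] * rhs(prc$tau[i], prc$cycle(prc$tau[i]))))
  expect_lt(max(abs(dots - 2 * pi / prc$period)), 1e-6)
})

test_that("adjoint PRC agrees with a direct finite-perturbation experiment", {
  omega <- 2 * pi / 5
  rhs <- function(t, x) {
    r2 <- sum(x^2)
    c(x[1] * (1 - r2) - omega * x[2], x[2] * (1 - r2) + omega * x[1])
  }
  jac <- function(t, x) {
    matrix(c(1 - 3 * x[1]^2 - x[2]^2, -omega - 2 * x[1] * x[2],
             omega - 2 * x[1] * x[2], 1 - x[1]^2 - 3 * x[2]^2),
           2, 2, byrow = TRUE)
  }
  prc <- adjoint_prc(rhs, jac, x0 = c(0.8, 0.3), guess_period = 5,
                     n_samples = 32)
  f_ode <- function(t, x, p) list(rhs(t, x))
  eps <- 1e-4
  phase_of <- function(x, t_int = 40) {
    # integrate long enough to relax onto the cycle, then read the angle
    sol <- deSolve::ode(x, c(0, t_int), f_ode, NULL, rtol = 1e-12, atol = 1e-12)
    atan2(sol[2, 3], sol[2, 2]) - omega * t_int
  }
  for (i in c(4, 12, 20)) {
    x <- prc$cycle(prc$tau[i])
    shift <- phase_of(x + c(eps, 0)) - phase_of(x)
    shift <- ((shift + pi) %% (2 * pi)) - pi
    expect_equal(unname(shift / eps), prc$Z[i, 1], tolerance = 0.02)
  }
})
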