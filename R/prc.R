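#' Tabulated phase response curve
#'
#' Samples of the phase response function Z(t): the asymptotic phase
#' advance (rad, under the \eqn{2\pi}-per-period convention) per unit
#' perturbation delivered at cycle position t.  Treated as T-periodic on
#' evaluation.
#'
#' @param tau sample times in `[0, period)` (ms), strictly increasing.
#' @param Z response values (rad per unit perturbation), same length.
#' @param period oscillation period T (ms).
#' @return object of class `prc_table`.
#' @export
prc_table <- function(tau, Z, period) {
  tau <- as.numeric(tau); Z <- as.numeric(Z)
  if (length(tau) == 0L || length(tau) != length(Z))
    stop("'tau' and 'Z' must be non-empty and of equal length")
  if (period <= 0) stop("'period' must be positive (ms)")
  if (is.unsorted(tau, strictly = TRUE)) stop("'tau' must be strictly increasing")
  if (tau[1L] < 0 || tau[length(tau)] >= period)
    stop("'tau' must lie in [0, period)")
  structure(list(period = period, tau = tau, Z = Z), class = "prc_table")
}

#' @export
print.prc_table <- function(x, ...) {
  cat("<prc_table>", length(x$tau), "samples over period", x$period, "ms\n")
  invisible(x)
}

# periodic linear interpolation of a PRC at arbitrary times
prc_eval <- function(prc, t) {
  T <- prc$period
  t <- t %% T
  tau <- c(prc$tau, prc$tau[1L] + T)
  Z <- c(prc$Z, prc$Z[1L])
  stats::approx(tau, Z, xout = ifelse(t < tau[1L], t + T, t),
                rule = 2)$y
}

#' Synaptic input kernel
#'
#' The within-cycle input waveform a sender delivers to a receiver, as seen
#' by the phase-averaging integral.  Kernels are wrapped to the period
#' (periodic steady state): an `"exponential"` kernel of decay
#' \eqn{\tau_d} becomes \eqn{e^{-t/\tau_d}/(1 - e^{-T/\tau_d})} on
#' `[0, T)`; `"bi_exponential"` is the difference of decay and rise
#' exponentials, each wrapped; `"delta"` is an instantaneous pulse of unit
#' area at the sender's spike; `"tabulated"` interpolates user samples on
#' `[0, T)`.  `weight` scales (and signs) the kernel: negative weight means
#' inhibition.
#'
#' @param kind one of `"delta"`, `"exponential"`, `"bi_exponential"`,
#'   `"tabulated"`.
#' @param weight signed synaptic weight (negative = inhibitory).
#' @param tau_d decay time constant (ms), for the exponential kernels.
#' @param tau_r rise time constant (ms), for `"bi_exponential"`.
#' @param t,values sample grid on `[0, period)` and values, for
#'   `"tabulated"`.
#' @return object of class `input_kernel`.
#' @export
input_kernel <- function(kind = c("delta", "exponential", "bi_exponential",
                                  "tabulated"),
                         weight = 1, tau_d = NULL, tau_r = NULL,
                         t = NULL, values = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(weight)) stop("'weight' must be finite")
  if (kind %in% c("exponential", "bi_exponential")) {
    if (is.null(tau_d) || tau_d <= 0) stop("'tau_d' must be positive (ms)")
  }
  if (kind == "bi_exponential") {
    if (is.null(tau_r) || tau_r <= 0 || tau_r >= tau_d)
      stop("'tau_r' must satisfy 0 < tau_r < tau_d")
  }
  if (kind == "tabulated") {
    if (is.null(t) || is.null(values) || length(t) != length(values))
      stop("'t' and 'values' must be supplied for a tabulated kernel")
  }
  structure(list(kind = kind, weight = weight, tau_d = tau_d, tau_r = tau_r,
                 t = t, values = values), class = "input_kernel")
}

# evaluate the (unweighted) kernel at offsets s in [0, T), wrapped to period T
kernel_eval <- function(k, s, period) {
  s <- s %% period
  switch(k$kind,
    exponential = exp(-s / k$tau_d) / (1 - exp(-period / k$tau_d)),
    bi_exponential = {
      wrap <- function(tc) exp(-s / tc) / (1 - exp(-period / tc))
      (wrap(k$tau_d) - wrap(k$tau_r)) / (k$tau_d - k$tau_r) * k$tau_d
    },
    tabulated = {
      tt <- c(k$t, k$t[1L] + period)
      vv <- c(k$values, k$values[1L])
      stats::approx(tt, vv, xout = ifelse(s < tt[1L], s + period, s),
                    rule = 2)$y
    },
    stop("delta kernels are handled analytically"))
}

# total integral of the kernel over one period (unweighted); analytic for
# the closed-form kernels, trapezoidal for tabulated ones
kernel_integral <- function(k, period, n = 4096L) {
  switch(k$kind,
    delta = 1,
    exponential = k$tau_d * (1 - exp(-period / k$tau_d)) /
      (1 - exp(-period / k$tau_d)),  # = tau_d
    bi_exponential = k$tau_d,
    tabulated = {
      s <- seq(0, period, length.out = n + 1L)
      v <- kernel_eval(k, s, period)
      (sum(v) - (v[1L] + v[n + 1L]) / 2) * period / n
    })
}

#' Theoretical interaction function from a PRC and an input kernel
#'
#' Averages the phase response against the periodic input over one cycle:
#' \deqn{\Gamma(\Delta\phi) = \frac{w}{T}\int_0^T Z(\tau)\,
#'  k\big((\tau - \Delta\phi\, T/2\pi) \bmod T\big)\, d\tau,}
#' i.e. the sender fires at its own phase zero, so its input arrives at
#' receiver-cycle position \eqn{\Delta\phi\, T/2\pi} where
#' \eqn{\Delta\phi = \phi_i - \phi_j}.  Quadrature is trapezoidal on a
#' uniform refinement of the PRC grid; a delta kernel is evaluated in
#' closed form (\eqn{\Gamma(\Delta\phi) = (w/T)\, Z(\Delta\phi\,T/2\pi)}).
#'
#' @param Z a [prc_table()].
#' @param k an [input_kernel()].
#' @param dphi_grid phase differences at which to evaluate (rad).
#' @param n_quad number of quadrature nodes over the period.
#' @param fit_harmonics if non-`NULL`, also return a discrete least-squares
#'   Fourier fit with this many harmonics (see [fit_fourier_series()]).
#' @return data frame with columns `dphi` and `gamma` (rad/ms); if
#'   `fit_harmonics` is set, the fit is attached as attribute `"fourier"`
#'   (list with `interaction` and `constant`).
#' @export
interaction_from_prc <- function(Z, k, dphi_grid = seq(0, 2 * pi,
                                                       length.out = 129L),
                                 n_quad = max(256L, 4L * length(Z$tau)),
                                 fit_harmonics = NULL) {
  stopifnot(inherits(Z, "prc_table"), inherits(k, "input_kernel"))
  T <- Z$period
  shift <- dphi_grid * T / (2 * pi)
  if (k$kind == "delta") {
    g <- (k$weight / T) * prc_eval(Z, shift)
  } else {
    # substitute u = tau - shift so the kernel's wrap discontinuity sits at
    # the integration boundary; trapezoidal rule is then O(step^2)
    u <- seq(0, T, length.out = n_quad + 1L)
    ku <- kernel_eval(k, pmin(u, T * (1 - 1e-12)), T)
    wts <- c(0.5, rep(1, n_quad - 1L), 0.5)
    g <- vapply(shift, function(d) {
      Zs <- prc_eval(Z, u + d)
      (k$weight / T) * sum(wts * Zs * ku) * (T / n_quad)
    }, 1)
  }
  out <- data.frame(dphi = dphi_grid, gamma = g)
  if (!is.null(fit_harmonics))
    attr(out, "fourier") <- fit_fourier_series(dphi_grid, g,
                                               M = fit_harmonics)
  out
}

#' Stability scan of the odd part across firing periods
#'
#' For each supplied period (each with its own PRC), computes the
#' theoretical interaction function, fits its Fourier series, finds the
#' stable zeros of the odd part, and reports whether the stable set changes
#' across periods -- a bifurcation of the locked states with firing rate.
#'
#' @param prc_by_period named list of [prc_table()] objects (names =
#'   periods, informational only).
#' @param k an [input_kernel()].
#' @param dphi_grid evaluation grid (rad).
#' @param M harmonics used for the Fourier fit of each sampled interaction.
#' @param match_tol roots closer than this (rad) are considered the same
#'   locked state across periods.
#' @return list with `results` (per-period [stable_phase_differences()]
#'   tables), `stable_sets` (per-period stable roots) and
#'   `bifurcation` (logical: does the stable set change?).
#' @export
odd_part_scan <- function(prc_by_period, k,
                          dphi_grid = seq(0, 2 * pi, length.out = 257L),
                          M = 5L, match_tol = 0.1) {
  if (length(prc_by_period) < 1L) stop("need at least one period entry")
  results <- lapply(prc_by_period, function(Z) {
    g <- interaction_from_prc(Z, k, dphi_grid, fit_harmonics = M)
    f <- attr(g, "fourier")$interaction
    stable_phase_differences(f)
  })
  stable_sets <- lapply(results, function(r) r$root[r$stability == "stable"])
  bif <- FALSE
  if (length(stable_sets) > 1L) {
    ref <- stable_sets[[1L]]
    same <- function(s) {
      if (length(s) != length(ref)) return(FALSE)
      all(vapply(s, function(r) {
        d <- abs(ref - r)
        any(pmin(d, 2 * pi - d) < match_tol)
      }, TRUE))
    }
    bif <- !all(vapply(stable_sets[-1L], same, TRUE))
  }
  list(results = results, stable_sets = stable_sets, bifurcation = bif)
}

#' Phase response curve of a limit-cycle ODE by the adjoint method
#'
#' Locates the attracting limit cycle of a user-supplied smooth ODE by long
#' integration followed by Poincare-section refinement of the period, then
#' integrates the adjoint system \eqn{\dot Z = -J(x(t))^\top Z} backward
#' over successive periods until the solution is periodic, and normalizes
#' so that \eqn{Z(t)\cdot f(x(t)) = 2\pi/T} at every time (phase convention
#' \eqn{[0, 2\pi)}).
#'
#' @param rhs function `(t, x)` returning the ODE right-hand side.
#' @param jacobian function `(t, x)` returning the Jacobian matrix.
#' @param x0 initial state from which the cycle is reachable.
#' @param guess_period rough period estimate (ms).
#' @param n_samples number of PRC samples over the period.
#' @param transient integration time (in multiples of `guess_period`) used
#'   to relax onto the cycle.
#' @param tol relative periodicity tolerance for adjoint convergence.
#' @param max_iter maximum number of backward periods.
#' @return a [prc_table()] whose rows are the PRC for perturbations of each
#'   state variable; stored as a list with `period`, `tau`, `Z` (matrix,
#'   one column per state variable) -- class `c("prc_matrix",
#'   "prc_table")`.  Use one column as a scalar PRC for a given
#'   perturbation direction.
#' @export
adjoint_prc <- function(rhs, jacobian, x0, guess_period,
                        n_samples = 256L, transient = 50, tol = 1e-7,
                        max_iter = 50L) {
  d <- length(x0)
  f_ode <- function(t, x, p) list(rhs(t, x))
  # relax onto the cycle
  relax <- deSolve::ode(y = x0, times = c(0, transient * guess_period),
                        func = f_ode, parms = NULL,
                        rtol = 1e-10, atol = 1e-10, maxsteps = 500000)
  xc <- as.numeric(relax[nrow(relax), -1L])
  # refine the period: return time to the Poincare section x1 = xc[1],
  # crossing upward, located by root-finding on the interpolated flow
  flow <- function(x, tmax, n = 2048L) {
    deSolve::ode(y = x, times = seq(0, tmax, length.out = n), func = f_ode,
                 parms = NULL, rtol = 1e-12, atol = 1e-12, maxsteps = 500000)
  }
  # Poincare section: hyperplane through x orthogonal to the flow there,
  # crossed in the flow direction -- transversal at x by construction
  find_return <- function(x) {
    fx <- rhs(0, x)
    tr <- flow(x, 1.5 * guess_period)
    s <- as.matrix(tr[, -1L, drop = FALSE])
    s <- drop(sweep(s, 2L, x) %*% fx)
    idx <- which(s[-1L] >= 0 & s[-length(s)] < 0)
    if (!length(idx)) stop("no return to the Poincare section: no limit cycle found")
    i <- idx[1L]
    g <- function(t) {
      st <- deSolve::ode(y = x, times = c(0, t), func = f_ode, parms = NULL,
                         rtol = 1e-12, atol = 1e-12)
      sum((as.numeric(st[2L, -1L]) - x) * fx)
    }
    stats::uniroot(g, c(tr[i, 1L], tr[i + 1L, 1L]), tol = 1e-12)$root
  }
  period <- find_return(xc)
  # land exactly on the cycle: one more return
  st <- deSolve::ode(y = xc, times = c(0, period), func = f_ode, parms = NULL,
                     rtol = 1e-12, atol = 1e-12)
  xc <- as.numeric(st[2L, -1L])
  period <- find_return(xc)
  # store the cycle finely for Jacobian interpolation
  n_store <- max(2048L, 8L * n_samples)
  tcyc <- seq(0, period, length.out = n_store + 1L)
  cyc <- deSolve::ode(y = xc, times = tcyc, func = f_ode, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  cyc_interp <- lapply(seq_len(d), function(k) {
    y <- cyc[, k + 1L]
    y[n_store + 1L] <- y[1L]  # close the loop exactly for the periodic spline
    stats::splinefun(tcyc, y, method = "periodic")
  })
  x_at <- function(t) vapply(cyc_interp, function(f) f(t %% period), 1)
  # adjoint system integrated backward: with s = -t, dZ/ds = J(x(-s))^T Z
  adj <- function(s, Z, p) {
    J <- jacobian(-s %% period, x_at(-s %% period))
    list(drop(t(J) %*% Z))
  }
  f0 <- rhs(0, xc)
  Z <- f0 / sum(f0 * f0) * (2 * pi / period)  # start in the right normalization
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- deSolve::ode(y = Z, times = c(0, period), func = adj, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
    Z_new <- as.numeric(sol[2L, -1L])
    # renormalize each pass so the neutral direction stays fixed
    Z_new <- Z_new * (2 * pi / period) / sum(Z_new * f0)
    if (sqrt(sum((Z_new - Z)^2)) < tol * max(1, sqrt(sum(Z^2)))) {
      Z <- Z_new; conv <- TRUE; break
    }
    Z <- Z_new
  }
  if (!conv) stop("adjoint iteration did not converge to a periodic solution")
  # sample the converged adjoint over one period (backward pass, re-ordered)
  s_grid <- seq(0, period, length.out = n_samples + 1L)
  sol <- deSolve::ode(y = Z, times = s_grid, func = adj, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  Zmat <- matrix(NA_real_, n_samples, d)
  tau <- period - s_grid[seq_len(n_samples) + 1L]  # Z(period - s)
  ord <- order(tau)
  for (k in seq_len(d)) Zmat[, k] <- sol[ord + 1L, k + 1L]
  tau <- tau[ord]
  # exact pointwise normalization check data are left to the caller/tests
  structure(list(period = period, tau = tau, Z = Zmat,
                 cycle = function(t) x_at(t), rhs = rhs),
            class = c("prc_matrix", "prc_table"))
}
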