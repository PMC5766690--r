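#' Normal-inverse-gamma state
#'
#' Hyperparameters of the conjugate joint distribution over the regression
#' coefficients c (effective frequency plus Fourier coupling coefficients)
#' and the noise variance \eqn{\sigma^2 = 2D/\Delta t}:
#' \deqn{c \mid \sigma^2 \sim N(\chi, \sigma^2 \Sigma), \qquad
#'       \sigma^2 \sim \mathrm{InvGamma}(\alpha, \beta).}
#'
#' @param chi location vector (length P).
#' @param Sigma symmetric positive-definite P x P scale matrix.
#' @param alpha,beta inverse-gamma shape and scale, both positive.
#' @return object of class `nig_state`.
#' @export
nig_state <- function(chi, Sigma, alpha, beta) {
  chi <- as.numeric(chi)
  Sigma <- as.matrix(Sigma)
  P <- length(chi)
  if (!all(dim(Sigma) == P)) stop("'Sigma' must be P x P")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
    stop("'Sigma' must be symmetric")
  if (!(alpha > 0) || !(beta > 0)) stop("'alpha' and 'beta' must be positive")
  # positive definiteness checked lazily at first factorization
  structure(list(chi = chi, Sigma = Sigma, alpha = alpha, beta = beta, P = P),
            class = "nig_state")
}

#' @export
print.nig_state <- function(x, ...) {
  cat("<nig_state> P =", x$P, " alpha =", signif(x$alpha, 5),
      " beta =", signif(x$beta, 5), "\n")
  invisible(x)
}

#' Weakly informative default prior
#'
#' Location zero, scale `prior_scale^2 * I`, and a vague inverse-gamma on
#' the noise variance.  With the defaults the posterior mean is essentially
#' the least-squares solution once T is moderately large, while evidence
#' comparisons between harmonic counts remain proper.
#'
#' @param P coefficient dimension (`1 + 2*M*(n_observed - 1)`).
#' @param prior_scale prior scale of each coefficient (default 1e3).
#' @param alpha0,beta0 inverse-gamma hyperparameters (default 1e-3 each).
#' @return an [nig_state()].
#' @export
default_prior <- function(P, prior_scale = 1e3, alpha0 = 1e-3, beta0 = 1e-3) {
  if (!(prior_scale > 0)) stop("'prior_scale' must be positive")
  nig_state(chi = numeric(P), Sigma = diag(prior_scale^2, P),
            alpha = alpha0, beta = beta0)
}

# Cholesky with a diagonal-jitter retry; failure means the update system is
# numerically singular (e.g. perfectly synchronous data), which must surface.
chol_jitter <- function(A, jitter = 1e-10) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(A + diag(jitter * max(diag(A)), nrow(A))),
                   error = function(e) NULL)
    if (is.null(ch))
      stop("singular update system: design is numerically degenerate; ",
           "raise the prior precision (smaller prior_scale) or supply ",
           "less collinear data")
  }
  ch
}

logdet_chol <- function(ch) 2 * sum(log(diag(ch)))

# sufficient statistics of a regression block
nig_suffstats <- function(F, delta) {
  F <- as.matrix(F)
  delta <- as.numeric(delta)
  if (nrow(F) != length(delta)) stop("nrow(F) must equal length(delta)")
  list(FtF = crossprod(F), Ftd = drop(crossprod(F, delta)),
       dtd = sum(delta^2), T = length(delta))
}

# core update from sufficient statistics; returns the posterior plus the
# log-determinant bookkeeping needed by the evidence
nig_update_stats <- function(prior, ss) {
  P <- prior$P
  ch_old <- chol_jitter(prior$Sigma)
  ld_old <- logdet_chol(ch_old)
  Prec_old <- chol2inv(ch_old)
  if (ss$T == 0L) {
    return(list(post = prior, ld_old = ld_old, ld_new = ld_old))
  }
  A <- Prec_old + ss$FtF
  ch_A <- chol_jitter(A)
  Sigma_new <- chol2inv(ch_A)
  rhs <- ss$Ftd + drop(Prec_old %*% prior$chi)
  chi_new <- drop(Sigma_new %*% rhs)
  alpha_new <- prior$alpha + ss$T / 2
  beta_new <- prior$beta + 0.5 * (ss$dtd +
    drop(crossprod(prior$chi, Prec_old %*% prior$chi)) -
    sum(chi_new * rhs))
  if (beta_new <= 0) beta_new <- .Machine$double.xmin  # numerically exact fit
  post <- nig_state(chi_new, Sigma_new, alpha_new, beta_new)
  list(post = post, ld_old = ld_old, ld_new = -logdet_chol(ch_A))
}

#' Conjugate posterior update
#'
#' Updates a normal-inverse-gamma state with a block of regression data
#' (design matrix rows and phase-increment responses):
#' \deqn{\Sigma' = (\Sigma^{-1} + F^\top F)^{-1},\quad
#'  \chi' = \Sigma' (F^\top\delta + \Sigma^{-1}\chi),\quad
#'  \alpha' = \alpha + T/2,}
#' \deqn{\beta' = \beta + \tfrac12(\delta^\top\delta +
#'  \chi^\top\Sigma^{-1}\chi - \chi'^\top\Sigma'^{-1}\chi').}
#' Implemented by Cholesky factorization with a diagonal-jitter retry; a
#' numerically singular system raises an error rather than returning a
#' silently unstable posterior.
#'
#' @param prior an [nig_state()].
#' @param F design matrix (T x P), see [build_design()]; `T = 0` returns the
#'   prior unchanged.
#' @param delta response vector of length T (rad/ms).
#' @return the posterior `nig_state`.
#' @export
nig_update <- function(prior, F, delta) {
  stopifnot(inherits(prior, "nig_state"))
  if (length(delta) == 0L) return(prior)
  nig_update_stats(prior, nig_suffstats(F, delta))$post
}

#' Sequential updating over data chunks
#'
#' Applies [nig_update()] chunk by chunk.  By conjugacy the result is
#' identical (to numerical precision) to a single batch update on the
#' concatenated data, in any chunk order.
#'
#' @param prior an [nig_state()].
#' @param chunks list of `list(F = , delta = )` blocks sharing the same
#'   coefficient dimension.
#' @return the final posterior `nig_state`.
#' @export
sequential_update <- function(prior, chunks) {
  stopifnot(inherits(prior, "nig_state"))
  for (ch in chunks) {
    if (ncol(as.matrix(ch$F)) != prior$P)
      stop("inconsistent chunk width: expected P = ", prior$P)
    prior <- nig_update(prior, ch$F, ch$delta)
  }
  prior
}

#' Log model evidence (marginal likelihood)
#'
#' Closed-form \eqn{\log \int p(\delta \mid c, \sigma^2)\, p(c, \sigma^2)\,
#' dc\, d\sigma^2} for the conjugate normal-inverse-gamma regression:
#' \deqn{\tfrac12\log|\Sigma'| - \tfrac12\log|\Sigma|
#'  + \alpha\log\beta - \alpha'\log\beta'
#'  + \log\Gamma(\alpha') - \log\Gamma(\alpha) - \tfrac{T}{2}\log 2\pi.}
#' This is exactly the likelihood-times-prior-over-posterior identity used
#' for Bayesian model comparison; the harmonic count is chosen by maximizing
#' it.
#'
#' @inheritParams nig_update
#' @return scalar log evidence.
#' @export
log_evidence <- function(prior, F, delta) {
  stopifnot(inherits(prior, "nig_state"))
  ss <- nig_suffstats(F, delta)
  up <- nig_update_stats(prior, ss)
  post <- up$post
  0.5 * (up$ld_new - up$ld_old) +
    prior$alpha * log(prior$beta) - post$alpha * log(post$beta) +
    lgamma(post$alpha) - lgamma(prior$alpha) -
    (ss$T / 2) * log(2 * pi)
}

#' Joint log density of a normal-inverse-gamma state
#'
#' Evaluates \eqn{\log\{N(c \mid \chi, \sigma^2\Sigma)\,
#' \mathrm{InvGamma}(\sigma^2 \mid \alpha, \beta)\}} -- the prior or
#' posterior density of the regression parameters.
#'
#' @param state an [nig_state()].
#' @param coef coefficient vector c.
#' @param sigma2 noise variance \eqn{\sigma^2 > 0}.
#' @return scalar log density.
#' @export
nig_log_density <- function(state, coef, sigma2) {
  stopifnot(inherits(state, "nig_state"), sigma2 > 0)
  ch <- chol_jitter(state$Sigma)
  r <- backsolve(ch, coef - state$chi, transpose = TRUE)
  q <- sum(r^2)
  lN <- -0.5 * state$P * log(2 * pi * sigma2) - 0.5 * logdet_chol(ch) -
    q / (2 * sigma2)
  lIG <- state$alpha * log(state$beta) - lgamma(state$alpha) -
    (state$alpha + 1) * log(sigma2) - state$beta / sigma2
  lN + lIG
}

#' Gaussian regression log likelihood
#'
#' \eqn{\sum_\tau \log N(\delta_\tau \mid (F c)_\tau, \sigma^2)}; the
#' likelihood of the phase increments under the discretized phase model.
#'
#' @param F design matrix.
#' @param delta response vector.
#' @param coef coefficient vector.
#' @param sigma2 noise variance.
#' @return scalar log likelihood.
#' @export
nig_log_likelihood <- function(F, delta, coef, sigma2) {
  mu <- drop(as.matrix(F) %*% coef)
  sum(stats::dnorm(delta, mu, sqrt(sigma2), log = TRUE))
}

#' Build the trigonometric design matrix
#'
#' One row per sample \eqn{\tau}: a leading 1 (absorbing the effective
#' frequency \eqn{\hat\omega}) followed, for each sender j in ascending id
#' order, by the block
#' \eqn{[\cos\Delta\phi_{ij}, \sin\Delta\phi_{ij},
#'        \cos 2\Delta\phi_{ij}, \sin 2\Delta\phi_{ij}, \ldots]}
#' up to harmonic M, giving width \eqn{P = 1 + 2M(n_{obs}-1)}.
#'
#' @param reg a [build_regression()] result.
#' @param M harmonic count (>= 1).
#' @return T x P numeric matrix with attribute `"column_map"`, a data frame
#'   mapping each column to (sender, harmonic, cos/sin).
#' @export
build_design <- function(reg, M) {
  stopifnot(inherits(reg, "regression_data"))
  M <- as.integer(M)
  if (M < 1L) stop("'M' must be >= 1")
  ns <- length(reg$senders)
  P <- 1L + 2L * M * ns
  F <- matrix(0, nrow = reg$T, ncol = P)
  F[, 1L] <- 1
  map <- data.frame(col = 1L, sender = NA_integer_, harmonic = NA_integer_,
                    fun = "const", stringsAsFactors = FALSE)
  col <- 2L
  for (js in seq_len(ns)) {
    d <- reg$dphi[, js]
    for (m in seq_len(M)) {
      F[, col] <- cos(m * d)
      F[, col + 1L] <- sin(m * d)
      map <- rbind(map,
        data.frame(col = c(col, col + 1L), sender = reg$senders[js],
                   harmonic = m, fun = c("cos", "sin"),
                   stringsAsFactors = FALSE))
      col <- col + 2L
    }
  }
  attr(F, "column_map") <- map
  F
}

# column indices of the M-harmonic submodel inside the M_max design
submodel_columns <- function(n_senders, M, M_max) {
  idx <- 1L
  for (js in seq_len(n_senders)) {
    block <- 1L + (js - 1L) * 2L * M_max
    idx <- c(idx, block + seq_len(2L * M))
  }
  idx
}

#' Select the harmonic count by model evidence
#'
#' Fits the conjugate model for each candidate harmonic count and returns
#' the count maximizing the log evidence (ties broken toward the smaller
#' count).  One shared M applies to all senders of the receiver.
#'
#' @param reg a [build_regression()] result.
#' @param m_range candidate harmonic counts (default `1:5`).
#' @param prior_scale,alpha0,beta0 prior hyperparameters, see
#'   [default_prior()].
#' @return list with `M` (selected count), `log_evidence` (named numeric,
#'   one entry per candidate) and `posteriors` (list of `nig_state`).
#' @export
select_harmonics <- function(reg, m_range = 1:5, prior_scale = 1e3,
                             alpha0 = 1e-3, beta0 = 1e-3) {
  stopifnot(inherits(reg, "regression_data"))
  m_range <- sort(unique(as.integer(m_range)))
  if (length(m_range) == 0L || any(m_range < 1L))
    stop("'m_range' must contain positive harmonic counts")
  M_max <- max(m_range)
  F <- build_design(reg, M_max)
  ss_full <- nig_suffstats(F, reg$delta)
  ns <- length(reg$senders)
  ev <- numeric(length(m_range))
  posts <- vector("list", length(m_range))
  for (k in seq_along(m_range)) {
    M <- m_range[k]
    idx <- submodel_columns(ns, M, M_max)
    ss <- list(FtF = ss_full$FtF[idx, idx, drop = FALSE],
               Ftd = ss_full$Ftd[idx], dtd = ss_full$dtd, T = ss_full$T)
    prior <- default_prior(length(idx), prior_scale, alpha0, beta0)
    up <- nig_update_stats(prior, ss)
    post <- up$post
    ev[k] <- 0.5 * (up$ld_new - up$ld_old) +
      prior$alpha * log(prior$beta) - post$alpha * log(post$beta) +
      lgamma(post$alpha) - lgamma(prior$alpha) - (ss$T / 2) * log(2 * pi)
    posts[[k]] <- post
  }
  names(ev) <- as.character(m_range)
  best <- which.max(ev)  # which.max returns the first (smallest M) on ties
  list(M = m_range[best], log_evidence = ev, posteriors = posts,
       column_map = attr(F, "column_map"))
}

#' Estimation settings
#'
#' @param dt sampling interval (ms); `NULL` = mean ISI of the observed units
#'   divided by 64.
#' @param m_range candidate harmonic counts.
#' @param prior_scale,alpha0,beta0 prior hyperparameters
#'   ([default_prior()]).
#' @return list of class `estimate_control`.
#' @export
estimate_control <- function(dt = NULL, m_range = 1:5, prior_scale = 1e3,
                             alpha0 = 1e-3, beta0 = 1e-3) {
  structure(list(dt = dt, m_range = m_range, prior_scale = prior_scale,
                 alpha0 = alpha0, beta0 = beta0), class = "estimate_control")
}

#' Fit the phase model for one receiver
#'
#' Full pipeline for a single receiver: interpolate phases of all observed
#' units on a shared grid, assemble the regression, select the harmonic
#' count by evidence, and return posterior summaries.  The first posterior
#' location entry is the effective frequency \eqn{\hat\omega} (which absorbs
#' the constant Fourier terms of all incoming couplings); the remaining
#' entries are the per-sender Fourier coefficients.  The noise intensity is
#' recovered from the posterior mean of \eqn{\sigma^2} as
#' \eqn{\hat D = E[\sigma^2]\,\Delta t/2}.
#'
#' @param dataset a [spike_dataset()].
#' @param receiver unit id to fit.
#' @param control an [estimate_control()].
#' @param units ids of the observed units (default all); must include
#'   `receiver`.  Restricting this emulates partial observation.
#' @param paths optionally, precomputed [phase_paths()] (shared across
#'   receivers to avoid recomputing interpolation).
#' @return object of class `phase_fit` with fields `receiver`, `senders`,
#'   `M`, `omega_hat` (rad/ms), `D_hat` (rad^2/ms), `couplings` (named list
#'   of [fourier_interaction()] posterior means), `coupling_sd` (posterior
#'   SDs of the coefficients, same shape), `posterior` ([nig_state()]),
#'   `log_evidence` (per candidate M), `dt`, `T`, `column_map`.
#' @export
fit_receiver <- function(dataset, receiver, control = estimate_control(),
                         units = NULL, paths = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (is.null(units)) units <- seq_len(dataset$n_units)
  if (!receiver %in% units) stop("'units' must include the receiver")
  if (is.null(paths)) paths <- phase_paths(dataset, dt = control$dt, units = units)
  reg <- build_regression(paths, receiver)
  sel <- select_harmonics(reg, m_range = control$m_range,
                          prior_scale = control$prior_scale,
                          alpha0 = control$alpha0, beta0 = control$beta0)
  post <- sel$posteriors[[match(sel$M, sort(unique(as.integer(control$m_range))))]]
  M <- sel$M
  coef_sd <- sqrt(pmax(post$beta / (post$alpha - 1), 0) * diag(post$Sigma))
  couplings <- list()
  coupling_sd <- list()
  ns <- length(reg$senders)
  for (js in seq_len(ns)) {
    block <- 1L + (js - 1L) * 2L * M
    cols <- block + seq_len(2L * M)
    a_idx <- cols[seq(1L, 2L * M, by = 2L)]
    b_idx <- cols[seq(2L, 2L * M, by = 2L)]
    key <- as.character(reg$senders[js])
    couplings[[key]] <- fourier_interaction(post$chi[a_idx], post$chi[b_idx])
    coupling_sd[[key]] <- list(a = coef_sd[a_idx], b = coef_sd[b_idx])
  }
  structure(list(receiver = as.integer(receiver), senders = reg$senders,
                 M = M, omega_hat = post$chi[1L],
                 D_hat = (post$beta / (post$alpha - 1)) * reg$dt / 2,
                 couplings = couplings, coupling_sd = coupling_sd,
                 posterior = post, log_evidence = sel$log_evidence,
                 dt = reg$dt, T = reg$T),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit> receiver", x$receiver, "- M =", x$M,
      ", omega_hat =", signif(x$omega_hat, 5), "rad/ms",
      ", D_hat =", signif(x$D_hat, 4), "rad^2/ms, T =", x$T, "\n")
  invisible(x)
}

#' Posterior-mean coupling from a fit
#'
#' @param fit a [fit_receiver()] result.
#' @param sender sender unit id.
#' @return the sender's estimated [fourier_interaction()].
#' @export
coupling_estimate <- function(fit, sender) {
  stopifnot(inherits(fit, "phase_fit"))
  f <- fit$couplings[[as.character(sender)]]
  if (is.null(f)) stop("sender ", sender, " was not among the observed units")
  f
}

#' Fit the phase model for every observed unit
#'
#' @inheritParams fit_receiver
#' @return object of class `phase_network_fit`: list of per-receiver
#'   [fit_receiver()] results (`fits`, named by receiver id) plus `units`
#'   and `dt`.
#' @export
fit_network <- function(dataset, control = estimate_control(), units = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (is.null(units)) units <- seq_len(dataset$n_units)
  paths <- phase_paths(dataset, dt = control$dt, units = units)
  fits <- lapply(units, function(u)
    fit_receiver(dataset, u, control = control, units = units, paths = paths))
  names(fits) <- as.character(units)
  structure(list(fits = fits, units = as.integer(units), dt = fits[[1L]]$dt),
            class = "phase_network_fit")
}

#' @export
print.phase_network_fit <- function(x, ...) {
  cat("<phase_network_fit>", length(x$fits), "receivers, dt =",
      signif(x$dt, 4), "ms\n")
  invisible(x)
}

#' Pointwise credible band of an estimated interaction function
#'
#' For each grid value of \eqn{\Delta\phi}, the linear functional
#' \eqn{g(\Delta\phi)^\top c} of the coefficients has a scaled Student-t
#' posterior marginal with \eqn{2\alpha} degrees of freedom and
#' scale\eqn{^2 = (\beta/\alpha)\, g^\top \Sigma g}; the band is the central
#' interval at the requested level (pointwise, not simultaneous).
#'
#' @param fit a [fit_receiver()] result.
#' @param sender sender unit id.
#' @param dphi_grid phase differences at which to evaluate (rad).
#' @param level credible level in `[0, 1)`; `level = 0` collapses the band
#'   onto the posterior mean.
#' @return data frame with columns `dphi`, `mean`, `lo`, `hi`.
#' @export
interaction_credible_band <- function(fit, sender,
                                      dphi_grid = seq(0, 2 * pi,
                                                      length.out = 129L),
                                      level = 0.95) {
  stopifnot(inherits(fit, "phase_fit"), level >= 0, level < 1)
  sender <- as.integer(sender)
  if (!sender %in% fit$senders) stop("sender must be an observed unit other than the receiver")
  js <- match(sender, fit$senders)
  post <- fit$posterior
  M <- fit$M
  G <- matrix(0, nrow = length(dphi_grid), ncol = post$P)
  block <- 1L + (js - 1L) * 2L * M
  for (m in seq_len(M)) {
    G[, block + 2L * m - 1L] <- cos(m * dphi_grid)
    G[, block + 2L * m] <- sin(m * dphi_grid)
  }
  mean <- drop(G %*% post$chi)
  scale2 <- (post$beta / post$alpha) * rowSums((G %*% post$Sigma) * G)
  half <- stats::qt((1 + level) / 2, df = 2 * post$alpha) * sqrt(pmax(scale2, 0))
  data.frame(dphi = dphi_grid, mean = mean, lo = mean - half, hi = mean + half)
}
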