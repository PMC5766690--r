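# Dense grid-quadrature oracle for the normal-inverse-gamma regression:
# integrates likelihood x prior over (c, sigma^2) numerically and returns
# posterior moments and the log marginal likelihood.  Deliberately
# independent of the package's closed-form update: grids are centred with an
# ordinary least-squares fit and the integrand is evaluated pointwise.
nig_grid_oracle <- function(F, delta, prior_scale = 1e3, alpha0 = 1e-3,
                            beta0 = 1e-3, n_c = 51L, n_s = 101L, k_sd = 7) {
  F <- as.matrix(F)
  P <- ncol(F)
  Tn <- length(delta)
  ls <- stats::lm.fit(F, delta)
  chat <- ls$coefficients
  s2hat <- sum(ls$residuals^2) / (Tn - P)
  XtX <- crossprod(F)
  sds <- sqrt(s2hat * diag(solve(XtX)))
  grids <- lapply(seq_len(P), function(k)
    seq(chat[k] - k_sd * sds[k], chat[k] + k_sd * sds[k], length.out = n_c))
  steps_c <- vapply(grids, function(g) g[2L] - g[1L], 1)
  Cmat <- as.matrix(expand.grid(grids))
  # sum of squares E(c) = |delta - F c|^2 via sufficient statistics
  quad <- rowSums((Cmat %*% XtX) * Cmat)
  cross <- drop(Cmat %*% crossprod(F, delta))
  Ec <- sum(delta^2) - 2 * cross + quad
  cc2 <- rowSums(Cmat^2)
  # integrate over log(sigma^2); generous range around the residual variance
  ls2 <- seq(log(s2hat / 8), log(s2hat * 8), length.out = n_s)
  h_s <- ls2[2L] - ls2[1L]
  slice_logmass <- numeric(n_s)
  slice_mc <- matrix(0, n_s, P)     # E[c | sigma^2] per slice
  slice_mc2 <- matrix(0, n_s, P)    # E[c^2 | sigma^2]
  for (si in seq_len(n_s)) {
    s2 <- exp(ls2[si])
    loglik <- -Tn / 2 * log(2 * pi * s2) - Ec / (2 * s2)
    logprior_c <- -P / 2 * log(2 * pi * s2 * prior_scale^2) -
      cc2 / (2 * s2 * prior_scale^2)
    logprior_s <- alpha0 * log(beta0) - lgamma(alpha0) -
      (alpha0 + 1) * log(s2) - beta0 / s2
    li <- loglik + logprior_c + logprior_s
    m <- max(li)
    w <- exp(li - m)
    sw <- sum(w)
    slice_logmass[si] <- m + log(sw) + sum(log(steps_c)) + log(h_s) + log(s2)
    slice_mc[si, ] <- colSums(w * Cmat) / sw
    slice_mc2[si, ] <- colSums(w * Cmat^2) / sw
  }
  m <- max(slice_logmass)
  w <- exp(slice_logmass - m)
  sw <- sum(w)
  s2g <- exp(ls2)
  post_mean_c <- colSums(w * slice_mc) / sw
  post_mean_c2 <- colSums(w * slice_mc2) / sw
  list(log_evidence = m + log(sw),
       mean_c = post_mean_c,
       var_c = post_mean_c2 - post_mean_c^2,
       mean_s2 = sum(w * s2g) / sw,
       var_s2 = sum(w * s2g^2) / sw - (sum(w * s2g) / sw)^2)
}

# fixed tiny regression instance used by the quadrature comparisons
tiny_regression_instance <- function(seed = 42L, Tn = 50L) {
  set.seed(seed)
  x <- stats::runif(Tn, 0, 2 * pi)
  F <- cbind(1, cos(x), sin(x))
  coef_true <- c(0.25, 0.01, -0.05)
  delta <- drop(F %*% coef_true) + stats::rnorm(Tn, 0, 0.05)
  list(F = F, delta = delta, coef = coef_true)
}
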