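#' Finite Fourier interaction function
#'
#' A 2\eqn{\pi}-periodic phase interaction function represented by a finite
#' Fourier series,
#' \deqn{\Gamma(\Delta\phi) = \sum_{m=1}^{M} a^{(m)} \cos(m\,\Delta\phi) +
#'       b^{(m)} \sin(m\,\Delta\phi),}
#' in units of rad/ms.  The constant term is deliberately absent: in the
#' phase model it is not separable from the natural frequency and is absorbed
#' into the effective frequency \eqn{\hat\omega}.
#'
#' @param a numeric vector of cosine coefficients, one per harmonic (rad/ms).
#' @param b numeric vector of sine coefficients, same length as `a` (rad/ms).
#' @return An object of class `fourier_interaction` with fields `M`, `a`, `b`.
#' @examples
#' f <- fourier_interaction(a = c(0.3, -0.1), b = c(0.2, 0.4))
#' eval_interaction(f, pi / 3)
#' @export
fourier_interaction <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 1L || length(a) != length(b))
    stop("'a' and 'b' must have equal length M >= 1")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("Fourier coefficients must be finite")
  structure(list(M = length(a), a = a, b = b), class = "fourier_interaction")
}

#' @export
print.fourier_interaction <- function(x, ...) {
  cat("<fourier_interaction> M =", x$M, "harmonics (rad/ms)\n")
  cat("  a:", signif(x$a, 4), "\n")
  cat("  b:", signif(x$b, 4), "\n")
  invisible(x)
}

is_fourier_interaction <- function(x) inherits(x, "fourier_interaction")

#' Evaluate an interaction function at phase differences
#'
#' @param f a [fourier_interaction()].
#' @param dphi numeric vector of phase differences (rad); any real value,
#'   periodicity is implicit in the trigonometric terms.
#' @return numeric vector, \eqn{\Gamma(\Delta\phi)} in rad/ms.
#' @export
eval_interaction <- function(f, dphi) {
  stopifnot(is_fourier_interaction(f))
  if (!is.numeric(dphi) || length(dphi) == 0L || !all(is.finite(dphi)))
    stop("'dphi' must be finite numeric")
  m <- seq_len(f$M)
  # rows: harmonics, cols: evaluation points
  arg <- outer(m, dphi)
  drop(crossprod(f$a, cos(arg)) + crossprod(f$b, sin(arg)))
}

#' Odd part of an interaction function
#'
#' The phase-difference dynamics of a symmetrically coupled pair are governed
#' by \eqn{\Gamma_{\mathrm{odd}}(\Delta\phi) = \Gamma(\Delta\phi) -
#' \Gamma(-\Delta\phi)}.  For a Fourier series the cosine (even) terms cancel
#' and the sine coefficients double.
#'
#' @param f a [fourier_interaction()].
#' @return A `fourier_interaction` with `a = 0` and `b = 2 * f$b`.
#' @export
odd_part <- function(f) {
  stopifnot(is_fourier_interaction(f))
  fourier_interaction(a = numeric(f$M), b = 2 * f$b)
}

#' Phase-difference dynamics of an asymmetric pair
#'
#' Generalizes [odd_part()] to a pair with unequal couplings: the phase
#' difference \eqn{\Delta\phi = \phi_i - \phi_j} of two equal-frequency
#' oscillators evolves as \eqn{\Gamma_{ij}(\Delta\phi) -
#' \Gamma_{ji}(-\Delta\phi)}.  With `f_ij == f_ji` this reduces to the odd
#' part.  This is an extension beyond the symmetric-pair analysis; its zeros
#' are the locked states of the specific ordered pair, not of a shared
#' coupling function.
#'
#' @param f_ij coupling from j onto i (a `fourier_interaction`).
#' @param f_ji coupling from i onto j.
#' @return A `fourier_interaction` for the difference dynamics:
#'   coefficients `a = a_ij - a_ji`, `b = b_ij + b_ji` (harmonics padded to
#'   the longer of the two).
#' @export
pair_difference_dynamics <- function(f_ij, f_ji) {
  stopifnot(is_fourier_interaction(f_ij), is_fourier_interaction(f_ji))
  M <- max(f_ij$M, f_ji$M)
  pad <- function(x) c(x, numeric(M - length(x)))
  fourier_interaction(a = pad(f_ij$a) - pad(f_ji$a),
                      b = pad(f_ij$b) + pad(f_ji$b))
}

# analytic derivative of the Fourier series at x
interaction_deriv <- function(f, x) {
  m <- seq_len(f$M)
  arg <- outer(m, x)
  drop(crossprod(-f$a * m, sin(arg)) + crossprod(f$b * m, cos(arg)))
}

#' Locked phase differences of a symmetric pair and their stability
#'
#' Finds the zeros of the odd part of `f` on \eqn{[0, 2\pi)} by a sign-change
#' scan on a uniform grid followed by bisection, and classifies each root by
#' the analytic derivative of the odd part's sine series: negative slope is a
#' stable locked state, positive slope unstable.  Slopes within
#' `degenerate_tol` of zero are labelled `"degenerate"` rather than silently
#' classified.
#'
#' @param f a [fourier_interaction()] (the shared pair coupling).
#' @param grid_n number of scan points on \eqn{[0, 2\pi)} (at least 64).
#' @param tol bisection tolerance on the root location (rad).
#' @param degenerate_tol slopes with absolute value below this are labelled
#'   degenerate.
#' @return An object of class `stability_result`: a data frame with columns
#'   `root` (rad, ascending), `slope` (rad/ms per rad) and `stability`
#'   (`"stable"`, `"unstable"` or `"degenerate"`).
#' @export
stable_phase_differences <- function(f, grid_n = 512L, tol = 1e-10,
                                     degenerate_tol = 1e-9) {
  stopifnot(is_fourier_interaction(f))
  if (grid_n < 64L) stop("'grid_n' must be at least 64")
  g <- odd_part(f)
  if (all(abs(g$b) < .Machine$double.eps * 10))
    stop("odd part is identically zero: every phase difference is neutral")
  gfun <- function(x) eval_interaction(g, x)
  x <- seq(0, 2 * pi, length.out = grid_n + 1L)
  v <- gfun(x)
  roots <- numeric(0)
  for (k in seq_len(grid_n)) {
    v1 <- v[k]; v2 <- v[k + 1L]
    if (v1 == 0) {
      roots <- c(roots, x[k])
    } else if (sign(v1) != sign(v2) && v2 != 0) {
      r <- stats::uniroot(gfun, lower = x[k], upper = x[k + 1L],
                          f.lower = v1, f.upper = v2, tol = tol)$root
      roots <- c(roots, r)
    }
  }
  roots <- roots %% (2 * pi)
  roots <- sort(roots)
  # merge duplicates (a zero sitting on a grid point is found twice)
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > max(tol * 10, 1e-8))
    # also merge wrap-around duplicate near 2*pi vs 0
    if ((2 * pi - roots[length(roots)]) + roots[1L] < max(tol * 10, 1e-8))
      keep[length(keep)] <- FALSE
    roots <- roots[keep]
  }
  slope <- interaction_deriv(g, roots)
  stability <- ifelse(abs(slope) <= degenerate_tol, "degenerate",
                      ifelse(slope < 0, "stable", "unstable"))
  structure(data.frame(root = roots, slope = slope,
                       stability = stability,
                       stringsAsFactors = FALSE),
            class = c("stability_result", "data.frame"))
}

#' @export
print.stability_result <- function(x, ...) {
  cat("<stability_result>", nrow(x), "root(s) of the odd part on [0, 2pi)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Least-squares Fourier fit of a sampled periodic function
#'
#' Fits \eqn{a_0 + \sum_m a_m \cos(m x) + b_m \sin(m x)} to samples of a
#' 2\eqn{\pi}-periodic function by linear least squares and returns the
#' harmonic part as a [fourier_interaction()] (the fitted constant is
#' reported separately, mirroring how the estimator absorbs it into
#' \eqn{\hat\omega}).
#'
#' @param x sample locations (rad).
#' @param y sampled values (rad/ms).
#' @param M number of harmonics to fit.
#' @return list with `interaction` (a `fourier_interaction`) and `constant`.
#' @export
fit_fourier_series <- function(x, y, M = 5L) {
  stopifnot(length(x) == length(y), M >= 1L, length(x) >= 2L * M + 1L)
  X <- cbind(1, do.call(cbind, lapply(seq_len(M), function(m)
    cbind(cos(m * x), sin(m * x)))))
  cf <- stats::lsfit(X, y, intercept = FALSE)$coefficients
  idx <- matrix(seq_len(2L * M) + 1L, nrow = 2L)
  list(interaction = fourier_interaction(a = cf[idx[1L, ]], b = cf[idx[2L, ]]),
       constant = unname(cf[1L]))
}
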