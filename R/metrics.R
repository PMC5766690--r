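#' L2 distance between interaction functions in coefficient space
#'
#' Both coefficient vectors are zero-padded per harmonic to `n_pad`
#' harmonics and compared term by term; unmodeled harmonics of either
#' function are penalized against zero.  Constant terms are excluded (the
#' estimator absorbs them into \eqn{\hat\omega}).  By default the square
#' root of the summed squared differences is returned, making this a true
#' metric on the padded coefficient vectors; `squared = TRUE` returns the
#' plain sum of squares.
#'
#' @param c_true,c_est [fourier_interaction()] objects.
#' @param n_pad number of harmonics after padding; at least
#'   `max(M_true, M_est)` (default: exactly that).
#' @param squared if `TRUE`, skip the square root.
#' @return scalar distance (rad/ms).
#' @export
l2_distance <- function(c_true, c_est, n_pad = NULL, squared = FALSE) {
  stopifnot(is_fourier_interaction(c_true), is_fourier_interaction(c_est))
  if (is.null(n_pad)) n_pad <- max(c_true$M, c_est$M)
  if (n_pad < max(c_true$M, c_est$M))
    stop("'n_pad' must be at least max(M_true, M_est)")
  pad <- function(x) c(x, numeric(n_pad - length(x)))
  ss <- sum((pad(c_true$a) - pad(c_est$a))^2) +
        sum((pad(c_true$b) - pad(c_est$b))^2)
  if (squared) ss else sqrt(ss)
}

#' Summed Fourier power of an interaction function
#'
#' \eqn{P = \sum_m (a^{(m)2} + b^{(m)2})}; the connection-strength
#' criterion used for connectivity inference.
#'
#' @param f a [fourier_interaction()].
#' @return scalar power ((rad/ms)^2).
#' @export
summed_power <- function(f) {
  stopifnot(is_fourier_interaction(f))
  sum(f$a^2) + sum(f$b^2)
}

#' Otsu threshold by exhaustive split search
#'
#' Scans the midpoints between consecutive sorted unique values and returns
#' the split maximizing the between-class variance
#' \eqn{\omega_0\omega_1(\mu_0-\mu_1)^2}, ties broken toward the smallest
#' threshold.  Exact for the few hundred values arising here (no histogram
#' binning).
#'
#' @param values numeric vector with at least two distinct values.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (length(unique(values)) < 2L)
    stop("degenerate input: all values identical, no threshold exists")
  n <- length(values)
  sv <- sort(values)
  csum <- cumsum(sv)
  best <- -Inf; thr <- NA_real_
  # split between sorted positions k and k+1 (only where the values differ)
  for (k in seq_len(n - 1L)) {
    if (sv[k + 1L] <= sv[k]) next
    w0 <- k / n; w1 <- 1 - w0
    mu0 <- csum[k] / k
    mu1 <- (csum[n] - csum[k]) / (n - k)
    bc <- w0 * w1 * (mu0 - mu1)^2
    if (bc > best * (1 + 1e-12)) { best <- bc; thr <- (sv[k] + sv[k + 1L]) / 2 }
  }
  thr
}

#' Matthews correlation coefficient of two binary adjacency matrices
#'
#' \deqn{\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
#' {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' over the off-diagonal entries (self-connections excluded).  If any
#' denominator factor is zero the conventional value 0 is returned with a
#' warning.
#'
#' @param w_est,w_act binary matrices of the same shape (`w[i, j] = 1`
#'   meaning an edge from sender j onto receiver i).
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(w_est, w_act) {
  w_est <- as.matrix(w_est); w_act <- as.matrix(w_act)
  if (!all(dim(w_est) == dim(w_act))) stop("shape mismatch")
  off <- row(w_est) != col(w_est)
  e <- w_est[off] != 0
  a <- w_act[off] != 0
  tp <- sum(e & a); tn <- sum(!e & !a)
  fp <- sum(e & !a); fn <- sum(!e & a)
  den2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (den2 == 0) {
    warning("MCC denominator has a zero factor; returning 0")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(den2)
}

#' Summed-power matrix of a network fit
#'
#' @param fit a [fit_network()] result.
#' @return square matrix over the observed units (rows = receivers,
#'   columns = senders), `NA` on the diagonal; entry (i, j) is the
#'   [summed_power()] of the posterior-mean interaction from j onto i.
#' @export
interaction_powers <- function(fit) {
  stopifnot(inherits(fit, "phase_network_fit"))
  units <- fit$units
  n <- length(units)
  P <- matrix(NA_real_, n, n, dimnames = list(units, units))
  for (i in seq_len(n)) {
    f <- fit$fits[[as.character(units[i])]]
    for (j in f$senders)
      P[i, match(j, units)] <- summed_power(f$couplings[[as.character(j)]])
  }
  P
}

#' Infer binary connectivity from interaction powers
#'
#' Normalizes the summed powers by their maximum, thresholds them with
#' [otsu_threshold()], and (when the true adjacency is supplied) scores the
#' result with [mcc()].
#'
#' @param x a [fit_network()] result or a numeric matrix of summed powers
#'   (rows = receivers, columns = senders, diagonal ignored).
#' @param truth optional true binary adjacency over the same units.
#' @return object of class `connectivity_inference`: `powers`,
#'   `normalized_powers`, `threshold`, `w_est` (binary matrix) and, with
#'   truth, `mcc` and the confusion counts.
#' @export
infer_connections <- function(x, truth = NULL) {
  P <- if (inherits(x, "phase_network_fit")) interaction_powers(x) else as.matrix(x)
  off <- row(P) != col(P)
  vals <- P[off]
  if (sum(is.finite(vals)) < 2L) stop("need at least 2 observed pairs")
  pmax_ <- max(vals, na.rm = TRUE)
  if (pmax_ <= 0) stop("degenerate input: all powers are zero")
  N <- P / pmax_
  thr <- otsu_threshold(N[off][is.finite(N[off])])
  w_est <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  w_est[off][which(N[off] > thr)] <- 1L
  out <- list(powers = P, normalized_powers = N, threshold = thr,
              w_est = w_est)
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    if (!all(dim(truth) == dim(P))) stop("truth adjacency shape mismatch")
    e <- w_est[off] != 0; a <- truth[off] != 0
    out$confusion <- c(TP = sum(e & a), FP = sum(e & !a),
                       TN = sum(!e & !a), FN = sum(!e & a))
    out$mcc <- mcc(w_est, truth)
  }
  structure(out, class = "connectivity_inference")
}

#' @export
print.connectivity_inference <- function(x, ...) {
  cat("<connectivity_inference> threshold =", signif(x$threshold, 4),
      ";", sum(x$w_est), "edges inferred\n")
  if (!is.null(x$mcc)) cat("  MCC =", signif(x$mcc, 4), "\n")
  invisible(x)
}

#' Pairwise spike-train coherence
#'
#' Bins the recording into windows of `bin_size` ms, marks each bin 1 if the
#' unit spiked in it (multiple spikes count once), and computes for each
#' pair \eqn{\kappa_{ij} = \sum_n x_i x_j / \sqrt{\sum_n x_i \sum_n x_j}}.
#' For synchronous populations the mean coherence saturates as the bin
#' grows; for asynchronous ones it rises roughly linearly before
#' saturating.
#'
#' @param dataset a [spike_dataset()].
#' @param bin_sizes numeric vector of bin widths (ms).
#' @param pairs optional 2-column matrix of unit-id pairs; default all
#'   unordered pairs.
#' @return object of class `coherence_result`: `bin_sizes`, `kappa_mean`
#'   (one per bin size), `kappa_pairs` (list of per-pair data frames) and
#'   `n_excluded` (pairs dropped because a unit had no occupied bin).
#' @export
coherence <- function(dataset, bin_sizes, pairs = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (any(bin_sizes <= 0)) stop("'bin_size' must be positive")
  n <- dataset$n_units
  if (n < 2L) stop("need at least two units")
  if (sum(vapply(dataset$spikes, length, 1L)) == 0L) stop("empty dataset")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2L))
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  kappa_mean <- numeric(length(bin_sizes))
  n_excluded <- integer(length(bin_sizes))
  kappa_pairs <- vector("list", length(bin_sizes))
  for (bi in seq_along(bin_sizes)) {
    b <- bin_sizes[bi]
    n_bins <- max(1L, ceiling((dataset$t_end - dataset$t_start) / b))
    occ <- lapply(dataset$spikes, function(s) {
      if (!length(s)) return(integer(0))
      unique(pmin(pmax(floor((s - dataset$t_start) / b), 0), n_bins - 1L))
    })
    counts <- vapply(occ, length, 1L)
    kap <- numeric(nrow(pairs))
    ok <- logical(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1L]; j <- pairs[p, 2L]
      if (counts[i] == 0L || counts[j] == 0L) { ok[p] <- FALSE; next }
      both <- length(intersect(occ[[i]], occ[[j]]))
      kap[p] <- both / sqrt(counts[i] * counts[j])
      ok[p] <- TRUE
    }
    kappa_mean[bi] <- mean(kap[ok])
    n_excluded[bi] <- sum(!ok)
    kappa_pairs[[bi]] <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                    kappa = ifelse(ok, kap, NA_real_))
  }
  structure(list(bin_sizes = bin_sizes, kappa_mean = kappa_mean,
                 kappa_pairs = kappa_pairs, n_excluded = n_excluded),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("<coherence_result>\n")
  print(data.frame(bin_ms = x$bin_sizes, kappa_mean = signif(x$kappa_mean, 4),
                   excluded_pairs = x$n_excluded))
  invisible(x)
}

#' L2 distances of a network fit against ground truth
#'
#' Computes [l2_distance()] between every estimated interaction (posterior
#' mean) and the corresponding true coupling (zero function for unconnected
#' pairs), over all ordered pairs of observed units.
#'
#' @param fit a [fit_network()] result.
#' @param net the `ground_truth_network` that generated the data.
#' @param n_pad harmonic padding (default 5, comfortably above the
#'   candidate range).
#' @param squared passed to [l2_distance()].
#' @return data frame with columns `receiver`, `sender`, `connected`,
#'   `distance`.
#' @export
l2_distance_table <- function(fit, net, n_pad = 5L, squared = FALSE) {
  stopifnot(inherits(fit, "phase_network_fit"),
            inherits(net, "ground_truth_network"))
  zero <- fourier_interaction(numeric(n_pad), numeric(n_pad))
  rows <- list()
  for (f in fit$fits) {
    for (j in f$senders) {
      truth <- coupling_of(net, f$receiver, j)
      connected <- !is.null(truth)
      if (!connected) truth <- zero
      rows[[length(rows) + 1L]] <- data.frame(
        receiver = f$receiver, sender = j, connected = connected,
        distance = l2_distance(truth, f$couplings[[as.character(j)]],
                               n_pad = n_pad, squared = squared))
    }
  }
  do.call(rbind, rows)
}
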