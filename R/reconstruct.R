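#' Common analysis window across units
#'
#' Phase is only defined between a unit's first and last spike, so the
#' shared analysis window is `[max of first spikes, min of last spikes]`.
#'
#' @param x a [spike_dataset()] or a list of numeric spike-time vectors.
#' @param units optional subset of unit ids to consider.
#' @return numeric `c(t_lo, t_hi)` in ms.
#' @export
common_window <- function(x, units = NULL) {
  spikes <- if (inherits(x, "spike_dataset")) x$spikes else x
  if (!is.null(units)) spikes <- spikes[units]
  if (any(vapply(spikes, length, 1L) < 2L))
    stop("every unit needs at least 2 spikes to define a phase")
  t_lo <- max(vapply(spikes, function(s) s[1L], 1))
  t_hi <- min(vapply(spikes, function(s) s[length(s)], 1))
  if (t_hi <= t_lo) stop("insufficient overlap: recordings are disjoint")
  c(t_lo, t_hi)
}

#' Interpolate spike times to an unwrapped phase path
#'
#' Defines each spike as phase zero (mod \eqn{2\pi}) and interpolates
#' linearly in between: for \eqn{t \in [t_s, t_{s+1})},
#' \eqn{\phi(t) = 2\pi s + 2\pi (t - t_s)/(t_{s+1} - t_s)} (unwrapped, so
#' \eqn{\phi} accumulates \eqn{2\pi} per cycle and increments are continuous
#' across spikes).  Samples are taken on the global grid
#' `window[1] + k * dt` restricted to the unit's spike span, so that paths
#' of different units share grid points.
#'
#' @param spikes sorted spike times of one unit (ms); at least 2.
#' @param dt sampling interval (ms).
#' @param window analysis window `c(t_lo, t_hi)` (ms) defining the grid
#'   origin; defaults to the unit's own spike span.
#' @param unit_id optional id carried along.
#' @return object of class `phase_path`: fields `unit_id`, `dt`, `t0`,
#'   `times`, `phi` (rad, unwrapped, 0 at the first spike of the window) and
#'   `spike_grid_marks` (grid indices just after each phase crossing of a
#'   multiple of \eqn{2\pi}).
#' @export
interpolate_phase <- function(spikes, dt, window = NULL, unit_id = NA_integer_) {
  spikes <- as.numeric(spikes)
  if (length(spikes) < 2L)
    stop("unit unusable: fewer than 2 spikes, phase undefined")
  if (is.unsorted(spikes, strictly = FALSE)) stop("spike times must be sorted")
  if (any(diff(spikes) <= 0)) stop("zero-length interspike interval")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive (ms)")
  if (is.null(window)) window <- c(spikes[1L], spikes[length(spikes)])
  t_lo <- max(window[1L], spikes[1L])
  t_hi <- min(window[2L], spikes[length(spikes)])
  if (t_hi <= t_lo) stop("window does not intersect the unit's spike span")
  k_lo <- ceiling((t_lo - window[1L]) / dt - 1e-9)
  k_hi <- floor((t_hi - window[1L]) / dt + 1e-9)
  if (k_hi < k_lo) stop("no grid points inside the window")
  times <- window[1L] + (k_lo:k_hi) * dt
  s <- findInterval(times, spikes, rightmost.closed = FALSE)
  s[s >= length(spikes)] <- length(spikes) - 1L  # last grid point at t_hi
  s[s < 1L] <- 1L
  isi <- spikes[s + 1L] - spikes[s]
  phi <- 2 * pi * ((s - 1L) + (times - spikes[s]) / isi)
  marks <- which(diff(floor(phi / (2 * pi) + 1e-12)) >= 1) + 1L
  structure(list(unit_id = unit_id, dt = dt, t0 = times[1L], times = times,
                 phi = phi, spike_grid_marks = marks, spikes = spikes),
            class = "phase_path")
}

#' @export
print.phase_path <- function(x, ...) {
  cat("<phase_path> unit", x$unit_id, "-", length(x$phi),
      "samples, dt =", x$dt, "ms,", length(x$spikes), "spikes\n")
  invisible(x)
}

#' Interpolate all units of a dataset on a shared grid
#'
#' Convenience wrapper: computes the [common_window()] of the chosen units
#' and returns one [interpolate_phase()] path per unit on the shared grid.
#'
#' @param dataset a [spike_dataset()].
#' @param dt sampling interval (ms); `NULL` selects half the mean interspike
#'   interval of the chosen units (two samples per mean cycle; see Details
#'   in the package vignette for why faster sampling is counterproductive).
#' @param units unit ids to include (default: all).
#' @return named list of `phase_path` objects.
#' @export
phase_paths <- function(dataset, dt = NULL, units = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (is.null(units)) units <- seq_len(dataset$n_units)
  win <- common_window(dataset, units)
  if (is.null(dt)) dt <- auto_dt(dataset, units)
  paths <- lapply(units, function(u)
    interpolate_phase(dataset$spikes[[u]], dt = dt, window = win, unit_id = u))
  names(paths) <- as.character(units)
  paths
}

# Default sampling interval: half the mean ISI over the chosen units, i.e.
# two samples per mean cycle.  Spike-interpolated phase carries essentially
# one increment of independent information per cycle (the ISI); sampling much
# faster only replicates interpolated values, which violates the likelihood's
# independence assumption by the oversampling factor and makes the model
# evidence grossly overconfident (it then selects the maximal harmonic count
# on single-harmonic data).  Two samples per cycle keep that factor ~2 while
# still resolving within-cycle curvature of the phase differences.
auto_dt <- function(dataset, units) {
  isi <- unlist(lapply(dataset$spikes[units], diff), use.names = FALSE)
  mean(isi) / 2
}

#' Assemble regression data for one receiver
#'
#' Builds the response vector \eqn{\delta(\tau) = (\phi_i(\tau+1) -
#' \phi_i(\tau))/\Delta t} (rad/ms) and the matrix of pairwise phase
#' differences \eqn{\Delta\phi_{ij}(\tau) = \phi_i(\tau) - \phi_j(\tau)} for
#' every other observed unit, truncated to the grid points all paths share.
#' Phase differences are used only inside sines/cosines downstream, so they
#' are left unwrapped.
#'
#' @param paths list of [interpolate_phase()] paths on a shared grid (see
#'   [phase_paths()]).
#' @param receiver unit id of the receiver (must be among the paths).
#' @return object of class `regression_data`: `receiver`, `senders`,
#'   `delta` (length T), `dphi` (T x n_senders matrix, columns named by
#'   sender id), `dt`, `T`.
#' @export
build_regression <- function(paths, receiver) {
  ids <- vapply(paths, function(p) as.integer(p$unit_id), 1L)
  names(paths) <- as.character(ids)
  rec <- as.character(receiver)
  if (!rec %in% names(paths)) stop("receiver not among the supplied paths")
  dts <- vapply(paths, `[[`, 1, "dt")
  if (max(dts) - min(dts) > 1e-12) stop("grid mismatch: unequal dt")
  # align on shared grid indices (paths share origin by construction)
  t0s <- vapply(paths, `[[`, 1, "t0")
  dt <- dts[[1L]]
  k0 <- round((t0s - min(t0s)) / dt)
  if (max(abs((t0s - min(t0s)) / dt - k0)) > 1e-6)
    stop("grid mismatch: paths are not on a common grid")
  t_lo <- max(t0s)
  t_hi <- min(vapply(paths, function(p) p$times[length(p$times)], 1))
  if (t_hi <= t_lo + dt / 2) stop("insufficient grid overlap between paths")
  sub <- lapply(paths, function(p) {
    i1 <- round((t_lo - p$t0) / dt) + 1L
    i2 <- round((t_hi - p$t0) / dt) + 1L
    p$phi[i1:i2]
  })
  n_grid <- length(sub[[rec]])
  Tn <- n_grid - 1L
  if (Tn < 1L) stop("not enough samples in the common window")
  delta <- diff(sub[[rec]]) / dt
  senders <- names(paths)[order(ids)]
  senders <- setdiff(senders, rec)
  dphi <- if (length(senders))
    vapply(senders, function(j) sub[[rec]][1:Tn] - sub[[j]][1:Tn],
           numeric(Tn))
  else matrix(numeric(0), nrow = Tn, ncol = 0L)
  dphi <- matrix(dphi, nrow = Tn, dimnames = list(NULL, senders))
  structure(list(receiver = as.integer(receiver),
                 senders = as.integer(senders),
                 delta = delta, dphi = dphi, dt = dt, T = Tn),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat("<regression_data> receiver", x$receiver, "-", x$T,
      "samples, dt =", signif(x$dt, 4), "ms,",
      length(x$senders), "senders\n")
  invisible(x)
}
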