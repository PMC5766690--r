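#' Read spike times from a TSV file
#'
#' Expected format: two tab-separated columns `unit_id<TAB>time_ms`, one
#' spike per line; lines starting with `#` are comments.  Times unsorted
#' within a unit are sorted with a warning; duplicate times within a unit
#' are deduplicated with a warning; negative times are an error.
#'
#' @param path file path.
#' @param n_units optional total unit count (ids without spikes get empty
#'   trains); default is the largest id seen.
#' @param t_start,t_end recording window (ms); defaults to `0` and the last
#'   spike time.
#' @return a [spike_dataset()].
#' @export
read_spikes <- function(path, n_units = NULL, t_start = NULL, t_end = NULL) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#",
                           col.names = c("unit_id", "time_ms"),
                           colClasses = c("integer", "numeric"))
  bad <- which(!is.finite(raw$time_ms) | is.na(raw$unit_id))
  if (length(bad))
    stop("malformed spike lines (after comment stripping) at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(raw$time_ms < 0)) stop("negative spike times are not allowed")
  n <- if (is.null(n_units)) max(raw$unit_id) else n_units
  spikes <- vector("list", n)
  for (u in seq_len(n)) {
    s <- raw$time_ms[raw$unit_id == u]
    if (is.unsorted(s)) {
      warning("unit ", u, ": spike times were unsorted; sorting")
      s <- sort(s)
    }
    if (anyDuplicated(s)) {
      warning("unit ", u, ": duplicate spike times removed")
      s <- unique(s)
    }
    spikes[[u]] <- s
  }
  if (is.null(t_start)) t_start <- 0
  if (is.null(t_end)) t_end <- max(raw$time_ms)
  spike_dataset(spikes, t_start = t_start, t_end = t_end)
}

#' Write spike times to a TSV file
#'
#' Inverse of [read_spikes()]: writes `unit_id<TAB>time_ms` sorted by time,
#' with a small `#`-prefixed header recording the window.
#'
#' @param dataset a [spike_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  df <- do.call(rbind, lapply(seq_len(dataset$n_units), function(u) {
    s <- dataset$spikes[[u]]
    if (!length(s)) return(NULL)
    data.frame(unit_id = u, time_ms = s)
  }))
  df <- df[order(df$time_ms, df$unit_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spike times (ms)",
               sprintf("# n_units=%d t_start=%.9g t_end=%.9g",
                       dataset$n_units, dataset$t_start, dataset$t_end)), con)
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fourier_to_list <- function(f) list(M = f$M, a = f$a, b = f$b)
fourier_from_list <- function(x) fourier_interaction(unlist(x$a), unlist(x$b))

#' Write / read a ground-truth network as JSON
#'
#' The schema is versioned (`format_version`); unknown fields present in a
#' file are preserved on a read/write round trip (kept in an `extras`
#' attribute).  Units: omega in rad/ms, D in rad^2/ms, coupling
#' coefficients in rad/ms.
#'
#' @param net a `ground_truth_network`.
#' @param path file path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the network.
#' @export
write_truth <- function(net, path) {
  stopifnot(inherits(net, "ground_truth_network"))
  obj <- list(format_version = 1L,
              n_units = net$n_units,
              omega = net$omega, D = net$D,
              period_mean = net$period_mean,
              adjacency = net$adjacency,
              couplings = lapply(net$couplings, fourier_to_list),
              seed = net$config$seed)
  extras <- attr(net, "extras")
  if (!is.null(extras)) obj <- c(obj, extras)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("format_version", "n_units", "omega", "D", "adjacency",
                "couplings", "period_mean")
  miss <- setdiff(required, names(obj))
  if (length(miss))
    stop("truth file is missing required field(s): /",
         paste(miss, collapse = ", /"))
  couplings <- lapply(obj$couplings, fourier_from_list)
  cfg <- synth_config(n_units = obj$n_units, k_in = 0L,
                      period_mean = obj$period_mean,
                      seed = if (!is.null(obj$seed)) obj$seed else 0L)
  net <- structure(list(n_units = as.integer(obj$n_units),
                        omega = as.numeric(obj$omega),
                        D = as.numeric(obj$D),
                        adjacency = matrix(as.integer(obj$adjacency),
                                           obj$n_units, obj$n_units),
                        couplings = couplings,
                        period_mean = obj$period_mean,
                        config = cfg),
                   class = "ground_truth_network")
  extras <- obj[setdiff(names(obj), c(required, "seed"))]
  if (length(extras)) attr(net, "extras") <- extras
  net
}

#' Write / read an estimated phase model as JSON
#'
#' Serializes a [fit_network()] result: per receiver the effective
#' frequency, noise intensity, selected harmonic count, per-sender Fourier
#' coefficients with posterior SDs, and the log evidence per candidate M.
#' The schema carries a `format_version`; unknown fields in a file survive
#' a round trip.
#'
#' @param fit a `phase_network_fit`.
#' @param path file path.
#' @return `write_model`: `path` invisibly; `read_model`: a list mirroring
#'   the file, with couplings revived as [fourier_interaction()] objects.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "phase_network_fit"))
  rec <- lapply(fit$fits, function(f) {
    list(receiver = f$receiver, M = f$M,
         omega_hat = f$omega_hat, D_hat = f$D_hat, dt = f$dt, T = f$T,
         log_evidence = as.list(f$log_evidence),
         couplings = lapply(f$couplings, fourier_to_list),
         coupling_sd = f$coupling_sd)
  })
  obj <- list(format_version = 1L, units = fit$units, dt = fit$dt,
              receivers = rec)
  extras <- attr(fit, "extras")
  if (!is.null(extras)) obj <- c(obj, extras)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  required <- c("format_version", "units", "receivers")
  miss <- setdiff(required, names(obj))
  if (length(miss))
    stop("model file is missing required field(s): /",
         paste(miss, collapse = ", /"))
  obj$units <- as.integer(unlist(obj$units))
  obj$receivers <- lapply(obj$receivers, function(r) {
    r$couplings <- lapply(r$couplings, fourier_from_list)
    r$log_evidence <- unlist(r$log_evidence)
    r
  })
  obj
}

#' Scenario configuration for seeded end-to-end experiments
#'
#' Describes a sweep experiment: a base synthetic network, estimator
#' settings, data lengths in cycles, replicate seeds, and one swept
#' variable (`sigma_rel`, `D`, `subset` for partial observation, or
#' `n_units` with the scaling preset of [scale_network_config()]).
#'
#' @param synth a [synth_config()] (the base condition).
#' @param control an [estimate_control()].
#' @param cycle_counts positive data lengths in mean cycles.
#' @param seeds distinct replicate seeds.
#' @param sweep name of the swept variable, or `"none"`.
#' @param sweep_values values of the swept variable (subset sizes for
#'   `"subset"`, size factors for `"n_units"`).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(synth = synth_config(), control = estimate_control(),
                            cycle_counts = c(100, 500, 1000),
                            seeds = 1:3,
                            sweep = c("none", "sigma_rel", "D", "subset",
                                      "n_units"),
                            sweep_values = NULL) {
  sweep <- match.arg(sweep)
  if (length(cycle_counts) == 0L || any(cycle_counts < 1))
    stop("'cycle_counts' must be a non-empty list of positive cycle counts")
  if (anyDuplicated(seeds)) stop("'seeds' must be distinct")
  if (sweep != "none" && (is.null(sweep_values) || length(sweep_values) == 0L))
    stop("'sweep_values' must be supplied for a sweep")
  if (sweep == "none") sweep_values <- NA
  structure(list(synth = synth, control = control,
                 cycle_counts = cycle_counts, seeds = as.integer(seeds),
                 sweep = sweep, sweep_values = sweep_values),
            class = "scenario_config")
}

# deterministic per-cell seed derived from the replicate seed and the cell
# index: cells are independent, so parallel or re-ordered execution yields
# identical results.  Kept below 2^31.
cell_seed <- function(seed, cell_idx) {
  (as.integer(seed) * 7919L + cell_idx * 104729L) %% 2147483647L
}

apply_sweep <- function(synth, sweep, value) {
  switch(sweep,
    none = synth,
    sigma_rel = { synth$sigma_rel <- value; synth },
    D = { synth$D <- value; synth },
    subset = synth,  # handled at fit time
    n_units = scale_network_config(synth, value))
}

#' Run a seeded sweep scenario end to end
#'
#' For every (seed, sweep value, cycle count) cell: generates the network,
#' simulates the longest requested data length once, fits the estimator on
#' each cycle-count prefix, and records the mean/median L2 distance over
#' ordered pairs, the connectivity MCC, and the mean coherence at a bin of
#' one tenth of the mean period.  Failures in a cell are recorded in the
#' `error` column and the run continues.
#'
#' @param cfg a [scenario_config()].
#' @param verbose print per-cell progress.
#' @return list with `results` (data frame, one row per cell) and
#'   `manifest` (config hash, seeds, per-cell runtimes, package version).
#' @export
run_scenario <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  rows <- list()
  times <- numeric(0)
  cell_idx <- 0L
  for (sv in cfg$sweep_values) {
    synth <- apply_sweep(cfg$synth, cfg$sweep, sv)
    for (seed in cfg$seeds) {
      cell_idx <- cell_idx + 1L
      cs <- cell_seed(seed, cell_idx)
      t0 <- proc.time()[["elapsed"]]
      cell <- tryCatch({
        synth$seed <- cs
        net <- generate_network(synth)
        dur_max <- cycles_to_duration(net, max(cfg$cycle_counts))
        ds_full <- simulate_phases(net, dur_max, seed = cs + 1L)
        units <- seq_len(net$n_units)
        if (cfg$sweep == "subset")
          units <- sort(sample(seq_len(net$n_units), sv))
        lapply(cfg$cycle_counts, function(nc) {
          dur <- cycles_to_duration(net, nc)
          ds <- truncate_dataset(ds_full, dur)
          fit <- fit_network(ds, control = cfg$control, units = units)
          tab <- l2_distance_table(fit, net)
          inf <- infer_connections(fit,
            truth = net$adjacency[units, units, drop = FALSE])
          coh <- coherence(ds, bin_sizes = net$period_mean / 10)
          data.frame(seed = seed, cell_seed = cs, sweep = cfg$sweep,
                     sweep_value = if (is.na(sv)) NA else sv,
                     cycles = nc, n_units_fit = length(units),
                     l2_mean = mean(tab$distance),
                     l2_median = stats::median(tab$distance),
                     mcc = inf$mcc, kappa = coh$kappa_mean,
                     error = NA_character_)
        })
      }, error = function(e) {
        list(data.frame(seed = seed, cell_seed = cs, sweep = cfg$sweep,
                        sweep_value = if (is.na(sv)) NA else sv,
                        cycles = NA, n_units_fit = NA,
                        l2_mean = NA, l2_median = NA, mcc = NA, kappa = NA,
                        error = conditionMessage(e)))
      })
      times <- c(times, proc.time()[["elapsed"]] - t0)
      rows <- c(rows, cell)
      if (verbose)
        message("cell ", cell_idx, " (seed ", seed, ", value ", sv, ") done")
    }
  }
  results <- do.call(rbind, rows)
  manifest <- list(config_hash = config_hash(cfg),
                   package_version = as.character(utils::packageVersion("phasebayes")),
                   cell_runtimes_s = times)
  list(results = results, manifest = manifest)
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Truncate a spike dataset to an initial time window
#'
#' @param dataset a [spike_dataset()].
#' @param t_end new end of the window (ms).
#' @return a [spike_dataset()] on `[t_start, t_end]`.
#' @export
truncate_dataset <- function(dataset, t_end) {
  stopifnot(inherits(dataset, "spike_dataset"), t_end > dataset$t_start)
  spikes <- lapply(dataset$spikes, function(s) s[s <= t_end])
  spike_dataset(spikes, t_start = dataset$t_start, t_end = t_end)
}
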