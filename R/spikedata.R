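#' Trial-structured spike trains for one neuron
#'
#' Container for repeated-trial spike times of a single neuron on a common
#' clock.  Times are in seconds, 0-based within each trial, and must be
#' strictly increasing and lie in \code{(0, trial_length]}.
#'
#' @param trials named list of numeric vectors of spike times (seconds); names
#'   are trial identifiers.  Empty trials are retained.
#' @param trial_length trial duration \code{T} in seconds.
#' @param neuron_id label for the neuron.
#' @return an object of class \code{"spike_trains"}.
#' @examples
#' spike_train_set(list(`1` = c(0.01, 0.02)), trial_length = 2)
#' @export
spike_train_set <- function(trials, trial_length, neuron_id = "neuron") {
  .check(is.list(trials), "`trials` must be a list of numeric vectors")
  .check(is.numeric(trial_length) && trial_length > 0,
         "`trial_length` must be a positive number")
  if (is.null(names(trials))) names(trials) <- seq_along(trials)
  for (id in names(trials)) {
    tt <- trials[[id]]
    if (length(tt) == 0) next
    .check(all(diff(tt) > 0),
           "spike times not strictly increasing in trial %s", id)
    .check(all(tt > 0 & tt <= trial_length),
           "spike time outside (0, T] in trial %s", id)
    trials[[id]] <- as.numeric(tt)
  }
  structure(list(neuron_id = neuron_id, trials = trials,
                 trial_length = as.numeric(trial_length)),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  ns <- lengths(x$trials)
  cat(sprintf("Spike trains: neuron '%s', %d trial(s) of %.3g s\n",
              x$neuron_id, length(x$trials), x$trial_length))
  cat(sprintf("  %d spikes total, mean rate %.2f Hz\n", sum(ns),
              sum(ns) / (length(x$trials) * x$trial_length)))
  invisible(x)
}

#' Read spike trains from delimited text
#'
#' Expects a header \code{trial_id,neuron_id,spike_time_s} (comma or tab
#' separated).  Returns one \code{\link{spike_train_set}} per neuron; a trial
#' listed in \code{trials} (or seen for any neuron) with no rows for some
#' neuron is kept as an empty trial for that neuron.
#'
#' @param path file path.
#' @param trial_length trial duration in seconds; rows with
#'   \code{spike_time_s > trial_length} are rejected with their row index.
#' @param trials optional character vector of trial ids (the trial manifest).
#' @param sep field separator, \code{","} by default.
#' @return named list of \code{spike_trains}, one per neuron.
#' @export
read_spike_trains <- function(path, trial_length, trials = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("trial_id", "neuron_id", "spike_time_s")
  .check(all(need %in% names(df)),
         "file must have columns trial_id, neuron_id, spike_time_s")
  bad <- which(df$spike_time_s > trial_length | df$spike_time_s <= 0)
  if (length(bad))
    stop(sprintf("spike_time_s outside (0, T] at data row %d (t = %g, T = %g)",
                 bad[1], df$spike_time_s[bad[1]], trial_length), call. = FALSE)
  all_trials <- unique(c(as.character(trials), as.character(df$trial_id)))
  out <- list()
  for (nid in unique(as.character(df$neuron_id))) {
    sub <- df[df$neuron_id == nid, , drop = FALSE]
    tr <- lapply(all_trials, function(id) {
      rows <- which(as.character(sub$trial_id) == id)
      tt <- sub$spike_time_s[rows]
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        k <- which(diff(tt) <= 0)[1]
        stop(sprintf(
          "non-monotone spike times for neuron %s trial %s at data row %s",
          nid, id, rownames(sub)[rows[k + 1]]), call. = FALSE)
      }
      tt
    })
    names(tr) <- all_trials
    out[[nid]] <- spike_train_set(tr, trial_length, neuron_id = nid)
  }
  out
}

#' Write spike trains to delimited text
#'
#' Emits the same dialect \code{\link{read_spike_trains}} reads, at full
#' double precision so a round trip reproduces times exactly.
#'
#' @param x a \code{spike_trains} object or list of them.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_spike_trains <- function(x, path, sep = ",") {
  if (inherits(x, "spike_trains")) x <- list(x)
  rows <- c("trial_id,neuron_id,spike_time_s")
  if (sep != ",") rows <- gsub(",", sep, rows, fixed = TRUE)
  for (st in x) {
    for (id in names(st$trials)) {
      tt <- st$trials[[id]]
      if (length(tt))
        rows <- c(rows, sprintf("%s%s%s%s%.17g", id, sep, st$neuron_id, sep, tt))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Oscillation phase series on the model bin grid
#'
#' Generates the instantaneous phase \eqn{\Phi_t = \mathrm{wrap}(\phi_0 + 2\pi
#' f t)} of a constant-frequency oscillation, sampled at bin left edges, one
#' column per trial.  The initial phase is either fixed or drawn uniformly on
#' \eqn{[-\pi,\pi)} per trial (and can be shared across a neuron pair by
#' reusing the returned object).
#'
#' @param freq oscillation frequency in Hz.
#' @param trial_length trial duration in seconds.
#' @param n_trials number of trials.
#' @param delta bin width in seconds (default 1 ms).
#' @param rule \code{"random"} (uniform initial phase per trial) or
#'   \code{"fixed"}.
#' @param phi0 initial phase used when \code{rule = "fixed"}.
#' @param seed optional integer seed.
#' @return a \code{"phase_series"} object: a K x n_trials matrix of phases in
#'   \eqn{[-\pi,\pi)} with attributes \code{delta}, \code{times} (bin left
#'   edges), \code{freq}, \code{phi0} (per-trial initial phases).
#' @examples
#' ph <- make_oscillation(40, 2, 3, rule = "fixed", phi0 = 0)
#' @export
make_oscillation <- function(freq, trial_length, n_trials, delta = 1e-3,
                             rule = c("random", "fixed"), phi0 = 0,
                             seed = NULL) {
  rule <- match.arg(rule)
  .check(freq > 0, "`freq` must be positive")
  if (!is.null(seed)) set.seed(seed)
  K <- round(trial_length / delta)
  times <- (seq_len(K) - 1) * delta
  p0 <- if (rule == "random") runif(n_trials, -pi, pi) else rep(phi0, n_trials)
  ph <- wrap_phase(outer(2 * pi * freq * times, p0, `+`))
  phase_series(ph, delta = delta, freq = freq, phi0 = p0)
}

#' Construct a phase series from a matrix of phases
#'
#' @param phase K x n_trials matrix of phases (radians; wrapped internally).
#' @param delta sampling interval (the model bin width), seconds.
#' @param freq optional nominal frequency (Hz), for metadata only.
#' @param phi0 optional per-trial initial phases.
#' @return a \code{"phase_series"} object.
#' @export
phase_series <- function(phase, delta, freq = NA_real_, phi0 = NULL) {
  phase <- as.matrix(phase)
  structure(wrap_phase(phase), delta = delta,
            times = (seq_len(nrow(phase)) - 1) * delta,
            freq = freq, phi0 = phi0, class = "phase_series")
}

#' Bin spike trains onto the model grid
#'
#' Divides each trial of length \code{T} into \code{K = T/delta} half-open
#' bins \eqn{[t_k - \Delta, t_k)}; a spike exactly on a boundary belongs to
#' the later bin.  Each bin must contain at most one spike.  For bin \code{k}
#' the last-spike lag is the bin's left edge minus the most recent spike time
#' before it; bins preceding a trial's first spike are flagged as having no
#' history.
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param phase optional \code{\link{phase_series}} with matching grid
#'   (required to fit phase-modulated models).
#' @param delta bin width in seconds, default 1 ms.
#' @return an object of class \code{"binned_design"} with elements
#'   \code{counts} (K x n 0/1 matrix), \code{lag} (K x n last-spike lag in
#'   seconds, \code{NA} where no history), \code{phase} (K x n or NULL),
#'   \code{times} (bin left edges), \code{delta}, \code{trial_length},
#'   \code{trial_ids}, \code{spike_times} (the original per-trial times).
#' @export
bin_spikes <- function(spikes, phase = NULL, delta = 1e-3) {
  .check(inherits(spikes, "spike_trains"), "`spikes` must be a spike_trains object")
  T <- spikes$trial_length
  K <- round(T / delta)
  .check(abs(K * delta - T) < 1e-9, "trial_length must be a multiple of delta")
  n <- length(spikes$trials)
  if (!is.null(phase)) {
    .check(nrow(phase) == K && ncol(phase) == n,
           "phase series grid (%d x %d) does not match design (%d x %d)",
           nrow(phase), ncol(phase), K, n)
    .check(abs(attr(phase, "delta") - delta) < 1e-12,
           "phase series bin width differs from `delta`")
  }
  counts <- matrix(0L, K, n)
  lag <- matrix(NA_real_, K, n)
  times <- (seq_len(K) - 1) * delta
  for (j in seq_len(n)) {
    tt <- spikes$trials[[j]]
    if (length(tt)) {
      idx <- pmin(floor(tt / delta) + 1L, K)
      if (anyDuplicated(idx)) {
        d <- idx[duplicated(idx)][1]
        stop(sprintf(
          "two spikes fall in bin %d of trial %s; use a smaller delta",
          d, names(spikes$trials)[j]), call. = FALSE)
      }
      counts[idx, j] <- 1L
      prev <- findInterval(times - 1e-12, tt)
      has <- prev > 0
      lag[has, j] <- times[has] - tt[prev[has]]
    }
  }
  structure(list(counts = counts, lag = lag,
                 phase = if (!is.null(phase)) unclass(phase)[, , drop = FALSE],
                 times = times, delta = delta, trial_length = T,
                 trial_ids = names(spikes$trials),
                 spike_times = spikes$trials),
            class = "binned_design")
}

#' @export
print.binned_design <- function(x, ...) {
  cat(sprintf("Binned design: %d bins x %d trials (delta = %g ms, T = %g s)\n",
              nrow(x$counts), ncol(x$counts), x$delta * 1e3, x$trial_length))
  cat(sprintf("  %d spikes; phase covariate: %s\n", sum(x$counts),
              if (is.null(x$phase)) "absent" else "present"))
  invisible(x)
}

## internal: rebuild a binned design directly from a 0/1 count matrix
## (spike event times taken at bin centers), used by the parametric bootstrap.
.design_from_counts <- function(counts, delta, phase = NULL, trial_length = NULL) {
  K <- nrow(counts)
  if (is.null(trial_length)) trial_length <- K * delta
  lagb <- lag_bins_cpp(counts)
  lag <- ifelse(lagb > 0, (lagb - 0.5) * delta, NA_real_)
  st <- lapply(seq_len(ncol(counts)),
               function(j) (which(counts[, j] > 0) - 0.5) * delta)
  names(st) <- as.character(seq_len(ncol(counts)))
  structure(list(counts = counts, lag = lag,
                 phase = if (!is.null(phase)) unclass(phase)[, , drop = FALSE],
                 times = (seq_len(K) - 1) * delta, delta = delta,
                 trial_length = trial_length,
                 trial_ids = names(st), spike_times = st),
            class = "binned_design")
}

## internal: spike_trains from a 0/1 count matrix (bin-center convention)
.spikes_from_counts <- function(counts, delta, trial_length = NULL,
                                neuron_id = "sim") {
  if (is.null(trial_length)) trial_length <- nrow(counts) * delta
  tr <- lapply(seq_len(ncol(counts)),
               function(j) (which(counts[, j] > 0) - 0.5) * delta)
  names(tr) <- as.character(seq_len(ncol(counts)))
  spike_train_set(tr, trial_length, neuron_id = neuron_id)
}
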