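#' Band-pass filter an LFP trace (zero phase)
#'
#' Chebyshev type II design with at least 40 dB stopband attenuation,
#' applied forward and backward (\code{filtfilt}) so the output has zero
#' phase distortion — essential because the instantaneous phase of the
#' filtered trace feeds the spiking model, and a causal filter would bias
#' preferred-phase estimates.  Stopband edges are placed at
#' \code{0.6 * band[1]} and \code{1.6 * band[2]}.
#'
#' @param x numeric vector (one trace) or matrix (one column per channel).
#' @param fs sampling rate, Hz.
#' @param band passband \code{c(lo, hi)} in Hz (default 4–25 Hz).
#' @param order filter order per pass (default 4).
#' @param stopband_db stopband attenuation in dB (default 40).
#' @return filtered trace(s), same shape as \code{x}; attributes
#'   \code{band}, \code{order}, \code{stopband_db} record the design.
#' @export
lfp_bandpass <- function(x, fs, band = c(4, 25), order = 4,
                         stopband_db = 40) {
  .check(band[1] > 0 && band[2] > band[1], "invalid passband")
  .check(1.6 * band[2] < fs / 2,
         "passband too close to the Nyquist frequency %g Hz", fs / 2)
  Ws <- c(0.6 * band[1], 1.6 * band[2]) / (fs / 2)
  flt <- signal::cheby2(order, stopband_db, Ws, type = "pass")
  run <- function(v) signal::filtfilt(flt, v)
  out <- if (is.matrix(x)) apply(x, 2, run) else run(x)
  attr(out, "band") <- band
  attr(out, "order") <- order
  attr(out, "stopband_db") <- stopband_db
  out
}

#' Instantaneous phase via the analytic signal
#'
#' Hilbert-transform phase of a (narrowband) trace: the angle of the
#' analytic signal built in the frequency domain.  With the cosine
#' convention the phase is 0 at local maxima of the trace.
#'
#' @param x numeric vector, a band-limited trace.
#' @return phases in \eqn{[-\pi, \pi)}, same length as \code{x}.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' ph <- instantaneous_phase(cos(2 * pi * 10 * t))
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- fft(X * h, inverse = TRUE) / n
  wrap_phase(Arg(a))
}

#' Electrode array layout
#'
#' Rectangular grid layout mapping channel labels to (row, col) positions,
#' with an optional set of missing channels, for neighbor queries on
#' multi-electrode arrays.
#'
#' @param rows,cols grid dimensions.
#' @param missing character vector of absent channel labels.
#' @param labels channel labels in row-major order; default
#'   \code{ch_1 ... ch_{rows*cols}}.
#' @return object of class \code{"electrode_layout"}.
#' @export
electrode_layout <- function(rows, cols, missing = character(),
                             labels = NULL) {
  n <- rows * cols
  if (is.null(labels)) labels <- sprintf("ch_%d", seq_len(n))
  .check(length(labels) == n && !anyDuplicated(labels),
         "need %d unique channel labels", n)
  pos <- data.frame(label = labels,
                    row = rep(seq_len(rows), each = cols),
                    col = rep(seq_len(cols), rows),
                    present = !(labels %in% missing),
                    stringsAsFactors = FALSE)
  structure(list(rows = rows, cols = cols, pos = pos),
            class = "electrode_layout")
}

#' Neighbors of a channel on the array
#'
#' @param layout an \code{\link{electrode_layout}}.
#' @param channel channel label.
#' @param adjacency 8 (default, includes diagonals) or 4.
#' @return character vector of present neighboring channel labels (never the
#'   query channel itself).
#' @export
array_neighbors <- function(layout, channel, adjacency = 8) {
  p <- layout$pos
  k <- match(channel, p$label)
  .check(!is.na(k), "channel '%s' not in layout", channel)
  dr <- abs(p$row - p$row[k]); dc <- abs(p$col - p$col[k])
  near <- if (adjacency == 8) pmax(dr, dc) == 1 else dr + dc == 1
  p$label[near & p$present]
}

#' Neighbor-averaged LFP for a channel
#'
#' The LFP assigned to a neuron is the unweighted mean of the traces on the
#' electrodes adjacent to its own, which avoids spike-waveform bleed-through
#' from the neuron's own electrode.  Edge and corner channels use their
#' available neighbors.
#'
#' @param lfp numeric matrix, one column per channel, with column names
#'   matching the layout labels.
#' @param layout an \code{\link{electrode_layout}}.
#' @param channel channel label whose surround is averaged.
#' @param adjacency 8 (default) or 4.
#' @return numeric vector, the averaged trace.
#' @export
neighbor_average <- function(lfp, layout, channel, adjacency = 8) {
  nb <- array_neighbors(layout, channel, adjacency)
  nb <- intersect(nb, colnames(lfp))
  .check(length(nb) > 0, "channel '%s' has no available neighbors", channel)
  rowMeans(lfp[, nb, drop = FALSE])
}

#' Spike-triggered average of an LFP trace
#'
#' Mean LFP segment aligned to spike times.  Spikes whose window would be
#' clipped by the trial edges are excluded and their count reported.
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param lfp numeric matrix, one column per trial, sampled at \code{fs}
#'   from time 0.
#' @param fs sampling rate, Hz.
#' @param window \code{c(pre, post)} in seconds around each spike.
#' @return list with \code{lag} (seconds), \code{sta} (mean trace),
#'   \code{n_spikes} (used), \code{n_clipped}.
#' @export
spike_triggered_average <- function(spikes, lfp, fs, window = c(0.1, 0.1)) {
  lfp <- as.matrix(lfp)
  .check(ncol(lfp) == length(spikes$trials),
         "lfp must have one column per trial")
  pre <- round(window[1] * fs); post <- round(window[2] * fs)
  n <- nrow(lfp)
  segs <- list(); clipped <- 0L
  for (j in seq_along(spikes$trials)) {
    for (t in spikes$trials[[j]]) {
      k <- round(t * fs) + 1L
      if (k - pre < 1 || k + post > n) { clipped <- clipped + 1L; next }
      segs[[length(segs) + 1]] <- lfp[(k - pre):(k + post), j]
    }
  }
  .check(length(segs) > 0, "all spike windows are clipped; nothing to average")
  M <- do.call(rbind, segs)
  list(lag = seq(-pre, post) / fs, sta = colMeans(M),
       n_spikes = length(segs), n_clipped = clipped)
}

#' Phase series from per-trial LFP traces
#'
#' End-to-end helper: band-pass each trial's LFP, take the Hilbert phase,
#' and resample onto the model bin grid (bin left edges).  The first and
#' last \code{edge_flag} seconds of each trial are subject to filter edge
#' effects; their bin indices are returned so fits can exclude them.
#'
#' @param lfp numeric matrix, one column per trial, sampled at \code{fs}.
#' @param fs LFP sampling rate, Hz.
#' @param trial_length trial duration, seconds.
#' @param delta model bin width (default 1 ms).
#' @param band passband in Hz (default 4–25).
#' @param edge_flag edge margin flagged per trial end, seconds (default 0.5).
#' @return a \code{\link{phase_series}}; attribute \code{edge_bins} holds the
#'   flagged bin indices.
#' @export
lfp_phase_series <- function(lfp, fs, trial_length, delta = 1e-3,
                             band = c(4, 25), edge_flag = 0.5) {
  lfp <- as.matrix(lfp)
  filt <- lfp_bandpass(lfp, fs, band)
  K <- round(trial_length / delta)
  times <- (seq_len(K) - 1) * delta
  src_t <- (seq_len(nrow(lfp)) - 1) / fs
  ph <- apply(as.matrix(filt), 2, function(v) {
    p <- instantaneous_phase(v)
    ## interpolate the unwrapped phase so wrapping points do not corrupt it
    up <- p + 2 * pi * cumsum(c(0, diff(p) < -pi)) -
      2 * pi * cumsum(c(0, diff(p) > pi))
    wrap_phase(approx(src_t, up, xout = times, rule = 2)$y)
  })
  out <- phase_series(ph, delta = delta)
  ne <- round(edge_flag / delta)
  attr(out, "edge_bins") <- unique(pmin(pmax(c(seq_len(ne), K - ne + seq_len(ne)), 1), K))
  out
}

#' Read multi-channel LFP traces from delimited text
#'
#' Expects a header \code{time_s, ch_<1>, ch_<2>, ...} with a uniform time
#' grid.  Returns the trace matrix (one column per channel) with the
#' sampling rate attached.
#'
#' @param path file path.
#' @param sep field separator, \code{","} by default.
#' @return numeric matrix with channel columns; attributes \code{fs}
#'   (sampling rate, Hz) and \code{time} (the time column).
#' @export
read_lfp <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE)
  .check("time_s" %in% names(df), "file must have a time_s column")
  tt <- df$time_s
  dt <- diff(tt)
  .check(length(dt) >= 1 && max(abs(dt - dt[1])) < 1e-9 * max(abs(tt), 1),
         "time_s must be a uniform grid")
  out <- as.matrix(df[setdiff(names(df), "time_s")])
  attr(out, "fs") <- 1 / dt[1]
  attr(out, "time") <- tt
  out
}

#' Write multi-channel LFP traces to delimited text
#'
#' Emits the dialect \code{\link{read_lfp}} reads.
#'
#' @param x numeric matrix, one column per channel.
#' @param path output file path.
#' @param fs sampling rate, Hz.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_lfp <- function(x, path, fs, sep = ",") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("ch_%d", seq_len(ncol(x)))
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1) / fs, x,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
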