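#' Generator specification for oscillation-driven GLM neurons
#'
#' Describes a ground-truth conditional intensity
#' \eqn{\lambda(t\mid H_t,\Phi_t) = \lambda_1(t)\,\lambda_2(t-t^*)\,
#' \lambda_3(\Phi_t)} together with the oscillatory drive.  The component
#' curves are plain R functions; see \code{\link{stim_constant}},
#' \code{\link{stim_fluctuating}}, \code{\link{hist_refractory}},
#' \code{\link{phase_cosine}} for standard shapes.
#'
#' @param stimulus function of trial time returning a rate in Hz.
#' @param history function of lag (s) returning a positive multiplier;
#'   \code{\link{hist_poisson}} for Poisson firing.
#' @param phase_mod function of phase returning a positive multiplier,
#'   normalized so \eqn{(1/2\pi)\int \lambda_3 = 1} when used as ground truth
#'   for recovery tests.
#' @param freq oscillation frequency, Hz.
#' @param trial_length,n_trials,delta trial geometry (seconds / count /
#'   seconds).
#' @param phase_rule,phi0 initial-phase rule per trial, see
#'   \code{\link{make_oscillation}}.
#' @return an object of class \code{"sim_spec"}.
#' @export
sim_spec <- function(stimulus = stim_constant(25),
                     history = hist_refractory(),
                     phase_mod = phase_cosine(0.4, pref = pi),
                     freq = 40, trial_length = 2, n_trials = 100,
                     delta = 1e-3, phase_rule = c("random", "fixed"),
                     phi0 = 0) {
  phase_rule <- match.arg(phase_rule)
  structure(list(stimulus = stimulus, history = history,
                 phase_mod = phase_mod, freq = freq,
                 trial_length = trial_length, n_trials = n_trials,
                 delta = delta, phase_rule = phase_rule, phi0 = phi0),
            class = "sim_spec")
}

#' Standard ground-truth component curves
#'
#' \code{stim_constant}: flat stimulus rate.  \code{stim_fluctuating}: a
#' smooth multiplicatively modulated rate
#' \eqn{r\,e^{d\sin(2\pi f_s t)}/E[e^{d\sin}]} whose mean is exactly
#' \code{rate}.  \code{hist_refractory}: sigmoidal relative-refractory
#' multiplier \eqn{1/(1+e^{-(\tau - t_{ref})/s})}, near 0 for lags below
#' \code{t_ref} and 1 beyond.  \code{hist_poisson}: constant 1 (Poisson
#' firing).  \code{phase_cosine}: \eqn{1 + a\cos(\phi - \phi_{pref})}, the
#' sinusoidal phase modulation with preferred phase \eqn{\phi_{pref}}; its
#' phase-average is 1.
#'
#' @param rate mean firing rate, Hz.
#' @param depth log-modulation depth of the fluctuating stimulus.
#' @param f_slow slow stimulus frequency, Hz.
#' @param t_ref refractory midpoint, seconds.
#' @param steep refractory steepness, seconds.
#' @param a modulation amplitude in (0, 1).
#' @param pref preferred phase, radians.
#' @return a function usable in \code{\link{sim_spec}}.
#' @name truth-curves
NULL

#' @rdname truth-curves
#' @export
stim_constant <- function(rate = 25) {
  force(rate)
  function(t) rep(rate, length(t))
}

#' @rdname truth-curves
#' @export
stim_fluctuating <- function(rate = 25, depth = 0.4, f_slow = 1.5) {
  force(rate); force(depth); force(f_slow)
  g <- seq(0, 1, length.out = 4096)
  norm <- mean(exp(depth * sin(2 * pi * g)))
  function(t) rate * exp(depth * sin(2 * pi * f_slow * t)) / norm
}

#' @rdname truth-curves
#' @export
hist_refractory <- function(t_ref = 0.003, steep = 0.001) {
  force(t_ref); force(steep)
  function(lag) 1 / (1 + exp(-(lag - t_ref) / steep))
}

#' @rdname truth-curves
#' @export
hist_poisson <- function() function(lag) rep(1, length(lag))

#' @rdname truth-curves
#' @export
phase_cosine <- function(a = 0.4, pref = 0) {
  force(a); force(pref)
  .check(a >= 0 && a < 1, "`a` must be in [0, 1) to keep the multiplier positive")
  function(phi) 1 + a * cos(phi - pref)
}

#' Simulate spike trains from a generator specification
#'
#' Discrete-time generation: at each bin (default 1 ms) the conditional
#' intensity is computed from the time since the last simulated spike and the
#' current oscillation phase, and a spike is drawn as Bernoulli with
#' \eqn{p_k = \lambda(t_k\mid H,\Phi)\Delta}.  Spike event times are bin
#' centers; bases and intensities are evaluated at bin left edges, matching
#' the fitting likelihood exactly.  \code{method = "ogata"} instead simulates
#' in continuous time by Ogata thinning, as a cross-check of the
#' discretization.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed optional integer seed.
#' @param phase optional \code{\link{phase_series}} to use instead of drawing
#'   one (e.g. to share an oscillation between two neurons).
#' @param method \code{"discrete"} (default) or \code{"ogata"}.
#' @return list with \code{spikes} (\code{\link{spike_train_set}}),
#'   \code{phase} (\code{phase_series}), \code{counts} and \code{lambda}
#'   (K x n matrices; discrete method only), and \code{spec}.
#' @export
simulate_spike_trains <- function(spec, seed = NULL, phase = NULL,
                                  method = c("discrete", "ogata")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  K <- round(spec$trial_length / spec$delta)
  if (is.null(phase))
    phase <- make_oscillation(spec$freq, spec$trial_length, spec$n_trials,
                              spec$delta, rule = spec$phase_rule,
                              phi0 = spec$phi0)
  times <- attr(phase, "times")
  s1 <- spec$stimulus(times)
  base <- s1 * apply(unclass(phase), 2, spec$phase_mod)
  hmult <- spec$history(pmin((seq_len(K) - 0.5) * spec$delta, spec$trial_length))
  lam_max <- max(base) * max(hmult, 1)
  .check(lam_max * spec$delta < 1,
         "peak bin probability %.2f >= 1; decrease delta", lam_max * spec$delta)
  if (lam_max * spec$delta >= 0.2)
    warning("peak bin probability >= 0.2; the Poisson approximation degrades")

  if (method == "ogata") {
    spikes <- .sim_ogata(spec, phase, lam_max)
    return(list(spikes = spikes, phase = phase, counts = NULL, lambda = NULL,
                spec = spec))
  }
  s <- sim_binned_cpp(base, hmult, spec$delta)
  list(spikes = .spikes_from_counts(s$counts, spec$delta, spec$trial_length),
       phase = phase, counts = s$counts, lambda = s$lambda, spec = spec)
}

## continuous-time Ogata thinning (cross-validation of the discrete mode)
.sim_ogata <- function(spec, phase, lam_max) {
  p0 <- attr(phase, "phi0")
  w <- 2 * pi * spec$freq
  trials <- lapply(seq_len(spec$n_trials), function(j) {
    tt <- numeric(0); t <- 0; last <- -Inf
    repeat {
      t <- t + stats::rexp(1, lam_max)
      if (t > spec$trial_length) break
      lam <- spec$stimulus(t) * spec$history(t - last) *
        spec$phase_mod(wrap_phase(p0[j] + w * t))
      if (runif(1) < lam / lam_max) { tt <- c(tt, t); last <- t }
    }
    tt
  })
  names(trials) <- as.character(seq_len(spec$n_trials))
  spike_train_set(trials, spec$trial_length, neuron_id = "ogata")
}

#' Simulate a pair of neurons sharing one oscillatory drive
#'
#' Draws a single phase series (shared network-wide oscillation) and
#' simulates both neurons conditionally independently given it.
#'
#' @param spec1,spec2 \code{\link{sim_spec}} objects with identical trial
#'   geometry and frequency.
#' @param seed optional integer seed.
#' @return list with elements \code{n1}, \code{n2} (each as returned by
#'   \code{\link{simulate_spike_trains}}) and the shared \code{phase}.
#' @export
simulate_pair <- function(spec1, spec2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check(spec1$n_trials == spec2$n_trials &&
           spec1$trial_length == spec2$trial_length &&
           spec1$delta == spec2$delta,
         "the two specs must share trial geometry")
  phase <- make_oscillation(spec1$freq, spec1$trial_length, spec1$n_trials,
                            spec1$delta, rule = spec1$phase_rule,
                            phi0 = spec1$phi0)
  n1 <- simulate_spike_trains(spec1, phase = phase)
  n2 <- simulate_spike_trains(spec2, phase = phase)
  list(n1 = n1, n2 = n2, phase = phase)
}

#' Inject excess synchrony into an independent pair at a target \eqn{\zeta}
#'
#' Implements the synchrony-injection / marginal-thinning construction used
#' for power analysis.  Two neurons are first simulated independently from
#' fixed per-bin intensities (history-free).  All synchronous spikes (pairs
#' in the same \eqn{\delta} bin) are removed and replaced by synchronous
#' events drawn with per-\eqn{\delta}-bin probability
#' \eqn{\zeta\lambda^{(1)}\lambda^{(2)}\delta^2} at a common uniform time in
#' the bin; remaining non-synchronous spikes of neuron \eqn{j} are thinned
#' with \deqn{p^{(j)} = \frac{\lambda^{(j)} -
#' \zeta\lambda^{(1)}\lambda^{(2)}\delta}{\lambda^{(j)} -
#' \lambda^{(1)}\lambda^{(2)}\delta}} so each neuron's marginal rate is
#' preserved in expectation while the expected synchrony ratio equals
#' \eqn{\zeta}.
#'
#' @param lambda1,lambda2 K x n_trials intensity matrices (Hz) on the
#'   \code{delta} grid (per-bin fixed, i.e. history-free generators).
#' @param zeta target synchrony ratio, \eqn{\zeta \ge 1}.
#' @param delta_sync synchrony bin \eqn{\delta} (default 5 ms).
#' @param delta model bin width (default 1 ms); \code{delta_sync} must be a
#'   multiple.
#' @param seed optional integer seed.
#' @return list with \code{spikes1}, \code{spikes2}
#'   (\code{\link{spike_train_set}}), \code{counts1}, \code{counts2},
#'   \code{n_injected}.
#' @export
inject_synchrony <- function(lambda1, lambda2, zeta, delta_sync = 5e-3,
                             delta = 1e-3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check(all(dim(lambda1) == dim(lambda2)), "intensity matrices must match")
  g <- round(delta_sync / delta)
  .check(abs(g * delta - delta_sync) < 1e-12,
         "delta_sync must be a multiple of delta")
  K <- nrow(lambda1); n <- ncol(lambda1)
  .check(K %% g == 0, "number of bins must be a multiple of delta_sync/delta")
  nb <- K %/% g
  grp_mean <- function(M) {
    dim(M) <- c(g, nb * n)
    out <- colMeans(M)
    dim(out) <- c(nb, n)
    out
  }
  l1 <- grp_mean(lambda1); l2 <- grp_mean(lambda2)
  prod_d <- l1 * l2 * delta_sync
  p1 <- (l1 - zeta * prod_d) / (l1 - prod_d)
  p2 <- (l2 - zeta * prod_d) / (l2 - prod_d)
  bad <- which(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)
  if (length(bad))
    stop(sprintf("thinning probability outside [0, 1] at sync bin %d", bad[1]),
         call. = FALSE)

  y1 <- matrix(rbinom(K * n, 1L, pmin(lambda1 * delta, 1)), K, n)
  y2 <- matrix(rbinom(K * n, 1L, pmin(lambda2 * delta, 1)), K, n)

  grp_sum <- function(M) { dim(M) <- c(g, nb * n); out <- colSums(M)
                           dim(out) <- c(nb, n); out }
  c1 <- grp_sum(y1); c2 <- grp_sum(y2)
  co <- which(c1 > 0 & c2 > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(co))) {          # remove synchronous pairs
    b <- co[r, 1]; tr <- co[r, 2]
    rows <- ((b - 1) * g + 1):(b * g)
    m <- min(c1[b, tr], c2[b, tr])
    for (M in 1:2) {
      y <- if (M == 1) y1 else y2
      sp <- rows[y[rows, tr] > 0]
      y[sp[seq_len(m)], tr] <- 0L
      if (M == 1) y1 <- y else y2 <- y
    }
  }

  ## thin surviving non-synchronous spikes to restore the marginals
  keep_thin <- function(y, p) {
    sp <- which(y > 0, arr.ind = TRUE)
    if (nrow(sp)) {
      b <- (sp[, 1] - 1) %/% g + 1
      pk <- p[cbind(b, sp[, 2])]
      drop <- runif(nrow(sp)) >= pk
      y[sp[drop, , drop = FALSE]] <- 0L
    }
    y
  }
  y1 <- keep_thin(y1, p1)
  y2 <- keep_thin(y2, p2)

  ## inject synchronous events at a common uniform bin within each delta bin
  pr_sync <- pmin(zeta * prod_d * delta_sync, 1)
  inj <- matrix(rbinom(nb * n, 1L, pr_sync), nb, n)
  hit <- which(inj > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    off <- sample.int(g, nrow(hit), replace = TRUE)
    rows <- (hit[, 1] - 1) * g + off
    y1[cbind(rows, hit[, 2])] <- 1L
    y2[cbind(rows, hit[, 2])] <- 1L
  }
  list(spikes1 = .spikes_from_counts(y1, delta, neuron_id = "n1"),
       spikes2 = .spikes_from_counts(y2, delta, neuron_id = "n2"),
       counts1 = y1, counts2 = y2, n_injected = sum(inj))
}

#' Oscillation phase at each spike
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param phase a \code{\link{phase_series}} on the same trial grid.
#' @return numeric vector of phases, one per spike (all trials pooled).
#' @export
phase_at_spikes <- function(spikes, phase) {
  K <- nrow(phase); delta <- attr(phase, "delta")
  .check(length(spikes$trials) == ncol(phase),
         "phase series and spike trains have different trial counts")
  out <- lapply(seq_along(spikes$trials), function(j) {
    tt <- spikes$trials[[j]]
    if (!length(tt)) return(numeric(0))
    unclass(phase)[pmin(floor(tt / delta) + 1L, K), j]
  })
  unlist(out, use.names = FALSE)
}
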