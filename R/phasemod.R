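#' Empirical spike-phase histogram
#'
#' The classical estimator of phase locking: the distribution of oscillation
#' phases at spike times, as a normalized histogram over \eqn{[-\pi,\pi)}.
#' On the \code{"lambda3"} scale the density is multiplied by \eqn{2\pi} for
#' direct comparison with the (normalized) phase-modulation curve; for
#' Poisson firing the histogram estimates \eqn{\lambda_3(\phi)/2\pi}, but for
#' non-Poisson firing it is a biased estimator of the modulation (see
#' \code{\link{theoretical_phase_distribution}}).
#'
#' @param spikes a \code{\link{spike_train_set}}.
#' @param phase a \code{\link{phase_series}} on the same grid.
#' @param n_bins number of phase bins (default 16).
#' @param scale \code{"density"} (integrates to 1) or \code{"lambda3"}
#'   (density \eqn{\times 2\pi}).
#' @return object of class \code{"phase_distribution"}: list with
#'   \code{bin_edges}, \code{mass} (per-bin density on the chosen scale),
#'   \code{kind = "empirical"}, \code{n_spikes}.
#' @export
spike_phase_histogram <- function(spikes, phase, n_bins = 16,
                                  scale = c("density", "lambda3")) {
  scale <- match.arg(scale)
  ph <- phase_at_spikes(spikes, phase)
  .check(length(ph) > 0, "no spikes: the spike-phase histogram is undefined")
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- pmin(findInterval(ph, edges), n_bins)
  counts <- tabulate(idx, n_bins)
  bw <- 2 * pi / n_bins
  dens <- counts / (length(ph) * bw)
  structure(list(bin_edges = edges,
                 mass = if (scale == "lambda3") dens * 2 * pi else dens,
                 scale = scale, kind = "empirical", n_spikes = length(ph)),
            class = "phase_distribution")
}

#' @export
print.phase_distribution <- function(x, ...) {
  cat(sprintf("Phase distribution (%s, %d bins, %s scale)\n", x$kind,
              length(x$mass), x$scale))
  if (!is.null(x$eigenvalue))
    cat(sprintf("  transition-operator eigenvalue: %.8f\n", x$eigenvalue))
  invisible(x)
}

#' Waiting-time density of the next spike
#'
#' For a constant-stimulus generator \eqn{\lambda(t) = C\,\lambda_2(t -
#' t^*)\,\lambda_3(\phi_t)} with the previous spike at phase \eqn{\phi_0},
#' the density of the waiting time to the next spike is
#' \eqn{f(t) = \lambda(t)\exp\{-\int_0^t \lambda\}}.
#'
#' @param C constant stimulus rate, Hz.
#' @param history lag-multiplier function \eqn{\lambda_2}.
#' @param phase_mod phase-multiplier function \eqn{\lambda_3}.
#' @param freq oscillation frequency, Hz.
#' @param phi0 phase at the previous spike.
#' @param t_max grid horizon, seconds; extended automatically until the
#'   survival probability drops below \code{tol} when NULL.
#' @param dt grid step (default \eqn{1/(512 f)}).
#' @param tol survival-mass truncation tolerance (default 1e-8).
#' @return data frame with \code{t}, \code{density}, and attribute
#'   \code{survival_end}.
#' @export
waiting_time_density <- function(C, history = hist_poisson(),
                                 phase_mod = function(phi) rep(1, length(phi)),
                                 freq = 10, phi0 = 0, t_max = NULL,
                                 dt = NULL, tol = 1e-8) {
  if (is.null(dt)) dt <- 1 / (512 * freq)
  if (is.null(t_max)) t_max <- 20 / C
  w <- 2 * pi * freq
  repeat {
    t <- seq(0, t_max, by = dt)
    lam <- C * history(t) * phase_mod(wrap_phase(phi0 + w * t))
    Lam <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
    S <- exp(-Lam)
    if (S[length(S)] < tol || t_max > 3600 / C) break
    t_max <- t_max * 2
  }
  structure(data.frame(t = t, density = lam * S),
            survival_end = S[length(S)])
}

#' Phase-transition operator of the spike-phase chain
#'
#' Builds the discretized transition matrix \eqn{A} whose entry
#' \eqn{A_{ij}} is the probability that the next spike occurs at phase bin
#' \eqn{i} given the previous spike at phase bin \eqn{j}, by integrating the
#' waiting-time density over all lags that land in bin \eqn{i} (the lag set
#' \eqn{\{\Delta u = (\phi-\phi_0)/w + k/f\}} summed over cycles
#' \eqn{k}).  Each time step's probability mass is the exact survival
#' difference, so columns sum to \eqn{1 - S(t_{max}) \le} \code{tol} short
#' of 1 and the stationary eigenvalue is recovered to that accuracy.
#'
#' @param C,history,phase_mod,freq the generator, as in
#'   \code{\link{waiting_time_density}}.
#' @param m number of phase bins (default 64).
#' @param sub time substeps per phase bin (default 8).
#' @param tol survival truncation (default 1e-8).
#' @return m x m column-stochastic matrix; attribute \code{centers} holds the
#'   bin-center phases.
#' @export
phase_transition_matrix <- function(C, history = hist_refractory(),
                                    phase_mod = phase_cosine(0.4, pref = pi),
                                    freq = 10, m = 64, sub = 8, tol = 1e-8) {
  .check(m >= 16, "use at least 16 phase bins")
  edges <- seq(-pi, pi, length.out = m + 1)
  centers <- (edges[-1] + edges[-(m + 1)]) / 2
  w <- 2 * pi * freq
  dt <- 1 / (freq * m * sub)
  A <- matrix(0, m, m)
  for (j in seq_len(m)) {
    phi0 <- centers[j]
    t_max <- 20 / C
    repeat {
      t <- seq(0, t_max, by = dt)
      lam <- C * history(t) * phase_mod(wrap_phase(phi0 + w * t))
      Lam <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * dt))
      S <- exp(-Lam)
      if (S[length(S)] < tol || t_max > 3600 / C) break
      t_max <- t_max * 2
    }
    mass <- S[-length(S)] - S[-1]                  # exact per-step mass
    tm <- (t[-length(t)] + t[-1]) / 2
    phim <- wrap_phase(phi0 + w * tm)
    bin <- pmin(findInterval(phim, edges), m)
    A[, j] <- vapply(split(mass, factor(bin, levels = seq_len(m))),
                     sum, numeric(1))
  }
  attr(A, "centers") <- centers
  A
}

#' Theoretical spike-phase distribution from the transition operator
#'
#' Solves \eqn{P = A P}: the stationary spike-phase distribution is the
#' eigenvector of the phase-transition matrix with eigenvalue 1.  For
#' Poisson firing (\eqn{\lambda_2 \equiv 1}) the solution is
#' \eqn{\lambda_3(\phi)/2\pi}, so the spike-phase histogram is unbiased; for
#' non-Poisson firing the stationary distribution departs from
#' \eqn{\lambda_3/2\pi} in a firing-rate-dependent way, which is the
#' intrinsic bias of the histogram method.
#'
#' @inheritParams phase_transition_matrix
#' @param eig_tol maximum allowed distance of the leading eigenvalue from 1
#'   (default 1e-6).
#' @return a \code{"phase_distribution"} (density scale) with elements
#'   \code{eigenvalue} and \code{centers}.
#' @export
theoretical_phase_distribution <- function(C, history = hist_refractory(),
                                           phase_mod = phase_cosine(0.4, pref = pi),
                                           freq = 10, m = 64, sub = 8,
                                           eig_tol = 1e-6) {
  A <- phase_transition_matrix(C, history, phase_mod, freq, m, sub)
  e <- eigen(A)
  k <- which.min(Mod(e$values - 1))
  .check(Mod(e$values[k] - 1) < eig_tol,
         "no eigenvalue within %g of 1 (found %g); model or discretization invalid",
         eig_tol, Mod(e$values[k] - 1))
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0
  bw <- 2 * pi / m
  dens <- v / (sum(v) * bw)
  structure(list(bin_edges = seq(-pi, pi, length.out = m + 1), mass = dens,
                 scale = "density", kind = "theoretical",
                 eigenvalue = Re(e$values[k]), centers = attr(A, "centers")),
            class = "phase_distribution")
}

#' Compare histogram and GLM estimators of the phase modulation
#'
#' Repeated-simulation study of the mean integrated squared error
#' \eqn{MISE = n^{-1}\sum_i \int [\hat\lambda_3^i(\phi) -
#' \lambda_3(\phi)]^2 d\phi} of the spike-phase histogram versus the
#' point-process GLM across sample sizes, with the decomposition into
#' integrated variance (about the sample mean curve) plus integrated squared
#' bias.  The histogram bin size is chosen per sample size to minimize its
#' MISE over \code{hist_bins}.
#'
#' @param spec a \code{\link{sim_spec}} whose \code{phase_mod} is the true
#'   \eqn{\lambda_3} (phase-normalized).
#' @param trial_counts vector of trial counts to study.
#' @param n_datasets simulated datasets per trial count (default 10).
#' @param hist_bins candidate histogram bin counts.
#' @param knots,penalty passed to \code{\link{ppm}}.
#' @param seed optional integer seed.
#' @param grid_n evaluation grid size over \eqn{[-\pi,\pi]}.
#' @return data frame with columns \code{method}, \code{n_trials},
#'   \code{mise}, \code{variance}, \code{bias_sq}, \code{hist_bins}.
#' @export
compare_phase_estimators <- function(spec, trial_counts = c(10, 40),
                                     n_datasets = 10,
                                     hist_bins = c(8, 12, 16, 24),
                                     knots = NULL, penalty = 1, seed = NULL,
                                     grid_n = 128) {
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(-pi, pi, length.out = grid_n)
  truth <- spec$phase_mod(grid)
  rows <- list()
  for (N in trial_counts) {
    sp <- spec; sp$n_trials <- N
    hist_est <- array(NA_real_, c(length(hist_bins), n_datasets, grid_n))
    glm_est <- matrix(NA_real_, n_datasets, grid_n)
    for (i in seq_len(n_datasets)) {
      sim <- simulate_spike_trains(sp)
      for (hb in seq_along(hist_bins)) {
        h <- spike_phase_histogram(sim$spikes, sim$phase, hist_bins[hb],
                                   scale = "lambda3")
        bin <- pmin(findInterval(grid, h$bin_edges), hist_bins[hb])
        hist_est[hb, i, ] <- h$mass[bin]
      }
      d <- bin_spikes(sim$spikes, sim$phase, sp$delta)
      fit <- suppressWarnings(ppm(d, knots = knots, penalty = penalty))
      cv <- ppm_curves(fit, n = grid_n)
      glm_est[i, ] <- cv$phase$mult
    }
    err <- function(est) {   # est: n_datasets x grid_n
      ise <- apply(est, 1, function(v) .trapz(grid, (v - truth)^2))
      mbar <- colMeans(est)
      vari <- .trapz(grid, colMeans(sweep(est, 2, mbar)^2))
      bias2 <- .trapz(grid, (mbar - truth)^2)
      c(mise = mean(ise), variance = vari, bias_sq = bias2)
    }
    h_err <- t(apply(hist_est, 1, err))
    best <- which.min(h_err[, "mise"])
    rows[[length(rows) + 1]] <- data.frame(
      method = "histogram", n_trials = N, mise = h_err[best, "mise"],
      variance = h_err[best, "variance"], bias_sq = h_err[best, "bias_sq"],
      hist_bins = hist_bins[best])
    g <- err(glm_est)
    rows[[length(rows) + 1]] <- data.frame(
      method = "glm", n_trials = N, mise = g[["mise"]],
      variance = g[["variance"]], bias_sq = g[["bias_sq"]],
      hist_bins = NA_integer_)
  }
  do.call(rbind, rows)
}
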