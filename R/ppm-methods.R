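#' @export
print.ppm <- function(x, ...) {
  cat("Point-process GLM (", paste(x$terms, collapse = " + "), ")\n", sep = "")
  cat(sprintf("  %d spikes, %d bins used, delta = %g ms\n",
              x$n_spikes, x$n_bins_used, x$delta * 1e3))
  cat(sprintf("  penalized objective %.4f after %d cycles (%s)\n",
              x$objective, x$n_cycles,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.ppm <- function(object, ...) {
  cv <- ppm_curves(object, n = 512)
  out <- list(terms = object$terms, converged = object$converged,
              n_cycles = object$n_cycles, objective = object$objective,
              n_spikes = object$n_spikes, delta = object$delta,
              mean_rate = object$n_spikes /
                (ncol(object$design$counts) * object$trial_length))
  if (!is.null(cv$phase)) {
    out$phase_amplitude <- (max(cv$phase$mult) - min(cv$phase$mult)) / 2
    out$preferred_phase <- cv$phase$phi[which.max(cv$phase$mult)]
  }
  if (!is.null(cv$history))
    out$min_history_mult <- min(cv$history$mult)
  structure(out, class = "summary.ppm")
}

#' @export
print.summary.ppm <- function(x, ...) {
  cat("Point-process GLM summary\n")
  cat(sprintf("  terms: %s\n", paste(x$terms, collapse = " + ")))
  cat(sprintf("  spikes: %d (mean rate %.2f Hz)\n", x$n_spikes, x$mean_rate))
  cat(sprintf("  objective: %.4f (%d cycles, %s)\n", x$objective, x$n_cycles,
              if (x$converged) "converged" else "not converged"))
  if (!is.null(x$phase_amplitude))
    cat(sprintf("  phase modulation amplitude (max-min)/2: %.3f, preferred phase %.2f rad\n",
                x$phase_amplitude, x$preferred_phase))
  if (!is.null(x$min_history_mult))
    cat(sprintf("  minimum history multiplier: %.3f\n", x$min_history_mult))
  invisible(x)
}

#' @export
coef.ppm <- function(object, ...) object$coef

#' @export
logLik.ppm <- function(object, ...) {
  ll <- ppm_loglik(object)
  attr(ll, "df") <- length(unlist(object$coef))
  class(ll) <- "logLik"
  ll
}

#' Predict from a fitted point-process GLM
#'
#' @param object a \code{\link{ppm}} fit.
#' @param design a binned design (default: the training design).
#' @param type \code{"intensity"} for the per-bin conditional intensity
#'   matrix (Hz, conditioned on each bin's own history and phase) or
#'   \code{"curves"} for the normalized effect curves.
#' @param n grid size for \code{type = "curves"}.
#' @param ... unused.
#' @return a K x n_trials matrix, or the list from \code{\link{ppm_curves}}.
#' @export
predict.ppm <- function(object, design = object$design,
                        type = c("intensity", "curves"), n = 200, ...) {
  type <- match.arg(type)
  if (type == "curves") return(ppm_curves(object, n = n))
  exp(.eta_matrix(object, design))
}

#' @export
fitted.ppm <- function(object, ...) {
  exp(.eta_matrix(object, object$design)) * object$delta
}

#' Residuals of a fitted point-process GLM
#'
#' \code{type = "rescaled"} applies the time-rescaling theorem: interspike
#' intervals are transformed by the integrated fitted intensity,
#' \eqn{z_i = 1 - \exp(-\int \lambda)}, which are iid uniform on (0,1) under
#' a correct model.  \code{type = "raw"} returns per-bin \eqn{y_k - p_k}.
#'
#' @param object a \code{\link{ppm}} fit.
#' @param type \code{"rescaled"} or \code{"raw"}.
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.ppm <- function(object, type = c("rescaled", "raw"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  if (type == "raw") return(as.vector(object$design$counts - p))
  .rescaled_intervals(object$design$counts, p)
}

## rescaled waiting times z in (0,1): cumulative integrated intensity between
## consecutive spikes within each trial
.rescaled_intervals <- function(counts, p) {
  z <- numeric(0)
  for (j in seq_len(ncol(counts))) {
    Lam <- cumsum(p[, j])
    sp <- which(counts[, j] > 0)
    if (length(sp) >= 2) {
      dLam <- diff(Lam[sp])
      z <- c(z, 1 - exp(-dLam))
    }
  }
  z
}

#' Simulate spike trains from a fitted model
#'
#' Parametric simulation: per-bin Bernoulli draws from the fitted conditional
#' intensity, sequentially so each draw conditions on the simulated history,
#' using the phase series of the training design (or a new one).
#'
#' @param object a \code{\link{ppm}} fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param phase optional \code{\link{phase_series}} to condition on.
#' @param ... unused.
#' @return list of \code{nsim} \code{\link{spike_train_set}} objects.
#' @export
simulate.ppm <- function(object, nsim = 1, seed = NULL, phase = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sims <- replicate(nsim, {
    s <- .sim_from_fit(object, phase = phase)
    .spikes_from_counts(s$counts, object$delta, object$trial_length)
  }, simplify = FALSE)
  if (nsim == 1) sims[[1]] else sims
}

## precompute the per-bin base rate exp(f1 + f3) and the history-multiplier
## lookup once per fit, so repeated simulation (bootstrap) is cheap
.sim_precompute <- function(fit, phase = NULL) {
  design <- fit$design
  K <- nrow(design$counts); n <- ncol(design$counts)
  base_eta <- matrix(0, K, n)
  if ("stimulus" %in% fit$terms)
    base_eta <- base_eta +
      drop(bspline_basis(design$times, fit$knots$stimulus, fit$order) %*%
             fit$coef$alpha) + fit$offsets["f1"]
  if ("phase" %in% fit$terms) {
    ph <- if (!is.null(phase)) unclass(phase) else design$phase
    base_eta <- base_eta +
      matrix(circular_basis(as.vector(ph), knots = fit$knots$phase,
                            m_max = fit$m_max, convention = fit$convention) %*%
               fit$coef$gamma + fit$offsets["f3"], K, n)
  }
  hmult <- rep(1, K)
  if ("history" %in% fit$terms) {
    lag_grid <- pmin((seq_len(K) - 0.5) * fit$delta, fit$hist_span)
    hmult <- exp(drop(bspline_basis(lag_grid, fit$knots$history, fit$order) %*%
                        fit$coef$beta) + fit$offsets["f2"])
  }
  list(base = exp(base_eta), hmult = hmult, delta = fit$delta)
}

## fast path: returns counts + per-bin lambda, reusing the fitted curves.
.sim_from_fit <- function(fit, phase = NULL, pc = NULL) {
  if (is.null(pc)) pc <- .sim_precompute(fit, phase)
  sim_binned_cpp(pc$base, pc$hmult, pc$delta)
}

#' Plot fitted effect curves
#'
#' One panel per fitted term: stimulus rate \eqn{\exp f_1(t)}, history
#' multiplier \eqn{\exp f_2(\tau)}, and phase modulation \eqn{\exp f_3(\phi)},
#' with 95% confidence bands if attached by \code{\link{ppm_confband}}.
#'
#' @param x a \code{\link{ppm}} fit.
#' @param truth optional list of true curves to overlay, with the structure
#'   of \code{\link{ppm_curves}} output.
#' @param ... passed to \code{plot}.
#' @export
plot.ppm <- function(x, truth = NULL, ...) {
  cv <- ppm_curves(x)
  bands <- x$confband
  op <- par(mfrow = c(1, length(cv)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  panel <- function(df, xn, yn, main, band, tr) {
    plot(df[[1]], df[[2]], type = "n", xlab = xn, ylab = yn, main = main,
         ylim = range(df[[2]], band$lo, band$hi, tr, na.rm = TRUE), ...)
    if (!is.null(band))
      polygon(c(df[[1]], rev(df[[1]])), c(band$lo, rev(band$hi)),
              col = "#00cccc44", border = NA)
    lines(df[[1]], df[[2]], col = "blue", lwd = 2)
    if (!is.null(tr)) lines(df[[1]], tr, col = "red", lwd = 1.5)
  }
  if (!is.null(cv$stimulus))
    panel(cv$stimulus, "time (s)", "rate (Hz)", "stimulus",
          bands$stimulus, truth$stimulus$rate)
  if (!is.null(cv$history))
    panel(cv$history, "lag (s)", "multiplier", "auto-history",
          bands$history, truth$history$mult)
  if (!is.null(cv$phase))
    panel(cv$phase, "phase (rad)", "multiplier", "phase modulation",
          bands$phase, truth$phase$mult)
  invisible(x)
}
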