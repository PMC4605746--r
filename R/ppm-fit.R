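#' Fit a point-process GLM for spike trains
#'
#' Fits the multiplicative conditional-intensity model
#' \deqn{\log\lambda(t \mid H_t, X_t) = f_1(t) + f_2(t - t^*) + f_3(\Phi_t)}
#' by penalized maximum likelihood.  \eqn{f_1} (stimulus / PSTH effect) and
#' \eqn{f_2} (post-spike auto-history, a function of the lag since the most
#' recent spike \eqn{t^*}) use cubic B-spline bases; \eqn{f_3} (oscillation
#' phase modulation) uses a periodic circular-spline basis.  Any subset of the
#' three terms can be included: the "reduced" phase-free model is the full
#' model with the phase block removed and never touches phase inputs.
#'
#' Optimization is by back-fitting: the coefficient blocks are updated
#' cyclically, each by penalized Newton/IRLS steps
#' \eqn{\Theta \leftarrow \Theta - H^{-1}\nabla Q} with
#' \eqn{\nabla Q = V^T[\exp(V\Theta + \mathrm{offset}) - Y] + \lambda\Theta}
#' and \eqn{H = V^T W V + \lambda}, with step halving so the accepted
#' objective never increases.  The outer loop stops when the penalized
#' objective changes by at most \code{tol}.  Design columns are standardized
#' to unit root-mean-square internally so a single ridge weight acts
#' comparably on all blocks; coefficients are reported on the original basis
#' scale.
#'
#' After fitting, identifiability constraints are enforced by
#' \code{\link{enforce_identifiability}}: the reported history and phase
#' curves satisfy \eqn{(1/L)\int_0^L e^{f_2} = 1} (over the history span) and
#' \eqn{(1/2\pi)\int_{-\pi}^{\pi} e^{f_3} = 1}, with the normalizing constants
#' absorbed into \eqn{f_1}; the fitted intensity is unchanged.
#'
#' @param design a \code{\link{bin_spikes}} design.
#' @param formula model terms, a one-sided formula over the reserved names
#'   \code{stimulus}, \code{history}, \code{phase}; default all three.
#' @param knots list with components \code{stimulus}, \code{history},
#'   \code{phase} (see \code{\link{default_knots}}).
#' @param penalty ridge weight \eqn{\lambda \ge 0} on standardized
#'   coefficients (default 1).
#' @param order B-spline order (default 4 = cubic).
#' @param m_max circular-basis harmonic cutoff (default 4).
#' @param convention circular-basis convention, see
#'   \code{\link{circular_basis}}.
#' @param tol convergence tolerance on the change in the penalized objective
#'   (default 1e-6).
#' @param max_cycles maximum back-fitting cycles (default 100).
#' @param drop_no_history drop bins before each trial's first spike from the
#'   likelihood when a history term is included (default TRUE); their
#'   intensity is \eqn{\exp(f_1 + f_3)}.
#' @param unpenalized_intercept if TRUE, the constant component of the
#'   stimulus block is exempt from the ridge penalty.
#' @param init optional list of starting coefficients (\code{alpha},
#'   \code{beta}, \code{gamma}), e.g. from a previous fit.
#' @param verbose print the objective each cycle.
#' @return an object of class \code{"ppm"}; see
#'   \code{\link{ppm_curves}}, \code{\link{predict.ppm}},
#'   \code{\link{ppm_confband}}, \code{\link{ppm_gof}}.
#' @examples
#' spec <- sim_spec(n_trials = 10)
#' sim <- simulate_spike_trains(spec, seed = 1)
#' d <- bin_spikes(sim$spikes, sim$phase)
#' fit <- ppm(d, ~ stimulus + history + phase)
#' fit
#' @export
ppm <- function(design, formula = ~ stimulus + history + phase,
                knots = NULL, penalty = 1, order = 4, m_max = 4,
                convention = c("radian", "literal"),
                tol = 1e-6, max_cycles = 100, drop_no_history = TRUE,
                unpenalized_intercept = FALSE, init = NULL, verbose = FALSE) {
  convention <- match.arg(convention)
  .check(inherits(design, "binned_design"), "`design` must come from bin_spikes()")
  .check(is.finite(penalty) && penalty >= 0, "`penalty` must be finite and >= 0")
  terms_used <- .ppm_terms(formula)
  if ("phase" %in% terms_used)
    .check(!is.null(design$phase), "phase term requested but design has no phase series")
  .check(sum(design$counts) >= 1, "design has no spikes; nothing to fit")

  if (is.null(knots)) knots <- default_knots(design$trial_length)
  hist_span <- max(knots$history)
  bld <- .ppm_build(design, terms_used, knots, order, m_max, convention,
                    drop_no_history)
  y <- bld$y; Vstd <- bld$Vstd; scales <- bld$scales

  ## penalty projection: identity, or (for the stimulus block) exempt the
  ## constant direction; a constant f1 is alpha = c * 1, i.e. theta_std = c * s.
  Pmats <- lapply(Vstd, function(V) NULL)
  if (unpenalized_intercept && "stimulus" %in% terms_used) {
    u <- scales$stimulus
    Pmats$stimulus <- diag(length(u)) - tcrossprod(u) / sum(u^2)
  }

  theta <- lapply(Vstd, function(V) numeric(ncol(V)))
  if ("stimulus" %in% terms_used) {
    theta$stimulus <- .init_alpha(design, knots$stimulus, order) * scales$stimulus
  }
  if (!is.null(init)) {
    map <- c(stimulus = "alpha", history = "beta", phase = "gamma")
    for (b in names(theta)) {
      ini <- init[[map[[b]]]]
      if (!is.null(ini) && length(ini) == length(theta[[b]]))
        theta[[b]] <- ini * scales[[b]]
    }
  }

  fit0 <- .ppm_irls(y, Vstd, theta, penalty, Pmats, log(design$delta),
                    tol, max_cycles, verbose)

  coefs <- Map(function(th, s) th / s, fit0$theta, scales)
  names(coefs) <- c(stimulus = "alpha", history = "beta",
                    phase = "gamma")[names(coefs)]
  ## centered blocks contribute -(m' theta) constants in-fit; fold them into
  ## the stimulus level (B-splines are a partition of unity) so the
  ## uncentered-basis representation reproduces the fitted intensity exactly
  if (!is.null(coefs$alpha) && length(bld$centers)) {
    cshift <- 0
    for (b in names(bld$centers))
      cshift <- cshift + sum(bld$centers[[b]] * fit0$theta[[b]])
    coefs$alpha <- coefs$alpha - cshift
  }

  fit <- structure(list(
    terms = terms_used, knots = knots, order = order, m_max = m_max,
    convention = convention, coef = coefs,
    offsets = c(f1 = 0, f2 = 0, f3 = 0),
    penalty = penalty, scales = scales,
    unpenalized_intercept = unpenalized_intercept,
    converged = fit0$converged, n_cycles = fit0$n_cycles,
    objective = fit0$Q, obj_trace = fit0$trace,
    delta = design$delta, trial_length = design$trial_length,
    hist_span = hist_span, drop_no_history = drop_no_history,
    n_spikes = sum(design$counts), n_bins_used = length(y),
    design = design, call = match.call()),
    class = "ppm")
  if (!fit$converged)
    warning(sprintf("back-fitting did not converge in %d cycles (|dQ| = %.3g)",
                    max_cycles, fit0$dQ))
  enforce_identifiability(fit)
}

## parse the term formula
.ppm_terms <- function(formula) {
  if (is.character(formula)) {
    labs <- formula
  } else {
    labs <- attr(stats::terms(formula), "term.labels")
  }
  ok <- c("stimulus", "history", "phase")
  .check(length(labs) >= 1, "at least one model term must be included")
  .check(all(labs %in% ok), "model terms must be among: %s",
         paste(ok, collapse = ", "))
  ok[ok %in% labs]
}

## assemble the response and standardized design blocks for the fit rows;
## the history/phase blocks are additionally column-centered (their constant
## component is unidentified against the stimulus level, and removing it
## in-fit keeps back-fitting from zigzagging along the shared DC direction)
.ppm_build <- function(design, terms_used, knots, order, m_max, convention,
                       drop_no_history) {
  K <- nrow(design$counts); n <- ncol(design$counts)
  hist_span <- max(knots$history)
  keep_v <- rep(TRUE, K * n)
  if ("history" %in% terms_used && drop_no_history)
    keep_v <- !is.na(as.vector(design$lag))
  y <- as.vector(design$counts)[keep_v]
  Vs <- list()
  if ("stimulus" %in% terms_used) {
    A1 <- bspline_basis(design$times, knots$stimulus, order)
    Vs$stimulus <- A1[rep(seq_len(K), n), , drop = FALSE][keep_v, , drop = FALSE]
  }
  if ("history" %in% terms_used) {
    lagv <- as.vector(design$lag)[keep_v]
    nohist <- is.na(lagv)
    lagv[nohist] <- 0
    B <- bspline_basis(pmin(lagv, hist_span), knots$history, order)
    if (any(nohist)) B[nohist, ] <- 0
    Vs$history <- B
  }
  if ("phase" %in% terms_used)
    Vs$phase <- circular_basis(as.vector(design$phase)[keep_v],
                               knots = knots$phase, m_max = m_max,
                               convention = convention)
  scales <- lapply(Vs, function(V) {
    s <- sqrt(colMeans(V^2)); s[s < 1e-12] <- 1; s
  })
  Vstd <- Map(function(V, s) sweep(V, 2, s, "/"), Vs, scales)
  centers <- list()
  if ("stimulus" %in% terms_used) {
    for (b in intersect(c("history", "phase"), names(Vstd))) {
      m <- colMeans(Vstd[[b]])
      Vstd[[b]] <- sweep(Vstd[[b]], 2, m, "-")
      centers[[b]] <- m
    }
  }
  list(y = y, Vstd = Vstd, scales = scales, centers = centers)
}

## alpha start: least squares of the smoothed log-PSTH on the stimulus basis
.init_alpha <- function(design, knots_stim, order) {
  K <- nrow(design$counts); n <- ncol(design$counts)
  rate <- rowSums(design$counts) / (n * design$delta)
  w <- min(51, K)
  sm <- stats::filter(c(rev(rate[seq_len(w)]), rate, rev(rate[K - seq_len(w) + 1])),
                      rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)[w + seq_len(K)]
  target <- log(pmax(sm, 0.1))
  A <- bspline_basis(design$times, knots_stim, order)
  qr.coef(qr(A), target)
}

## penalized objective: Q = -(sum y*log p - sum p) + (pen/2) * sum theta'P theta
.ppm_Q <- function(eta, y, logdelta, theta, pen, Pmats) {
  lp <- eta + logdelta
  Q <- -(sum(lp[y == 1]) - sum(exp(lp)))
  for (b in names(theta)) {
    th <- theta[[b]]
    P <- Pmats[[b]]
    Q <- Q + if (is.null(P)) (pen / 2) * sum(th^2) else
      (pen / 2) * sum(th * drop(P %*% th))
  }
  Q
}

## back-fitting penalized IRLS over coefficient blocks
.ppm_irls <- function(y, Vstd, theta, pen, Pmats, logdelta,
                      tol, max_cycles, verbose = FALSE) {
  blocks <- names(Vstd)
  etas <- Map(function(V, th) drop(V %*% th), Vstd, theta)
  eta <- Reduce(`+`, etas)
  Q <- .ppm_Q(eta, y, logdelta, theta, pen, Pmats)
  trace <- Q
  converged <- FALSE
  dQ <- Inf
  for (cyc in seq_len(max_cycles)) {
    Qprev <- Q
    for (b in blocks) {
      V <- Vstd[[b]]
      P <- Pmats[[b]]
      for (it in 1:8) {
        p <- exp(eta + logdelta)
        th <- theta[[b]]
        pg <- if (is.null(P)) pen * th else pen * drop(P %*% th)
        g <- drop(crossprod(V, p - y)) + pg
        H <- crossprod(V, V * p)
        diagH <- if (is.null(P)) pen * diag(ncol(V)) else pen * P
        H <- H + diagH
        step <- tryCatch(solve(H, g), error = function(e) {
          message("singular Hessian in block '", b, "'; ridge bump applied")
          solve(H + (pen + 1) * diag(ncol(V)), g)
        })
        s <- 1
        repeat {
          th_new <- th - s * step
          eta_b_new <- drop(V %*% th_new)
          eta_new <- eta - etas[[b]] + eta_b_new
          theta_try <- theta; theta_try[[b]] <- th_new
          Qnew <- .ppm_Q(eta_new, y, logdelta, theta_try, pen, Pmats)
          if (is.finite(Qnew) && Qnew <= Q + 1e-12) break
          s <- s / 2
          if (s < 1e-6) { Qnew <- Q; th_new <- th; eta_new <- eta
                          eta_b_new <- etas[[b]]; break }
        }
        dQb <- Q - Qnew
        theta[[b]] <- th_new; etas[[b]] <- eta_b_new; eta <- eta_new; Q <- Qnew
        if (dQb < tol / 10) break
      }
    }
    trace <- c(trace, Q)
    dQ <- abs(Qprev - Q)
    if (verbose) message(sprintf("cycle %d: Q = %.8f", cyc, Q))
    if (dQ <= tol) { converged <- TRUE; break }
  }
  list(theta = theta, Q = Q, trace = trace, converged = converged,
       n_cycles = length(trace) - 1, dQ = dQ)
}

#' Enforce the identifiability constraints on a fitted model
#'
#' Computes the normalizing constants \eqn{\log[(1/L)\int_0^L e^{f_2}]} and
#' \eqn{\log[(1/2\pi)\int_{-\pi}^{\pi} e^{f_3}]} by the trapezoid rule on a
#' 1000-point grid and stores them as offsets on the reported history and
#' phase curves, absorbing their negatives into the stimulus curve.  The
#' fitted intensity is unchanged at every bin, and the operation is
#' idempotent.
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param n_grid quadrature grid size (default 1000).
#' @return the fit, with offsets updated.
#' @export
enforce_identifiability <- function(fit, n_grid = 1000) {
  off2 <- off3 <- 0
  if ("history" %in% fit$terms) {
    tau <- seq(0, fit$hist_span, length.out = n_grid)
    f2 <- drop(bspline_basis(tau, fit$knots$history, fit$order) %*% fit$coef$beta)
    off2 <- -log(.trapz(tau, exp(f2)) / fit$hist_span)
  }
  if ("phase" %in% fit$terms) {
    phi <- seq(-pi, pi, length.out = n_grid)
    f3 <- drop(circular_basis(phi, knots = fit$knots$phase, m_max = fit$m_max,
                              convention = fit$convention) %*% fit$coef$gamma)
    off3 <- -log(.trapz(phi, exp(f3)) / (2 * pi))
  }
  fit$offsets <- c(f1 = -(off2 + off3), f2 = off2, f3 = off3)
  fit
}

#' Evaluate the fitted effect curves
#'
#' Returns the three normalized effect curves on dense grids: the stimulus
#' firing-rate curve \eqn{\exp f_1(t)} (Hz), the history multiplier
#' \eqn{\exp f_2(\tau)} over the history span, and the phase modulation
#' \eqn{\exp f_3(\phi)} over \eqn{[-\pi, \pi]}.
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param n grid size per curve (default 200).
#' @return list of data frames (\code{stimulus}: \code{t}, \code{rate};
#'   \code{history}: \code{lag}, \code{mult}; \code{phase}: \code{phi},
#'   \code{mult}), for the included terms.
#' @export
ppm_curves <- function(fit, n = 200) {
  out <- list()
  if ("stimulus" %in% fit$terms) {
    t <- seq(0, fit$trial_length, length.out = n)
    f1 <- drop(bspline_basis(t, fit$knots$stimulus, fit$order) %*%
                 fit$coef$alpha) + fit$offsets["f1"]
    out$stimulus <- data.frame(t = t, rate = exp(f1))
  }
  if ("history" %in% fit$terms) {
    tau <- seq(0, fit$hist_span, length.out = n)
    f2 <- drop(bspline_basis(tau, fit$knots$history, fit$order) %*%
                 fit$coef$beta) + fit$offsets["f2"]
    out$history <- data.frame(lag = tau, mult = exp(f2))
  }
  if ("phase" %in% fit$terms) {
    phi <- seq(-pi, pi, length.out = n)
    f3 <- drop(circular_basis(phi, knots = fit$knots$phase, m_max = fit$m_max,
                              convention = fit$convention) %*%
                 fit$coef$gamma) + fit$offsets["f3"]
    out$phase <- data.frame(phi = phi, mult = exp(f3))
  }
  out
}

## per-bin log-intensity matrix (K x n_trials) for a design, on the
## normalized reporting scale; no-history bins get exp(f1 + f3).
.eta_matrix <- function(fit, design) {
  K <- nrow(design$counts); n <- ncol(design$counts)
  eta <- matrix(0, K, n)
  if ("stimulus" %in% fit$terms) {
    f1 <- drop(bspline_basis(design$times, fit$knots$stimulus, fit$order) %*%
                 fit$coef$alpha) + fit$offsets["f1"]
    eta <- eta + f1
  }
  if ("phase" %in% fit$terms) {
    .check(!is.null(design$phase), "design lacks the phase series this model needs")
    f3 <- circular_basis(as.vector(design$phase), knots = fit$knots$phase,
                         m_max = fit$m_max, convention = fit$convention) %*%
      fit$coef$gamma
    eta <- eta + matrix(f3 + fit$offsets["f3"], K, n)
  }
  if ("history" %in% fit$terms) {
    lag <- as.vector(design$lag)
    has <- !is.na(lag)
    f2 <- rep(0, length(lag))
    f2[has] <- drop(bspline_basis(pmin(lag[has], fit$hist_span),
                                  fit$knots$history, fit$order) %*%
                      fit$coef$beta) + fit$offsets["f2"]
    eta <- eta + matrix(f2, K, n)
  }
  eta
}

#' Conditional intensity of a fitted model
#'
#' Evaluates \eqn{\lambda(t \mid H_t, X_t) = e^{f_1(t)} e^{f_2(t-t^*)}
#' e^{f_3(\phi)}} in Hz.  Terms not in the model contribute a factor of 1, as
#' does the history term at bins flagged as having no history
#' (\code{lag = NA}).
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param t trial time(s), seconds.
#' @param lag last-spike lag(s), seconds (> 0), or \code{NA} for no history.
#' @param phase oscillation phase(s), radians (wrapped internally).
#' @return intensity in Hz (vectorized).
#' @export
conditional_intensity <- function(fit, t, lag = NA, phase = NA) {
  nmax <- max(length(t), length(lag), length(phase))
  t <- rep_len(t, nmax); lag <- rep_len(lag, nmax); phase <- rep_len(phase, nmax)
  eta <- rep(fit$offsets["f1"], nmax)
  if ("stimulus" %in% fit$terms)
    eta <- eta + drop(bspline_basis(t, fit$knots$stimulus, fit$order) %*%
                        fit$coef$alpha)
  if ("history" %in% fit$terms) {
    has <- !is.na(lag)
    .check(all(lag[has] > 0), "last-spike lag must be positive (or NA)")
    if (any(has))
      eta[has] <- eta[has] +
        drop(bspline_basis(pmin(lag[has], fit$hist_span), fit$knots$history,
                           fit$order) %*% fit$coef$beta) + fit$offsets["f2"]
    ## no-history bins get no f2 contribution: lambda = exp(f1 + f3)
  }
  if ("phase" %in% fit$terms) {
    .check(all(is.finite(phase)), "phase must be finite to lie in [-pi, pi)")
    eta <- eta + drop(circular_basis(wrap_phase(phase), knots = fit$knots$phase,
                                     m_max = fit$m_max,
                                     convention = fit$convention) %*%
                        fit$coef$gamma) + fit$offsets["f3"]
  }
  unname(exp(eta))
}

#' Point-process log likelihood of a design under a fitted model
#'
#' Computes \eqn{L = \sum_k [y_k \log p_k - p_k]} with
#' \eqn{p_k = \lambda(t_k\mid\cdot)\Delta}, over all bins of the design, with
#' intensities from the fitted model conditioned on each bin's own history
#' and phase.
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param design a binned design (defaults to the one the model was fit to).
#' @return the log likelihood (a scalar).
#' @export
ppm_loglik <- function(fit, design = fit$design) {
  lp <- .eta_matrix(fit, design) + log(design$delta)
  if (!all(is.finite(lp))) {
    k <- which(!is.finite(lp))[1]
    stop(sprintf("non-finite intensity at bin %d", k), call. = FALSE)
  }
  y <- design$counts
  sum(lp[y == 1]) - sum(exp(lp))
}
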