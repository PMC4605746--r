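#' Parametric-bootstrap confidence bands for the fitted curves
#'
#' Simulates \code{n_boot} replicate datasets from the fitted model
#' (conditioning on the training phase series), refits each, and returns
#' pointwise percentile bands for the stimulus, history, and phase curves.
#' Non-convergent refits are dropped with a warning; more than 10% dropped is
#' an error.
#'
#' @param fit a converged \code{\link{ppm}} fit.
#' @param n_boot number of bootstrap replicates (default 200);
#'   \code{n_boot = 0} returns the fit unchanged.
#' @param level band level (default 0.95).
#' @param seed optional integer seed.
#' @param n curve grid size (default 200, matching \code{\link{ppm_curves}}).
#' @return the fit with a \code{confband} element: per-term list of
#'   \code{lo}/\code{hi} vectors on the \code{\link{ppm_curves}} grids.
#' @export
ppm_confband <- function(fit, n_boot = 200, level = 0.95, seed = NULL,
                         n = 200) {
  if (n_boot == 0) return(fit)
  .check(fit$converged, "confidence bands require a converged fit")
  if (!is.null(seed)) set.seed(seed)
  curves <- vector("list", n_boot)
  dropped <- 0
  pc <- .sim_precompute(fit)
  for (b in seq_len(n_boot)) {
    s <- .sim_from_fit(fit, pc = pc)
    d <- .design_from_counts(s$counts, fit$delta,
                             phase = fit$design$phase,
                             trial_length = fit$trial_length)
    rf <- tryCatch(suppressWarnings(
      ppm(d, fit$terms, knots = fit$knots, penalty = fit$penalty,
          order = fit$order, m_max = fit$m_max, convention = fit$convention,
          drop_no_history = fit$drop_no_history,
          unpenalized_intercept = fit$unpenalized_intercept,
          init = fit$coef)), error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { dropped <- dropped + 1; next }
    curves[[b]] <- ppm_curves(rf, n = n)
  }
  if (dropped > 0)
    warning(sprintf("%d of %d bootstrap refits dropped (non-convergent)",
                    dropped, n_boot))
  .check(dropped <= 0.1 * n_boot,
         "more than 10%% of bootstrap refits failed to converge")
  curves <- curves[!vapply(curves, is.null, logical(1))]
  a <- (1 - level) / 2
  band <- function(term, col) {
    M <- vapply(curves, function(cv) cv[[term]][[col]],
                numeric(nrow(curves[[1]][[term]])))
    list(lo = apply(M, 1, quantile, a), hi = apply(M, 1, quantile, 1 - a))
  }
  cb <- list()
  if ("stimulus" %in% fit$terms) cb$stimulus <- band("stimulus", "rate")
  if ("history" %in% fit$terms) cb$history <- band("history", "mult")
  if ("phase" %in% fit$terms) cb$phase <- band("phase", "mult")
  fit$confband <- cb
  fit$confband_n <- length(curves)
  fit
}

#' Time-rescaling goodness of fit
#'
#' Transforms interspike intervals by the integrated fitted intensity
#' (\eqn{z_i = 1 - e^{-\int\lambda}}) and tests the rescaled intervals for
#' uniformity with a Kolmogorov–Smirnov test.  A correct model yields
#' uniform \eqn{z_i}.
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param design a binned design (default: training design).
#' @return list with \code{statistic} (KS distance), \code{p_value}
#'   (NA with a warning when fewer than 10 spikes), and \code{z} (the
#'   rescaled intervals).
#' @export
ppm_gof <- function(fit, design = fit$design) {
  p <- exp(.eta_matrix(fit, design)) * design$delta
  z <- .rescaled_intervals(design$counts, p)
  if (length(z) < 10) {
    warning("fewer than 10 rescaled intervals; p value not reported")
    ks <- suppressWarnings(ks.test(z, "punif"))
    return(list(statistic = unname(ks$statistic), p_value = NA_real_, z = z))
  }
  ks <- suppressWarnings(ks.test(z, "punif"))
  list(statistic = unname(ks$statistic), p_value = ks$p.value, z = z)
}

#' Serialize a fitted model to JSON
#'
#' Writes the model specification (terms, knots, basis orders, convention),
#' coefficients, offsets, penalty, convergence diagnostics, and objective
#' trace, so fits are portable without R serialization.
#'
#' @param fit a \code{\link{ppm}} fit.
#' @param path output file; if NULL, the JSON string is returned.
#' @return \code{path} (or the JSON string), invisibly.
#' @export
write_ppm <- function(fit, path = NULL) {
  obj <- list(terms = fit$terms, knots = fit$knots, order = fit$order,
              m_max = fit$m_max, convention = fit$convention,
              coef = fit$coef, offsets = as.list(fit$offsets),
              penalty = fit$penalty, converged = fit$converged,
              n_cycles = fit$n_cycles, objective = fit$objective,
              obj_trace = fit$obj_trace, delta = fit$delta,
              trial_length = fit$trial_length, hist_span = fit$hist_span)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
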