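#' Trials needed to detect excess synchrony (closed form)
#'
#' Normal approximation to the synchrony test: with
#' \eqn{\log\hat\zeta \sim N(\log\zeta,\ \zeta^{-1}(NT\lambda_1\lambda_2
#' \delta)^{-1})}, the number of trials needed to reach the target power at
#' the given one-sided level is
#' \deqn{N = \left\lceil \frac{1}{T\lambda_1\lambda_2\delta}
#' \left(\frac{\Phi^{-1}(1-\alpha) -
#' \Phi^{-1}(1-\beta)/\sqrt{\zeta}}{\log\zeta}\right)^2 \right\rceil,}
#' where \eqn{1-\beta} is the target power.  \code{formula = "printed"}
#' divides the second quantile by \eqn{\zeta} instead of \eqn{\sqrt\zeta}
#' (the typographically ambiguous grouping of the source formula); the
#' default follows the variance derivation.
#'
#' @param zeta true synchrony ratio (\eqn{\zeta \neq 1}).
#' @param trial_length trial duration \eqn{T}, seconds.
#' @param rate1,rate2 mean firing rates, Hz.
#' @param delta synchrony bin, seconds (default 5 ms).
#' @param power target power (default 0.8).
#' @param alpha test level (default 0.05, one-sided as in the derivation).
#' @param formula \code{"derived"} (default) or \code{"printed"}.
#' @return integer number of trials.
#' @examples
#' sync_trials_needed(1.4, 2, 25, 25)
#' @export
sync_trials_needed <- function(zeta, trial_length, rate1, rate2,
                               delta = 5e-3, power = 0.8, alpha = 0.05,
                               formula = c("derived", "printed")) {
  formula <- match.arg(formula)
  .check(zeta > 0, "`zeta` must be positive")
  .check(abs(zeta - 1) > 1e-12, "zeta = 1: no effect to detect, N is infinite")
  .check(rate1 > 0 && rate2 > 0 && trial_length > 0 && delta > 0,
         "rates, trial length and delta must be positive")
  za <- qnorm(1 - alpha)
  zb <- qnorm(1 - power)
  denom <- if (formula == "derived") sqrt(zeta) else zeta
  as.integer(ceiling(((za - zb / denom) / log(zeta))^2 /
                       (trial_length * rate1 * rate2 * delta)))
}

#' Approximate power of the synchrony test (normal approximation)
#'
#' Two-sided rejection at level \code{alpha} using the null standard
#' deviation \eqn{(NT\lambda_1\lambda_2\delta)^{-1/2}} and the alternative
#' \eqn{\log\hat\zeta \sim N(\log\zeta, \zeta^{-1}(NT\lambda_1\lambda_2
#' \delta)^{-1})}.
#'
#' @inheritParams sync_trials_needed
#' @param n_trials number of trials.
#' @return power in [0, 1].
#' @export
analytic_sync_power <- function(zeta, n_trials, trial_length, rate1, rate2,
                                delta = 5e-3, alpha = 0.05) {
  base <- n_trials * trial_length * rate1 * rate2 * delta
  sd0 <- sqrt(1 / base)
  sdz <- sqrt(1 / (zeta * base))
  crit <- qnorm(1 - alpha / 2) * sd0
  pnorm((log(zeta) - crit) / sdz) + pnorm((-crit - log(zeta)) / sdz)
}

#' Power of the synchrony test by simulation
#'
#' Repeatedly generates an independent pair from fixed per-bin intensities,
#' injects synchrony at the target \eqn{\zeta} with
#' \code{\link{inject_synchrony}}, and estimates the rejection probability at
#' level \code{alpha}.  \code{method = "fast"} computes \eqn{\hat\zeta}
#' against the known generating intensities and uses the two-sided normal
#' approximation for the p value; \code{method = "full"} runs the entire
#' fit-and-parametric-bootstrap pipeline on every replicate (slow, but
#' end-to-end).
#'
#' @param zeta injected synchrony ratio (\eqn{\ge 1}).
#' @param n_trials trials per replicate dataset.
#' @param rate1,rate2 mean rates of the two (history-free) neurons, Hz.
#' @param trial_length trial duration, seconds.
#' @param reps number of replicate datasets (default 200).
#' @param alpha test level (default 0.05).
#' @param delta synchrony bin (default 5 ms).
#' @param delta_bin model bin (default 1 ms).
#' @param method \code{"fast"} or \code{"full"}.
#' @param G bootstrap size for \code{method = "full"}.
#' @param seed optional integer seed.
#' @return list with \code{power}, \code{se} (binomial), \code{reps},
#'   \code{log_zeta_hat} (per-replicate estimates).
#' @export
simulate_sync_power <- function(zeta, n_trials, rate1 = 25, rate2 = 25,
                                trial_length = 2, reps = 200, alpha = 0.05,
                                delta = 5e-3, delta_bin = 1e-3,
                                method = c("fast", "full"), G = 400,
                                seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  K <- round(trial_length / delta_bin)
  l1 <- matrix(rate1, K, n_trials)
  l2 <- matrix(rate2, K, n_trials)
  n_pred <- predict_sync(lambdaA = l1, lambdaB = l2, delta = delta,
                         delta_bin = delta_bin)
  sd0 <- sqrt(1 / (n_trials * trial_length * rate1 * rate2 * delta))
  lz <- numeric(reps)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    pair <- inject_synchrony(l1, l2, zeta, delta_sync = delta,
                             delta = delta_bin)
    n_obs <- .count_sync_binned(pair$counts1, pair$counts2, delta_bin, delta,
                                mode = "min")
    lz[r] <- log(n_obs / n_pred)
    if (method == "fast") {
      p <- 2 * pnorm(-abs(lz[r]) / sd0)
      rej[r] <- p < alpha
    } else {
      dA <- .design_from_counts(pair$counts1, delta_bin,
                                trial_length = trial_length)
      dB <- .design_from_counts(pair$counts2, delta_bin,
                                trial_length = trial_length)
      fitA <- suppressWarnings(ppm(dA, ~ stimulus + history))
      fitB <- suppressWarnings(ppm(dB, ~ stimulus + history))
      ts <- synchrony_test(fitA, fitB, G = G, delta = delta)
      rej[r] <- ts$p_value < alpha
    }
  }
  pw <- mean(rej)
  list(power = pw, se = sqrt(pw * (1 - pw) / reps), reps = reps,
       log_zeta_hat = lz)
}
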