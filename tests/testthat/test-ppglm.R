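test_that("log likelihood matches a brute-force per-bin loop", {
  spec <- quick_spec(n_trials = 2)
  sim <- simulate_spike_trains(spec, seed = 5)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- suppressWarnings(ppm(d, max_cycles = 3))
  ll <- ppm_loglik(fit, d)
  ## independent loop over every bin through the scalar intensity API
  acc <- 0
  for (j in 1:2) {
    for (k in seq_len(nrow(d$counts))) {
      lam <- conditional_intensity(fit, d$times[k], d$lag[k, j], d$phase[k, j])
      p <- lam * d$delta
      acc <- acc + d$counts[k, j] * log(p) - p
    }
  }
  expect_equal(ll, acc, tolerance = 1e-10)
})

test_that("log likelihood limiting cases hold", {
  spec <- quick_spec(n_trials = 1, history = hist_poisson())
  sim <- simulate_spike_trains(spec, seed = 6)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d, ~ stimulus)
  ## a design with no spikes gives -sum(p)
  empty <- spike_train_set(setNames(list(numeric(0)), "1"), 2)
  d0 <- bin_spikes(empty, sim$phase)
  expect_equal(ppm_loglik(fit, d0), -sum(predict(fit, d0)) * d0$delta,
               tolerance = 1e-12)
})

test_that("a constant-rate neuron is recovered by a stimulus-only model", {
  spec <- sim_spec(stimulus = stim_constant(20), history = hist_poisson(),
                   phase_mod = function(phi) rep(1, length(phi)),
                   n_trials = 60)
  sim <- simulate_spike_trains(spec, seed = 7)
  d <- bin_spikes(sim$spikes)
  fit <- ppm(d, ~ stimulus)
  cv <- ppm_curves(fit)
  mean_rate <- mean(cv$stimulus$rate)
  se <- sqrt(20 / (60 * 2))          # Poisson SE of the mean rate
  expect_lt(abs(mean_rate - 20), 3 * se)
  expect_null(cv$history)
  expect_null(cv$phase)
})

test_that("identifiability constraints hold and enforcement is inert", {
  spec <- quick_spec(n_trials = 10)
  sim <- simulate_spike_trains(spec, seed = 8)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d)
  cv <- ppm_curves(fit, 1000)
  norm3 <- oscsync:::.trapz(cv$phase$phi, cv$phase$mult) / (2 * pi)
  expect_equal(norm3, 1, tolerance = 1e-8)
  norm2 <- oscsync:::.trapz(cv$history$lag, cv$history$mult) / fit$hist_span
  expect_equal(norm2, 1, tolerance = 1e-8)

  ## idempotent, and the conditional intensity is untouched at every bin
  lam <- predict(fit)
  fit2 <- enforce_identifiability(fit)
  expect_equal(fit2$offsets, fit$offsets, tolerance = 1e-12)
  lam2 <- predict(fit2)
  idx <- cbind(sample(nrow(lam), 100, TRUE), sample(ncol(lam), 100, TRUE))
  expect_equal(lam2[idx], lam[idx], tolerance = 1e-10)
})

test_that("accepted back-fitting iterations never increase the objective", {
  spec <- quick_spec(n_trials = 5)
  sim <- simulate_spike_trains(spec, seed = 9)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d)
  expect_true(all(diff(fit$obj_trace) <= 1e-12))
  expect_true(fit$converged)
})

test_that("fit agrees with a generic optimizer on the penalized objective", {
  spec <- sim_spec(stimulus = stim_constant(120),
                   history = hist_refractory(0.004, 0.001),
                   phase_mod = phase_cosine(0.4, 0), freq = 40,
                   trial_length = 0.05, n_trials = 1)
  sim <- simulate_spike_trains(spec, seed = 20)    # 50-bin design
  d <- bin_spikes(sim$spikes, sim$phase)
  kn <- list(stimulus = seq(0, 0.05, length.out = 3),
             history = c(0, 0.005, 0.02), phase = phase_knots(3))
  fit <- ppm(d, knots = kn, order = 2, penalty = 0.5, tol = 1e-10)
  bld <- oscsync:::.ppm_build(d, fit$terms, kn, 2, 4, "radian", TRUE)
  np <- vapply(bld$Vstd, ncol, integer(1))
  Qfun <- function(th) {
    thl <- split(th, rep(seq_along(np), np))
    names(thl) <- names(np)
    eta <- Reduce(`+`, Map(function(V, t) drop(V %*% t), bld$Vstd, thl))
    oscsync:::.ppm_Q(eta, bld$y, log(d$delta), thl, 0.5,
                     lapply(thl, function(x) NULL))
  }
  o <- optim(rep(0, sum(np)), Qfun, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(fit$objective - o$value), 1e-6)
})

test_that("the reduced model never touches phase inputs", {
  spec <- quick_spec(n_trials = 5)
  sim <- simulate_spike_trains(spec, seed = 10)
  d_with <- bin_spikes(sim$spikes, sim$phase)
  d_without <- bin_spikes(sim$spikes)
  f1 <- ppm(d_with, ~ stimulus + history)
  f2 <- ppm(d_without, ~ stimulus + history)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_null(f1$coef$gamma)
  ## and requesting phase without a phase series fails up front
  expect_error(ppm(d_without, ~ stimulus + phase), "phase")
})

test_that("conditional intensity honors the omitted-factor contract", {
  spec <- quick_spec(n_trials = 5)
  sim <- simulate_spike_trains(spec, seed = 11)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d)
  ## no-history bins equal exp(f1 + f3) exactly
  lam_nh <- conditional_intensity(fit, 0.4, NA, 1.2)
  a <- drop(bspline_basis(0.4, fit$knots$stimulus, fit$order) %*%
              fit$coef$alpha) + fit$offsets["f1"]
  g <- drop(circular_basis(1.2, knots = fit$knots$phase) %*%
              fit$coef$gamma) + fit$offsets["f3"]
  expect_equal(lam_nh, unname(exp(a + g)), tolerance = 1e-12)
  expect_error(conditional_intensity(fit, 0.4, -0.01, 0), "positive")
  expect_error(conditional_intensity(fit, 0.4, NA, NaN), "finite")
  ## wrapping is applied before evaluation
  expect_equal(conditional_intensity(fit, 0.4, 0.05, 1.0),
               conditional_intensity(fit, 0.4, 0.05, 1.0 + 2 * pi),
               tolerance = 1e-12)
})

test_that("non-convergence is reported honestly", {
  spec <- quick_spec(n_trials = 3)
  sim <- simulate_spike_trains(spec, seed = 12)
  d <- bin_spikes(sim$spikes, sim$phase)
  expect_warning(fit <- ppm(d, max_cycles = 1), "did not converge")
  expect_false(fit$converged)
})

test_that("bootstrap confidence bands behave and cover the truth", {
  spec <- quick_spec(n_trials = 12)
  sim <- simulate_spike_trains(spec, seed = 13)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d)
  expect_identical(ppm_confband(fit, n_boot = 0), fit)
  fit <- ppm_confband(fit, n_boot = 25, seed = 14)
  expect_equal(fit$confband_n, 25)
  cv <- ppm_curves(fit)
  tr3 <- spec$phase_mod(cv$phase$phi)
  tr1 <- spec$stimulus(cv$stimulus$t)
  cover <- mean(c(tr3 >= fit$confband$phase$lo & tr3 <= fit$confband$phase$hi,
                  tr1 >= fit$confband$stimulus$lo & tr1 <= fit$confband$stimulus$hi))
  expect_gt(cover, 0.7)
})

test_that("time-rescaling flags a missing phase term when nothing can absorb it", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = phase_cosine(0.7, 0), freq = 2, n_trials = 30)
  p_full <- p_red <- numeric(3)
  for (s in 1:3) {
    sim <- simulate_spike_trains(spec, seed = 100 + s)
    d <- bin_spikes(sim$spikes, sim$phase)
    p_full[s] <- ppm_gof(ppm(d, ~ stimulus + phase))$p_value
    p_red[s] <- ppm_gof(ppm(d, ~ stimulus))$p_value
  }
  expect_true(all(p_red < p_full))
  expect_lt(mean(p_red), 0.05)
  ## the correctly specified model is not rejected
  expect_gt(mean(p_full), 0.01)
})

test_that("the unpenalized-intercept flag leaves the rate level unshrunk", {
  spec <- sim_spec(stimulus = stim_constant(40), history = hist_poisson(),
                   phase_mod = function(phi) rep(1, length(phi)), n_trials = 10)
  sim <- simulate_spike_trains(spec, seed = 15)
  d <- bin_spikes(sim$spikes)
  f_pen <- ppm(d, ~ stimulus, penalty = 200)
  f_unp <- ppm(d, ~ stimulus, penalty = 200, unpenalized_intercept = TRUE)
  r_pen <- mean(ppm_curves(f_pen)$stimulus$rate)
  r_unp <- mean(ppm_curves(f_unp)$stimulus$rate)
  ## heavy ridge pulls the penalized level toward zero; the exempted one stays
  expect_lt(r_pen, r_unp)
  expect_lt(abs(r_unp - 40), 3)
})
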