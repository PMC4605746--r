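test_that("identical spec and seed give identical spike trains", {
  spec <- quick_spec(n_trials = 5)
  s1 <- simulate_spike_trains(spec, seed = 1)
  s2 <- simulate_spike_trains(spec, seed = 1)
  expect_identical(s1$spikes$trials, s2$spikes$trials)
  expect_identical(unclass(s1$phase), unclass(s2$phase))
  s3 <- simulate_spike_trains(spec, seed = 2)
  expect_false(identical(s1$spikes$trials, s3$spikes$trials))
})

test_that("a homogeneous generator is Poisson-dispersed at the right rate", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = function(phi) rep(1, length(phi)),
                   trial_length = 2, n_trials = 200)
  sim <- simulate_spike_trains(spec, seed = 3)
  counts <- colSums(sim$counts)
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 200))
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("a hard refractory kernel forbids short ISIs and regularizes firing", {
  spec <- sim_spec(stimulus = stim_constant(60),
                   history = function(lag) as.numeric(lag >= 0.003),
                   phase_mod = function(phi) rep(1, length(phi)),
                   n_trials = 30)
  sim <- simulate_spike_trains(spec, seed = 4)
  isi <- unlist(lapply(sim$spikes$trials, diff))
  expect_gt(length(isi), 500)
  expect_true(all(isi >= 0.003))
  expect_lt(sd(isi) / mean(isi), 1)     # CV below the Poisson value
})

test_that("spike phases concentrate at the preferred phase for Poisson firing", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = phase_cosine(0.6, pref = 1.0), n_trials = 50)
  sim <- simulate_spike_trains(spec, seed = 5)
  ph <- phase_at_spikes(sim$spikes, sim$phase)
  circ_mean <- atan2(mean(sin(ph)), mean(cos(ph)))
  expect_lt(abs(circ_mean - 1.0), 0.15)
})

test_that("the oscillation phase series obeys its defining contracts", {
  ## fixed phi0 = 0: at t = 1/(2f) the phase is pi (wrapped to -pi)
  ph <- make_oscillation(50, 1, 1, rule = "fixed", phi0 = 0)
  k <- which.min(abs(attr(ph, "times") - 1 / (2 * 50)))
  expect_equal(abs(ph[k, 1]), pi, tolerance = 1e-9)
  ## f*T full cycles: the unwrapped phase advances by 2 pi f T
  d <- diff(ph[, 1]); d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_equal(sum(d) / (2 * pi), 50 * 1, tolerance = 0.01)
  ## uniform initial phases
  ph2 <- make_oscillation(40, 0.01, 1000, rule = "random", seed = 6)
  ks <- suppressWarnings(ks.test(attr(ph2, "phi0"), "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("discrete-time and Ogata continuous-time generation agree", {
  spec <- sim_spec(stimulus = stim_constant(30),
                   history = hist_refractory(0.004, 0.001),
                   phase_mod = phase_cosine(0.3, 0), freq = 20,
                   trial_length = 1, n_trials = 120)
  sd_ <- simulate_spike_trains(spec, seed = 7)
  so <- simulate_spike_trains(spec, seed = 8, method = "ogata")
  nd <- mean(lengths(sd_$spikes$trials))
  no <- mean(lengths(so$spikes$trials))
  pooled_se <- sqrt(var(lengths(sd_$spikes$trials)) / 120 +
                      var(lengths(so$spikes$trials)) / 120)
  expect_lt(abs(nd - no), 3.5 * pooled_se)
  expect_lt(abs(mean(unlist(lapply(sd_$spikes$trials, diff))) -
                  mean(unlist(lapply(so$spikes$trials, diff)))), 0.004)
})

test_that("synchrony injection preserves marginals and is a no-op at zeta = 1", {
  K <- 2000; n <- 15
  l <- matrix(25, K, n)
  set.seed(9)
  ## zeta = 1: thinning probability is exactly 1 and rates are untouched
  rates1 <- replicate(40, sum(inject_synchrony(l, l, 1)$counts1) / (n * 2))
  expect_lt(abs(mean(rates1) - 25), 0.015 * 25)
  ## zeta = 1.4: marginal rates preserved to the small-delta approximation
  rates <- replicate(40, {
    p <- inject_synchrony(l, l, 1.4)
    c(sum(p$counts1), sum(p$counts2)) / (n * 2)
  })
  expect_lt(abs(mean(rates) - 25), 0.02 * 25)

  ## infeasible thinning is reported with a bin index
  expect_error(inject_synchrony(l, l, zeta = 300), "bin")
  expect_error(inject_synchrony(l, l, zeta = 0.5), "bin")
})

test_that("mean of zeta-hat over replicates equals the injected zeta", {
  K <- 2000; n <- 15
  l <- matrix(25, K, n)
  np <- predict_sync(lambdaA = l, lambdaB = l, delta = 5e-3, delta_bin = 1e-3)
  set.seed(10)
  zh <- replicate(80, {
    p <- inject_synchrony(l, l, zeta = 1.5)
    oscsync:::.count_sync_binned(p$counts1, p$counts2, 1e-3, 5e-3,
                                 mode = "min") / np
  })
  expect_lt(abs(mean(zh) - 1.5), 3 * sd(zh) / sqrt(80))
})

test_that("simulating from a fitted model reproduces its firing statistics", {
  spec <- quick_spec(n_trials = 15)
  sim <- simulate_spike_trains(spec, seed = 11)
  d <- bin_spikes(sim$spikes, sim$phase)
  fit <- ppm(d)
  reps <- simulate(fit, nsim = 20, seed = 12)
  nsim <- mean(vapply(reps, function(s) sum(lengths(s$trials)), numeric(1)))
  nobs <- sum(d$counts)
  expect_lt(abs(nsim - nobs) / nobs, 0.05)
})
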