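test_that("the spike-phase histogram is a normalized density", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = function(phi) rep(1, length(phi)),
                   n_trials = 40)
  sim <- simulate_spike_trains(spec, seed = 1)
  h <- spike_phase_histogram(sim$spikes, sim$phase, n_bins = 16)
  bw <- diff(h$bin_edges)[1]
  expect_equal(sum(h$mass * bw), 1, tolerance = 1e-12)
  ## unmodulated firing gives a flat histogram within sampling error
  p_per_bin <- 1 / 16
  se <- sqrt(p_per_bin * (1 - p_per_bin) / h$n_spikes) / bw
  expect_lt(max(abs(h$mass - 1 / (2 * pi))), 4 * se)

  empty <- spike_train_set(setNames(rep(list(numeric(0)), 40),
                                    seq_len(40)), 2)
  expect_error(spike_phase_histogram(empty, sim$phase), "no spikes")
})

test_that("histogram estimates lambda3/2pi for Poisson firing", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = phase_cosine(0.4, pi), freq = 10, n_trials = 60)
  sim <- simulate_spike_trains(spec, seed = 2)
  h <- spike_phase_histogram(sim$spikes, sim$phase, n_bins = 16,
                             scale = "lambda3")
  centers <- (h$bin_edges[-1] + h$bin_edges[-17]) / 2
  expect_lt(max(abs(h$mass - spec$phase_mod(centers))), 0.12)
})

test_that("waiting-time density reduces to the exponential and integrates to 1", {
  C <- 25
  wt <- waiting_time_density(C, hist_poisson(),
                             function(phi) rep(1, length(phi)))
  expect_lt(max(abs(wt$density - C * exp(-C * wt$t))), 1e-3 * C)
  expect_equal(oscsync:::.trapz(wt$t, wt$density), 1, tolerance = 1e-4)
  expect_lt(attr(wt, "survival_end"), 1e-8)
})

test_that("waiting-time density matches the empirical ISI distribution", {
  histf <- hist_refractory(0.006, 0.002)
  spec <- sim_spec(stimulus = stim_constant(40), history = histf,
                   phase_mod = function(phi) rep(1, length(phi)),
                   n_trials = 60)
  sim <- simulate_spike_trains(spec, seed = 3)
  isi <- unlist(lapply(sim$spikes$trials, diff))
  wt <- waiting_time_density(40, histf, function(phi) rep(1, length(phi)))
  cdf <- cumsum(wt$density) * diff(wt$t)[1]
  th_q <- approx(cdf, wt$t, xout = c(0.25, 0.5, 0.75))$y
  em_q <- unname(quantile(isi, c(0.25, 0.5, 0.75)))
  expect_lt(max(abs(th_q - em_q)), 0.002)
})

test_that("the transition operator is column-stochastic with unit eigenvalue", {
  A <- phase_transition_matrix(25, hist_refractory(0.015, 0.004),
                               phase_cosine(0.4, pi), freq = 10, m = 32)
  expect_lt(max(abs(colSums(A) - 1)), 1e-7)
  P <- theoretical_phase_distribution(25, hist_refractory(0.015, 0.004),
                                      phase_cosine(0.4, pi), freq = 10, m = 32)
  expect_lt(abs(P$eigenvalue - 1), 1e-6)
  bw <- 2 * pi / 32
  expect_equal(sum(P$mass * bw), 1, tolerance = 1e-10)
})

test_that("Poisson firing solves the fixed point at lambda3/2pi", {
  lam3 <- phase_cosine(0.4, pi)
  P <- theoretical_phase_distribution(25, hist_poisson(), lam3,
                                      freq = 10, m = 64)
  truth <- lam3(P$centers) / (2 * pi)
  expect_lt(max(abs(P$mass - truth)), 1e-3)
  ## plugging lambda3/2pi into the discretized operator returns itself
  ## (up to the operator's own phase-binning error)
  A <- phase_transition_matrix(25, hist_poisson(), lam3, freq = 10, m = 64)
  v <- truth / sum(truth)
  expect_lt(max(abs(drop(A %*% v) - v)), 1e-3 * max(v))
})

test_that("non-Poisson firing biases the histogram exactly as the operator predicts", {
  hist_np <- hist_refractory(0.015, 0.004)
  lam3 <- phase_cosine(0.4, pi)
  m <- 32
  P <- theoretical_phase_distribution(25, hist_np, lam3, freq = 10, m = m)
  truth <- lam3(P$centers) / (2 * pi)
  ## the prediction departs from lambda3/2pi ...
  expect_gt(max(abs(P$mass - truth)), 5e-3)
  ## ... and matches a long simulation better than lambda3/2pi does
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_np,
                   phase_mod = lam3, freq = 10, n_trials = 150)
  sim <- simulate_spike_trains(spec, seed = 4)
  h <- spike_phase_histogram(sim$spikes, sim$phase, n_bins = m)
  se <- sqrt((1 / m) / h$n_spikes) / (2 * pi / m)
  expect_lt(mean(abs(h$mass - P$mass)), 3 * se)
  expect_lt(mean(abs(h$mass - P$mass)), mean(abs(h$mass - truth)))
})

test_that("the eigenvector solution is stable under refinement of m", {
  lam3 <- phase_cosine(0.4, pi)
  hist_np <- hist_refractory(0.015, 0.004)
  P32 <- theoretical_phase_distribution(25, hist_np, lam3, freq = 10, m = 32)
  P64 <- theoretical_phase_distribution(25, hist_np, lam3, freq = 10, m = 64)
  at32 <- approx(P64$centers, P64$mass, xout = P32$centers, rule = 2)$y
  expect_lt(max(abs(P32$mass - at32)), 0.2 / 32)
})

test_that("MISE decomposes into variance plus squared bias", {
  spec <- sim_spec(stimulus = stim_constant(25), history = hist_poisson(),
                   phase_mod = phase_cosine(0.4, pi), freq = 10, n_trials = 8)
  out <- compare_phase_estimators(spec, trial_counts = 8, n_datasets = 4,
                                  hist_bins = c(8, 16), seed = 5)
  expect_equal(out$mise, out$variance + out$bias_sq, tolerance = 1e-6)
  expect_setequal(out$method, c("histogram", "glm"))
})
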