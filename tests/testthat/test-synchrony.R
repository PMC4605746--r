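test_that("synchronous-spike counting matches direct enumeration", {
  a <- spike_train_set(list(`1` = c(0.010, 0.020, 0.030)), 0.1)
  b <- spike_train_set(list(`1` = c(0.012, 0.040)), 0.1)
  expect_equal(count_sync(a, b, 5e-3, "interval"), 1L)
  ## identical trains: every spike is a coincidence
  expect_equal(count_sync(a, a, 5e-3, "interval"), 3L)
  expect_equal(count_sync(a, a, 5e-3, "binned"), 3L)
  ## mismatched trials rejected
  c2 <- spike_train_set(list(`1` = 0.01, `2` = 0.02), 0.1)
  expect_error(count_sync(a, c2), "mismatched")
})

test_that("both conventions match their oracles on random sparse trains", {
  set.seed(1)
  delta <- 5e-3
  for (r in 1:20) {
    ta <- sort(runif(6, 0, 1)); tb <- sort(runif(6, 0, 1))
    A <- spike_train_set(list(`1` = ta), 1)
    B <- spike_train_set(list(`1` = tb), 1)
    ## interval convention vs exhaustive greedy pair matching
    expect_equal(count_sync(A, B, delta, "interval"),
                 match_pairs_oracle(ta, tb, delta))
    ## binned conventions vs tabulated-count oracles
    ca <- tabulate(floor(ta / delta) + 1L, 200)
    cb <- tabulate(floor(tb / delta) + 1L, 200)
    expect_equal(count_sync(A, B, delta, "binned"), sum(pmin(ca, cb)))
    expect_equal(count_sync(A, B, delta, "pairs"), sum(ca * cb))
  }
})

test_that("conventions agree when spikes are clearly apart or exactly shared", {
  set.seed(2)
  delta <- 5e-3
  for (r in 1:10) {
    ## spikes on a 20 ms lattice: any close pair is exactly coincident
    ta <- sort(sample(seq(0.01, 0.99, 0.02), 8))
    shared <- sample(ta, 3)
    tb <- sort(c(shared, sample(setdiff(seq(0.02, 0.98, 0.02), ta), 4)))
    A <- spike_train_set(list(`1` = ta), 1)
    B <- spike_train_set(list(`1` = tb), 1)
    expect_equal(count_sync(A, B, delta, "binned"),
                 count_sync(A, B, delta, "interval"))
    expect_equal(count_sync(A, B, delta, "pairs"),
                 count_sync(A, B, delta, "interval"))
  }
})

test_that("predicted synchrony matches the constant-rate closed form", {
  K <- 2000
  l25 <- matrix(25, K, 1)
  expect_equal(predict_sync(lambdaA = l25, lambdaB = l25, delta = 5e-3,
                            delta_bin = 1e-3), 6.25, tolerance = 1e-12)
  expect_equal(predict_sync(lambdaA = l25 * 0, lambdaB = l25, delta = 5e-3,
                            delta_bin = 1e-3), 0)
  ## doubling delta approximately doubles N_pred for smooth rates
  lam <- matrix(25 * (1 + 0.3 * sin(2 * pi * (1:K) / K)), K, 1)
  r <- predict_sync(lambdaA = lam, lambdaB = lam, delta = 1e-2,
                    delta_bin = 1e-3) /
    predict_sync(lambdaA = lam, lambdaB = lam, delta = 5e-3, delta_bin = 1e-3)
  expect_equal(r, 2, tolerance = 0.01)
})

test_that("zeta-hat is invariant to relabeling the neurons", {
  spec <- quick_spec(n_trials = 10)
  set.seed(3)
  pair <- simulate_pair(spec, spec)
  d1 <- bin_spikes(pair$n1$spikes, pair$phase)
  d2 <- bin_spikes(pair$n2$spikes, pair$phase)
  f1 <- ppm(d1); f2 <- ppm(d2)
  z12 <- estimate_zeta(f1, f2)
  z21 <- estimate_zeta(f2, f1)
  expect_equal(z12$zeta_hat, z21$zeta_hat, tolerance = 1e-12)
  expect_equal(z12$n_obs, z21$n_obs)
})

test_that("zero observed coincidences yield a flagged -Inf log zeta", {
  a <- spike_train_set(list(`1` = c(0.2, 0.6)), 2)
  b <- spike_train_set(list(`1` = c(1.0, 1.5)), 2)
  fa <- ppm(bin_spikes(a), ~ stimulus, penalty = 5)
  fb <- ppm(bin_spikes(b), ~ stimulus, penalty = 5)
  expect_warning(z <- estimate_zeta(fa, fb), "-Inf")
  expect_true(z$degenerate)
  expect_identical(z$log_zeta_hat, -Inf)
})

test_that("the bootstrap p value is the exact exceedance fraction", {
  spec <- quick_spec(n_trials = 12)
  set.seed(4)
  pair <- simulate_pair(spec, spec)
  f1 <- ppm(bin_spikes(pair$n1$spikes, pair$phase))
  f2 <- ppm(bin_spikes(pair$n2$spikes, pair$phase))
  ts <- synchrony_test(f1, f2, G = 120, seed = 5)
  expect_equal(ts$p_value,
               mean(abs(ts$log_zeta_boot) > abs(ts$log_zeta_hat)))
  expect_equal(ts$G, 120)
  expect_warning(synchrony_test(f1, f2, G = 60, seed = 6), "resolution")
})

test_that("a shared-oscillation pair is explained by the full model only", {
  ## different preferred phases suppress synchrony; the phase-free model
  ## misses it, the phase-including model explains it (the headline workflow)
  spec1 <- quick_spec(n_trials = 80, a = 0.7, pref = 0)
  spec2 <- quick_spec(n_trials = 80, a = 0.7, pref = pi)
  spec2$stimulus <- stim_fluctuating(25, f_slow = 1)
  set.seed(7)
  pair <- simulate_pair(spec1, spec2)
  d1 <- bin_spikes(pair$n1$spikes, pair$phase)
  d2 <- bin_spikes(pair$n2$spikes, pair$phase)
  r1 <- ppm(d1, ~ stimulus + history); r2 <- ppm(d2, ~ stimulus + history)
  ts_red <- synchrony_test(r1, r2, G = 200, seed = 8)
  u1 <- ppm(d1); u2 <- ppm(d2)
  ts_full <- synchrony_test(u1, u2, G = 200, seed = 9)
  expect_lt(ts_red$log_zeta_hat, 0)          # suppressed synchrony
  expect_lt(ts_red$p_value, 0.05)            # reduced model rejected
  expect_gt(ts_full$p_value, 0.05)           # full model explains it
  expect_lt(abs(ts_full$log_zeta_hat), abs(ts_red$log_zeta_hat))
})

test_that("N_pred matches the mean simulated N_obs under the fitted model", {
  spec <- quick_spec(n_trials = 15)
  set.seed(10)
  pair <- simulate_pair(spec, spec)
  f1 <- ppm(bin_spikes(pair$n1$spikes, pair$phase))
  f2 <- ppm(bin_spikes(pair$n2$spikes, pair$phase))
  ts <- synchrony_test(f1, f2, G = 300, seed = 11)
  ## bootstrap replicates are generated from the fitted models, so their
  ## mean log zeta must sit near zero
  expect_lt(abs(mean(ts$log_zeta_boot)), 3 * sd(ts$log_zeta_boot) / sqrt(300))
})
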