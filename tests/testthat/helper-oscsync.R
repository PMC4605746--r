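# shared fixtures: small generator specs used across test files

quick_spec <- function(n_trials = 20, rate = 25, a = 0.4, pref = pi,
                       freq = 40, history = hist_refractory(),
                       trial_length = 2) {
  sim_spec(stimulus = stim_fluctuating(rate),
           history = history,
           phase_mod = phase_cosine(a, pref = pref),
           freq = freq, trial_length = trial_length, n_trials = n_trials)
}

## independent greedy pair-matching oracle: O(nA * nB) enumeration of pairs
## closer than delta, matched earliest-first, each spike used once
match_pairs_oracle <- function(ta, tb, delta) {
  usedA <- rep(FALSE, length(ta)); usedB <- rep(FALSE, length(tb))
  n <- 0L
  repeat {
    best <- NULL
    for (i in seq_along(ta)) {
      if (usedA[i]) next
      for (k in seq_along(tb)) {
        if (usedB[k]) next
        if (abs(ta[i] - tb[k]) < delta &&
            (is.null(best) || min(ta[i], tb[k]) < best$t)) {
          best <- list(i = i, k = k, t = min(ta[i], tb[k]))
          break
        }
      }
    }
    if (is.null(best)) break
    usedA[best$i] <- TRUE; usedB[best$k] <- TRUE
    n <- n + 1L
  }
  n
}

## textbook Cox-de Boor recursion, independent of splines::splineDesign
cox_de_boor <- function(x, knots, order) {
  lo <- knots[1]; hi <- knots[length(knots)]
  aug <- c(rep(lo, order - 1), knots, rep(hi, order - 1))
  nb <- length(aug) - order
  B <- function(i, k, x) {
    if (k == 1) {
      ## right-closed at the last interior boundary
      if (aug[i] <= x && (x < aug[i + 1] ||
                          (x == hi && aug[i + 1] == hi && aug[i] < hi))) 1 else 0
    } else {
      d1 <- aug[i + k - 1] - aug[i]
      d2 <- aug[i + k] - aug[i + 1]
      a <- if (d1 > 0) (x - aug[i]) / d1 * B(i, k - 1, x) else 0
      b <- if (d2 > 0) (aug[i + k] - x) / d2 * B(i + 1, k - 1, x) else 0
      a + b
    }
  }
  vapply(seq_len(nb), function(i) B(i, order, x), numeric(1))
}
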