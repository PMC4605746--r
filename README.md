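# oscsync

Point-process regression linking network oscillations to spike synchrony.

Neurons recorded together often fire within a few milliseconds of each
other more (or less) often than chance.  `oscsync` asks whether a
network-wide oscillation — measured as the phase of a band-limited local
field potential (LFP) — statistically explains that excess or suppressed
synchrony.  It is written for electrophysiologists and statisticians
working with trial-structured spike trains plus an oscillatory covariate
(in vitro paired recordings, multi-electrode array data, or simulations).

## The method

Each neuron's spiking is a point process with multiplicative conditional
intensity

&nbsp;&nbsp;log λ(t | H_t, X_t) = f₁(t) + f₂(t − t\*) + f₃(Φ_t)

where f₁ is the trial-locked stimulus (PSTH) effect on a cubic B-spline
basis, f₂ is the auto-history effect of the lag since the most recent spike
t\* (refractoriness, bursting) on a short-lag B-spline basis, and f₃ is the
modulation by the oscillation phase Φ_t on a periodic circular-spline
basis.  The model is fitted by penalized maximum likelihood on a 1 ms bin
grid with back-fitting IRLS, under the identifiability constraints
(1/L)∫e^{f₂} = 1 and (1/2π)∫e^{f₃} = 1.

For a pair of neurons, the number of near-coincident spikes expected under
conditional independence is accumulated over δ = 5 ms bins,

&nbsp;&nbsp;N_pred = Σ_trials Σ_bins [∫_bin λ̂_A] · [∫_bin λ̂_B],

and compared with the observed count through the synchrony ratio
ζ̂ = N_obs / N_pred.  H₀: log ζ = 0 is tested by parametric bootstrap from
the fitted single-neuron models.  Fitting the pair **without** the phase
term and then **with** it turns the comparison into an attribution: if the
phase-free model is rejected but the phase-including model is not, the
shared oscillation accounts for the synchrony.  The package also ships the
theory of spike-phase-histogram bias for non-Poisson firing (stationary
eigenvector of the phase-transition operator), estimator comparisons
(MISE = variance + bias²), a closed-form and simulation-based power
analysis for synchrony detection, and LFP preprocessing (zero-phase 4–25 Hz
band-pass, Hilbert phase, electrode-neighbor averaging, spike-triggered
averages).

## Worked example

Two simulated neurons share a 40 Hz oscillatory drive but prefer opposite
phases, which *suppresses* their coincidences; each neuron is then fitted
separately and the pair tested, first without and then with the phase term:

```r
library(oscsync)

spec1 <- sim_spec(stimulus = stim_fluctuating(25), history = hist_refractory(),
                  phase_mod = phase_cosine(0.7, pref = 0), freq = 40,
                  trial_length = 2, n_trials = 80)
spec2 <- spec1
spec2$stimulus  <- stim_fluctuating(25, f_slow = 1)
spec2$phase_mod <- phase_cosine(0.7, pref = pi)
pair <- simulate_pair(spec1, spec2, seed = 42)

d1 <- bin_spikes(pair$n1$spikes, pair$phase)
d2 <- bin_spikes(pair$n2$spikes, pair$phase)

## phase-free (reduced) models: is the pair conditionally independent?
r1 <- ppm(d1, ~ stimulus + history)
r2 <- ppm(d2, ~ stimulus + history)
synchrony_test(r1, r2, G = 400, seed = 1)
#> Spike synchrony (delta = 5 ms, pairs convention)
#>   N_obs = 360, N_pred = 429.63
#>   zeta-hat = 0.8379, log zeta-hat = -0.1768
#>   bootstrap (G = 400): SE = 0.0496, 95% CI [-0.2741, -0.0796], p = 0

## full models including the oscillatory phase term
f1 <- ppm(d1)
f2 <- ppm(d2)
synchrony_test(f1, f2, G = 400, seed = 2)
#> Spike synchrony (delta = 5 ms, pairs convention)
#>   N_obs = 360, N_pred = 348.45
#>   zeta-hat = 1.0332, log zeta-hat = 0.0326
#>   bootstrap (G = 400): SE = 0.0535, 95% CI [-0.0723, 0.1375], p = 0.4975

summary(f1)
#> Point-process GLM summary
#>   terms: stimulus + history + phase
#>   spikes: 3672 (mean rate 22.95 Hz)
#>   objective: 16411.2487 (10 cycles, converged)
#>   phase modulation amplitude (max-min)/2: 0.730, preferred phase -0.06 rad
#>   minimum history multiplier: 0.044
```

Reading the numbers: 360 coincidences were observed against 429.6 predicted
by the phase-free models — 16% fewer than chance (log ζ̂ = −0.18), and no
bootstrap replicate was that extreme (p < 1/400), so conditional
independence given stimulus and history alone is rejected.  Adding the
phase term moves the prediction to 348.5 (log ζ̂ = 0.03, p = 0.50): the
shared oscillation fully accounts for the suppressed synchrony.  The fitted
phase curve recovers the generating modulation (amplitude 0.73 vs. 0.7,
preferred phase −0.06 vs. 0), and the history multiplier shows the imposed
refractoriness.  `plot(f1)` draws the three effect curves;
`ppm_confband()` adds bootstrap bands; `ppm_gof()` checks fit by time
rescaling.

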