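---
title: "An entropy-maximization recurrent network model of early auditory processing and tinnitus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An entropy-maximization recurrent network model of early auditory processing and tinnitus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`emrnet` simulates a rate network of `M` input neurons `x` (inner-hair-cell
channels on a log-frequency axis) feeding `N > M` output neurons `s`
(an overcomplete representation, as in the dorsal cochlear nucleus). The
activity obeys

$$\tau \frac{ds_i}{dt} = -s_i + g\Big(\sum_j W_{ij} x_j + \sum_k K_{ik} s_k - T_i\Big),
\qquad g(h) = \frac{1}{1+e^{-h}},$$

with feed-forward weights `W`, recurrent weights `K` and thresholds `T`.
Stimuli vary slowly relative to `tau`, so the network's response to a
stimulus is taken to be the steady state

$$s_i = g\Big(\sum_j W_{ij} x_j + \sum_k K_{ik} s_k - T_i\Big).$$

A fixed point is linearly stable iff every eigenvalue of `I - G K` has
positive real part, where `G = diag(g'(h_i))`. Because `max g' = 1/4`
(attained at `h = 0`), stability is guaranteed while the spectral radius
`rho(K) < 4`; the surface `rho(K) = 4` is the practical surrogate for the
critical point, and `scripts/acceptance.R` recomputes that boundary from
scratch.

## The learning rule

Plasticity maximizes the entropy of the output representation. For the
steady-state map, the susceptibility matrix is
`chi = ds/dx = phi W` with `phi = (I - G K)^{-1} G`, and the objective
(to be minimized) is

$$\varepsilon = -\tfrac{1}{2}\,\big\langle \log\det(\chi^\top \chi)\big\rangle_x
 + \lambda_W \sum_{ij} |W_{ij}| + \tfrac{\lambda_K}{2}\sum_{ik} K_{ik}^2 .$$

The log-determinant of the Gram matrix of the tall Jacobian is the
standard entropy payoff for an overcomplete map; increasing it inflates
the singular values of `chi`, which is achieved by driving the eigenvalues
of `I - G K` toward zero — i.e. unregularized entropy maximization pushes
the network *into* the critical point. The regularization terms (an l1
penalty on `W`, an l2 penalty on `K` by default; both norms are available
for both matrices) hold the dynamics in the subcritical regime and play
the role of a homeostatic cost on strong synapses.

Gradient descent on `eps` gives, per sample,

* `dW`-payoff: `phi^T ((chi^+)^T + y x^T)`,
* `dK`-payoff: `phi^T (chi chi^+ + y s^T)`,
* `dT`-payoff: `-phi^T y`,

with `chi^+ = (chi^T chi)^{-1} chi^T` and
`y_l = (chi chi^+ phi)_{ll}\, g''(h_l)/g'(h_l)^3`. These expressions are
implemented in `em_gradients()` and are gated, in the test suite, by a
central-finite-difference oracle on the scalar objective: every entry of
every block must agree with the numerical derivative to better than
`1e-5` relative error, for both regularization norms. That oracle is the
package's primary correctness guarantee, and it also fixes the
interpretation of the matrix logarithm in the objective as a
log-determinant: with any other reading the analytic and numerical
gradients disagree immediately.

Autapses are excluded: the diagonal of `K` is truncated to zero after
every update. The expectation over stimuli is approximated by online
single-sample updates; batch evaluation is kept for the objective and the
gradient tests.

## Stimuli and deprivation

Each synthetic stimulus is a mixture of 1–5 Gaussian tones on the channel
axis — centers uniform on `[1, M]`, amplitudes uniform on `[7, 10]`
(arbitrary units, reflecting the roughly uniform distribution of
log-amplitudes after peripheral gain control), widths folded-normal with
scale `M/2` (floored at 0.25 channels to avoid single-sample spikes) —
plus per-channel uniform `[0, 1]` noise. A calibration batch (10,000
samples by default) fixes the global divisor at twice the largest observed
activation, putting all subsequent samples in `[0, 0.5]`; the scale is
frozen thereafter because an online generator cannot know the global
maximum, and rare later exceedances are clipped. The tone count is drawn
uniformly from `{1, ..., 5}`: a zero-tone stimulus would be pure noise,
and tone Gaussians add linearly where they overlap.

Hearing loss is a multiplicative envelope on the input:
`a(k) = 1/(1 + exp(-beta (k0 - k)))` for a sloping loss (positive `beta`
attenuates the high-frequency side; `beta = -10` mirrors it), and a
two-sigmoid combination for a band loss between `k1` and `k2`. Channel
indices are 1-based throughout, matching the convention that `k0 = M/2`
sits mid-band.

## Training schedule

Training is divided into three phases (`default_schedule()`):

1. **Feed-forward phase** — `W` and `T` learn on unattenuated stimuli
   (`eta = 0.1`, `lambda_W = 0.001`), with `K = 0`. `W` starts from weak
   Gaussian bumps with ordered centers (amplitude 0.5, width 1 channel,
   `T = 0`), and the tonotopic order survives training.
2. **Recurrent phase** — only `K` learns (`eta = 0.001`), on unattenuated
   stimuli. The aligned average row profile of the learned `K` develops a
   Mexican-hat shape: excitation at small preferred-frequency offsets,
   inhibition at intermediate ones.
3. **Deprivation phase** — identical settings, but stimuli are attenuated.
   Only the recurrent connections adapt; this is the sensory-deprivation
   experiment.

## Choosing `lambda_K`, and the two problem sizes

The location of the sharp drop in `rho(K)` as a function of `lambda_K`
depends mainly on the number of output neurons, so the recurrent
regularization coefficient must be chosen per network size by a coarse
grid search (`lambda_sweep()`, driven by `analysis/05_lambda_sweep.R`).
The usable range is the *hallucination interval*: below it the recurrent
pretraining itself goes near-critical, above it deprivation can no longer
pull the network to the critical point. A value near the interval's upper
bound maximizes the homeostatic cost while still allowing the deprivation
transition, and favors single-peaked spontaneous profiles.

Two configurations are used throughout:

* **Full size** (`M = 40`, `N = 400`): the biological-scale configuration,
  `lambda_K = 0.226`, phase lengths 50k / up to 1M / up to 1M samples.
  One run takes hours on a single CPU; `analysis/02_train.R --full` runs
  it at 100k recurrent samples per phase (learning converges well before
  the nominal 1M).
* **Smoke size** (`M = 10`, `N = 40`): the default of
  `deprivation_experiment()` and the scale exercised by the test suite;
  phase lengths 20k / 30k / 30k, evaluation set of 200 stimuli, 25-point
  scaling grids. The grid search places the hallucination interval at
  roughly `lambda_K` in `[0.05, 0.12]` for this size, and the default
  `lambda_K = 0.12` sits at its upper bound. A full smoke run, including
  the measurement battery, takes on the order of a minute.

All qualitative signatures — the Mexican hat, the post-deprivation shift
of the critical scale toward the operating point, the deprived-zone
hallucination, the elevated in-band audiogram — appear at the smoke size.
The *printed* full-size quantities (critical scales near 3.14 before and
1.07 after deprivation, the hallucination interval near `[0.183, 0.228]`)
are properties of the `N = 400` configuration and are not expected to
match numerically at the smoke size.

## Numerical choices

* **Steady states.** Newton-Raphson on the fixed-point equation with
  update `s <- s - (I - G K)^{-1}(s - g(h))`, residual tolerance `1e-10`
  (tightened to `1e-12`/`1e-13` where a downstream derivative is taken),
  200-iteration budget. The initializer is the recurrence-free response
  `g(W x - T)`; iterates are clamped to the open unit cube. Failures are
  reported, never thrown; `steady_state()` optionally eigen-checks
  stability and falls back to Euler, which is how the symmetry-broken
  supercritical attractors are reached (Newton happily lands on the
  *unstable* homogeneous point there).
* **Euler integration.** `dt = 0.1 tau`, `tau = 1`, stopping when the
  per-step change drops below `1e-6` (all configurable). The step count
  doubles when `dt` halves, so convergence *times* are meaningful only up
  to the arbitrary time unit — the divergence location along a scaling
  sweep, not the absolute count, is the reproducible content.
* **Training robustness.** Samples whose solve or Jacobian fails are
  skipped and counted; a phase aborts when more than 1% of samples fail
  within any 10,000-sample window.
* **Silent attractors.** Found by Euler from `g(-T)` plus uniform noise
  of magnitude `1e-3`; a noiseless start would sit forever on the unstable
  homogeneous point. The hallucination flag compares the peak excess over
  the pre-deprivation baseline against 5 baseline standard deviations,
  floored at an absolute 0.01 so that a perfectly homogeneous baseline
  cannot make solver-precision wiggles look like pathology; the raw score
  is always reported alongside.
* **Audiograms.** Per channel, bisection on the probe amplitude in
  `[0, 100]` (tolerance `1e-6`) for an infinity-norm response difference
  of 0.01 against the silent response. The probe is a single-channel
  delta by default (a narrow Gaussian is available via `probe_width`),
  and it passes through the attenuation envelope when one is supplied —
  the hearing loss attenuates the periphery, which is what elevates
  in-band thresholds, up to the interval ceiling for strongly attenuated
  channels (flagged rather than extrapolated).
* **Measures.** The correlation ensemble is a fixed evaluation set drawn
  from the pre-deprivation stimulus distribution and reused across scales
  and checkpoints; zero-variance neurons are excluded pairwise and
  counted. The population vector uses angles `2 pi k / N` over the output
  index; boundary conditions are not periodic, but with `N >> 1` the edge
  effect is negligible. The scaling-sweep attractor search and
  convergence-time measures use the silent stimulus, since symmetry
  breaking is defined in the absence of structured input.

## What the synthetic data does and does not capture

The generator reproduces the statistical skeleton the analysis relies on:
log-spaced tonotopy, narrowband tone mixtures with uniform log-amplitudes,
additive background noise, bounded normalized activations, and
multiplicative band-limited deprivation. It contains no cochlear
mechanics, no temporal structure (every stimulus is a static snapshot
under the slow-modulation assumption), no realistic loudness model, and no
across-channel noise correlations. Consequently the tests certify the
plasticity-criticality mechanism — deprivation raising recurrent gain and
shifting the operating point toward criticality — not any quantitative
match to physiological tuning curves or psychoacoustic audiograms.

## Known limitations

* At the smoke size the deprived zone spans only a handful of channels,
  so the spontaneous bump is ragged: secondary local maxima appear inside
  the deprived zone even though the dominant peak is well localized. The
  full-size network sharpens this into the clean single peak.
* The 5-standard-deviation hallucination flag is conservative at small
  `N`, where the pre-deprivation silent response is itself structured;
  the raw score and population-vector magnitude are the robust readouts.
* Plain subgradient descent with an l1 recurrent penalty leaves pruned
  weights oscillating at the step quantum `eta * lambda_K` rather than
  exactly zero (there is no proximal step, matching the plain
  gradient-descent rule); sparsity is therefore assessed against a small
  multiple of that quantum.
* Near the critical point, Euler convergence times are capped by the
  sweep's step budget; capped points are reported as missing values.
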