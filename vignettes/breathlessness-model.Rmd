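---
title: "A Bayesian observer model of breathlessness perception: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian observer model of breathlessness perception: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathless)
```

## The scientific problem

In a hypercapnic rebreathing session a participant breathes from a closed
bag, so inhaled CO₂ rises steadily; end-tidal CO₂ (etCO₂, the maximum CO₂
concentration in each exhaled breath, a proxy for arterial CO₂) is recorded
alongside breathlessness ratings on a 0–100 visual analog scale every 10 s.
Strikingly, participants receiving essentially the same CO₂ stimulus report
very different breathlessness time courses: some track the stimulus and
recover quickly, some barely respond, and some remain intensely breathless
long after etCO₂ has returned to baseline. `breathless` implements a
single-mechanism explanation: perception reflects a Bayesian estimate of a
latent *respiratory state*, formed by combining noisy CO₂ measurements with
predictions from an internal model, and individuals differ only in how the
components are weighted.

## Model structure and assumptions

The model operates on the 10 s rating grid (the fitted observables are the
binned etCO₂ and the ratings), not on individual physiological breaths.
Four stages are composed per bin:

1. **Internal CO₂ estimation.** The internal representation assumes CO₂
   changes slowly but randomly between bins — a scalar random-walk
   state-space model. The optimal estimator is then a scalar Kalman filter
   whose behaviour depends only on the ratio `rho` of measurement-noise
   variance to process-noise variance; we therefore fix the process
   variance at 1 without loss of generality and fit `rho`. The filter is
   started diffusely (variance 10³) at the first observation, so the first
   estimate equals the first observation. We run the full time-varying
   recursion; `steady_state_gain()` exposes the closed-form fixed point
   for analysis.

2. **Activity context.** A constant context `A` — the expected respiratory
   demand of the current situation — exerts an effect that builds up by
   first-order relaxation with time constant `tau_a` and saturates at `A`.
   With the default `tau_a` = 40 s the effect passes 95 % of `A` after
   about two minutes, matching the build-up seen in prediction-dominated
   participants.

3. **Respiratory state.** The state predicted from the previous bin,
   `alpha * x[t-1] + (1 - alpha) * a[t]`, is updated toward the sensory
   term `c_hat[t] - c_ref` with an individual weight `w_c` in [0, 1]:

   `x[t] = (1 - w_c) (alpha x[t-1] + (1 - alpha) a[t]) + w_c (c_hat[t] - c_ref)`

   A small `w_c` means the state is dominated by prediction and context;
   `w_c = 1` makes it track the CO₂ estimate directly.

4. **Readout.** Ratings are a linear transformation of the state with gain
   and offset, clipped to the hard limits of the rating instrument,
   [0, 100].

The five free parameters (`rho`, `w_c`, `A`, `gain`, `offset`) are fitted
per participant; `alpha` (0.8 per 10 s bin, a state memory of roughly
45 s), `tau_a` (40 s) and `c_ref` (5 % CO₂, the initial bag concentration,
serving as a setpoint proxy) are structural constants shared across
participants and configurable in `model_params()`.

### Why the weighted (convex) state update

With a linear readout, an *additive* sensory term
(`x[t] = alpha x[t-1] + w_c (c_hat[t]-c_ref) + (1-alpha) a[t]`) leaves the
predicted ratings dependent only on the products `gain*w_c` and `gain*A`:
the latent-state scale is arbitrary, so `w_c`, `A` and `gain` would not be
separately estimable from any data. The weighted update used here removes
that degeneracy for the full and no-activity variants — `w_c` changes the
*shape* of the response (the effective memory is `(1 - w_c) * alpha`),
while `gain` changes only its amplitude — and directly expresses the
intended mechanism: when the sensory update is taken into account only to
a small extent, the state is governed by the prediction from the last
breath and the activity context. Two further consequences are worth
knowing:

* In the **no_memory** variant (`alpha` pinned to 0) the shape role of
  `w_c` disappears, so only `rho`, `offset`, `gain*w_c` and
  `gain*(1-w_c)*A` are identified; individual values of `w_c`, `A` and
  `gain` lie on a one-dimensional ridge. Tests of this variant therefore
  check the identified combinations.
* CO₂ enters as a deviation from `c_ref`, preventing near-collinearity
  between the sensory weight and the readout offset; the activity input is
  scaled by `(1 - alpha)` inside the prediction so that a saturated
  context contributes exactly `A` state units as `w_c` tends to 0.

## Model variants and comparison

Following the scientific question — which processing components are
necessary? — four models are compared on identical bins: the full model;
`no_activity` (A = 0, 4 free parameters); `no_memory` (alpha = 0, 5 free
parameters); and a linear regression of rating on etCO₂ (2 parameters).
Comparison uses the Gaussian least-squares AIC,
`n log(RSS/n) + 2 (k + 1)`, the `+1` counting the residual variance
uniformly so rankings are unaffected. Exact ties break toward fewer
parameters. Two structural facts temper interpretation:

* `no_activity` is a true parameter restriction of the full model, so its
  RSS can never undercut the full model's beyond optimizer slack.
  `no_memory` changes a structural constant instead and is *not* nested;
  on data generated by the full model it can undercut the full model's
  RSS by a fraction of a percent, and on its own data the full model can
  mimic it almost perfectly (fitted `w_c` near 1 with an inflated
  activity amplitude). With equal parameter counts, AIC consequently has
  limited power to distinguish these two variants at realistic noise
  levels; the comparison that carries the scientific weight — full model
  versus regression baseline, and the necessity of the activity context
  on decoupled data — is sharp.

## Fitting

`fit_model()` minimizes the sum of squared rating residuals (bins with
missing ratings are dropped, not imputed) with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`), the R analogue of the MATLAB `lsqnonlin` routine
typically used for such fits. Because the surface is multimodal, the
optimizer restarts from `n_starts` (default 20) Latin-hypercube points
over the box `log10(rho) ∈ [-3, 4]`, `w_c ∈ [0, 1]`, `A ∈ [-100, 100]`,
`gain ∈ [0, 50]`, `offset ∈ [-100, 100]`; `rho` is searched in log space
for conditioning. Candidate starts whose initial predictions are entirely
clipped off the rating scale are discarded (the clipped readout makes the
objective locally flat there, which stalls a gradient-based optimizer);
exactly `n_starts` restarts are always run, deterministically given the
seed. The reported fit is the restart with the lowest RSS. Tight
convergence tolerances (1e-13) are used so that noise-free optima are
located to near machine precision.

## The synthetic-data generator

`generate_co2_trace()` emulates the session's etCO₂: baseline 5.2 % CO₂, a
linear rebreathing ramp of 0.9 %/min (≈ 7.5 % at end of rebreathing), an
exponential recovery with 30 s time constant, and additive Gaussian
measurement noise of 0.08 % CO₂. `generate_participant()` pushes that
series through the *same* forward model used for fitting (one
implementation, so recovery studies probe the fitting, not model drift),
adds Gaussian rating noise (default SD 5 rating units) and clips to
[0, 100]. Three named profiles encode the heterogeneity classes seen in
rebreathing studies:

* `sensory_dominated` — rho = 0.1, w_c = 0.9, A = 0, gain = 30, offset = 5:
  ratings track etCO₂ and recover promptly;
* `persistent` — rho = 100, w_c = 0.15, A = 60, gain = 1, offset = 5:
  prediction-dominated with a strong context; ratings build up and remain
  above half their peak through the final minute while etCO₂ is back at
  baseline (the decoupled pattern);
* `low_responder` — rho = 1, w_c = 0.4, A = 5, gain = 2, offset = 2:
  ratings stay below 20 throughout.

The recovery/selection harness (`recovery_profile()`) uses separate
generating parameter sets chosen a priori for identifiability and
distinguishability at rating-noise SD 5 — each has a clear sensory
component and, where applicable, substantial activity — with peak
noise-free ratings kept inside the scale so no information is lost to
clipping. What the generator does **not** emulate: physiological gas
exchange (the CO₂ curve is a shape, not a simulation), real inter-breath
variability, rating quantization, drifting attention, or threshold-like
jumps in perception. Passing recovery tests therefore demonstrates that
the estimation machinery is correct and well-conditioned under the model's
own assumptions — not that the model is true of any particular
participant.

## Preprocessing raw capnograms

`segment_breaths()` reduces a uniformly sampled capnogram to per-breath
end-tidal values: a breath ends where the signal falls below a
configurable fraction (default 0.5) of the running peak of the current
cycle, and the detector re-arms when the signal rises back above that
threshold; etCO₂ is the cycle's maximum. This is a deliberately simple
detector for clean trapezoid-like cycles; it will merge breaths whose
plateaus drop by more than the trough fraction from one cycle to the next,
and it performs no artifact rejection or drift correction.
`bin_to_grid()` averages breaths into half-open 10 s bins `[start, end)`;
a bin without a breath inherits the previous bin's value (carry-forward
preserves grid length without inventing an interpolation model), and an
empty first bin is an error.

## Numerical choices and degenerate inputs

* Kalman initialization: mean = first observation, variance = 10³; the
  per-bin gain then settles to the closed-form steady state (checked to
  1e-10 in the tests). Note that the Riccati recursion's contraction rate
  is `(1-K)²`, so convergence from a diffuse start takes ~1500 iterations
  at `rho` = 10⁴ — the closed form is used wherever the fixed point itself
  is wanted.
* Constant ratings make the gain unidentifiable; `fit_model()` warns and
  returns the (perfect) fit.
* Constant etCO₂ makes the regression baseline singular; `fit_linear()`
  errors.
* A perfect fit (RSS = 0) maps to AIC = −∞ with a warning.
* `activity_trajectory()` warns when the bin width reaches `tau_a`
  (discrete relaxation would overshoot).
* All simulators and fitters are pure functions of their seeds; seeds are
  kept within 32-bit integer range.

## Problem sizes used in validation

The bundled validation studies use the sizes at which their outcomes are
stable: 10 noise-free virtual participants per variant with 20 restarts
for exact recovery; 50 replicates at rating-noise SD 5 for noisy recovery
(median relative error of `gain` ≈ 4 % and of `w_c` ≈ 10 %, against a
frozen 20 % harness tolerance); 50 datasets per generating variant with 10
restarts for model-selection recovery; and single sessions for the
decoupling checks. `scripts/acceptance.R` reruns all of these from one
seed.

## Known limitations

* CO₂ is the only sensory channel; proprioceptive/flow inputs and
  threshold or other nonlinear readout effects are out of scope.
* The `no_memory` variant's amplitude parameters are identified only as
  products (see above), and for strongly prediction-dominated data
  (`w_c` small) the full model's `gain` and `A` likewise approach a
  product ridge — report `gain*A` when `w_c` is near its lower bound.
* AIC separates the full model from the regression baseline decisively on
  decoupled data, but full versus `no_memory` is near the resolution
  limit at realistic noise.
* The breath detector assumes clean cyclic signals; real recordings with
  artifacts need upstream cleaning.
* Group-level (hierarchical) inference is not implemented; fitting is per
  participant.
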