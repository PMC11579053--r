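# breathless

Perceptual modelling of breathlessness from CO₂ rebreathing experiments.

Persistent breathlessness — for example after COVID-19 — is often not
explained by any measurable impairment of the lungs or heart. One candidate
mechanism is that the *processing* of respiratory signals in the brain is
altered: perception reflects not the raw sensory input but a Bayesian
combination of noisy sensory measurements with predictions from an internal
model of how the body's respiratory state evolves. `breathless` implements a
quantitative observer model of this idea for hypercapnic rebreathing
experiments (Read-type protocol: 60 s room-air baseline, 150 s rebreathing
from a closed bag so inhaled CO₂ rises steadily, 150 s room-air recovery;
end-tidal CO₂ binned on the same 10 s grid as the 0–100 breathlessness
ratings), and everything needed to fit and criticize it: per-participant
nonlinear least-squares estimation, reduced model variants compared by AIC,
preprocessing of raw capnogram traces, and a synthetic-experiment generator
for parameter-recovery and model-selection validation. It is aimed at
researchers in computational psychiatry and interoception working with
rebreathing or CO₂-challenge data.

## The model

For bins t = 1, …, n on the 10 s grid, with y_t the binned end-tidal CO₂
(% CO₂):

**1. Internal CO₂ estimate** — a scalar Kalman filter with random-walk
dynamics (process variance 1, measurement variance ρ):

    M_t = P_{t-1} + 1,   K_t = M_t / (M_t + ρ)
    ĉ_t = ĉ_{t-1} + K_t (y_t − ĉ_{t-1}),   P_t = (1 − K_t) M_t

Small ρ → gain near 1, sensory-dominated estimation; large ρ →
prediction-dominated estimation. The steady-state gain is
K∞ = M/(M + ρ) with M = (1 + √(1 + 4ρ))/2.

**2. Activity context** — a constant context A whose perceptual effect
builds up by first-order relaxation with time constant τ_a = 40 s and
saturates (≥ 95 % of A after about two minutes):

    a_t = A (1 − (1 − Δ/τ_a)^t),   Δ = 10 s

**3. Respiratory state** — the prediction from the last breath and the
activity effect, updated toward the sensory term with individual weight
w_c ∈ [0, 1]:

    x_t = (1 − w_c) (α x_{t-1} + (1 − α) a_t) + w_c (ĉ_t − c_ref)

with persistence α = 0.8 per bin and setpoint c_ref = 5 % CO₂.

**4. Readout** — breathlessness prediction on the visual analog scale:

    b_t = clip(g · x_t + o, 0, 100)

The five free parameters, fitted per participant, are ρ, w_c, A, g, o;
α, τ_a and c_ref are structural constants shared across participants.
Variants: `no_activity` pins A = 0 (4 free parameters), `no_memory` pins
α = 0 (5), and `linear_regression` is the baseline b = β₀ + β₁ y (2).
Variants are fitted by bounded Levenberg–Marquardt with Latin-hypercube
multi-start and compared by the least-squares AIC,
n·ln(RSS/n) + 2(k + 1).

## Worked example

Simulate a "persistent" virtual participant — prediction-dominated CO₂
estimation (ρ = 100, w_c = 0.15) with a strong activity context (A = 60) —
whose breathlessness stays high even after end-tidal CO₂ has returned to
baseline, then run the four-way model comparison:

```r
library(breathless)

prof <- profile_persistent(seed = 102)   # rating noise SD 5
sim  <- generate_participant(prof)
sim$trace
#> Rebreathing trace: 36 bins of 10 s, 36 rated
#>   time_s    phase etco2_pct    rating
#> 1      5 baseline  5.214442  3.652300
#> 2     15 baseline  5.262779 11.527706
#> ...

tab <- compare_models(sim$trace, fit_options(n_starts = 20, seed = 1))
tab
#> Model comparison (lower AIC is better)
#>             variant      rss n_obs k_free     aic delta_aic
#> 1              full  658.887    36      5 116.653   0.00000
#> 2       no_activity 1846.793    36      4 151.757  35.10352
#> 3         no_memory  729.897    36      5 120.338   3.68464
#> 4 linear_regression 3007.800    36      2 165.316  48.66283
#> Best model: full
```

The decoupled pattern defeats the regression baseline (ΔAIC ≈ 49) and the
variant without activity context (ΔAIC ≈ 35): ratings in the last minute
remain at 77 % of their peak although etCO₂ is back within 0.1 % CO₂ of
baseline. The fitted full model recovers the prediction-dominated regime
(large ρ, small w_c); for such participants the activity amplitude is
identified mainly through the product g·A, so individual values of g and A
should be interpreted with care:

```r
attr(tab, "fits")$full
#> Model fit (full): rss = 658.887 over 36 bins, k = 5
#>         rho         w_c           A        gain      offset
#> 10000.00000     0.13208   100.00000     0.64546     1.13157
```

Validation utilities operate on the same machinery:

```r
rec <- recovery_experiment(profile_sensory_dominated(rating_noise_sd = 0),
                           n_reps = 10, fit_options(n_starts = 20))
sel <- selection_experiment(recovery_profile("full"), n_reps = 50)
```

A thin command-line interface wraps the same functions
(`inst/cli/breathless.R`): `simulate` writes a trace CSV (and optionally
the generating truth as JSON), `fit` writes a fit JSON and latent-series
CSV, `compare` writes the AIC table.

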