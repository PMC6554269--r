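# beevision

Bees are trichromats: their photoreceptors peak in the UV (λmax ≈ 344 nm),
blue (≈ 436 nm) and green (≈ 544 nm). Electrophysiology in the bee optic
lobe has found a diversity of colour-sensitive neurons — narrow-band,
broad-band and colour-opponent — far exceeding the two opponent channels
known from primates. `beevision` implements and analyses a minimal circuit
model in which that diversity arises not from cell-type-specific wiring but
from **randomly weighted** receptor inputs: third-order medulla neurons of a
single morphological type, each with its own random synaptic weights and
response threshold, reproduce the full measured repertoire.

The package is for computational neuroscientists and vision scientists who
want to fit this model to spectral tuning curves, generate populations of
randomly wired model neurons, and analyse the structure of the resulting
weight distributions, tuning-curve repertoires and population-level
perceptual distances.

## The model

Quantum catch of receptor class *i* for stimulus *I_S*:

    P_i = R ∫ I_S(λ) S_i(λ) D(λ) dλ          (R = 6, D ≡ 1 by default)

with the saturating transduction `E = P / (P + 1)`. Transmedullary cells
relay each receptor channel one-to-one with inhibitory weight `v = −1`, so
a third-order neuron with synaptic weights `W = (w_S, w_M, w_L)` receives

    x = Σ_i w_i (v E_i) ,   Δy = F(x; α)

where `F` is an odd-symmetric sigmoid of steepness `α` whose half-response
input `b = ln(1/99)/α + 0.75` anchors every neuron at `F(0.75) = 0.99`
(a piecewise-linear variant with thresholds `t_min`, `t_max` is used for
large simulated populations). Fitting minimises the weighted least-squares
cost `G = Σ_m c_m (y_m − ŷ_m)²` by gradient descent with analytic
gradients (`η_w = η_α = 0.001`; peaks/troughs weighted 3×, no-response
points 2×).

## Worked example

```r
library(beevision)

# a synthetic "recorded" tuning curve with known ground truth
batch <- make_batch(n_curves = 1, seed = 7, noise_sd = 0.05)
fit <- fit_spectral_tuning(batch$curves[[1]],
                           config = fit_config(n_starts = 5))
print(fit)
#> Spectral tuning curve fit
#>   weights (S, M, L):  0.217, 0.678, -0.817
#>   alpha: 12.2  (half-response b = 0.375)
#>   weighted cost G: 0.0727   R-squared: 0.978
summary(fit)          # relative input shares + multi-/all-input flags
plot(fit)             # measured points vs fitted curve
```

The printed weights are the recovered synaptic strengths from the S, M and
L channels (positive = inhibitory after the `v = −1` relay), `alpha` the
recovered activation steepness, and `R-squared` the unweighted variance
explained on the measured points.

Population-level analyses:

```r
lib <- generate_library(library_config(n_neurons = 5500, seed = 1))
extrema_histogram(lib)               # where peaks/troughs concentrate
dpgmm_cluster_count(lib$curves, n_runs = 100, seed = 1)
kmeans_silhouette_scan(lib$curves, k_range = 2:20, seed = 1)
d <- ensemble_distance(lib)          # population perceptual distances
monotonicity_statistic(d)

# everything end to end, from config to plain-text outputs:
run_colour_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

## Package layout

- `fit_spectral_tuning()` — the core fitting routine (S3 class
  `tuning_fit` with `print`, `summary`, `coef`, `predict`, `fitted`,
  `residuals`, `plot`, `simulate` methods); `fit_tuning_batch()` for many
  curves.
- `quantum_catch()`, `receptor_response()`, `monochromatic_sweep()`,
  `honeybee_sensitivities()` — receptor front end.
- `tm_response()`, `presynaptic_input()`, `sigmoid_activation()`,
  `piecewise_activation()`, `tuning_curve()` — the circuit.
- `generate_library()`, `extrema_histogram()` — random populations.
- `dpgmm()`, `dpgmm_cluster_count()`, `pca_weights()`,
  `kmeans_silhouette_scan()`, `cluster_exemplars()` — structure analyses.
- `ensemble_distance()`, `receptor_distance()`, `opponent_distance()`,
  `monotonicity_statistic()` — perceptual distances.
- `make_batch()`, `km_synthetic_batch()`, `recovery_report()` — synthetic
  data with ground truth (`km_synthetic_batch()` is a synthetic stand-in
  emulating the published 22-neuron recordings).
- `run_colour_pipeline()` — end-to-end orchestration.

See the methods vignette (`vignettes/random-wiring-colour-model.Rmd`) for
the modelling assumptions, parameter choices and known limitations.
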