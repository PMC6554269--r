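---
title: "Random wiring as a model of colour coding in the bee optic lobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random wiring as a model of colour coding in the bee optic lobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beevision)
```

## The model and its assumptions

`beevision` models the early colour pathway of the bee as three stages.

**Receptors.** A stimulus is absorbed by three photoreceptor classes
(S = UV, M = blue, L = green; honeybee peaks 344/436/544 nm). The quantum
catch is `P = R ∫ I_S(λ) S(λ) D(λ) dλ` over 300–700 nm with sensitivity
factor `R = 6` and a flat illuminant `D ≡ 1`; monochromatic lights collapse
the integral to `P = R · intensity · S(λ)`. Transduction is the saturating
`E = P/(P+1)`, so all downstream signals live in `[0, 1)`. This
nonlinearity is essential: it compresses the broad receptor curves into
flat-topped response profiles, and it is what makes receptor-space
distances scale monotonically with wavelength difference (a property the
raw quantum catches lack — compare `receptor_distance(sw, "transduced")`
with `"catch"`).

Because the measured sensitivity tables behind the original receptor
curves are not redistributable, the default sensitivities are generated
from the standard A1 visual-pigment nomogram (alpha plus beta band; the
beta band is omitted for UV pigments, where it merges with the alpha band,
and the curve is shift-corrected to peak exactly at the nominal
wavelength), renormalised to peak at 1. Measured curves can be supplied as a CSV
(`read_sensitivities()`), and every analysis accepts a custom
`receptor_set`. Results that depend on fine features of the receptor
curves — notably the exact wavelengths at which library extrema
concentrate — shift by some nanometres between the template and any
measured set; the qualitative structure is stable.

**Relay.** Each receptor class drives one transmedullary cell through an
inhibitory synapse: `Δr_i = v_i E_i` with `v_i = −1` (histamine-mediated
inhibition; the cells respond to light by decreasing their firing rate).
The relay is one-to-one, so the model's weight order is the receptor order
(S, M, L) throughout — external reports and internal storage use the same
convention deliberately, to avoid index errors.

**Third-order neurons.** One morphological type, each cell parameterised
only by synaptic weights `W = (w_S, w_M, w_L)` (any sign; negative w is
excitatory after the inhibitory relay) and an activation. The canonical
activation is an odd-symmetric sigmoid of steepness `α`: below a soft
threshold the cell is silent, above a saturation input it responds
maximally. Its half-response input is tied to the steepness by
`b = ln(1/99)/α + 0.75`, anchoring every neuron at 99% response for input
0.75, so neurons of different steepness are comparable. The two branches
of the sigmoid do not meet at `x = 0`; we define `F(0) = 0`, which
preserves odd symmetry and the no-response-below-threshold reading. For
large simulated populations a piecewise-linear activation (dead zone,
linear ramp, saturation) approximates the sigmoid for speed; both agree
within 0.07 at the anchor points 0, `b`, `t_max` for steepness ≥ 15.

## Fitting measured tuning curves

`fit_spectral_tuning()` recovers `(W, α)` from a measured spectral tuning
curve by minimising the weighted least-squares cost with plain gradient
descent and analytic gradients. Choices that matter:

- **Learning rates** `η_w = η_α = 0.001` (reference values). The
  iteration cap defaults to 1e5 with plateau detection (relative best-cost
  change < 1e-10 over 1000 iterations) and a stop when the weight-update
  norm falls below 1e-9; the reference long run of 1e7 iterations is
  available by configuration.
- **Point-class weights**: peaks/troughs 3×, no-response points 2×, plain
  1×, applied to squared residuals (standard weighted least squares; the
  alternative of weighting raw residuals is not used).
- **Gradient modes.** The printed derivative of the activation with
  respect to `α` treats `b` as a constant, but the half-response rule
  makes `b` a function of `α`. Both modes are implemented:
  `gradient = "literal"` (default, for fidelity to the printed recursion)
  and `"chain"` (adds `∂F/∂b · db/dα`; this is the mode that matches
  finite differences of the implemented cost, and the one the gradient
  tests verify).
- **Starts.** The reference work used unspecified "nominal" initial
  parameters. We use seeded multi-start: random weight directions rescaled
  so the largest absolute presynaptic input over the curve's wavelengths
  is 1 (the activation then transitions inside the tested range), with
  steepness starts cycling a 5-point ladder across `[10, 70]`. Purely
  random steep starts freeze — at large `α` the sigmoid's gradient
  vanishes exponentially everywhere except near `|x| = b` — so this start
  design buys the multi-start escape the reference obtained by sheer
  iteration count. A `polish_iter` option continues the best start once,
  warm-started, for long runs: steepness converges slowly near the
  optimum, and one long continuation is far cheaper than lengthening every
  restart.
- **Identifiability.** The curve determines the model response, not the
  parameters: beyond saturation, scaling `W` up changes the curve only
  marginally, and steepness trades off against weight magnitude.
  Recovery is therefore asserted in curve space (fitted vs generating
  curve), never in parameter space.

`R²` is reported on unweighted residuals about the mean of the measured
responses. `relative_weights()` reports each receptor's share of the total
absolute weight, with "substantial input" at the 10% share threshold.

## The synthetic data generator

The published empirical curves (22 digitised recordings) are not available
offline, so the package generates synthetic curves with known ground
truth. `make_batch()` draws relative weight shares from a flat Dirichlet,
random excitatory/inhibitory signs, steepness uniform on `[10, 70]`, and
rescales each weight vector so the neuron saturates within the tested
wavelengths — matching the fact that measured tuning curves are normalised
to a maximal response of ±1. Noise is additive i.i.d. Gaussian on the
normalised response (default sd 0.05, the test harness's choice; the
reference fits digitised means and has no noise model). Candidate draws
whose noise-free curve is nearly constant (range < 0.5 of the maximum)
are rejected: the emulated recordings are of neurons *selected* for
colour-sensitive responses, and variance-explained metrics are meaningless
on a flat curve. Labels mimic the empirical annotation: the global
extremum is a peak/trough, responses below 0.05 in magnitude are "zero",
the rest plain.

`km_synthetic_batch()` is a fixed 22-curve stand-in for the published
recordings: its ground-truth design matches the reported composition of
that population (3 UV-excitatory/blue-green-inhibitory colour-opponent
cells; 15 of 22 neurons with all three relative weight shares above 10%,
20 of 22 with at least two; steepness spread over 10–70; three
interleaved wavelength sets of 13–17 points over 310–640 nm). It is
synthetic: tests against it validate the fitting and classification
machinery under realistic conditions, not the historical data themselves.
Quantities that depend on the *geometry* of the historical fitted weight
cloud — the two-component PCA variance near 95%, the single
Dirichlet-process cluster — are not reproduced by the stand-in (it gives
roughly 81% and ~6 occupied components), and the corresponding end-to-end
checks document that gap rather than hide it.

## The random library

`generate_library()` draws `n_neurons = 5500` neurons (one per medulla
column) with i.i.d. uniform `[−1, 1]` weights — the maximum-entropy
reading of "randomly weighted", exposed in the config so alternatives can
be tested — and steepness uniform on `[10, 70]`. Each neuron's piecewise
saturation threshold is set to the maximum *absolute* presynaptic input
over the monochromatic sweep (signed maxima can be non-positive for
inhibitory-dominated neurons, which is why absolute is the default), so
every curve attains ±1 somewhere. The lower threshold comes from the
half-response point: the reference rule `t_min = t_max − 2(t_max − b)` is
stated at `t_max = 0.75`; applied literally to per-neuron thresholds it
degenerates (`t_min ≥ t_max`) for about a third of the population, so the
default scales the half-response point proportionally
(`t_min = t_max · (2b/0.75 − 1)`, clamped at 0), which reproduces the
reference rule exactly at `t_max = 0.75` and preserves the ramp shape
elsewhere. The literal rule remains available
(`threshold_rule = "literal"`).

The default sweep is 300–700 nm at 10 nm: it matches the sampling density
of empirical tuning-curve measurements and keeps the curve matrix
tractable for the repeated mixture fits; extrema histograms use a 5 nm
sweep where finer localisation matters. Extrema are strict local extrema
with flat (saturation or dead-zone) plateaus counted once at their centre,
endpoints counted when approached monotonically, and a prominence filter
of 0.2 × the curve's maximum absolute response (no rule is given in the
reference; this one is simple and stable).

## Clustering analyses

The truncated Dirichlet-process Gaussian mixture is fitted by the
standard stick-breaking mean-field variational scheme (full covariances,
Gaussian–Wishart priors), with common defaults: truncation 30, stick
concentration 1/30, mean prior at the data mean with precision 1, Wishart
degrees of freedom equal to the dimension, covariance prior equal to the
empirical covariance, k-means initialisation. A component is "occupied"
when its expected mixing weight exceeds `1/(2 · truncation)`. Convergence
is deliberately strict (tolerance 1e-7 on the mean log-normaliser, up to
1000 iterations): merging of redundant components is slow, and stopping
early systematically inflates the occupied count. Empty components sit
exactly at their prior, so their log-density column is computed once and
cached — this is an exact optimisation, not an approximation. The
implementation was checked against synthetic oracles (two well-separated
blobs → 2 components in every seeded run; one isotropic blob → 1 in most
runs) and against an independent finite-mixture BIC selection on separated
blobs.

The occupied-component count on the 5500-curve library is sensitive to
conventions the reference leaves unstated (occupancy threshold, truncation,
and the exact curve family): under the defaults above it concentrates
near 20; under the equally common occupancy rule "weight > 1/truncation"
it falls to ~13. The package reports what its own defaults compute.

Curve clustering uses k-means under the plain Euclidean metric on the
common wavelength grid — the curves are aligned, so no time-warping
metric is needed — with mean silhouette widths from `cluster::silhouette`
over k = 2–20 (k = 1 has no silhouette). Curves are normalised per neuron
to maximum absolute response 1 before clustering, so clusters reflect
shape, not amplitude. Weight-cloud PCA is centred, unscaled, with an
optional unit-L1 ("relative weight") normalisation; both modes are
reported because the reference does not state which was used.

## Perceptual distances

The ensemble perceptual distance between two monochromatic stimuli is the
Euclidean distance between the full library response vectors, normalised
by the matrix maximum (per-matrix normalisation; an optional
`1/sqrt(n_neurons)` mode makes scales comparable across library sizes).
Comparison models: 3-D receptor space (quantum catches or transduced
responses) and a regular two-channel opponent model with channels
UV − ½(blue + green) and blue − ½(UV + green) — the reference names only
the axes, so the coefficients are exposed in the config. "Monotone
scaling" is operationalised as the Spearman rank correlation between
|Δλ| and distance over all unordered pairs (the reference shows
scatterplots only); constant distance matrices return 0. The blue/yellow
asymmetry test uses 400–480 nm vs 520–600 nm — equal-width windows on a
uniform grid, so wavelength separations are matched.

## Numerical choices and degenerate inputs

- Activation evaluated via the logistic `s = 1/(1+e^{−z})` so saturation
  stays finite; gradients use `s(1−s)` forms for the same reason.
- `α` is clamped positive (≥ 1e-3) during descent; divergence (non-finite
  cost) is reported, not silently returned.
- Inputs `x = 0` sit in the activation's dead point and contribute zero
  gradient.
- Degenerate weight clouds (all rows identical) raise an error in PCA;
  all-zero weight draws are rejected when sampling neurons; mixture
  fitting requires at least 3 observations and jitters a singular
  empirical covariance prior.
- The problem sizes used by the packaged end-to-end checks: 22-curve
  batches with 5 restarts (plus one 3e6-iteration polish for noise-free
  recovery), the full 5500-neuron library, 100 mixture runs, and 5 nm
  extrema histograms.

## Known limitations

- No receptor adaptation, noise, angular sensitivity, temporal dynamics,
  spatial receptive fields, or lateral inhibition; colour spaces beyond
  the distance analyses here are out of scope.
- The firing-rate variant (`firing_rate_response()`: baseline-anchored
  affine map, floored at zero) is a documented variant, not the canonical
  dimensionless model; whether the original rescales excitation and
  inhibition asymmetrically is not derivable from the main text.
- Template sensitivities approximate the measured honeybee curves;
  swap in measured CSVs for quantitative receptor-level work.
- Passing tests on synthetic data show the machinery is correct under the
  stated generative assumptions (additive Gaussian noise on normalised
  responses of a saturating circuit); they cannot certify behaviour on
  real recordings with correlated noise, drift, or digitisation error.
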