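---
title: "Methods: wavelet-domain augmentation and hybrid injury prediction"
author: "blastinjury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-domain augmentation and hybrid injury prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastinjury)
```

## The problem

Occupant injury assessment for vehicle underbody blast events faces an
extreme small-sample problem: physical blast tests with an instrumented
Hybrid III dummy are expensive and destructive, so a handful of load
records (pedal and seat accelerations, in g, at 10 kHz) must support
predictive modelling of two injury indices — the peak tibial axial
compression force `Fzp` (AEP-55 tolerance 5.4 kN) and the spinal Dynamic
Response Index `DRIz` (tolerance 17.7). `blastinjury` implements a hybrid
workflow: scarce physical signals are augmented by a conditional GAN
operating on their wavelet coefficients, an (external or surrogate)
response model converts augmented loads into responses, ISO 18571 ratings
and a load-peak rule gate the simulated data, and a Gaussian process
regressor trained on the pooled physical + simulated rows maps wavelet
energy features to injury indices.

## Wavelet analysis

All decompositions use the orthonormal 8-tap Daubechies-4 filter pair with
periodized boundary handling, `J` detail bands plus one approximation
band. Choices worth recording:

* **Depth `J = 5` (default, configurable).** The measured loads are
  bimodal — a global vehicle response near 11 Hz and a local structural
  ring near 4.5 kHz. At 10 kHz sampling, five levels put the high-frequency
  component in the first detail bands and the low-frequency content in the
  approximation band, while the shortest band of a 3000-sample record
  still holds 94 coefficients.
* **Non-dyadic lengths.** 3000 is not a power of two. Whenever a band of
  odd length must be split, it is zero-padded by one sample first. Zero
  padding (rather than sample replication) keeps the transform exactly
  energy-preserving (Parseval to machine precision) and exactly
  invertible, and produces the `ceil(N/2^j)` band-length convention used
  throughout.
* **Normalization.** The networks consume coefficients divided by the
  signal's maximum absolute sample value; the scale is stored on the
  decomposition and reapplied on reconstruction. Stored coefficients are
  *unnormalized*, so all energy quantities refer to the physical signal.

## The augmentation model

Each wavelet band is one channel of a fully connected conditional GAN.
Channel widths follow the small-sample design: generator hidden `Nj/5`,
discriminator hidden `Nj/4`, shared FC `Nj/10` per channel (rounded,
minimum 1), generator output `Nj`. Training uses 1000 epochs, batch 4,
one generator update per two discriminator updates, and SGD with learning
rate 0.001.

Design decisions in places the architecture leaves open:

* **Latent source.** The generator input is a per-channel standard-normal
  vector of length `Nj` — adversarial generation needs a stochastic
  source, and this keeps every layer shape unchanged.
* **Activations.** Only the output activation is prescribed (sigmoid, on
  the discriminator). Hidden and FC layers use `tanh` (bounded,
  zero-centred, matching normalized coefficients in `[-1, 1]`); the
  generator output layer is linear because it regresses real-valued
  coefficients.
* **The condition gate.** The energy condition
  `c = (Et - Emin)/(Emax - Emin)` drives a sigmoid gate with one gate
  value per hidden unit (`Wg` is a vector), multiplying the activated
  hidden layer element-wise. In the discriminator, `c` is instead appended
  as one extra unit to the flattened hidden vector.
* **Batch semantics.** Batch size 4, drawn with replacement whenever the
  corpus is smaller than the batch.
* **Gradients.** Backpropagation is derived analytically, including the
  product rule through the gate and the chain through the discriminator
  for the generator loss; the test suite verifies every parameter group
  against central finite differences at 1e-4 relative tolerance.

### Real-time perturbation

To diversify the tiny corpus, generated coefficient sets are perturbed
before the discriminator sees them. A probability table proportional to
squared coefficient magnitude is sampled through its CDF (a uniform draw
`u` selects the first coefficient whose cumulative probability reaches
`u`), and each selected coefficient is replaced by `alpha*phi + eps` with
`alpha ~ U(0.95, 1.05)` and `eps ~ N(0, sigma^2)`. High-energy
coefficients are therefore perturbed often; near-zero ones almost never,
which avoids injecting physically meaningless noise.

The noise scale is `sigma = beta * sqrt(sum(phi^2) / (J * sum(Nj)))`:
`beta` (0.01–0.1) times an RMS coefficient amplitude, additionally damped
by `1/sqrt(J)`. Of the plausible normalizations of this quantity, the
package adopts this one because `sigma` must carry amplitude units while
`beta` is a dimensionless noise-to-energy ratio. Per `perturb()` call, the pmf and
`sigma` are computed once from the decomposition as passed in; "real
time" refers to re-running the perturbation on every generated batch
during training, where 1% of all coefficients (at least one) are hit per
batch element. The gradient is taken exactly through the perturbation's
affine map.

### Synthesis

`synthesize()` draws latents, runs the generator at a target condition
`c`, optionally perturbs, reconstructs the time signal, and rescales the
amplitude so the realized energy-based condition equals the target
exactly; `Emin`/`Emax` are persisted with the model from the training
corpus.

## Injury criteria

* **Filtering.** SAE J211-1 channel frequency classes, realized as a
  2-pole Butterworth run forward and backward (phaseless, 4 poles
  total): CFC 600 with a 1000 Hz single-pass cutoff for tibial force,
  CFC 1000 with 1650 Hz for pelvis acceleration. Edge effects are
  suppressed by reflected padding plus steady-state initial conditions,
  which makes the DC gain exactly 1.
* **Sign conventions.** Compressive tibial force and downward (spine-
  compressing) pelvis acceleration are positive. `Fzp` is the peak of the
  compressive part only; an all-tension record yields `Fzp = 0` with a
  warning. Decisions are strict at the boundary: the channel fails at
  `Fzp >= 5.4` kN and at `DRIz >= 17.7`.
* **DRIz integration.** The spinal single-degree-of-freedom model
  (damping ratio 0.224, natural frequency 52.9 rad/s) is integrated with
  the *exact* zero-order-hold discretization of the state equations at the
  signal's own step (1e-4 s); for piecewise-constant input this is the
  continuous solution sampled, so refinement changes nothing beyond the
  peak-on-grid effect (< 0.01%). The deflection readout uses the
  compressive phase only, and input acceleration is the measured,
  gravity-free transient (g are converted to m/s² internally).

## ISO 18571 rating

The objective rating of a comparison curve `y` against a reference `x`
combines four components, `R = 0.4*Ec + 0.2*Ep + 0.2*Em + 0.2*Es` — the
corridor component is weighted highest because overall temporal agreement
of the loading matters most when the curves drive a dynamic model.

* **Corridors**: constant width, inner `0.05*Ynorm`, outer `0.5*Ynorm`,
  with `Ynorm` the larger absolute extremum of the reference; per-sample
  scores are 1 inside, 0 outside, quadratic in between, averaged.
* **Phase**: integer shifts up to `eps_pmax*N` are scanned in both
  directions with normalized cross-correlation over the window starting
  at the burst onset (first sample exceeding 5% of `Ynorm`; the onset
  falls back to the record start if the remaining window would be too
  short). `eps_pmax = 0.2` by default — the fraction is not dictated by
  the component definitions, and 20% of the record is the conventional
  choice. Ties prefer the smaller shift, so identical curves score 1
  exactly.
* **Magnitude**: unconstrained DTW with squared local cost and steps
  down/right/diagonal on the phase-aligned curves; DP ties break toward
  the diagonal, keeping aligned lengths in `n..2n-1`. The L1 amplitude
  error along the warping path maps to `Em` with scale 0.5. The DP runs
  in compiled code; a brute-force R dynamic program validates it on short
  curves.
* **Slope**: both aligned curves are smoothed by a 9-point moving average
  (windows shrink to 1–7 points near the ends), differentiated by central
  differences, and compared by an L1 ratio with scale 2.0.

Clipping of `Em`/`Es` to `[0, 1]` only guards floating-point rounding —
the error ratios are non-negative by construction. The rating is
deliberately asymmetric (corridors and onset come from the reference).

## Features and the predictor

Each load signal maps to four features: its log-compressed
(`ln(1 + E)`) wavelet scale-energy curve is projected onto the first
three principal components of the corpus, and the energy condition `c`
is appended as the fourth feature. Appending `c` resolves the tension
between "three principal components" and "dimension 4": the condition is
the one scalar the augmentation explicitly controls, and amplitude must
reach the predictor for injury scaling. PCA uses mean-centred curves with
the covariance divisor `M - 1` (`M` = curve dimension; the divisor
affects eigenvalue scale only, never projections or component
directions), eigenvalues sorted descending, and each eigenvector's sign
fixed so its largest-magnitude loading is positive (a reproducibility
convention).

The regressor is a zero-mean GP with an ARD-RBF kernel
(`sigma_f^2 exp(-0.5 sum((dx/l)^2))`) and homoscedastic noise `sigma_n` —
a single noise level shared by physical and simulated rows. Features are
standardized inside `gpr_fit()`; hyperparameters are found by L-BFGS-B on
the log marginal likelihood in log-space with analytic gradients, five
restarts by default (the first at `sigma_f = sd(y)`, unit length scales),
deterministic under the seed. A relative jitter of `1e-8 * mean(diag K)`
stabilizes the Cholesky. Predictions report the latent-function variance
(noise excluded) with `mean ± 1.96*sd` intervals: the quantity of
interest is the structural trend, not single-shot reproduction noise.
LOOCV reports the held-out relative error per row and the maximum
training error per cycle; relative error on a zero truth raises an error
rather than returning infinity.

Two independent predictors are built: pedal-load features predict `Fzp`,
seat-load features predict `DRIz` — each response channel is driven by
one load channel.

Simulated rows enter the training set only if their ISO total score is at
least 0.5 and their load peak does not exceed 600 g (pedal) or 400 g
(seat): beyond those loads the response model leaves its validated
regime.

## The synthetic data generator

Because no measured blast records are distributable, `make_corpus()`
fabricates the study conditions: each load is a decaying 11.4 Hz sinusoid
(global response) plus a rapidly decaying 4542.9 Hz burst (local
response, amplitude 30% of the peak — a package choice; the measured
spectra only show low-frequency dominance qualitatively) plus 2% white
noise, synthesized at 100 kHz and anti-alias decimated to 10 kHz, 3000
samples. Pedal peak amplitudes spread over 150–650 g (seat = 60% of
pedal) so that `Fzp` crosses 5.4 kN, `DRIz` crosses 17.7, and the top of
the range exercises the 600 g exclusion rule. Decay rates (10/s and
200/s) are set so both components visibly ring and die within the 0.3 s
record.

The surrogate occupant response stands in for the finite-element dummy:
a unity-DC-gain second-order transmissibility filter, a gain, and a soft
saturation that is exactly linear below its onset. Its parameters are
fabricated engineering choices, *not* biomechanical constants — they
exist so the pipeline's statistics can be exercised and tested. A
multiplicative `bias` emulates the systematic error of an imperfect
simulation model. Consequently, passing tests demonstrate the machinery
(transforms, training dynamics, rating, exclusion logic, regression),
not biofidelity: real blast records have richer modal content,
non-stationary noise, and sensor artifacts that the generator does not
emulate.

## Problem sizes and numerical choices

The test-suite and pipeline problem sizes are package choices made for a
desk-scale demonstration: the end-to-end run uses 8 physical conditions,
40 augmented signals per channel, a 12% simulation bias, GAN training at
150 epochs (full-length 3000-sample signals), and 3 GPR restarts; the
distributional-fidelity check trains 10 000 epochs on a 128-sample toy
corpus, where each epoch is three small matrix passes. Adversarial SGD at
learning rate 0.001 moves band-energy profiles slowly, so short runs are
used where only plumbing is under test and long runs where fidelity
itself is asserted. Probabilities entering GAN losses are clamped at
1e-12; non-finite losses abort training with the epoch index; non-finite
gradients abort the SGD step.

## Known limitations

* The GAN is a plain fully connected conditional GAN with SGD — no
  Wasserstein objective, gradient penalty, or convolutional structure;
  on hard corpora the discriminator can dominate (rising generator
  loss), and distributional fidelity then improves only slowly.
* The ISO 18571 implementation covers the constant-width corridor
  variant and single-channel ratings only.
* The GP is single-output with shared noise; source-dependent weighting
  of physical vs. simulated rows (e.g. Bayesian fusion of the two
  sources) is out of scope.
* Injury assessment covers the two stated indices and thresholds only —
  no injury-risk curves, HIC, neck or chest criteria.
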