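---
title: "Densely interconnected residual cascading reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densely interconnected residual cascading reconstruction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dircn)
```

## The reconstruction problem

Accelerated Cartesian MRI acquires only a subset of phase-encoding lines.
With a receive array of $c$ coils, the measured k-space of coil $i$ is

$$k_i = \mathcal{F}(S_i \circ x) + \varepsilon,$$

where $x$ is the complex object image, $S_i$ the coil's complex spatial
sensitivity, $\mathcal{F}$ the 2-D Fourier transform and $\varepsilon$
complex Gaussian noise. Undersampling applies a binary line mask $U$,
$k_u = U \circ k$, and the zero-filled inverse transform of $k_u$ is
aliased. This package reconstructs the magnitude image from $k_u$ with an
unrolled cascading network and provides everything around it: the operators,
masks, metrics, a phantom simulator, and a CPU training loop.

## The unrolled model

Each of the $m$ cascades performs five steps:

1. **Sensitivity estimation** (once per input, shared by all cascades): the
   fully sampled center of $k_u$ is extracted, inverse transformed per coil,
   refined by a CNN that sees each coil as a batch element with two real
   channels (real/imaginary), and normalized so that
   $\sum_i \bar S_i S_i = 1$ at every pixel. Placing coils on the batch axis
   makes the model agnostic to the coil count. The CNN is residual on top
   of the center-crop (autocalibration) estimate and its output head is
   zero-initialized, so an untrained model starts from the classical maps
   — a direct predictor trained jointly from random initialization feeds
   corrupted sensitivities to every cascade during early training, and at
   desk scale that stalls optimization before the estimator becomes useful.
2. **Coil reduction**: $I_{\mathrm{red}} = \sum_i \mathcal{F}^{-1}(k^i)\,\bar S_i$.
3. **CNN refinement** of the coil-reduced complex image (2 real channels).
4. **Coil expansion**: $I_{\mathrm{rec}} \circ S_i$ per coil, then a forward
   transform back to k-space.
5. **Soft data consistency** with a learnable scalar $\lambda$ (one per
   cascade, initialized to 0.01): sampled lines become
   $(k_u + \lambda k_p) / (1 + \lambda)$, unsampled lines pass through. As
   $\lambda \to 0$ the measurements are enforced exactly.

The final image is the root-sum-of-squares of the last cascade's
data-consistent coil images.

Three architectural extensions can be switched on independently:

* **Input-level dense connections** — the $k$-th cascade's CNN receives the
  concatenation of all prior coil-reduced images, newest first
  ($2k$ input channels at cascade $k$). Sub-network weights are never shared
  across cascades, so each cascade's first layer is sized for its own
  history length.
* **ResXUNet sub-networks** — the U-Net level blocks are replaced by
  aggregated residual blocks: two grouped $3{\times}3$ convolutions
  (cardinality = group count) with instance normalization and SiLU, gated by
  a squeeze-and-excitation block *before* the identity addition, so a
  zeroed branch is exactly the identity. The baseline U-Net uses ungrouped
  double convolutions with ReLU and no SE.
* **Interconnections** — each sub-network exports its final feature map at
  every resolution; the next sub-network concatenates these onto its encoder
  features at the matching resolution through $1{\times}1$ fusion
  convolutions. The first cascade receives no packet and is built without
  the fusion layers. Where the source of the packet is ambiguous
  (encoder vs decoder side), this implementation exports the decoder-side
  final maps (the bottom encoder block doubles as the coarsest entry).

The five presets map onto the ablation grid: `reference`, `dense`,
`resxunet`, `interconnections`, `dircn` (all three extensions). Flags are
strictly additive; with all of them off the model reduces exactly to the
reference composition.

## Numerical conventions

* **FFT**: centered orthonormal transform (roll by `floor(n/2)`, unitary
  scaling), so Parseval's identity is exact, the DC bin of an even-sized
  axis sits at index `n/2` (0-based), and the adjoint used in
  backpropagation equals the inverse transform.
* **Complex data** ride through the network as two real channels in the
  fixed order (real, imaginary). Internally the autodiff engine keeps
  complex arrays first-class; the gradient of a complex tensor packs
  $(\partial L/\partial\,\mathrm{Re}, \partial L/\partial\,\mathrm{Im})$
  into one complex array, which makes the adjoint of an elementwise product
  a product with the conjugate.
* **Sensitivity normalization** divides by $\sqrt{\sum_i |S_i|^2 + 10^{-12}}$;
  zero-energy pixels yield zero maps (flagged in a validity mask) instead of
  NaN.
* **Crops** use the floor convention: a centered crop starts at
  `floor((dim - target)/2)` (0-based). Sub-network inputs of arbitrary
  rectangular size are reflect-padded (bottom/right) to the next multiple of
  $2^{\mathrm{depth}-1}$ and cropped back.
* **Masks**: the center block has `round(center_fraction * n_ky)` lines
  starting at `floor((n_ky - count)/2)`; outside it, 0-based line $j$ is
  sampled iff $j \equiv \mathrm{offset} \pmod R$. Fourfold acceleration
  pairs with an 8% center, eightfold with 4%. An alternative `exact_rate`
  dialect widens the spacing so the sampled total approaches $n_{ky}/R$
  (the leaderboard-style convention); the literal every-$R$-th rule is the
  default. The reported `effective_acceleration` is the conventional
  total/sampled ratio — a definition of the acceleration factor as
  "masked over total" appears in the literature but is not adopted here.
  The equidistant offset defaults to 0; a seeded random offset per training
  step is available (`random_offset`).

## Training schedule and loss

The default schedule is AMSGrad Adam at learning rate 0.002, decayed by
0.1 every 60 "iterations", 120 iterations in total, mini-batch one, each
iteration an epoch-like pass over 10,000 randomly drawn slices with the
acceleration drawn uniformly from {4, 8} per slice. The loss is the equally
weighted sum of Gaussian-windowed structural dissimilarity and mean absolute
error, $(1 - \mathrm{SSIM}) + \mathrm{L1}$, with the SSIM data range taken
as the maximum of the reference slice (the convention when no volume
context exists at train time). Validation, when enabled, scores a fixed
subset after every iteration; the final checkpoint is the default
evaluation target, with best-validation checkpointing available.

SSIM uses an $11{\times}11$ Gaussian window with $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$, weight-normalized local statistics, and the
valid interior (no padded borders). At evaluation time SSIM is computed per
slice with the volume-level data range; NMSE and PSNR are volume-level, and
aggregates are unweighted means over volumes. PSNR of an exact match
returns a finite sentinel (`20*log10(L) + 160`) instead of infinity.

## Architecture scales

The widths and depths are free parameters in the original design; only the
total budget (about 45 million parameters at full scale, 12 cascades) is
fixed. Two presets are provided:

* `scale = "full"`: 12 cascades, depth 4, SE reduction 16, base width 36
  for the U-Net variants and 48 (cardinality 12) for the ResXUNet variants —
  grouped convolutions are leaner per channel, so the ResXUNet runs wider to
  land each configuration near the common budget of roughly 45 M parameters
  (48 M for the U-Net reference, 42 M for the ResXUNet configurations).
* `scale = "tiny"`: 2 cascades, depth 3, base width 8, cardinality 2,
  SE reduction 4 — about 0.1 M parameters, sized so that a full training
  experiment (a few hundred gradient steps on 64×64 phantoms) runs on one
  CPU core in minutes. All tests and the acceptance experiments use this
  scale.

The sensitivity network reuses the cascade sub-network architecture at half
the base width ("same architecture, fewer parameters").

## The synthetic study conditions

`make_dataset()` emulates a single-site acquisition:

* **Objects**: piecewise-constant complex ellipse composites (3–6 ellipses,
  amplitudes 0.3–1 with mild phase) under a smooth low-order polynomial
  phase field. This captures the complex-valued, piecewise-smooth structure
  the method assumes without modeling anatomy.
* **Coils**: 4 Gaussian sensitivity lobes spread around the field of view
  with per-coil linear phase ramps, normalized to unit pixelwise energy.
  One receive-array geometry is shared by all slices and volumes of a
  dataset (`coil_seed`) — a scanner's array does not change between
  acquisitions, and sensitivity estimation is only a well-posed learning
  task when the geometry is stable.
* **Acquisition**: 64×64 images generated at 64×80 and quadratically
  cropped in the image domain before re-transforming (the frequency
  oversampling removal path), then i.i.d. complex Gaussian noise with
  σ = 0.01 per component on unit-scale k-space.
* **Ground truth**: RSS of the noiseless coil images.

What passing on these phantoms does *not* show: robustness to anatomy-like
texture, contrast physics, coil noise correlation, or non-integer
acceleration — the generator makes no claim there.

## Problem sizes used by the test suite and acceptance script

The learning experiment trains the tiny `dircn` preset for 200 steps
(4 iterations × 50 steps) on 24 training slices at fourfold acceleration
and scores 12 held-out slices against the zero-filled baseline; the
gradient-flow check uses a 4-cascade tiny model on one 32×32 slice; the
ablation harness steps all five presets once at 32×32. These sizes are the
package's own desk-scale study conditions: large enough for the learning
signal to be unambiguous, small enough to re-run routinely.

## Known limitations

* The autodiff engine is dense and single-threaded R; it is sized for the
  tiny scale. The full-scale preset builds and runs but training it is a
  GPU-class workload far beyond this engine's intended use.
* Volumes are stored as RDS files mirroring the multi-coil layout
  (`kspace[kx, ky, coil, slice]`, `reconstruction_rss`, contrast attribute)
  rather than HDF5.
* Non-Cartesian trajectories, k-space-domain sub-networks, attention-gated
  interconnections and partial-Fourier handling are out of scope.
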