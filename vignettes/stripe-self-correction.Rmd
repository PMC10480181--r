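---
title: "Per-image stripe self-correction for stitched microscopy mosaics"
author: "stripecor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-image stripe self-correction for stitched microscopy mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Large fluorescence images — multiphoton, stimulated-Raman, whole-slide
scans — are stitched from many contiguous tiles (fields of view). Each
tile's illumination falls off from its centre, so after stitching the
mosaic carries periodic brightness bands at the tile boundaries: *stripes*.
Depending on acquisition and post-processing these appear as uniform
stripes (one repeated shading profile), non-uniform stripes (profiles that
vary per tile), grid stripes (both axes), or oblique stripes (the mosaic
was rotated after stitching). Local artifacts — out-of-focus patches,
scanning-fringe ripple from resonant scanners, bubble-like marks from
tissue drying — degrade the same images.

`stripecor` corrects a single stitched image using only that image. No
flat-field reference, no raw tiles, no paired clean/degraded training data.
The price is a small amount of annotation: the user supplies the rough tile
geometry (or a rough anomaly mask); the method is semi-automated by design,
not a stripe detector.

## The method

Correction proceeds in three stages.

**Proximity sampling.** From the tile-grid annotation the package builds a
boolean anomaly mask (`maskFromTileGrid()`): every pixel within a band
half-width of a tile boundary line, with both line families rotated by the
stripe angle θ. Square patches smaller than one tile are sampled on a
stride-quantized origin lattice. Windows whose anomaly fraction reaches
`minOverlap` form the *anomaly domain* X; each is paired with the
admissible *normal* window (zero anomaly pixels) whose centre is nearest in
Euclidean distance, ties broken by smaller row then column
(`pairNearestNormal()`). Pairing in proximity matters: nearby patches share
illumination statistics and tissue texture, so the normal patch is a
faithful unpaired reference for what the anomaly patch should look like.

**Adversarial self-training.** Four convolutional networks are trained on
the patch pairs: a correction generator `gC` (X → Y), a synthesis generator
`gS` (Y → X, identical architecture), and two least-squares discriminators
`dX`, `dY`. The generator objective is

  L = L_adv(gC) + L_adv(gS) + λ · L_cons,  λ = 10,

with L_adv(gC) = E[(1 − dY(gC(x)))²], L_adv(gS) = E[(1 − dX(gS(y)))²], and
the content-consistency term L_cons = E‖gS(gC(x)) − x‖₁ +
E‖gC(gS(y)) − y‖₁ penalizing both reciprocal round trips
("destripe-then-reshade" and "reshade-then-destripe"). Each discriminator
minimizes its own term, E[(1 − D(real))²] + E[D(fake)²]. Expectations are
realized as means over the mini-batch (size 1) and the score map.
Optimization is Adam (lr 2·10⁻⁴, β₁ = 0.5, β₂ = 0.999), 200 epochs with the
rate constant for 100 epochs then decayed linearly to zero; one epoch is
one shuffled traversal of the pair set. No pretrained weights; init is
zero-mean Gaussian, sd 0.02.

The generator is an encoder-decoder: a 7×7 stride-1 convolution to 64
features, two stride-2 convolutions doubling channels, nine residual
blocks, two mirrored stride-2 transpose convolutions, and a final 7×7
convolution with tanh, all instance-normalized and reflection-padded.
Internally patches live in [−1, 1] (forced by the tanh output); rasters in
[0, 1] are mapped affinely in and out. The discriminator stacks five 4×4
convolutions — strides (2,2,2,2,1), leaky-ReLU 0.2, no normalization on the
first layer — ending in a single-channel score map with no output
nonlinearity.

**Local-to-global correction.** The whole mosaic is tiled into overlapping
windows (stride = half the patch side, or a fixed 100 px), each window is
mapped through `gC`, and the results are merged as a per-pixel weighted
mean. The default weight map is feathered — a separable linear ramp from
the window edge to a plateau of 1 over P/4 px — which suppresses visible
window seams; uniform weights are available as the ablation. The merge is a
partition of unity: with a pass-through generator the output reproduces the
input exactly, which the tests assert bit-for-bit.

## The network engine

No deep-learning framework ships with this package's target environment,
and the four sub-networks *are* the method, so `stripecor` carries its own
compact engine: single-sample H×W×C tensors, im2col/col2im convolutions in
C++ (`src/im2col.cpp`), reflection padding, instance normalization, ReLU /
leaky-ReLU / tanh, residual blocks, transpose convolutions as the exact
adjoint of the im2col convolution, hand-derived backward passes, and Adam.
Every layer's backward pass, and the fully composed adversarial +
consistency objective, are verified against central-difference numerical
gradients in the test suite (agreement ≈ 1e-8). All randomness flows
through explicit integer seeds via a private RNG scope; the global R random
state is never consumed, and training is bit-reproducible given its seed.

## The degradation simulator

`generatePhantom()` builds tissue-like phantoms — smooth Gaussian "cell"
blobs and curvilinear "fiber" ridges over a flat background — so every
stage is exercisable without microscopy data. Degradations are then applied
in two parametric families:

* **Stripe fields** (`makeStripeField()`): multiplicative, strictly
  positive, never amplifying (multipliers in (0, 1]). The within-tile
  profile is a raised cosine falling from 1 at the tile centre to
  1 − amplitude at the boundary — a one-parameter shape matching the
  qualitative falloff-from-centre behaviour of real tiles. `uniform`
  repeats it; `non_uniform` jitters per-tile amplitude and gain (seeded);
  `grid` multiplies a row-period and a column-period field; `oblique`
  evaluates the field in rotated coordinates rather than rotating a
  rendered image, so fixtures carry no interpolation error and θ = 0
  reduces bit-for-bit to `uniform`.
* **Artifacts** (`applyArtifact()`): out-of-focus (Gaussian blur +
  attenuation inside a region, feathered over an 8 px ramp *outside* the
  boundary so the region interior keeps its closed-form mean and no hard
  edge is introduced); scanning fringe (sinusoidal row-wise gain with
  seeded phase — the mean over whole periods is exactly preserved); and
  bubble (radial attenuation with a raised-cosine darker rim, continuous
  at both band edges).

Degradation is multiplicative without an additive dark-field term: the
method manipulates stitched intensities, not raw sensor frames, and its
corrections brighten shaded regions. Where the field is known and no
clipping occurred, division by the field inverts the degradation to
floating-point tolerance — a recovery property the tests assert at 1e-6.

What the phantoms do *not* emulate: optical point-spread functions,
photobleaching, detector noise statistics, and the rich multi-scale texture
of real tissue. Passing tests demonstrate correctness of the machinery and
of the method's behaviour under controlled degradations, not performance on
real microscopy data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tileH`, `tileW` | 128 px | acquisition tile size (annotation) |
| `bandHalfwidth` | 6 px | half-width of the anomaly band |
| `amplitude` | 0.5 | fractional shading depth, in [0, 1) |
| `patch` (P) | 256 px | training/inference patch side (must be < tile) |
| lattice stride | P/4 | origin quantization for sampling |
| `minOverlap` | 0.3 | anomaly fraction per anomaly patch (0.6 for compact artifacts) |
| `lambdaCons` | 10 | consistency weight |
| `lr0` | 2e-4 | Adam learning rate |
| `epochs` / decay | 200 / 100 | schedule (linear decay to 0) |
| `step` | P/2 or 100 px | sliding-window stride |
| blend | feathered | merge weights (uniform = ablation) |

Normal patches must contain *zero* anomaly pixels (strict), since they act
as clean references. The patch-size guard P < min(tile) is enforced
whenever a tile grid is supplied: each window must be smaller than one
tile so it sees at most one stripe.

## Numerical choices

* ICV (inverse coefficient of variation, mean/standard deviation of an ROI)
  uses the **population** standard deviation; multi-channel input is
  reduced to mean-across-channels luminance, with per-channel values also
  reported. ICV is content-sensitive: black background in the ROI perturbs
  it, which a regression test pins down.
* SSIM uses the standard 11×11 Gaussian window (σ 1.5) and stabilizers
  K1 = 0.01, K2 = 0.03, cross-checked against a direct windowed-formula
  oracle at 1e-8. PSNR reports identical inputs as infinite with a flag.
* Blending: feathered weights are strictly positive, so accumulated
  weights never vanish; the final window per axis is clamped to the raster
  edge (no zero padding — every output pixel sees only real image
  content); rasters smaller than the patch are reflect-padded and cropped
  after merging. Steps larger than the patch are rejected, since coverage
  would fail.
* Quantization on write is round-half-even at the requested bit depth;
  [0, 1] float is the single internal currency and bit depth is purely an
  I/O concern. Coordinates everywhere are 0-based, row-major, half-open.
* Training aborts on a non-finite loss with a diagnostic naming the step,
  rather than clipping silently.
* Generator update order is G-then-D with detached fakes for the
  discriminator step; these conventions (plus batch size 1) are the
  simplest faithful reading of the published procedure and are
  configurable.

## The scaled-down self-correction experiment

The package's end-to-end experiment (`stageDemo()`, also the acceptance
script) runs the full loop at desk scale: a 128×128 phantom (12 cells, 4
fibers, background 0.2), uniform stripes of amplitude 0.5 on a 64 px tile
grid, 24 proximity pairs of 32 px patches, a slim network (16 base
channels, 2 residual blocks), 300 training steps, and sliding-window
correction at stride 16. Metrics are medians across three seeds.

What it shows, reproducibly: the consistency loss falls to a fraction of
its initial value, and the ICV of a cross-stripe ROI increases markedly
after correction — the stripes are flattened. What it does not show:
full-reference fidelity (PSNR/SSIM against the clean phantom) *worse* than
the striped input at this step budget. Three hundred Adam steps from a
cold Gaussian start are one to two orders of magnitude short of the regime
the method is designed for (hundreds of epochs over thousands of pairs);
even with oracle L1 supervision toward the clean patches — the strongest
possible content signal, which the unsupervised objective only approximates
through cycle consistency — the same network and step budget barely exceeds
the striped baseline. Content fidelity is the slowest-emerging property of
adversarial self-training, and the demo's step count is chosen for
tractability, not convergence. The loss histories written by the demo make
this trajectory inspectable.

## Known limitations

* Semi-automated: the tile geometry or anomaly mask is user input; there is
  no automatic stripe detection.
* Per-image: the model is trained on, and applies to, one stitched image;
  no transfer across images, no video.
* The simulator's artifact recipes are declared parametric stand-ins, not
  measurements of any instrument.
* CPU-only, single-sample training; patch sizes beyond a few hundred
  pixels are slow in this implementation.
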