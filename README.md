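# stripecor

Self-supervised stripe and artifact correction for stitched fluorescence
microscopy mosaics, in R.

Large microscopy images (multiphoton, stimulated-Raman, whole-slide
fluorescence) are stitched from many tiles, and each tile's illumination
falloff leaves periodic brightness stripes at tile boundaries — uniform,
non-uniform, grid, or oblique (angle θ) depending on acquisition and
post-processing. `stripecor` removes these stripes, and local artifacts
(out-of-focus regions, scanning fringes, bubbles), using **only the
degraded image itself** plus a rough tile-geometry annotation: no
flat-field reference, no raw tiles, no paired training data.

It is aimed at imaging scientists who receive stitched mosaics without
acquisition metadata and need per-image, content-preserving shading
correction.

## Method

Three stages:

1. **Proximity sampling** — mark pixels near tile-boundary lines as the
   anomaly domain X; sample patches on a quantized lattice; pair each
   anomaly patch with its nearest stripe-free patch (domain Y), so both
   share local illumination and texture.
2. **Adversarial self-training** — four networks: correction generator
   G<sub>C</sub> (X→Y), synthesis generator G<sub>S</sub> (Y→X), and
   least-squares discriminators D<sub>X</sub>, D<sub>Y</sub>. Generators
   minimize

   L = E[(1−D<sub>Y</sub>(G<sub>C</sub>(x)))²] +
   E[(1−D<sub>X</sub>(G<sub>S</sub>(y)))²] + λ·L<sub>cons</sub>,  λ = 10,

   with the content-consistency loss
   L<sub>cons</sub> = E‖G<sub>S</sub>(G<sub>C</sub>(x)) − x‖₁ +
   E‖G<sub>C</sub>(G<sub>S</sub>(y)) − y‖₁; each discriminator minimizes
   E[(1−D(real))²] + E[D(fake)²]. Adam, lr 2·10⁻⁴ (β₁ 0.5, β₂ 0.999),
   200 epochs with linear decay after 100.
3. **Local-to-global correction** — slide windows over the whole mosaic
   (stride P/2 or 100 px), map each through G<sub>C</sub>, merge by
   feathered weighted mean (an exact partition of unity).

Quality is scored with the inverse coefficient of variation
(ICV = R<sub>a</sub>/R<sub>sd</sub>, mean over population standard
deviation of an ROI; larger = flatter = better), intensity profiles across
the stripes, and — when a clean reference exists — PSNR and SSIM.

The package also ships a parametric degradation simulator (tissue-like
phantoms, the four stripe families, three artifact kinds), so the entire
pipeline is testable without any microscopy data, and a compact
convolutional-network engine (Rcpp im2col convolutions, manual backprop,
Adam) on which the four sub-networks run. Everything is S4: `ImageRaster`,
`StripeModel`, `ShadingField`, `RegionMask`, `TrainingSet`,
`CorrectionModel`, `SlidingWindowPlan`, `MetricsReport`, with accessors and
validity checks.

## Worked example

A complete scaled-down run — synthesize a striped phantom, sample pairs,
train, correct, evaluate:

```r
library(stripecor)
cfg <- asRunConfig(list(seed = 1, output_dir = "demo-out"))
res <- runPipeline("demo", cfg)
str(res$report)
```

which prints (seed 1):

```
List of 14
 $ seed          : int 1
 $ n             : int 128
 $ steps         : num 300
 $ psnr_striped  : num 21.1
 $ psnr_corrected: num 14.3
 $ psnr_improved : logi FALSE
 $ ssim_striped  : num 0.906
 $ ssim_corrected: num 0.221
 $ icv_clean     : num 1.61
 $ icv_striped   : num 1.72
 $ icv_corrected : num 2.67
 $ icv_improved  : logi TRUE
 $ l_cons_initial: num 1.2
 $ l_cons_final  : num 0.156
```

Reading: the 128×128 phantom is degraded by uniform amplitude-0.5 tile
shading (PSNR 21.1 dB vs clean). After 300 adversarial training steps the
consistency loss has dropped from 1.20 to 0.16 and the ICV of a
cross-stripe ROI has risen from 1.72 to 2.67 — the stripe profile is
flattened well beyond the clean image's own 1.61. Full-reference fidelity
(PSNR 14.3 dB, SSIM 0.22) is *not* yet recovered at this step budget:
300 steps from a cold start is deliberately far below the hundreds of
epochs the method trains for in practice; see the vignette for the
analysis. The run also writes the fixture set, the corrected TIFF, the
loss history CSV, and JSON manifests under `demo-out/`.

Individual stages are available as functions (`generatePhantom`,
`makeStripeField`, `buildTrainingSet`, `trainSelfCorrection`,
`correctWholeImage`, `evaluateCorrection`, ...) and as a thin CLI:

```sh
exec/stripecor demo --seed 1 --out demo-out
exec/stripecor correct --input in.tif --model demo-out/model.rds --output out.tif
```

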