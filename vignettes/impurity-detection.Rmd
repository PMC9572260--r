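---
title: "Image-based impurity-rate detection for mechanically harvested wheat"
author: "wheatSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based impurity-rate detection for mechanically harvested wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

The impurity rate of mechanically harvested wheat — the mass fraction of
straw, awn and husk in the grain stream, expressed in percent — is a primary
quality indicator of combine-harvester work. The reference measurement weighs
a hand-separated sample: `P_cz = w_z / w × 100`, with `w_z` the impurity mass
and `w` the sample mass (typically 500 g). It is accurate but slow and
off-line.

`wheatSeg` implements the image-based alternative. An RGB photograph of the
grain pile is segmented pixel-by-pixel into background (0), grain (1) and
impurity (2); the pixel tallies `T_w` (grain) and `T_z` (impurity) are then
converted to a mass-based rate through

$$P_z = \frac{T_z}{T_z + \partial\, T_w} \times 100\,\%$$

where $\partial$ is the ratio of grain mass to impurity mass covering 1000
pixels each. Grain is far denser per unit of projected area than straw, so
$\partial \gg 1$; the package ships the laboratory-calibrated default
$\partial = 11.8906$ and `calibrateDelta()` re-estimates it from paired pixel
counts and weighed masses. The identity behind the model is easy to state:
if the per-1000-pixel densities are exactly `d_w` and `d_z`, then
$P_z$ computed with $\partial = d_w / d_z$ equals $P_{cz}$ exactly — the
package's tests verify this to machine precision on noiseless synthetic
scenes.

### Calibration of ∂

Each calibration sample contributes a grain density `1000 (w − w_z) / T_w`
and an impurity density `1000 w_z / T_z`. Two estimators are exposed:

* **ratio of means** (default): mean grain density over mean impurity
  density. Stable when some samples contain few impurity pixels, which is the
  common case at ~1% impurity rates.
* **mean of ratios**: averages per-sample density ratios; requires both
  components in every sample.

The per-sample density spreads are returned as coefficient-of-variation
diagnostics. Under 5% multiplicative weighing noise and 30 samples, the
ratio-of-means estimate concentrates within about 1.3% of the truth (the
noise averages as $CV/\sqrt{n}$ per component), which is why the acceptance
checks demand recovery within 5% in at least 95% of replicates.

## The segmentation network

The model is a DeepLabV3+ encoder–decoder:

* **Backbone** — `tiny`, `mobilenetv2`, `resnet50`, `resnet101` or
  `xception65`, each defined at its canonical layout and uniformly
  width-scalable via `widthMultiplier`. The final stage replaces its stride
  with atrous (dilated) convolution so the encoder output keeps stride 16
  (or 8) while growing its receptive field.
* **ASPP** — parallel 3×3 atrous branches at rates (6, 12, 18) by default,
  plus a 1×1 branch and a global image-pooling branch; concatenated and
  projected by a 1×1 convolution.
* **Decoder** — bilinear 4× upsampling of the encoder output, concatenation
  with the backbone's stride-4 low-level features (projected to a small
  width), two 3×3 convolutions, a 1×1 classifier to 3 channels, and a final
  4× bilinear upsampling to input resolution.

`predictMask()` takes the per-pixel argmax (ties to the lower class index,
so inference is deterministic).

### The CPU engine

No deep-learning runtime is used: the package contains a small tape-based
layer engine. Feature maps are `(H·W) × C` matrices; a k×k convolution is
computed as the sum of k² shifted pointwise matrix products, which maps
stride and dilation onto precomputed index tables and delegates the
arithmetic to BLAS. Bilinear resampling is two dense interpolation matrices
(half-pixel centres, rows summing to 1), applied separably; its adjoint is
the exact backward pass. Every operation's backward pass is verified against
central finite differences in the test suite (exact to ~1e-8 under a smooth
quadratic loss; the assembled tiny network to ~1e-5 under its real
cross-entropy loss).

### Normalisation

The canonical backbones use batch normalisation; this engine trains at batch
size 1 on CPU, where batch statistics degenerate, so it uses **channel-wise
instance normalisation** (per-image spatial mean/variance, learned scale and
shift) everywhere a batch-norm would sit. One consequence is documented
rather than hidden: at extreme width multipliers (a handful of channels) a
channel can go constant, its variance collapses to the `1e-5` floor, and the
backward pass amplifies gradients by up to `1/sqrt(eps)`; stacked over the
~100 normalisation layers of a full-depth backbone this makes desk-scale
finite-difference checks of `resnet101`-class models disagree. The `tiny`
backbone and moderate widths are unaffected. Full-width training of the deep
backbones is in any case a GPU-scale undertaking outside this package's test
envelope.

### Training

`trainModel()` minimises unweighted per-pixel 3-class cross-entropy
(background included — the class imbalance at ~1% impurity rates is real but
mild at the pixel level, and weighting is deliberately not applied) with
Adam, gradients averaged over `batchSize` images per step, shuffling and
initialisation fixed by integer seeds, and a step-decayed learning rate
(default 3e-3, halved every 5 epochs). The best-on-validation weights (by
two-class MIOU) are retained. All randomness flows through per-call seeds; no
global RNG state leaks in or out.

## Evaluation metrics

Per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and
`IOU = TP/(TP+FP+FN)`, computed from confusion counts **pooled across the
image set** (micro averaging — duplicating images provably leaves every
metric unchanged). MIOU averages the grain and impurity IOUs only; this
two-class convention is what makes the published per-backbone MIOU values
consistent with their per-class IOUs, and the package adopts it throughout.
Zero denominators yield an explicit `NA` marker with a warning, never a
silent zero, and are excluded from averages.

Two published-table idiosyncrasies are handled explicitly: one backbone's
MIOU and one field-test IOU cell are not consistent with their own
printed companions under the identities `F1 = 2PR/(P+R)` and
`IOU = PR/(P+R−PR)`; the reference tables shipped in the package
(`benchmarkBackbones()`, `benchmarkOnline()`) carry consistency flags and the
inconsistent cells are excluded from identity checks.

## Trial statistics

A bench batch or field trip compares repeated device detections against
manual reference samples: absolute error `R_az = |mean_dev − mean_man|`
(percentage points), relative error `R_rz = R_az / mean_man × 100`, and the
coefficients of variation of both series. The CV uses the sample standard
deviation (divisor N−1); recomputing the published trial table from its
rounded printed means reproduces the published errors to within 0.06
percentage points, the residue being the source's rounding of the means.

## The synthetic scene generator

`renderScene()` emulates what the detection camera sees: a pile of wheat on
the dark floor of the sampling bin.

* **Grains** are filled ellipse polygons (semi-axes 5–11 px at the working
  512×512 resolution, warm ochre with per-object colour jitter), drawn first.
* **Impurities** are bent straw strips (piecewise-linear spines offset to a
  thin closed polygon) and thin husk arcs (partial annuli), pale yellow,
  40–110 px long — elongated shapes with colour and shape statistics distinct
  from grains.
* Later objects overwrite earlier ones (draw-order semantics, matching how
  polygon annotation tools resolve overlaps); masks and polygons are exact
  and mutually consistent, and blur (σ = 0.6 px) plus additive sensor noise
  (SD 0.015) touch only the image.
* Default composition: 900 grains and 18 impurities per 512×512 frame, i.e.
  ~36% grain cover and an impurity/grain pixel ratio of ~0.11, so the default
  pixel rate lands near the ~1% mass impurity rates typical of field
  operation.
* `MassModel` attaches per-1000-pixel densities whose ratio is the true ∂
  (default: the laboratory 11.8906), with optional multiplicative weighing
  noise.

What the generator does **not** emulate: perspective and occlusion depth in a
real pile, specular highlights, dust on the window, motion blur from the
elevator, and the long-tailed shape variety of real residue. Tests passing on
synthetic scenes therefore demonstrate that the pipeline's machinery is
correct and learnable, not that any given backbone reaches field-grade
accuracy — the published field scores required the original 500-image
annotated dataset and GPU training, which are out of scope here.

## Desk-scale study conditions

The test suite and the acceptance script train the `tiny` backbone (width
0.5) on 200 synthetic 128×128 scenes and evaluate on 20 held-out scenes. The
128×128 scenes are defined as a **cropped field of view** of the working
resolution: per-object pixel statistics identical to the 512×512 conditions
(grain semi-axes 5–11 px, straw 30–80 px), with proportionally fewer objects
(~56 grains, ~2 straws). The alternative reading — optically zooming out so
grains shrink to ~2 px — corresponds to no configuration of the real device
and was rejected on those grounds. Three epochs at batch size 2, learning
rate 5e-3, reach a held-out two-class MIOU around 0.9 in a few CPU-minutes;
the acceptance threshold is 0.6.

## Numerical choices and degenerate inputs

* Rasterisation: pixel centres, even-odd rule, half-open scanline intervals
  (shared edges never double-fill); checked against a per-pixel ray-casting
  oracle. Zero-area polygons are skipped with a warning.
* Mask resizing is nearest-neighbour (bilinear interpolation of labels would
  invent invalid classes); the 0.6×/1.8× augmentation variants are restored
  to the canvas by centre background-padding / centre cropping so tensor
  shapes stay constant.
* An all-background prediction yields an *undefined* impurity rate, not
  100%: a frame with no visible grain is a sampling failure in the device
  context and is logged as such.
* Argmax ties in `predictMask()` break to the lower class index;
  interpolation matrices are cached per geometry; `inputSize` must be a
  multiple of 16 so the stride-16 encoder and the two 4× upsamplings compose
  exactly.
* Images with zero grain **and** zero impurity pixels make `pixelRate()`
  return the undefined marker; `∂ ≤ 0` is an error.

## Known limitations

* Full-width `resnet101`/`xception65` training is impractically slow on one
  CPU core; they are provided at canonical structure for completeness and
  exercised at reduced width in tests.
* Instance norm in place of batch norm means models are not weight-compatible
  with externally pretrained checkpoints; `TrainConfig(init = <path>)`
  accepts only this package's own checkpoints.
* The quantification model assumes the calibrated ∂ transfers across frames;
  moisture, variety and camera geometry changes require recalibration.
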