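---
title: "Untrained perceptual losses for volumetric denoising: models, parameters, and numerical choices"
author: "uperc3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untrained perceptual losses for volumetric denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the loss

Magnitude MR volumes of sparse, line-like structures — plant roots in soil,
brain vessels in angiography — are dominated by dark background with thin,
connected bright filaments. Voxelwise training losses (L1, L2) are known to
wash out exactly those filaments, because a denoiser can buy a large
voxelwise reward by smoothing the background and pays almost nothing for
erasing a one-voxel-wide root. Perceptual losses compare images in the
feature space of a convolutional network instead, so that a missing filament
perturbs many feature channels over a neighborhood. In 2D the feature
network is usually a classifier pre-trained on natural images; no such
pre-trained 3D networks exist, which is where the *untrained* perceptual
loss (uPL) comes in: the feature extractor is a randomly initialized 3D
convolutional network that is never trained and stays frozen.

Given a frozen extractor with tap points $\phi_j$ (we expose every ReLU
output), the loss between a prediction $\hat y$ and its reference $y$ is

$$\mathrm{uPL}(\hat y, y) \;=\; \sum_j \frac{1}{C_j H_j W_j D_j}
\bigl\lVert \phi_j(\hat y) - \phi_j(y) \bigr\rVert_2^2 ,$$

the squared Frobenius norm over all $C_j H_j W_j D_j$ entries of tap $j$,
normalized by that same entry count. Two readings in this formula were
genuinely open and are our choices: the sum runs over *all* activation
outputs of the extractor (a layer mask can restrict it), and batched
training averages the per-volume loss over the batch so magnitudes are
comparable across batch sizes. `perceptualLoss()` reports the per-layer
contributions so the effect of the mask is inspectable.

The package also provides the two comparison objectives used throughout:
plain L1 (`l1Loss`) and an SSIM objective returned as $1 - \mathrm{SSIM}$
(`ssimObjective`) so that the minimization direction and a nonnegative range
are preserved.

## The frozen extractors

`buildLossNetwork()` constructs the "simple" family: `depth` identical
convolutions (same padding, stride 1, `nFeatures` channels each, first layer
single-channel input), ReLU after every convolution, and optional
window-2/stride-2 max-pooling after the layers listed in `poolingAfter`.
The studied ablation space is depth ∈ {3, 5, 7, 9, 13}, kernel ∈ {3, 5, 7,
9}, pooling after the first one, two or three layers, and five
initialization schemes. Tap points are the ReLU outputs *before* any pooling
that follows the layer, so each pooling halves all later taps; odd extents
are floor-pooled (the trailing voxel is dropped). 3D translations of the
VGG19 and AlexNet convolutional stacks are available as presets; by default
they expose their first 8 activations (the full stack is available by flag —
layers beyond the last tap are simply not materialized, which keeps a
VGG19-3D build at a few million parameters instead of hundreds of millions).

Initialization schemes (`initializeWeights`): Kaiming (fan-in) and Xavier
(mean of fan-in/fan-out), each in uniform and normal variants with zero
biases, plus `default_uniform`, which draws every weight *and bias* from
$U(-k, k)$ with $k = (C_{in} \prod_i K_i)^{-1}$ computed per layer. That
reciprocal fan-in bound is the method's defining choice even though common
practice uses the reciprocal *square root* of the fan-in; the conventional
variant is available via `legacySqrtBound = TRUE`. The reciprocal fan-in
makes the draws roughly 30× narrower for a 32-channel 3³ layer, which is a
plausible explanation for the underperformance this scheme shows relative
to the Kaiming/Xavier families, and we keep it as the faithful default.

Frozenness is structural, not procedural: extractor parameters are created
with gradient tracking disabled, so the reverse-mode engine never visits
them. The test suite additionally asserts bit-identity of every extractor
parameter across full training runs.

## The denoising networks

Three shape-preserving architectures (all kernel-3, same-padding), built by
`buildDnCNN`, `buildResNet` and `buildTransformer3d`:

* **DnCNN** — conv(1→64) + ReLU, three blocks of conv(64→64) + ReLU +
  batch-norm, conv(64→1): exactly five convolutions. The default predicts the clean
  image directly; `residualOutput = TRUE` switches to noise prediction.
* **Residual CNN** — head conv + PReLU, five residual blocks (conv +
  batch-norm + PReLU) each wrapped in an additive identity skip, a tail
  conv + batch-norm + PReLU, and a final kernel-3 projection to one
  channel. The skip topology of this architecture family is ambiguous, and a
  description ending at an activation cannot emit a one-channel image:
  per-block identity skips are the standard residual form, and the
  projection conv is the minimal completion. Head width defaults to 64 to
  match the DnCNN convention.
* **Sequential 3D transformer** — head conv (8 channels), then `tfBlocks`
  sequential blocks of channel attention + gated feed-forward (no spatial
  down/up-sampling anywhere, deliberately: down-sampling is what reportedly
  breaks fine-structure denoising), then a 1-channel tail conv. The
  attention is "transposed" (MDTA): per sample, kernel-3 convolutions form
  queries/keys/values, spatial dims are flattened to length $HWD$, channels
  are L2-normalized, and softmax rows of the temperature-scaled
  channels×channels similarity mix the values — cost quadratic in channels,
  linear in voxels. The feed-forward expands 8→16→32 with kernel-3
  convolutions, gates by the elementwise product of the two 16-channel
  halves, and projects back to 8 channels with a 1×1×1 convolution so the
  residual connection type-checks. Block count (4), head count (1) and the
  gating algebra are package choices, all configurable.

Batch normalization uses batch statistics in training and running averages
(momentum 0.1, unbiased variance) in eval mode. Default parameter counts are
regression-tested: 335,873 (DnCNN), 668,232 (residual CNN), 91,421
(transformer).

## Noise model and phantoms

Rician corruption is the standard magnitude construction
$\sqrt{(v + g_1)^2 + g_2^2}$ with two independent Gaussian fields of
standard deviation $\sigma$ — not Rician-distributed samples *added* to the
signal. A noise level given as a percentage (the studied levels are 1%, 5%,
10%, 20%) is read as
$\sigma = \text{level} \times \text{peak intensity}$. A percentage noise
level could also be read as a fraction of the mean signal; the
peak-intensity reading is the simplest and is the documented, configurable
default. Volumes are normalized to
peak 1 (`normalizeIntensity`, per-volume max rather than a percentile — a
documented choice), which is exactly what makes the percentage levels well
defined. Closed forms used as oracles: for a constant
amplitude $A$, $E[\text{out}^2] = A^2 + 2\sigma^2$; for zero signal the
output is Rayleigh with mean $\sigma\sqrt{\pi/2}$.

`generatePhantom()` emulates what the method's motivating data look like:
sparse, connected, curvilinear bright structures on a dark background. Tubes
are persistent random walks with bounded per-step curvature (default 0.3
rad), dilated to a radius drawn from `radiusRange` with soft (anti-aliased)
edges; branches inherit 0.7× the parent radius; primary tubes are placed
with a separation margin by rejection so they form distinct connected
components (a property the tests count with an independent flood fill).
Defaults (5 tubes, radii 1.5–3 voxels in a 64³ volume) give foreground
fractions of a few percent, matching the sparsity that motivates the
method. What the phantoms deliberately do **not** model: MR acquisition
physics (k-space, coil sensitivities), bias fields, partial-volume texture,
motion. Passing tests on phantoms therefore demonstrate that the losses,
networks and training loop behave as specified on sparse tubular data — not
that any particular SSIM level transfers to scanner data.

## Training harness and determinism

`train()` runs exactly `iterations` Adam steps (learning rate 0.001; the
optimizer's standard β/ε defaults) on randomly
cropped (noisy, clean) pairs; each clean volume is corrupted once and crops
are cut from identical coordinates. A master seed derives independent
sub-seeds for weight initialization, data order, noise realization and the
loss network (`deriveSeed`), so ablations vary exactly one factor and whole
runs are bit-reproducible — the acceptance tests compare serialized reports
byte for byte. Final-iteration weights are returned (no early stopping or
best-checkpoint selection — a deliberate, flagged choice);
validation SSIM is computed every `valEvery` iterations and always at the
end, on full (uncropped) volumes. A non-finite loss aborts with the
iteration number.

Working precision: volumes and parameters are stored as R doubles (R has no
native 32-bit float arrays), while the convolutions — the entirety of the
compute — run in single precision during training and inference
(`precision = "single"`, the universal deep-learning convention) and in
double precision wherever values feed an oracle-grade comparison. The
single/double paths share one templated kernel and are cross-checked in the
tests.

The full-scale settings of the original study are available as
`paperTrainConfig()` (30,000 iterations, batch 16, 96³ crops); they assume
GPU-class throughput. The package's desk-scale defaults, used by the tests
and the acceptance script, are sized for a single CPU core via the measured
cost of the BLAS-backed convolutions: 150 iterations, batch 2, 16³ crops, 64
training phantoms and 6 validation phantoms of 32³. At that scale a DnCNN
trained with the uPL (simple extractor, depth 3, kernel 3, 32 features,
Xavier normal) raises validation SSIM over the noisy input (≈ 0.37) by
roughly +0.04 to +0.5 depending on the seed at 10% noise — short runs are
strongly seed-variable, which is exactly why the learning check asks for a
gain of at least 0.05 in two of three seeds rather than in every seed.
Two further caveats follow from the scale, not from the method: L1 can look
*stronger* than uPL after so few iterations (voxelwise losses descend
fastest early; the reported advantage of uPL emerges over tens of thousands
of iterations on real data), and none of the study's absolute SSIM/PSNR
tables should be expected from these runs.

## Evaluation protocol

`ssim3d` computes mean local SSIM over a sliding Gaussian window — σ = 1.5,
window 11³ where it fits, otherwise the largest odd window that does, valid
positions only, constants $C_1 = (0.01 r)^2$, $C_2 = (0.03 r)^2$ with data
range $r = 1$ after normalization. Window shape and constants are configurable, since SSIM values shift with
the window. PSNR is $10\log_{10}(r^2/\mathrm{MSE})$, with an infinity sentinel
serialized as the string `"inf"` and excluded from means with a warning.
Region-of-interest crops: root-like volumes take a 52³ cube anchored at z
offset 0 and in-plane offset 70 — a conventional slice-range phrasing of
this window (70–132) would span 62 in-plane voxels, and the cube size 52 is
taken as authoritative; angiography-like volumes take a centered 68³ cube with the
floor convention. Out-of-bounds windows raise an error naming the axis,
never silent truncation. `aggregateResults` reports mean/sd both pooled over
images and over seed-level means.

## Numerical choices, edge cases, limitations

* Convolutions are im2col + GEMM per sample; degenerate output extents
  (input smaller than kernel/stride footprint) raise a dimensionality error
  rather than clamping.
* Channel L2-normalization in the attention adds $10^{-24}$ under the root
  so zero channels stay finite; softmax rows are max-shifted.
* Max-pooling records argmax indices for an exact backward scatter; ties
  resolve to the first maximum in memory order.
* `l1Loss`'s subgradient at zero is taken as 0 (the `sign` convention).
* The reverse-mode engine frees intermediate gradients as it walks the
  tape; memory is bounded by the forward activations.
* Known limitations: no DICOM/4D ingestion, no resampling or registration,
  no k-space simulation, no U-Net baselines (reported to fail on this data
  class and excluded by design), no statistical testing across losses; and
  the desk-scale experiment demonstrates learning signal and protocol
  correctness, not the study's full-scale rankings.
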