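---
title: "Attention-gated VGG19 U-Net segmentation with Ising-MRF polishing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated VGG19 U-Net segmentation with Ising-MRF polishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Gliomas are segmented from four co-registered MRI modalities (T1, T1ce,
T2, FLAIR) into voxel classes 0 (background/healthy), 1 (necrotic core),
2 (edema) and 3 (enhancing tumor), evaluated over the standard nested
region composites: whole tumor WT = {1,2,3}, tumor core TC = {1,3},
enhancing tumor ET = {3}. The published label caption conflates voxel
classes with these composites ("1 for CT, 2 for WT, 3 for ET"); taken
literally it is not computable (WT is a superset, not a voxel class), so
this package uses the BraTS convention above, which makes the reported
ET/WT/TC Dice scores well defined and nested.

The segmentation network is a U-Net whose encoder is the VGG19
convolutional stack — conv blocks of (2, 2, 4, 4, 4) layers with
(64, 128, 256, 512, 512) channels, all 3×3 kernels, five 2×2/stride-2
max-pools — with the fully connected layers discarded. The standard
classifier has 16 convolutional + 3 fully connected = 19 weight-bearing
layers and 143,667,240 trainable parameters ("144 million"); dropping the
FC stack leaves the 20,024,384-parameter conv stack. The published
"36.1 million" after discarding the FC layers cannot be reconciled with
either the encoder alone (~20.0 M) or any obvious encoder+decoder
accounting at the stated widths; the package documents the two exact
counts it can compute and asserts those instead.

Each conv is followed by ReLU and then batch normalization, in that
order, following the source description ("the ReLU transforms ... the
output is then batch normalized"); BN-after-ReLU is unusual but
well-defined and trains fine at this scale. The decoder is a symmetric
five-stage mirror: nearest-neighbor 2× upsampling, an attention gate on
the skip connection, channel concatenation, then two 3×3 conv+ReLU+BN
layers; a 1×1 conv and per-pixel softmax produce K = 4 class
probabilities. The decoder architecture is not specified in the source
beyond "adjacent decoder parts", so the standard U-Net mirror was chosen.

### The attention gate

For a skip feature map $e$ with $n$ spatial locations and the aligned
(upsampled) decoder state $o$, scores are
$s_j = V^\top \tanh(U e_j + W o_j)$, normalized by a softmax over the
locations: $\alpha_j \ge 0$, $\sum_j \alpha_j = 1$. The context vector
$C_t = \sum_j \alpha_j e_j$ is exposed by `attention_gate()`. Inside the
network the gated skip is $(n\,\alpha_j)\,e_j$: the $n$ rescaling makes
uniform attention the identity, reconciling the sum-to-one constraint
with a skip connection that must stay spatial. $V$ is initialized at
zero so every gate starts as the exact identity and learns to deviate.
The "previously predicted label" input of the sequential formulation has
no defined wiring in a feed-forward network and is deliberately not part
of the graph.

### Ising-MRF polishing

Binary masks are mapped to bipolar states $x \in \{-1,+1\}$. The energy
is

$$E(x, y) = -\sum_{\text{pairs}} x_p x_q - \eta \sum_{ij} x_{ij} y_{ij},$$

with pairs $((i,j),(i{+}1,j{+}1))$ for the `diag` neighborhood (the
literal index printed in the source) or 4-adjacency for `n4`. The printed
equation's sign, taken literally, *rewards* disagreeing with the
observation $y$; the package follows the standard construction, which is
also what the source's prose describes ("when pixels of both images
match ... the energy is low"). $\eta$ is labeled "learning rate" in the
source's symbol table but is used as the data-term weight, and is
implemented as such (default 15). ICM runs raster-order sweeps, each
pixel taking the sign of its local field with ties keeping the current
value, so every accepted update strictly lowers $E$ and the sweep count
is bounded. At $\eta = 15$ the data term ($2\eta = 30$) exceeds the
largest possible coupling change (8 under `n4`, 4 under `diag`), so ICM
provably returns its input unchanged — the package's default polish is a
no-op on clean argmax maps and only matters at smaller $\eta$.

Noise injection is $y = \operatorname{sign}(x + g)$, $g \sim N(0,
\sigma^2)$, $\sigma = 1.5$, giving a flip rate $\Phi(-1/\sigma) \approx
0.2525$. The source says "20% noise"; with bipolar states and
$\sigma = 1.5$ the rate is ≈25%, so $\sigma$ is treated as authoritative
and the discrepancy documented here. Whether noise is a training-time
regularizer or an inference step is ambiguous in the source; both are
provided (`noise_in_training` flips training label maps through the
bipolar channel; `inject_noise_first` replays it before ICM at
inference), and both default off at inference.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` builds an ellipsoidal "brain" (semi-axes
`brain_radius_frac` × grid, default 0.45) containing three concentric
tumor spheres — whole > core > enhancing, default radii (6, 4, 2.5)
voxels on a 96×96×16 grid — and renders each modality as a per-tissue
mean plus i.i.d. Gaussian noise (default sd 5 against means of order
100, i.e. 5% noise, a realistic SNR for normalized BraTS data). The
default means encode the two clinically load-bearing contrasts: edema
brighter than healthy tissue on FLAIR, enhancing tumor brighter than
necrotic core on T1ce. The default z-extent (16 slices) reflects the
thin-slab look of a desk-scale case; the tumor radii are capped by the
requirement that the whole-tumor sphere fit inside the brain ellipsoid,
which `phantom_spec()` validates.

The phantom has piecewise-constant tissue intensities, perfect sphere
geometry, no bias field, no partial-volume effects, no anatomy and no
inter-scanner variation. A network that reaches DSC ≈ 1 here has only
demonstrated that the pipeline is wired correctly and can fit a
separable intensity model — not that it segments real gliomas; the
published BraTS'20 headline numbers are out of reach of this package by
design (no external data, no GPU training).

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `input_size` | 224 | px | the published input size; must be divisible by 32 |
| `width_factor` | 1 | – | channel multiplier; 0.25 is the desk-scale test point |
| `eta` | 15 | – | MRF data-term weight, published value |
| `sigma` | 1.5 | – | noise sd, published value (≈25% flips) |
| `tumor_fraction` | 0.5 | – | minimum fraction of tumor-bearing patches |
| `lr` | 1e-3 | – | Adam step size (see below) |
| `batch_size` | 8 | patches | standard default; desk runs use 4 |
| `noise_sd` (phantom) | 5 | intensity | ~5% of the tissue means |

## Numerical choices

* **Learning rate.** The source never states one; the natural default
  1e-4 was measured against the package's own desk-scale acceptance
  point (quarter-width network, 96×96 inputs, 3 phantoms, ≤200 Adam
  steps) and the package default was set to the smallest power of ten
  that reliably reaches training-set DSC(WT) ≥ 0.95 there. The
  acceptance suite records the measurement.
* **Loss.** Per-pixel categorical cross-entropy (probabilities clipped
  at 1e-12). A soft-Dice auxiliary term was considered and not
  implemented: on the separable phantom it is unnecessary, and it would
  be untestable against any published value.
* **Normalization.** Per-modality z-score over nonzero (brain) voxels
  with the population-sd convention; background stays exactly 0. BN uses
  eps 1e-5 and momentum 0.1 on running statistics (inference uses the
  running buffers).
* **Patch sampling.** "Patch" = full `size`×`size` axial slice window,
  center-cropped/zero-padded, never resampled. At least
  ⌈`tumor_fraction`·N⌉ sampled slices must contain tumor; sampling is
  without replacement where the pool allows, with replacement otherwise.
* **Ties.** Softmax argmax ties resolve to the lowest class index
  (`max.col` ties are not an issue because probabilities are continuous);
  ICM field ties keep the current pixel; `to_bipolar` maps p = threshold
  to +1.
* **Recombination.** Polished per-class binary maps recombine by
  priority enhancing > core > edema; pixels claimed by no map become
  background. The source never specifies this step; priority by clinical
  specificity is the package's choice.
* **Cohort jitter.** `phantom_cohort()` jitters tumor centers (±2 voxels
  in-plane, ±0.5 axially) and radii (±0.5); jitter is halved until the
  tumor still fits the brain, so every generated case is valid.
* **Determinism.** All randomness flows through R's RNG from explicit
  seeds; single-threaded BLAS gives bit-identical results. Training
  reproducibility (identical loss curves, weights and predicted masks) is
  asserted in the test suite.

## Known limitations

* 2D axial slices only (the published input is 224×224 2D); no 3D
  convolutions.
* ImageNet encoder initialization is a loading hook
  (`pretrained_encoder` + weights file); weight values are not bundled.
* The NIfTI backend covers the BraTS-relevant subset of NIfTI-1 (3D,
  common dtypes, sform affine); qform-only files fall back to spacing
  from pixdim via the identity sform.
* The MRF polish is per-class binary; no multi-label Potts model, no
  graph-cut or annealing inference.
* Published Table 2/3 values on BRATS'20 require the external dataset
  and GPU-scale training and are intentionally not reproduced; the
  acceptance suite anchors on architecture counts and property-based
  checks instead.
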