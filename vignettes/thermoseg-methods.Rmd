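---
title: "thermoseg: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoseg: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Elevated plantar temperature is an established early marker of ulceration
risk in diabetic feet. `thermoseg` implements an integrated analysis of
plantar thermograms in three tiers:

1. **Segmentation** of hyperthermic lesion regions with a U-shaped
   segmenter whose encoder and decoder are built from modified
   Swin-transformer blocks (shifted-window self-attention, a hybrid
   channel–spatial attention variant, and multi-level feature fusion).
2. **Feature extraction** with a capsule network: primary capsules formed
   from the segmenter's bottleneck, iterative dynamic routing by agreement,
   and a fully connected reduction to a flat feature vector.
3. **Classification** (control vs diabetic, CG vs DM) with an extreme
   learning machine (ELM): a fixed random hidden layer and output weights
   solved in closed form by ridge-regularized least squares.

Because the clinical thermogram collection the design targets is not
redistributable, the package ships a synthetic generator that emulates its
structure (122 DM / 45 CG subjects; files named
`{group}{code}{gender}_{side}`), and every quantitative claim made by the
test suite is made on that synthetic cohort.

## The segmenter

Images enter as single-channel arrays in `[0, 1]`. A patch-partition layer
cuts non-overlapping `patch_size × patch_size` squares (default 4) and
embeds each into `embed_dim` channels. Three encoder stages follow; between
stages a patch-merging layer concatenates 2×2 token neighborhoods and
projects `4C → 2C`, so the grid halves and the channels double at each
stage. Each stage applies transformer blocks with the pre-norm residual
structure

    u   = x + Attn(Norm(x))
    out = u + MLP(Norm(u))

where the attention slot alternates between shifted-window multi-head
self-attention (SW-MHSA, with relative position bias and exact masking of
token pairs separated by the cyclic roll) and the hybrid channel–spatial
gate (SW-HCMA): the window content is multiplied by a sigmoid channel gate
(window-pooled descriptor through a small MLP) and a sigmoid spatial gate
(channel-pooled map through a 3×3 convolution). `Norm` is batch norm in the
modified block (the architecture's default) or layer norm in the standard
variant; both are available via `umst_config(norm_kind=)`.

A fusion module bridges encoder and decoder: each stage map is downsampled
by a strided 2×2 projection and folded into the next deeper stage along the
channel axis (concatenate, then project back to that stage's width). The
decoder mirrors the encoder: a block at the bottleneck, then two stages of
learned 2× upsampling (projection + pixel shuffle), skip concatenation with
the fused encoder map, projection, and a transformer block. The head
projects to `patch_size² × n_seg_classes` and pixel-shuffles back to input
resolution, so every output pixel owns a logit. We chose the learned
pixel-shuffle over fixed bilinear upsampling because the lesions of
interest are only a few pixels wide at desk scale; a fixed interpolator
from the token grid cannot place boundaries at pixel resolution, which
caps the attainable Dice well below what the same network reaches with a
learned expansion.

Segmentation trains with the soft Dice loss
`1 − (2|S·T| + ε)/(|S| + |T| + ε)` on the foreground probability map
(ε = 1, so an all-background target stays finite).

## The capsule head and the ELM

The bottleneck map is projected 1×1, reshaped into pose vectors of length
`primary_dim`, and squashed (`v ↦ v·‖v‖/(1+‖v‖²)`, direction preserved,
norm in `[0, 1)`). Transformation matrices shared across primary capsules
("global parameter sharing") produce prediction vectors; dynamic routing
runs `routing_iters` iterations (default 3) of: couplings =
softmax of the logits over output capsules, weighted sums, squash,
agreement update. Gradients flow through the unrolled loop. A fully
connected reduction flattens the output capsules into the feature vector
`Z` (default length 32).

During backprop training a plain softmax head on `Z` provides the
classification term of the combined loss
`L = α·Dice + β·CrossEntropy` (α = 0.6, β = 0.4). The ELM is deliberately
not trained by gradient descent: after backprop converges, the hidden layer
(uniform(−1,1) weights, sigmoid activation; "arbitrary" allocation is the
point of an ELM) maps the frozen features, and the output weights solve the
ridge problem — dual form `β = Hᵀ(I/C + HHᵀ)⁻¹O` when `N ≤ L`, primal form
`β = (I/C + HᵀH)⁻¹HᵀO` otherwise; as `C → ∞` both tend to the
Moore–Penrose minimum-norm solution. This two-phase scheme is the only
consistent way a closed-form ELM can coexist with end-to-end ADAM
training, and it is what the package's cross-validation harness does in
every fold.

## Training protocol and its parameters

| parameter | default | meaning |
|---|---|---|
| `lr` | 0.001 | initial ADAM learning rate |
| `epochs_max` | 289 | epoch budget |
| `batch_size` | 30 | minibatch size |
| `alpha`, `beta` | 0.6, 0.4 | combined-loss weights |
| `momentum_param` | 0.02 | recorded passthrough; consumed only by the SGD fallback (ADAM has no classical momentum constant) |
| `early_stop_patience` | 20 | epochs without validation improvement (`min_delta` = 1e-4) |
| `dropout` | 0 | rate inside the block MLPs |

Early stopping requires a validation signal the protocol itself does not
specify; the harness holds out 10% of training *subjects* (at least one)
inside each training fold. Gradients are clipped to unit global norm —
small-minibatch Dice gradients are heavy-tailed, and unclipped ADAM steps
can collapse the foreground probability irrecoverably.

Augmentation (uniform affine: translation, scale, rotation; bilinear for
images, nearest-neighbor for masks so they stay binary) is applied to
training folds only. Applying it before the split would leak augmented
copies of test subjects into training; the cross-validation is
subject-level and stratified by group for the same reason.

## The synthetic generator

Each record is a foot-shaped support (two overlapping ellipses plus five
toe discs) carrying a smooth low-frequency temperature field, additive
Gaussian noise (`noise_sd` = 0.02), and — for DM subjects only — one to
three Gaussian-profile hot spots with half-max radius 3–6 px and peak
elevation `lesion_contrast` = 0.35 above the local field. The ground-truth
mask is the half-max disc of each lesion; lesions are placed inside the
eroded support with a separation margin, so mask components are connected
and countable. Defaults were chosen once as a plausible desk-scale
emulation of "elevated plantar temperature" hot spots on a 64×64 grid.

What the generator does *not* emulate: camera calibration and radiometry
(values are relative, not °C), anatomical temperature asymmetries,
artefacts (emissivity variation, motion), and the ambiguity of real lesion
boundaries. Passing tests therefore demonstrate that the implementation
learns and evaluates correctly on data of this structure — not clinical
performance.

## Numerical choices

* The trainable tiers run on an in-package reverse-mode tape over base-R
  arrays; every operator's vector–Jacobian product is tested against
  central finite differences, and a full transformer block matches to
  1e-3 relative.
* Attention restricted to a window equal to the token grid reproduces
  dense attention to machine precision (oracle-tested); masked pairs in
  shifted windows receive exactly zero weight.
* `squash` at `v = 0` returns 0 (the defined limit); its backward guards
  the `‖v‖ → 0` singularity.
* Dice smoothing ε = 1; ELM ridge `C` = 1e3 by default; probabilities are
  floored at 1e-12 inside cross-entropy.
* Ties in mask argmax resolve to the first (background) channel.
* Batch norm uses per-channel statistics over (batch, height, width) with
  running-stat momentum 0.1; evaluation uses the running statistics.

## Desk-scale study sizes

The packaged evaluation runs are sized for a single CPU. The learnability
check overfits 8 synthetic images with an `embed_dim` 32, depths
(1, 1, 1) model (layer-norm blocks, minibatch 2, lr 1e-3) to soft-Dice
≥ 0.95. The end-to-end five-fold cross-validation (`desk_cv()`) uses a
30 DM / 12 CG cohort at 64×64 with the default (high-contrast) generator
settings and an `embed_dim` 16 model. These sizes are the package's own
scaled-down study conditions; the architecture accepts larger settings
unchanged. Because the tape allocates heavily, long-running evaluations
are executed in fresh R sessions (the test suite shells out per
cross-validation run); this keeps the interpreter's heap compact and makes
the seed-for-seed reproducibility check a comparison across independent
processes.

## Known limitations

* The pure-R tape is compute-bound well below GPU-framework scale; the
  configurations above train in minutes, clinical-resolution training does
  not.
* Binary segmentation only (lesion vs background); no region taxonomy.
* The generator's lesions are circular by construction; real ulcer-risk
  regions are not.
* Checkpoints serialize with `saveRDS` and are R-specific.
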