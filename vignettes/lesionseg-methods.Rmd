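---
title: "Methods: a modified U-Net for dermoscopic lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a modified U-Net for dermoscopic lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Delineating a pigmented lesion from surrounding skin in dermoscopy images is
the binary-segmentation step on which downstream melanoma classification
rests. `lesionseg` implements an encoder–decoder convolutional segmenter for
this task: every pixel of a 192×256 RGB dermoscopy frame is classified as
lesion or background, so the input and output share the same spatial size.

The package has five coordinated parts: a *declarative architecture
description* with an exact parameter accountant, an *executable network
engine* (forward pass, backpropagation, Adam/SGD/Adadelta), a *segmentation
metric suite*, *paired offline augmentation*, and a *seeded synthetic
dermoscopy generator* plus the training/sweep harness that ties them
together. Everything is testable end to end without downloading any external
dataset.

## The architecture

`modified_unet_spec()` builds the reference ladder: five encoder levels of
3×3 same-padded convolutions (each followed by batch normalization), 2×2 max
pooling between levels, a 6×8 bottleneck, and a mirrored decoder of
parameter-free 2×2 nearest-neighbour upsampling and further 3×3
convolutions, ending in a single-channel sigmoid head. Channel widths run
64→64 | 128→128 | 256×3 | 512×3 | 512×3 on the encoder and mirror back down
512×3 | 512,512,256 | 256,256,128 | 128,64 | 64,1 on the decoder. The
spatial ladder at the default input is 192×256 → 96×128 → 48×64 → 24×32 →
12×16 → 6×8 and back.

Several aspects of the published layer table are internally inconsistent,
and the package resolves them explicitly, always in favour of the
*Parameters column*, which is the only reading that closes the books:

* **Channel wiring.** The printed per-row parameter cells force the channel
  counts above (e.g. a 73,856-parameter 3×3 convolution must have 64 input
  and 128 output channels). The printed *Input Image Size* column
  contradicts this in several rows and is treated as typographical.
* **Skip connections.** The printed decoder parameter counts admit feature
  concatenation *only* at the coarsest (12×16) level: the first decoder
  convolution needs 1024 input channels (4,719,104 parameters), while the
  later decoder rows (e.g. 2,359,808) rule out concatenation at finer
  levels. The default `skip = "single"` wiring implements exactly that;
  `skip = "full"` (concatenation at every level, the textbook U-Net) is
  available but is not the reference surface.
* **Pooling count.** Six pooling rows are printed, but the stated spatial
  ladder (192×256 down to 6×8) requires exactly five halvings; one row is a
  duplicate and five pools are used.
* **Output head.** The final convolution is printed with ReLU, but a
  per-pixel probability map requires a `[0,1]` codomain, so the default head
  is sigmoid (`final_activation = "relu"` restores the printed reading).
* **Footer totals.** The printed footer total (33,393,669) exceeds the sum
  of the printed per-row cells (31,818,757) by 1,574,912; whatever layers
  account for the difference are not recoverable from the table. The
  accountant treats the *row cells* and the non-trainable total (15,874,
  which the batch-norm channel sum reproduces exactly) as ground truth;
  `spec_self_check()` reports both grand totals side by side rather than
  forcing agreement.

### Parameter accounting

`count_layer_params()` implements the usual bookkeeping: a convolution holds
`k²·c_in·c_out + c_out` weights (bias included — the printed cells contain
it, e.g. 1792 = 1728 + 64), batch normalization holds `4·c` (scale and shift
trainable, running mean and variance not), and pooling, upsampling and
concatenation hold none. `count_model_params()` sums the description;
`network_param_count()` measures the arrays of a *built* network. The two
paths are independent by construction and are cross-checked in the test
suite — the declarative path never touches the engine's storage.

## The executable engine

No deep-learning framework is assumed: the forward and backward passes are
implemented in the package (im2col + GEMM convolutions via RcppArmadillo,
exact-argmax pooling, nearest-neighbour upsampling, batch normalization in
R's vectorized arithmetic). Choices a framework would otherwise make:

* **Operation order** is conv → batch-norm → activation, so the sigmoid head
  emits calibrated probabilities (a head normalized *after* the sigmoid
  could leave `[0,1]`).
* **Initialization** is He-uniform for convolutions
  (`U(±sqrt(6/fan_in))`), zeros for biases, ones/zeros for batch-norm
  scale/shift; all seeded through R's RNG, so equal seeds give bit-identical
  networks.
* **Batch normalization** uses per-batch statistics during training
  (`eps = 1e-5`), exponential running statistics (momentum 0.9) at
  inference.
* **Loss** is mean per-pixel binary cross-entropy, folded analytically with
  the sigmoid head (`dL/dz = (p − y)/N`) for numerical stability;
  probabilities are clipped at `1e-7` when the loss value itself is
  reported.
* **Optimizers** use the conventional defaults: Adam (`lr 1e-3`,
  `β = 0.9/0.999`), plain SGD (`lr 1e-2`), Adadelta (`lr 1.0`, `ρ = 0.95`).
  Learning rates are recorded in every sweep row.
* **Gradient correctness** is not assumed: the test suite checks
  backpropagation against central finite differences through the full depth
  of a scaled network, and the convolution kernel against an explicit dense
  loop.

One empirical property worth knowing: because the head is itself
batch-normalized, logits stay near unit scale until the head's scale
parameter grows, so the cross-entropy declines slowly even while the Dice
overlap climbs quickly. This is a property of the reference design, not of
the optimizer.

## Metrics

`confusion_counts()` tallies TP/FP/FN/TN over strictly binary masks;
`overlap_scores()` derives Jaccard, Dice, precision, recall and accuracy.
With `smooth = 0` the standard definitions apply, and the identity
`D = 2J/(1+J)` (hence `D ≥ J`) holds whenever the union is non-empty — a
property the suite verifies on a thousand random mask pairs. Published
evaluations of this architecture report Jaccard *above* Dice (e.g. 96.35 vs
89.01), which no standard, smoothed, or soft variant can produce; the
package therefore ships all three variants side by side
(`overlap_scores(smooth =)`, `soft_overlap()`) and documents the anomaly
instead of guessing an unstated formula. Conventions: empty-vs-empty overlap
is 1 (and flagged); 0/0 precision/recall is `NA` and flagged; binarization
threshold defaults to 0.5; `evaluate_split()` reports scores ×100 and loss
as 100 × mean cross-entropy, matching the reporting scale of the published
tables (a batch-18/100-epoch validation loss of 16.24 on that scale is 0.16
nats).

`evaluate_split()` offers `per_image_mean` (default: average of per-image
scores) and `global_pixels` (pool all counts first); the two coincide
exactly when all images carry identical counts, and the suite asserts the
global mode against manually summed confusion matrices.

## Augmentation

Offline, paired, and mask-exact by default: horizontal/vertical flips and
quarter-turn rotations are pure pixel permutations, so masks stay binary and
foreground counts are conserved — properties tested exhaustively on 100
generated pairs. The default recipe `c("flip_h", "rot90")` triples a
dataset. Arbitrary-angle rotation (`rot_angle`, the non-axis-aligned case
seen in practice) is available behind the same interface with bilinear image
and nearest-neighbour mask resampling; it does not conserve counts exactly
and is therefore not in the default recipe. Augmentation is applied by the
harness to the *training split only, after splitting* — the published
pipeline leaves the order unstated, and augment-then-split would leak
near-duplicates of evaluation frames into training.

## The synthetic generator

`generate_dataset()` emulates what the pipeline needs from a dermoscopy
archive, not its photorealism: a skin-toned background with low-frequency
multiplicative texture, exactly one darker, brown-shifted lesion per frame
with a smooth edge transition, optional dark hair strokes (random quadratic
curves) and a corner vignette. Masks are star-convex regions
`r(θ) = r₀(1 + Σ aⱼ sin(jθ + φⱼ))` on an elliptical base: star-convexity
guarantees a single connected component, `boundary_irregularity = 0`
recovers an exact ellipse (measured area within 2% of `π·rₓ·r_y`), and
raising the irregularity strictly raises mean perimeter²/area — the
difficulty knob the tests exercise. Defaults mirror the emulated archive:
192×256 frames, lesion area 5–35% of the frame, up to 4 hairs, and a
160:40 non-melanoma:melanoma labelling recorded in the manifest only
(appearance is not class-conditioned; the labels exist for layout
fidelity). Deliberately not modelled: gel glare, colour charts and ruler
markers, multi-lesion frames, diagnostic-class-specific texture. Passing
the recovery test below therefore demonstrates that the architecture,
gradients, optimizers and metrics cooperate correctly — not clinical-grade
accuracy on real dermoscopy.

## Training harness and the sweep

`split_dataset()` partitions 70/15/15 (rounded test/validation, remainder
to train — fractions are unstated in the published evaluation, so the
conventional split is used and is configurable). `sweep_architectures()`
mirrors the published experimental design: one model per
optimizer × batch-size × epochs cell, identical initialization seed across
cells, all three splits evaluated per cell, results in the published column
order, and the *best cell selected by validation-accuracy argmax* (the
published procedure; no early stopping). The full published grid —
{Adam, SGD, Adadelta} × {8, 18, 32} × {25, 50, 75, 100} — enumerates 36
cells; the package executes arbitrary sub-grids, and the published PH2
numbers themselves are out of scope (external data, unstated split,
GPU-scale stochastic training). The published 100-epoch loss blow-up is
read as a training-instability observation, not a behaviour to reproduce.

## Problem sizes and the recovery benchmark

The package's end-to-end benchmark trains the width-1/4 reference network
(channels quartered; ~2.0 M parameters) on 60 generated 64×64 pairs,
offline-augmented ×3 with the default recipe, Adam, batch 8, 12 epochs, and
requires standard Dice ≥ 0.85 on 20 held-out pairs for each of three seeds.
64×64 frames (the smallest fully generic multiple of the 2⁵ pooling
requirement above 32) were chosen as the benchmark scale so the whole
three-seed run completes in minutes on a single CPU core; the geometry of
the task is scale-free, and nothing in the engine is specialized to the
reduced size. With only the coarsest-level skip connection, boundary detail
must survive five pooling stages, which caps achievable Dice well below the
ceiling a full-skip U-Net would reach — the benchmark threshold reflects
the reference wiring, and `skip = "full"` is the lever a user should reach
for first on real data.

## Known limitations

* The engine is CPU-only and single-threaded beyond BLAS; full-width
  training at 192×256 is out of desk scale by design (the full-width network
  is still *built* and counted exactly).
* `skip = "single"` (the reference wiring) structurally limits boundary
  precision, as above.
* The Jaccard-above-Dice values of the published tables cannot be
  reproduced by any formula shipped here; the discrepancy is documented,
  not imitated.
* The synthetic generator is a correctness instrument; no claim is made
  that Dice on generated data predicts Dice on clinical dermoscopy.
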