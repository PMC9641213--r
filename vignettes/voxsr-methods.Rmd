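---
title: "Volumetric MRI super-resolution with residual U-Nets: models and methods"
author: "VoxSR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric MRI super-resolution with residual U-Nets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-resolution (HR) anatomical MRI of children is expensive: long
acquisitions are poorly tolerated and often end in motion artifacts.
Single-image super-resolution (SR) offers a way to acquire faster,
lower-resolution (LR) scans and recover resolution computationally. VoxSR
implements the full supervised pipeline for this problem: because genuine
LR/HR pairs are never available, LR observations are *simulated* from HR
ground truth, a convolutional network is trained to invert the simulated
degradation, and recovered volumes are compared against the ground truth
they came from.

The degradation model is

$$Y = T(X) = (D_\downarrow S)\,X + N,$$

where $S$ is a smoothing operator (a normalized cubic Gaussian kernel of 5
voxels per side, $\sigma = 1$ voxel), $D_\downarrow$ subsamples one of
every $N$ voxels per axis ($N \in \{2,3,4\}$ is the scaling factor), and
$N$ (the noise of the transformation) is not explicitly injected — the
simulation chain itself adds nothing beyond interpolation error, though
`simulatePair(noiseSd = ...)` exposes an optional additive Gaussian hook,
off by default. The network does not operate on the small LR grid:
the LR volume is first re-upsampled to the HR grid with separable cubic
interpolation, $I^\uparrow(Y)$, which keeps one network applicable to all
scaling factors. The recovery operator $R$ is learned as

$$\hat R = \arg\min_R \sum_i \lVert X_i - R(I^\uparrow(Y_i)) \rVert,$$

conceptually a least-squares objective; the loss actually optimized is the
tissue-masked L1 + gradient loss described below, which favors the edges
and contours that squared error over-smooths.

## Preprocessing conventions

* **Size standardization.** Volumes are zero-padded to a cube
  (`padToCube`), keeping the brain centered; when the deficit along an
  axis is odd the extra zero plane goes on the *trailing* side. This is a
  fixed convention so that patch origins and stitching coordinates are
  bit-reproducible. Larger-grid clinical volumes are first resized with
  cubic interpolation (`resizeVolume`); the resize method is our
  assumption, since only the grid sizes of that step are fixed by the
  protocol.
* **Masking and background.** A binary tissue mask is computed by global
  Otsu thresholding, keeping the largest 6-connected component, closing
  with a 3-voxel cubic structuring element, and filling interior holes.
  The construction is not prescribed by the protocol we follow — it was
  chosen because it is deterministic and directly testable against the
  phantom generator's ground-truth support (Dice > 0.99 on clean
  phantoms). The background is then homogenized to exactly 0
  (`homogenizeBackground`), an idempotent operation.
* **Normalization.** Min–max normalization maps each HR volume to [0, 1]
  with its own extrema. Each simulated LR volume is normalized *with the
  extrema of its paired HR image*, so both live on one scale; values
  pushed outside [0, 1] by the shared reference are clipped, keeping the
  data inside the sigmoid-bounded codomain of the network. At inference on
  a genuine LR volume there is no HR counterpart, so the volume's own
  extrema are used — the only definable reference in that setting.
* **No denoising, bias-field correction, registration or anatomical
  reorientation** is applied anywhere; arrays keep their stored axis
  order.

## Architecture

The network is a 9-stage residual U-Net: four encoder stages, a latent
stage, four decoder stages. Stage $s$ of the encoder runs
`stageBlocks[s]` conv blocks — convolution (3 voxels per axis), batch
normalization, ReLU — doubles the filter count
(64, 128, 256, 512 with the default 64 initial filters; the latent stage
has 1024, following the doubling rule literally since per-stage filter
counts are not printed anywhere authoritative), and halves each spatial
dimension by 2×2×2 max pooling. Decoder stages mirror this with
transposed convolutions (stride 2), concatenate the homologous encoder
stage's feature maps (skip connections), and halve the filter count. The
default block layout (2,2,3,3,3,3,3,2,2) yields **23 conv blocks**, and
with the 4 transposed convolutions and the final 1-kernel sigmoid head,
**28 convolutional layers**; `countLayers()` derives these by walking the
structure table rather than quoting constants.

Residual shortcuts sit before each max pooling and after each transposed
convolution: the stage input is projected by a 1-kernel convolution to the
stage's filter count and combined with the stage output. Open design
points, resolved here and flagged as assumptions:

* "Appending" the projected input is implemented as **elementwise
  addition** — the 1-kernel projection to the matching channel count is
  exactly what addition requires, and "residual operation" conventionally
  means addition.
* In the decoder the order is: transposed convolution → skip
  concatenation → conv blocks → residual addition, with the transposed
  convolution's output as the shortcut source.
* Transposed convolutions use kernel size 2 (equal to their stride),
  which cannot produce checkerboard overlap.
* The 1-kernel shortcut projections are *excluded* from the 28-layer
  count (23 + 4 + 1 = 28) and reported separately (8 of them).
* Weights are initialized with fan-in-scaled Gaussian draws (He
  initialization), deterministically in the seed.

The 2D variant is identical apart from kernel dimensionality: it consumes
complete slices instead of 32³ patches, implemented internally as
degenerate-depth volumes with 1×3×3 kernels and 1×2×2 pooling, so the 2D
and 3D networks share one engine and identical structural counts.

The engine itself — direct convolutions, batch normalization, pooling,
transposed convolutions, the masked loss and Adam — is implemented in
C++ (RcppArmadillo) in single precision, with the channel axis contiguous
so the inner filter loops vectorize; CPU-specific code paths are emitted
as compiled clones and selected at load time. Everything around the
engine is double precision.

## Training

* **Patching.** Training and validation patches are 32³ (16³ in the tiny
  test configuration) extracted at stride = patch size (no overlap).
  Patches containing no tissue are kept; the loss simply assigns them
  zero (below). For the 2D network, complete slices are used; the slicing
  axis defaults to axis 1 (the zero-padded axis), an assumption since the
  orientation is not recorded in the protocol.
* **Augmentation.** Each training volume is replaced, once per epoch, by
  a randomly rotated copy: three angles drawn uniformly from
  [−30°, 30°], one per rotation plane — (1,2), (1,3), (2,3), applied
  successively in that fixed order — about the volume center with cubic
  interpolation and zero fill. 30° is the largest plausible shift of a
  subject inside the scanner bore. The rotation seed derives from
  (run seed, epoch, volume), so runs are exactly reproducible. Validation
  data are never augmented (the multiplicity — one copy per volume per
  epoch — and the validation exclusion are our choices; only the
  transform itself is prescribed).
* **Loss.** The objective is
  $L = \mathrm{MAE}_m + G_m$: the mean absolute intensity error over
  tissue voxels plus the mean absolute difference of forward finite
  differences, pooled over the three axes and over stencils whose two
  voxels are both tissue, with equal 1:1 weighting ("the sum"). A patch
  with an empty mask contributes 0 rather than being excluded, keeping
  batch composition simple. The loss is zero iff prediction equals target
  on the mask and is invariant to anything outside it.
* **Optimization.** Adam (default moment parameters; only the
  learning-rate policy is prescribed) with initial rate $10^{-4}$,
  divided by $e^{0.2}$ whenever the validation loss fails to improve for
  more than 4 epochs, floored at $10^{-5}$; the patience counter resets
  on improvement or reduction. Batch size is 12 patches (3D) or 8 slices
  (2D). The reference protocol trains 50 epochs on adults and 100 on
  children.
* **Splits and model selection.** Cohorts are shuffled deterministically
  and partitioned by rounded fractions: 33 adults → 26 train / 7 test
  (no validation group), 90 children → 54/18/18. The returned checkpoint
  minimizes validation loss (earliest epoch on ties); when a plan has no
  validation group the final epoch is kept — our convention for the
  adult-style split.
* **Transfer learning.** `transferLearn()` initializes every parameter
  (and the batch-norm running statistics) from a pretrained base and
  retrains with all parameters free; zero epochs returns the base
  unchanged. Adam moments restart. Pathological cohorts
  (e.g. dysplasia) are evaluated by running the healthy-trained model
  directly, without fine-tuning.

## Inference and stitching

Whole volumes are reconstructed from overlapping patch predictions:
patches of side $p$ are extracted at stride $s = p/2$, and each
prediction contributes only its central *inner cube* of side $s$ — except
that patches touching a volume face keep their outer margin on that face,
so the volume is covered completely. Every voxel is written exactly once;
the implementation asserts this and fails loudly otherwise (volume
dimensions must be multiples of the stride). The alternative — reflecting
the volume by $s/2$ before patching — was rejected to keep the output
grid identical to the input grid. No weighted blending is performed: the
hard inner-cube fusion is the method being replicated, and a test pins
down the sharp transition it produces between neighboring constant
patches.

Because the training loss never sees background voxels, the network's
output there is unconstrained noise. `superResolve()` therefore
homogenizes the output background to exactly 0 whenever a tissue mask is
supplied, mirroring the preprocessing applied to every input volume. This
is a pipeline design decision, fixed before any evaluation was run.

## Evaluation

* **PSNR** $= 20\log_{10}(\mathrm{MAX}/\sqrt{\mathrm{MSE}})$ dB with
  MAX = 1; identical inputs are reported as `Inf`, a sentinel rather than
  an error.
* **MAE** is reported on the standard [0, 255] intensity range.
* **SSIM**: the headline metric is the standard windowed form — local
  moments over a 7³ uniform sliding window (symmetric reflection at the
  borders), constants $c_1 = 0.01^2$, $c_2 = 0.03^2$ for unit dynamic
  range. The formulation we follow prints the *single-window* (global)
  statistic and repeats $c_1$ where the standard form has $c_2$ in the
  variance factor; `ssim(..., global = TRUE)` reproduces that printed
  formula verbatim. The discrepancy is documented rather than silently
  corrected, and the window size/shape of the windowed form is our
  assumption (none is stated anywhere authoritative).
* Metrics are computed on whole volumes by default (the stated
  convention), with an optional masked mode.
* **Statistics.** `compareMethods()` runs a repeated-measures ANOVA per
  metric (method, scaling factor, interaction; volumes as the repeated
  unit) followed by pairwise paired Wilcoxon signed-rank tests per metric
  and factor — exact null for n ≤ 25 without ties, normal approximation
  otherwise — flagging significance at α = 0.05. Method pairs with no
  nonzero differences are reported as degenerate with `p = NA` rather
  than manufacturing a p-value.

## The phantom generator

Real pediatric MRI cannot ship with a package. `generatePhantom()` builds
seeded, brain-like test volumes: three nested ellipsoid shells
(CSF/GM/WM-like) with increasing base intensities (0.35, 0.55, 0.8 by
default), optional band-limited texture (white noise smoothed to a
correlation length of 2 voxels, fixed amplitude 0.06), optional additive
Gaussian noise (sd 0.01 by default), clipped to [0, 1], with an exactly
zero background. The generator returns the ground-truth support and shell
labels, so masking, degradation, training and stitching can all be
validated against known structure. `generateCohort()` varies semi-axes
(±8%), centers (±2 voxels) and intensities (±0.04, order-preserving) with
per-phantom seeds derived from (seed, index).

What the phantoms *do* share with real data: piecewise-smooth tissue
regions, sharp tissue boundaries, fine texture, zero background — the
structure that Gaussian degradation measurably destroys and SR must
recover. What they do *not* model: anatomy, partial-volume gradients,
bias fields, Rician noise, lesions. Tests passing on phantoms therefore
certify the pipeline's mechanics and its ability to learn an inverse
degradation — not clinical image quality.

## Numerical choices and reproducibility

* The network engine computes in float32 (the standard deep-learning
  precision); compiled with floating-point reassociation enabled, so its
  results are deterministic for a given binary but not bit-identical
  across compilers. All public metrics, the standalone loss
  (`maskedL1GradientLoss`) and the degradation operators are double
  precision; the loss is tested to 1e-12 against a brute-force oracle and
  the degradation to 1e-10 against dense convolution + decimation.
* Decimation anchors at index 0 of each axis; smoothing borders use
  symmetric reflection (zero-padding would create dark rims; the
  background is zero anyway). Both are fixed so outputs are
  bit-reproducible.
* The LR-to-HR upsampling uses the *same* anchor: output voxel $i$ reads
  LR coordinate $i/N$. A pixel-center mapping here would misregister the
  upsampled volume by $(N-1)/2$ voxels against the HR grid — enough to
  make fidelity non-monotone in $N$ on grids that $N$ does not divide.
  Generic resizing (`resizeVolume`) keeps the conventional pixel-center
  mapping.
* Cubic interpolation is the separable Catmull–Rom (Keys) kernel with
  pixel-center grid alignment: exact on the sample grid, exact on linear
  ramps, constant-preserving.
* All randomness — weight init, shuffling, splits, rotations, phantoms —
  derives from explicit integer seeds; repeated runs are identical.
* Model selection ties break to the earliest epoch. Empty masks give
  zero loss. PSNR of identical volumes is `Inf`, never an exception.
* Batch normalization uses momentum 0.1 running statistics; with very few
  optimization steps (a handful of batches) evaluation-mode outputs lag
  training-mode outputs, so validation losses are only meaningful after a
  few dozen updates. The test configurations are sized accordingly.

## Desk-scale test configuration

Full-scale replication (256³ volumes, 64 initial filters, 32³ patches,
50–100 epochs, cohorts of 33–90 subjects) is expressible in
`defaultRunConfig()`'s keys but is not what the test-suite runs. The
package's experiments are validated at desk scale, a configuration we
fixed once: 25 phantoms of 64³ (20 for training + validation, 5 held
out), scaling factor 2, a 3D network with 8 initial filters, 16³ patches,
15 epochs. Under those conditions the trained network beats bicubic
interpolation on all three metrics on the held-out phantoms (the margin
is typically +1.5 to +3 dB PSNR), and the suite asserts the sign of that
difference as its end-to-end check — the printed full-scale result tables
require the original cohort and full-scale training and are out of desk
scope.

## Known limitations

* The engine is CPU-only and single-threaded; full-scale training is
  supported by configuration but is a multi-day computation.
* Memory: training caches activations per layer; large batch × patch
  combinations are bounded by available RAM.
* The phantom generator is structural, not anatomical (see above).
* Stitching requires volume dimensions divisible by the inference
  stride; pad first (`padToCube`) otherwise.
* The 2D slice network shares the engine's 3D data path; per-slice
  batch normalization statistics are computed over the batch of slices,
  matching the 3D convention.
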