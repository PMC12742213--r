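---
title: "Multi-stage windowed-attention affine registration: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stage windowed-attention affine registration: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Preclinical (rodent) fMRI analysis pipelines align every subject's brain
volume to a standard atlas before any group-level statistics. The alignment
step considered here is purely *affine*: 12 degrees of freedom —
translation, rotation, scaling and shear — bringing each subject into
coarse correspondence with the atlas. `msaffine` implements an unsupervised,
learning-based estimator of that transform: a three-stage coarse-to-fine
network built from shifted-window self-attention blocks and dilated
convolutions, trained end-to-end by maximizing an image-similarity
objective, with no manual labels.

# The geometric model

The transform is parameterized as $[t, r, s, h] \in \mathbb{R}^{12}$ and
assembled as the ordered homogeneous product

$$A = T \, (C\, R_x R_y R_z\, S\, H \, C^{-1}),$$

where $C$ translates the pivot (by default the moving image's intensity
centre of mass) to the origin. Parameters are constrained by smooth
squashing rather than clipping, so the network head can emit unconstrained
reals and remain differentiable everywhere:

* translation $t = 0.5\tanh(\cdot)$, i.e. $|t| \le 0.5$ in the normalized
  frame;
* rotation and shear $= \pi\tanh(\cdot)$, i.e. within $[-\pi, \pi]$;
* scale $= 1 + 0.5\tanh(\cdot)$, i.e. within $[0.5, 1.5]$.

Zero raw output is exactly the identity transform, and any in-range
parameter vector yields a positive-determinant linear block (no
reflections).

**Coordinate convention.** All matrices act in normalized coordinates: the
voxel-centre lattice of each axis maps linearly onto $[-1, 1]$, with the
origin at the volume centre. This makes parameters resolution-independent
across pyramid levels, which matters because the three stages operate at
scales $0.25/0.5/1$. Matrices are *sampling* (pull) maps — warping $M$ by
$A$ produces the volume $x \mapsto M(Ax)$ — the standard spatial-transformer
convention: it is hole-free and makes the composition of cascade stages a
plain matrix product. The forward motion of image content corresponds to
the inverse matrix; the exported plain-text matrices are tagged with the
convention.

# The network

Each stage sees the fixed image and the *currently warped* moving image at
one pyramid level (the moving volume is always resampled directly from the
original data through the accumulated matrix — one interpolation, no
stacking):

1. **Linear patch embedding** with windows of $2^3$, $4^3$, $8^3$ voxels
   for the three stages, flattening 8-, 64- and 512-vectors and projecting
   to width $C$. Because the window grows with resolution, every stage
   works on the same token-grid size.
2. **Pair fusion**: feature-wise concatenation of the two token grids
   followed by a learned projection back to width $C$. The fusion weights
   are *initialized* as difference + context channels — half the output
   responds to the token-wise difference between fixed and warped-moving
   (zero at perfect alignment, first order in the residual misalignment),
   half to their shared content. The operator itself is the generic
   concatenate-project; the initialization merely starts it at the most
   informative point for short training schedules.
3. **Attention block pairs** (Swin-style): LayerNorm → windowed multi-head
   self-attention → residual, LayerNorm → MLP → residual, then the same
   with the window grid cyclically shifted by half a window (cross-boundary
   attention masked). Two heads everywhere; a learned relative position
   bias indexed by 3D token offsets, zero-initialized. In the default
   preset the deeper stages carry two block pairs with a patch merge
   ($2^3$ neighbourhoods → width $2C$) between them; the tiny preset uses
   one pair per stage.
4. **Dilated convolutional block**: tokens reshaped to a spatial map, two
   $3^3$ convolutions with dilations 1 and 2 (BatchNorm + ReLU after each),
   reshaped back. The stacked dilations give a $7^3$ effective receptive
   field without resolution loss.
5. **Affine head**: mean over tokens, linear → tanh → linear to the raw
   12-vector, squashed into ranges as above and composed into the stage
   matrix. The final transform is the accumulated product of the
   centre-of-mass initialization and all stage matrices; the moving image
   (or every frame of a 4D series) is resampled exactly once by it.

## Normalization in the batch-size-1 regime

Training uses batch size 1, so BatchNorm statistics are taken over the
spatial positions of the single volume being processed. The package uses
these per-sample statistics at *inference as well* (instance-normalization
behaviour): with batch 1, stored running averages drift away from the
statistics the features were trained under, which measurably destabilized
registration of held-out volumes in our experiments. Running statistics are
still tracked and can be selected (`bn_mode = "running"`), which is also
how the receptive-field check bypasses normalization.

# The objective

Training minimizes

$$\mathcal{L} = \sum_{i=1}^{L} -\tfrac{1}{2^{(L-i)}}\,
  \mathrm{NCC}_w\!\left(F_i, M_i(\phi)\right) \;+\; \lambda R(\phi),$$

a multi-resolution ($L = 3$, weights $-1, -\tfrac12, -\tfrac14$ from fine
to coarse) windowed local normalized cross-correlation plus a parameter
penalty. Identical pyramids give exactly $-1.75$ on volumes without flat
windows — a closed form the test suite checks.

Numerical choices:

* **NCC window** $w = 7$ voxels (odd, the common choice for this loss
  family; `w = 0` selects a single global window). Local sums are computed
  with separable box filters clipped at the volume boundary.
* **Variance guard** $\varepsilon = 10^{-5}$ inside the square root: flat
  windows (e.g. background) contribute 0, never NaN, and the loss gradient
  is finite everywhere.
* **Penalty** $R$: the sum of squared identity-deviations with each
  component normalized by its admissible half-range
  ($t^2$, $(r/\pi)^2$, $((s-1)/0.5)^2$, $(h/\pi)^2$); zero iff the
  transform is the identity. $\lambda = 0.01$.

# Training

Adam, batch size 1, default learning rate $10^{-4}$; the desk-scale
experiments below use $3\times10^{-3}$, appropriate for the tiny preset and
a few hundred steps. Model selection keeps the epoch with the lowest mean
validation *similarity* loss (a label-free criterion, matching the
unsupervised setting; ties go to the earliest epoch), with early stopping
after 30 epochs without improvement. A divergence guard aborts after 10
consecutive non-finite losses. One master seed covers weight
initialization, data splitting, shuffling and phantom sampling; two runs
with the same seed are bitwise-reproducible.

**Gradient routing.** The final matrix is the product of the
centre-of-mass initialization and the three stage matrices, so every stage
head receives gradient through the product rule (the Jacobian of the
ordered composition $T\,C R S H C^{-1}$ with respect to each parameter is
assembled analytically). The *feature* inputs of later stages — the
progressively warped moving image — are treated as detached constants, a
standard stabilization for cascaded registration networks that avoids
backpropagating through repeated resampling. All hand-written gradients
(attention, LayerNorm, BatchNorm, convolutions via im2col, trilinear
sampling, the NCC loss, the composition chain) are verified against finite
differences in the test suite.

**Calibrated head initialization.** The pooled head inputs vary across
training pairs by roughly two orders of magnitude less than their mean, and
that variation concentrates in a few correlated directions. Before the
first optimizer step the first head layer is therefore centred on the mean
observed over (up to) 40 training pairs and rotated/rescaled so its tanh
pre-activations are decorrelated with spread ≈ 0.3 (an LSUV-style,
data-dependent initialization). Without it, the small readout regression
the heads must solve is so ill-conditioned that batch-1 SGD makes no
visible progress within a few hundred steps. All parameters remain fully
trainable afterwards; `head_calibration = FALSE` disables it.

# The synthetic phantom generator

Real rodent cohorts and their atlas cannot be redistributed, so all
training, recovery and metric tests run on seeded phantoms: an ellipsoidal
"brain" with a smooth dome-shaped intensity profile containing $K$
labelled interior ellipsoids of distinct intensity in a deliberately
*asymmetric* arrangement (so rotations are identifiable), per-subject
jitter of structure positions and sizes, light smoothing, and min–max
normalization. Misaligned pairs are built by warping the phantom with the
*inverse* of a sampled ground-truth transform (plus optional Gaussian
noise), so the forward transform is exactly the recovery target and no
inverse-consistency ambiguity enters. Default misalignment ranges are
milder than the hard constraint bounds — rotations $\le 0.3$ rad,
translations $\le 0.15$, scales in $[0.9, 1.1]$, shears $\le 0.1$ — so
that recovery is well-posed; the full constraint ranges sit behind a flag.

What the phantoms do *not* emulate: MR physics (bias fields, EPI
distortion, susceptibility), realistic noise correlations, motion, or the
anatomical variability of real animals. Passing the recovery experiments
therefore demonstrates the correctness and trainability of the machinery,
not performance on real data.

# Desk-scale recovery: what it shows and where the protocol saturates

The packaged experiment (also re-run by `scripts/acceptance.R`) trains the
tiny preset ($C = 16$, one block pair per stage) on 50 phantom pairs at
$64\times64\times32$ for a few hundred batch-1 iterations and registers 10
held-out pairs. Problem sizes were chosen so the whole experiment runs in
minutes on one CPU.

Two results are robust across seeds. First, registration improves the mean
label Dice over the unregistered baseline on every held-out pair — the
centre-of-mass initialization plus the learned residual reliably removes
translation and part of the remaining misalignment. Second, the same
differentiable machinery, optimizing the 12 parameters directly for a
single pair (no network), recovers ground-truth rotations to ~0.01 rad in
a few dozen steps — the objective, its gradients and the geometric model
support full recovery.

What the short protocol does *not* achieve is full amortized recovery: a
few hundred batch-1 steps are one to two orders of magnitude fewer than
what networks of this family are normally trained for, and within that
budget the mean-pooled features of an essentially untrained encoder carry
only part of the per-pair rotation information (their best linear readout
explains a minority of the rotation variance, and regression dilution
shrinks the learned corrections accordingly). The cascade compounds three
such partial corrections but still leaves a substantial residual rotation.
We report this saturation honestly rather than tuning the experiment
around it; training for many more iterations (or on many more pairs) is
the expected remedy and is outside the desk-scale budget this package
targets.

# Evaluation metrics

Per structure $k$, Dice $= 2|S_M^k \cap S_F^k| / (|S_M^k| + |S_F^k|)$
(both sets empty counts as 1 — a vacuous success; exactly one empty as 0),
with label maps always warped nearest-neighbour. DSC30 is the *mean of*
the lowest $\lceil 0.3n \rceil$ Dice values after ascending sort — the
aggregator is our choice, documented here. HD95 is the 95th percentile of
the pooled directed boundary-to-boundary Euclidean distances (6-neighbour
boundary voxels, exact pairwise nearest distances), symmetric by
construction; it is reported in voxel units by default, with a
spacing-aware mode, and structures empty after warping are excluded with a
warning.

# Preprocessing and I/O

NIfTI volumes (3D or 4D) are read and written with their voxel spacing;
the affine-stage preprocessing resamples to a target spacing (default
$0.3\times0.3\times0.4$ mm), pads/crops symmetrically to a target grid
(default $96\times96\times48$) and min–max normalizes intensities to
$[0, 1]$. 4D series are registered through their temporal mean: one matrix
is estimated from the mean volume and applied to every frame, preserving
the frame count. World-space coordinates are touched only at I/O; the
exported transform is the 4-line plain-text matrix in the normalized
convention with a JSON sidecar carrying the parameter record and the
convention tag.

# Known limitations

* Affine only; no deformable refinement.
* Mean pooling over tokens includes window-padding tokens (kept simple and
  documented); padding is zero-filled on the high side.
* Batch-1 BatchNorm is intrinsically noisy; the instance-statistics mode
  mitigates but does not remove this.
* The desk-scale training protocol saturates well before full parameter
  recovery (see above).
* Phantom realism is deliberately limited; no claims transfer to real
  animal data without retraining and validation.
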