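# msaffine

Unsupervised affine registration of preclinical (rodent) MRI/fMRI volumes
to a standard atlas, for neuroimaging pipelines that need every subject in
a common space before group-level analysis. The estimator is a three-stage
coarse-to-fine network — linear patch embedding, shifted-window multi-head
self-attention block pairs, dilated convolutional blocks and a per-stage
affine head — trained end-to-end with an image-similarity objective and no
manual labels. Everything, including the forward and backward passes of
the network, is implemented in R.

## The model

The transform is parameterized as $[t, r, s, h] \in \mathbb{R}^{12}$
(translation, rotation, scale, shear) and assembled as the ordered
homogeneous product

$$A = T\,(C\,R_x R_y R_z\,S\,H\,C^{-1}),$$

with the pivot $C$ at the moving image's centre of mass and smooth range
constraints ($|t| \le 0.5$ normalized, $r, h \in [-\pi, \pi]$,
$s \in [0.5, 1.5]$) enforced by tanh squashing. A three-level image
pyramid (scales $0.25/0.5/1$) feeds three cascade stages with patch/
attention windows $2^3/4^3/8^3$; each stage sees the fixed image and the
currently warped moving image, estimates a residual transform, and the
final matrix — centre-of-mass initialization times all stage matrices —
resamples the moving volume exactly once through a differentiable
spatial transformer. Training minimizes

$$\mathcal{L} = \sum_{i=1}^{3} -\tfrac{1}{2^{(3-i)}}\,
\mathrm{NCC}_7(F_i, M_i(\phi)) + 0.01\,R(\phi),$$

a multi-resolution windowed local normalized cross-correlation plus a
quadratic identity-deviation penalty, with Adam at batch size 1.
Evaluation uses per-structure Dice, the mean of the worst 30% of Dice
scores (DSC30), and the 95th-percentile boundary distance (HD95). A
seeded phantom generator (brain-like labelled volumes with sampled affine
misalignments and noise) makes training and verification fully
self-contained. See `vignettes/methods.Rmd` for the complete account.

## Worked example

Train the tiny preset briefly on a small phantom cohort and register a
held-out misaligned phantom:

```r
library(msaffine)
set.seed(1)
co <- generate_cohort(10, seed = 42, shape = c(32, 32, 32), K = 5)
pairs <- lapply(co$pairs, function(p) list(fixed = p$fixed, moving = p$moving))
cfg <- train_config(lr = 3e-3, epochs = 10, max_iterations = 80, seed = 42)
fit <- train_network(pairs, net_config = stage_config("tiny", C = 8), cfg = cfg)

test <- make_pair(generate_phantom(777, c(32, 32, 32), 5),
                  sample_affine_params(777))
reg <- register_pair(fit$model, test$fixed, test$moving)
print(reg$transform)
#> affine transform (normalized frame, sampling convention):
#>          [,1]     [,2]      [,3]      [,4]
#> [1,] 0.966847 0.020375 -0.014147  0.061246
#> [2,] 0.012413 0.947716 -0.013449  0.005701
#> [3,] 0.025317 0.005714  1.000752 -0.050290
#> [4,] 0.000000 0.000000  0.000000  1.000000
round(unlist(reg$decomposition), 3)
#>     t1     t2     t3     r1     r2     r3     s1     s2     s3     h1     h2     h3
#>  0.061  0.005 -0.049  0.005 -0.026  0.013  0.967  0.947  1.001  0.034  0.012 -0.009
```

The printed matrix is the estimated sampling transform in the normalized
frame; the decomposition lists the recovered translation (fraction of the
half-extent), rotations (radians), scales and shears. Scoring the labelled
structures before and after:

```r
dsc_before <- mean(sapply(1:5, function(k)
  dice(test$fixed_labels == k, test$moving_labels == k)))
warped_labels <- warp_volume(test$moving_labels, reg$transform, "nearest")
dsc_after <- mean(sapply(1:5, function(k)
  dice(test$fixed_labels == k, warped_labels == k)))
cat(sprintf("mean label DSC: %.3f unregistered -> %.3f registered\n",
            dsc_before, dsc_after))
#> mean label DSC: 0.481 unregistered -> 0.499 registered
```

An 80-step training run only begins to improve on the centre-of-mass
initialization; the methods vignette discusses how recovery quality scales
with the training budget and where the desk-scale protocol saturates.

A command-line interface (`inst/cli/msaffine`) wraps the same functions:
`simulate` writes seeded phantom cohorts with a ground-truth manifest,
`train` fits a model on a cohort directory, `register` aligns a 3D volume
or 4D series (via its temporal mean — one matrix applied to every frame)
to an atlas, and `evaluate` scores label maps.

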