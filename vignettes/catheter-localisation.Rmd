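---
title: "Hybrid catheter tip localisation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid catheter tip localisation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathtrack)
```

Catheter-based cardiac interventions are commonly monitored with
transoesophageal echocardiography (TOE), where the catheter appears as a
thin, low-contrast curvilinear structure inside a speckled sector image —
hard to localise by eye, and hard for purely image-based methods because the
tip has few distinctive features in ultrasound. cathtrack implements a
hybrid localisation strategy: an electromagnetic (EM) tracking side that
pins down the physical tip position by pivot calibration, and an image side
that segments the catheter in 2-D echo frames with a patch-based UNet
trained under a smoothed Dice loss. This vignette documents the models, the
parameter choices, and the design decisions that were genuinely open.

## 1. Pivot calibration

A 6-DOF EM sensor is attached near the catheter tip; it reports, per
timestamp, a rotation $R_i$ (stored as a scalar-first unit quaternion) and a
translation $t_i$ in the tracker frame. When the tool is pivoted about a
physically fixed point, every pose satisfies the rigid constraint

$$ R_i \, p_{\mathrm{offset}} + t_i = p_{\mathrm{fix}}, $$

where $p_{\mathrm{offset}}$ is the unknown tip position in the sensor's
local frame and $p_{\mathrm{fix}}$ the unknown pivot point in the tracker
frame. Rearranged per pose into $[R_i \mid -I]\,(p_{\mathrm{offset}},
p_{\mathrm{fix}}) = -t_i$ and stacked over $N$ poses, this yields an
over-determined $3N \times 6$ linear system solved by the singular-value
pseudo-inverse (`solve_pivot()`). Numerical choices:

* **Pseudo-inverse cutoff.** Singular values below $10^{-10}$ of the
  largest are treated as zero. With six retained singular values the
  solution equals the unique least-squares minimiser; with fewer, the
  motion did not excite all six degrees of freedom.
* **Degeneracy is an error.** If all recorded rotations are (numerically)
  identical the offset is unobservable, and `solve_pivot()` raises a
  degenerate-motion error instead of silently returning the minimum-norm
  vector. A calibration that is clinically meaningless should never look
  like a number.
* **Residual statistic.** The per-pose residual is
  $\lVert R_i \hat p_{\mathrm{offset}} + t_i - \hat p_{\mathrm{fix}}\rVert$
  in mm; the headline scalar is its RMS. Because "calibration error" is
  sometimes also read as the distance between the recovered and true tip
  offset, the report exposes both the RMS residual and (in simulation,
  where truth is known) the recovery error; noiseless recovery is exact to
  floating-point precision, far inside the 0.1 mm accuracy expected of a
  pivot calibration.
* **No outlier rejection by default.** A `trim_outliers` flag refits once
  without the worst 5% of poses by residual; it is off by default because
  the reference procedure uses all recorded poses.

The pose-log reader (`parse_pose_log()`) accepts a plain CSV dialect
(`timestamp,q0,qx,qy,qz,tx,ty,tz,status`). Records flagged `MISSING` are
dropped with a warning, not interpolated — calibration needs only valid
poses, and interpolating orientation data would fabricate measurements.
Quaternions are stored scalar-first with four components and are normalized
on ingest with the sign convention $q_0 \ge 0$.

`simulate_pivot_motion()` generates calibration recordings for testing and
power analysis: rotations uniform over SO(3) (normalized-Gaussian
quaternion method — uniform coverage gives the best-conditioned design),
translations constructed to satisfy the pivot constraint exactly, plus
isotropic Gaussian noise of configurable standard deviation. All lengths
are mm throughout, matching EM tracker native units.

## 2. The synthetic echocardiography generator

No phantom or patient echo data ship with the package, so the generator is
the package's study bed: it emulates the appearance that matters for
catheter segmentation, and its defaults define the conditions under which
the pipeline is tested.

A frame is composed inside a fan-shaped sector (default $160 \times 160$
px at 0.5 mm/px, apex near the top, 70° opening, depth 12–150 px) as a
clipped sum of:

1. **Speckle**: exponential-distributed texture smoothed by a small
   Gaussian kernel ($\sigma = 1$ px) and normalized to a configurable mean
   (default 0.22) — the standard first-order approximation of fully
   developed multiplicative speckle. Its histogram stays right-skewed, and
   per-frame redraws make sequences temporally incoherent, as real speckle
   decorrelates under probe and tissue motion.
2. **Background structures**: a few low-contrast soft-edged ellipses
   standing in for cardiac anatomy (default 3 per frame).
3. **The catheter**: a bright quadratic-Bézier ribbon ending at the tip
   (default length 60 px, width 5 px ≈ a 2.5 mm ablation catheter at 0.5
   mm/px, added intensity 0.9, curvature parameter 0.15; curvature 0 gives
   the straight "vertical line" appearance). The ground-truth mask is the
   ribbon's anti-aliased support at $\alpha \ge 0.5$, and only that: a
   catheter rendered with zero intensity is invisible and therefore
   unlabeled.
4. **A reverberation artifact**: a horizontal bright band (default
   intensity 0.5 at 55% of max depth), visible in the image but *never*
   labeled — mirroring the labelling rule for water-tank reverberations,
   and forcing the network to learn the distinction rather than "bright =
   catheter".

What the generator does **not** emulate: anatomically realistic chambers,
beam-formation physics, shadowing, out-of-plane catheter sections, or
probe-motion view changes. Tests passing on this generator therefore show
that the pipeline works end to end on low-contrast speckled sector images
with a labelled thin bright target and an unlabelled distractor — they do
not certify clinical performance on real TOE data.

The EM-to-image bridge (`map_tip_to_image()`) applies a user-supplied rigid
transform and plane spec: points within a slice-thickness tolerance
(default 2 mm) of the imaging plane map to pixels via the isotropic
spacing, others are flagged out-of-plane. Estimating the probe calibration
itself is out of scope; the transform is configuration, not inference.
Image coordinates are (row, col), row increasing with depth — a convention
that must simply be fixed once for reproducibility.

Datasets are written as 16-bit TIFF frames plus binary PNG masks and a
JSON metadata file. (The installed PNG writer is 8-bit; TIFF keeps the
full 16-bit quantization so that write/read round-trips are exact at the
16-bit grid.)

## 3. Patch-based UNet segmentation

The image side follows a six-step pipeline: read frames, augment offline,
sample positive/negative patches, train a 2-D UNet, monitor the Dice-loss
curves, and predict. The reference hyperparameter profile
(`train_config()`) is: single-channel 448×448 patches, batch size 4, up to
30000 iterations with early stopping at a patience of 6000, UNet depth 5,
ReLU activations, dropout 0.5 before the final layer, positive-patch rate
0.95, offline augmentation ×10, Dice loss with additive (Laplace)
smoothing, binarization threshold 0.5.

The loss is the smoothed soft Dice

$$ L = 1 - \frac{2\sum p\,t + s}{\sum p + \sum t + s}, $$

with $s = 1$ by default (the conventional smooth-Dice constant; it keeps
the ratio defined on empty patches and tempers gradients on sparse
targets). Soft Dice (probabilities in the intersection term) is used for
training; hard Dice on thresholded masks is used for evaluation, where it
equals $2TP/(2TP+FP+FN)$ and `dice_accuracy() + dice_loss(smoothing = 0)`
is exactly 1.

Design decisions where the procedure was genuinely open:

* **Positivity is per patch**: a patch is positive iff its mask contains at
  least one catheter pixel, drawn with probability 0.95 by rejection
  sampling (50 tries, then fall back to centring on a random foreground
  pixel). Deciding positivity at whole-slice level instead would make the
  rate a property of the dataset rather than the sampler.
* **Iterations count batches**, not samples.
* **Augmentation ops**: horizontal flip, rotation within ±15°, intensity
  scaling within ±20%, and a small elastic deformation (max 3 px, 8 px
  smoothness); image and mask share the geometric transform and masks are
  re-binarized after interpolation. Each op can be disabled. The first
  copy of every frame is always the identity.
* **Optimiser**: Adam at learning rate $10^{-3}$, validation every 100
  iterations on a fixed seeded patch set, best-validation weights returned.
  These are unstated in the original procedure and are pinned in the
  config because reproducibility requires them to be fixed somewhere.
* **The engine.** The convolutional network (im2col convolutions, max
  pooling, nearest upsampling, the backward passes, and Adam) is
  implemented in the package on RcppArmadillo, with BLAS doing the heavy
  multiplications. The backward pass is verified against finite
  differences in the test suite; training is single-threaded and
  bit-reproducible from the config seed.

### The desk-scale profile

`desk_config()` is the profile used throughout the examples, tests, and the
acceptance script: depth-3 UNet with 8 base filters on 64×64 patches, batch
4, up to 600 iterations (validation every 50, patience 300), augmentation
×4, on a study of 40 synthetic frames (26 train / 6 validation / 8 held
out). These sizes are chosen so a full study trains in a few minutes on a
single CPU core while exercising every code path of the reference profile —
patch sampling, augmentation, early stopping, tiled prediction. On this
task the desk model reliably exceeds held-out hard Dice 0.7, with the
training-loss median dropping by well over 0.3 from the first to the last
decile of iterations.

### Prediction

Full frames are predicted by tiling with half-patch stride and averaging
overlapping probabilities, then thresholding; images no larger than a patch
are zero-padded to the divisibility the depth requires
($2^{\mathrm{depth}-1}$) and run in one pass.

## 4. Tip extraction and sequence tracking

`extract_tip()` reduces a predicted mask to a tip coordinate: largest
8-connected component (ties broken by scan order, so the component
containing the topmost-leftmost pixel wins — determinism matters more than
the tie itself), principal axis from the coordinate covariance, and the two
extremal pixels along that axis as candidates. With an external reference —
in the hybrid setting, the EM-mapped tip — the nearer candidate is
returned; without one, the deeper candidate (larger row), matching the
downward-pointing catheter convention. Flipping the mask flips the
extracted tip.

`track_sequence()` runs predict → extract → score per frame and aggregates
mean/min/max Dice, mean tip error (in px and, via the pixel spacing, mm)
and the count of frames with no detection. Empty-vs-empty masks score Dice
1.0 (both agree there is no target). Tip error against ground truth is
reported even though the image side alone has no EM reference — tip
localisation is the point of the hybrid framework, so the metric belongs in
the report. No temporal smoothing (Kalman or otherwise) is applied; each
frame is scored independently.

## 5. Interface shape

The package's tabular surfaces — pose logs, tip trajectories, loss
histories, per-frame tracking rows — are tibbles that pipe through dplyr,
with broom-style `tidy()`/`glance()` on fitted objects and `autoplot()`
methods for each result type. Images, sector geometry and network weights
are not naturally tabular and stay as lightweight S3 records (matrices and
named lists), the way R's image-analysis packages handle them; forcing a
448×448 intensity grid into a long data frame would cost memory and
clarity for no analytic gain.

## 6. Known limitations

* The generator's catheter is always partly in view and in plane; missed
  detections on real data (out-of-plane sweeps, acoustic shadowing) are
  not represented.
* The desk-scale study is a small, easy task by clinical standards; its
  Dice scores say the pipeline learns, not that the architecture is
  state of the art.
* Probe-to-image calibration is supplied, never estimated.
* The elastic-deformation transform moves the stored tip metadata only
  approximately (first-order displacement at the tip); augmented frames
  are used for training patches, where only image/mask alignment matters.
* Checkpoints store weights as JSON text: portable and diff-able, but not
  compact; at reference scale a binary format would be preferable.
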