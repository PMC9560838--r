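# cathtrack

Hybrid catheter tip localisation in 2-D echocardiography, combining
electromagnetic (EM) pose tracking with deep-learning image segmentation.

During catheter-based cardiac interventions the device is monitored with
transoesophageal echocardiography (TOE), where the catheter is a thin,
low-contrast curvilinear structure buried in speckle — difficult to
localise by visual inspection, and difficult for image-only methods because
the tip has few distinctive features in ultrasound. External EM tracking
pins down the tip physically but shows nothing of the anatomy. cathtrack
implements both halves of a hybrid solution and the bridge between them,
for engineers and researchers building image-guided-intervention pipelines:

* **Pivot calibration** (`solve_pivot()`): with a 6-DOF sensor pivoted
  about a fixed point, every pose satisfies
  `R_i · p_offset + t_i = p_fix`. Stacking the constraints as
  `[R_i | −I] (p_offset, p_fix) = −t_i` over N poses gives a 3N×6
  least-squares system solved by SVD pseudo-inverse, recovering the
  sensor-to-tip offset and the pivot point with residual diagnostics and
  degenerate-motion detection. Pose logs in a plain tracker CSV dialect
  are parsed with `parse_pose_log()`; `simulate_pivot_motion()` generates
  seeded synthetic recordings with known ground truth.
* **Synthetic echocardiography** (`render_frame()`,
  `simulate_sequence()`): speckled sector images containing a bright
  curvilinear catheter with a paired ground-truth mask, low-contrast
  background structures, and a horizontal reverberation artifact that is
  visible but never labelled.
* **Patch-based 2-D UNet** (`train_unet()`, `predict()`): positive/negative
  patch sampling at rate 0.95, offline augmentation, smoothed Dice loss
  `L = 1 − (2Σpt + s)/(Σp + Σt + s)`, Adam, early stopping, tiled
  prediction — on a compact CPU convolutional engine built into the
  package (RcppArmadillo), with gradients verified against finite
  differences.
* **Evaluation and tracking** (`track_sequence()`, `extract_tip()`,
  `dice_accuracy()`): hard-Dice scoring, principal-axis tip extraction
  from predicted masks (optionally disambiguated by the EM-mapped tip from
  `map_tip_to_image()`), per-frame and summary tracking reports.

Pose logs, loss histories and tracking reports are tibbles; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Calibrate from a simulated pivot recording (200 poses, 0.2 mm translation
noise) and map the tracked tip into image coordinates:

```r
library(cathtrack)

sim <- simulate_pivot_motion(true_offset = c(2.5, 2.0, 3.5),
                             fixed_point = c(20, -15, -120),
                             n = 200, noise_sd = 0.2, seed = 42)
fit <- solve_pivot(sim$poses)
fit
#> Pivot calibration
#>   Poses used:        200
#>   Tip offset (mm):   [2.4891, 2.0077, 3.4729] (sensor frame)
#>   Offset magnitude:  4.7209 mm
#>   Pivot point (mm):  [19.9652, -14.9986, -120.0084] (tracker frame)
#>   RMS residual: 0.338 mm
#>   Condition number:  1.08
```

The recovered offset is within 0.03 mm of the simulated truth; the RMS
residual reflects the injected 0.2 mm-per-axis noise; the offset magnitude
(4.72 mm) is the quantity comparable to a physically measured tip length.
With zero noise the recovery is exact to machine precision. Mapping a
tracked tip at (5, 40, 0.5) mm into the default sector:

```r
map_tip_to_image(c(5, 40, 0.5), geometry = sector_geometry())
#> # A tibble: 1 × 5
#>     row   col elevation_mm in_plane in_sector
#>   <dbl> <dbl>        <dbl> <lgl>    <lgl>
#> 1    84    90          0.5 TRUE     TRUE
```

The image side at desk scale — generate frames, augment, train, track:

```r
geo <- sector_geometry()
frames <- lapply(1:40, function(i)
  render_frame(scene_config(seed = i), geo, tip_position = c(60 + 2 * i, 80)))
cfg <- desk_config()   # depth-3 UNet, 64x64 patches, <= 600 iterations
fit <- train_unet(cfg, augment_dataset(frames[1:26], 4, seed = 7),
                  frames[27:32])
mask <- predict(fit, frames[[33]])
dice_accuracy(mask, frames[[33]]$mask)
```

A command-line front end over the same functions is installed at
`inst/cli/cathtrack` (subcommands `calibrate`, `simulate`, `train`,
`predict`, `evaluate`, `track`).

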