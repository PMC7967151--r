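# ankleproj

Sagittal-plane ankle angles from an integrated RGB + depth camera, by the
**projection-line method**, with everything needed to validate them: a
keypoint comparator, a dual-IMU gold standard with recording-clock
correction, method-agreement statistics, depth-error propagation, and a
synthetic articulated-leg scene generator with known ground truth.

It is written for movement-analysis researchers who have an RGB-D
recording (depth frames plus person-segmentation masks) and want
per-frame ankle angles without marker-based motion capture — including at
ranges below 1 m where skeleton trackers and pose estimation stop
working.

## The method

A body mask detected in the colour image is registered onto the depth
image through the camera-overlap model (columns
`x_IR = (x_RGB − 220 − 16)·512/1480`, rows `y_IR = 21 + 382·y_RGB/1080`
for the reference device), cleaned by a depth window
`[d̄ − 700, d̄ + 300]` mm around the mean body distance, and restricted to
the lower leg. Along the scan column crossing the leg, the depth profile
is lifted to world millimetres (`x = x′·z·tan 35°/256`,
`y = y′·z·tan 30.1°/212`), Savitzky–Golay smoothed, and rotated about the
foot end by `β = atan2(d_L − d_F, h_L − h_F)` so both ends share one
depth; the deepest point of the rotated curve is the ankle. A
least-squares line through the foot part and one through the leg part
meet at the interior angle `α` — the ankle angle.

The gold standard combines two Euler-pitch streams (leg and foot IMU) as
`θ = 180 − α_leg + β_foot`, after replacing the host-distorted
timestamps with the nominal 100 Hz grid (N samples must span
`(N−1)/100` s). Agreement between methods is summarized by Pearson's r
and Spearman's ρ with Fisher-Z confidence intervals
(`atanh r ± z_{α/2}/√(n−3)`, mapped back with tanh), RMSE and MAE; the
depth-accuracy law `δz = 0.013 z + 0.0253` is propagated to a per-frame
angle uncertainty via `δα = |dα/dz|·δz`.

See `vignettes/projection-line-method.Rmd` for the full model, the
parameter defaults and the design rationale.

## Worked example

A two-second synthetic knee bend at 2 m (ankle angle 90° ± 15°), 5 mm
depth noise, measured by the projection line and scored against the
clock-corrected IMU standard:

```r
library(ankleproj)

spec <- scene_spec(distance_mm = 2000,
                   ankle_angle_deg = function(t) 90 + 15 * sin(pi * t),
                   duration_s = 2, depth_noise_sigma_mm = 5,
                   clock_distortion = list(c = 0.3, k = 500), seed = 1)
scene <- render_scene(spec)

kinect <- profile_angle_series(scene$frames, scene$masks, f = 0.55)
head(as.data.frame(kinect), 3)
#>   timestamp_s angle_deg sigma_deg         method
#> 1  0.00000000  90.83851 0.2123196 projected_line
#> 2  0.03333333  90.49110 0.2207715 projected_line
#> 3  0.06666667  95.79326 0.2139184 projected_line

imus <- synth_imu(scene$truth, spec)
gold <- imu_ankle_angle(correct_clock(imus$leg), correct_clock(imus$foot))
agreement_report(kinect, gold)
#> agreement over 60 pairs (lag 0.000 s):
#>   Pearson r  0.912 (0.857, 0.947)
#>   Spearman   0.916 (0.863, 0.949)
#>   RMSE 4.46 deg, MAE 3.57 deg
```

Each row of the angle series is one video frame: the measured angle and
its propagated depth-error band. The report says the projection line
tracks the reference trajectory (r = 0.91 despite 5 mm of per-pixel
noise) with under 5° RMS disagreement, and that no residual clock lag was
detected between the devices.

The same pipeline is scriptable from a shell via the installed CLI
(`inst/cli/ankleproj`): `simulate`, `angles`, `imu`, `compare`, and
`demo`, which chains all four on a synthetic scene, e.g.

```sh
Rscript inst/cli/ankleproj demo --out_dir /tmp/run --distance_m 2 --angle_deg 90 --seed 1
```

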