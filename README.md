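# platescale

Marker-free dining plate size estimation from egocentric image
sequences.

Passive dietary assessment with a chest-worn camera needs a metric
scale reference in every image — traditionally a checkerboard fiducial
card placed on the table before each meal, which undermines the whole
point of a passive system. `platescale` eliminates the card for people
who eat at fixed locations: after a **one-time calibration meal** with a
circular plate of known radius, the package estimates the radius of any
later circular plate directly from the sequence of ellipses it traces
in the images, and that radius then serves as the scale reference for
everything on the table.

## Method in brief

A plate of radius *R* images as an ellipse with center (*x*, *y*),
semi-axes *a* ≥ *b* and orientation *θ* (mm on the sensor).
Back-projecting the ellipse through the optical center gives a cone;
cutting it with a plane in a circle of radius *R* recovers the
camera-to-plate distance

> *D* = *g*(*x*, *y*, *a*, *b*, *θ*, *R*),

exact but scale-ambiguous: doubling *R* doubles *D*. The ambiguity is
broken statistically. During eating the torso moves quasiperiodically,
but the *range* of *D* at a fixed dining location is stable from meal
to meal. Calibration measures that range [*D*<sub>l</sub>,
*D*<sub>u</sub>] (with a sparse-extreme-bin histogram trim). For an
unknown plate, each candidate radius *R*<sub>t</sub> (30–165 mm, 1 mm
steps) yields a pool of distances — from the exact inversion and from a
per-radius linear model *D* ≈ *m*/*a* + *n* fit to simulations of the
simplified relationship 1/*a* = (1/*f*)·√((*D*/*R*)² − cos²*γ*) over
the tilt band *γ* ∈ 20–70° — and the inclusion index

> *P*(*R*<sub>t</sub>) = |{*D*<sub>i</sub> ∈ [*D*<sub>l</sub>, *D*<sub>u</sub>]}| / |{*D*<sub>i</sub>}|

peaks near the true radius. A Gaussian fit of the *P* curve gives the
estimate as its mean. Cross-estimation over *M* plates (each one
calibrating in turn, *M*(*M*−1) estimates) is summarized by mPE, maPE
and mrRMSE of the percentage errors.

## Worked example

```r
library(platescale)
cam <- camera_intrinsics(focal_length_mm = 3, pixel_pitch_mm = 0.003,
                         principal_point_px = c(640, 480),
                         image_size_px = c(1280, 960))

# one-time calibration meal with a measured 100 mm plate
cal  <- generate_episode(episode_config(true_radius = 100, seed = 1), cam)
prof <- calibrate(cal$observations, cam, R_ref = 100)
prof
#> Calibration profile: R_ref = 100 mm, D range [332.8, 582.8] mm from 60 frames (10 bins)

# later meal with an unknown plate (ground truth: 120 mm)
tab <- build_line_table(cam$focal_length_mm,
                        distance_band_mm = table_band_for_profile(prof),
                        seed = 2)
unk <- generate_episode(episode_config(true_radius = 120, seed = 3), cam)
est <- estimate_radius(unk$observations, cam, prof, tab)
est
#> Estimated plate radius: 123.3 mm (Gaussian mean 123.27, sd 29.58, amplitude 0.851)
#>   60 frames used, 0 outliers removed
```

The calibrated range says this person's camera sat 333–583 mm from the
plate center during the reference meal; the unknown plate's ellipse
sizes are most consistent with that range at a radius of 123 mm, a
2.7% error against the true 120 mm. `plot(est)` shows the *P* curve
and its fitted Gaussian.

A command-line interface wrapping the same functions is installed at
`exec/platescale` (subcommands `calibrate`, `lines`, `estimate`,
`simulate`, `evaluate`, `fit-ellipse`; run it with `Rscript`).

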