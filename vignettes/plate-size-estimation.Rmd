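---
title: "Estimating dining plate size from egocentric ellipse sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dining plate size from egocentric ellipse sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platescale)
```

## The problem

Passive, image-based dietary assessment records a person's meals with a
chest-worn camera and estimates food amounts from the pictures.  Every
such estimate needs a metric scale reference inside the image — the role
a checkerboard fiducial card normally plays.  Carrying and placing a
card before every meal defeats the purpose of a passive system.

`platescale` removes the card.  Its premise is behavioral: most people
eat at a small number of fixed locations, with fixed table and chair
heights and the camera worn at the same spot on the chest.  Under those
conditions the camera-to-plate distance during a meal, although it
fluctuates quasiperiodically as the person leans in to fetch food, stays
within a *stable statistical range* from meal to meal.  One calibration
meal with a circular plate of known radius measures that range; the
radius of any later circular plate at the same location is then the
value that best maps its observed image-ellipse sizes back into the
calibrated range.

## Geometry

A circular plate of radius $R$ (mm) images as an ellipse with center
$(x, y)$, semi-axes $a \ge b$ and orientation $\theta$, all measured in
millimeters on the sensor plane.  Back-projecting the image ellipse
through the optical center yields an elliptic cone; planes cutting that
cone in a circle recover the plate's pose, and scaling the cut so the
circle radius equals a candidate $R$ gives the camera-to-plate distance

$$D = g(x, y, a, b, \theta, R).$$

`distance_from_ellipse()` implements $g$ exactly: it eigen-decomposes
the cone's quadric, enumerates the (up to two) circular-section
orientations in closed form, and scales each to the candidate radius.
The two sections are mirror images under a symmetry plane of the cone,
so *both give the same distance*; the ambiguity affects only the
reported plane orientation, which is resolved by requiring the implied
tilt to fall in a configurable band (default 10–80°, a chest camera
looking down at a table) and, if both qualify, by the smaller
reprojection residual.  When the two transverse eigenvalues coincide
(plate seen frontally, a circular cone) the one-parameter family of cuts
collapses to the pinhole relation $D = fR/a$, which is used directly.
Distance is exactly homogeneous in the candidate radius: doubling $R$
doubles $D$.  This is the single-image scale ambiguity that makes
radius estimation from one frame impossible — and it is precisely what
the calibrated distance range later disambiguates.

With the optical axis through the plate center and the camera level but
tilted down by $\gamma$, the exact model simplifies to

$$\frac{1}{a} = \frac{1}{f}\sqrt{\left(\frac{D}{R}\right)^2 - \cos^2\gamma},$$

with $f$ the focal length in mm (`simplified_inverse_a()`).  The package
cross-checks this closed form against the exact projection to $10^{-9}$
relative over the whole operating envelope; the forward projection
itself (`project_circle()`) is computed in closed form through the
plane-to-image homography, never by point sampling.

## From curves to lines

Because $\gamma$ varies during eating, the $1/a$–$D$ relationship is a
band of curves.  Sampling $\gamma \sim U(20^\circ, 70^\circ)$ and
$D$ uniformly over a working band, then least-squares fitting
$D \approx m\,(1/a) + n$, gives one line per candidate radius
(`fit_line()`, `build_line_table()`).  The default table covers radii
30–165 mm in 1 mm steps (136 lines).  Over the default distance band
(250–800 mm) every line's RMS relative residual is about 2%, which is
what justifies replacing the curve family by lines.  Slopes increase
strictly with the radius: a larger plate produces the same image size
only when it is proportionally farther away.

Choices the underlying description leaves open, fixed here once:

* **Distance band for the simulation.**  Not stated; default
  $U(250, 800)$ mm, and when a calibration profile exists the band
  becomes $[0.8\,D_l,\ 1.2\,D_u]$ (`table_band_for_profile()`), so lines
  are fit over the regime in which they are evaluated.
* **Pairs per radius $N$.**  Not stated; default 2000, which stabilizes
  $m, n$ to below 0.5% run-to-run and keeps the whole 136-line table
  under a few seconds.  Each radius draws an independent sub-seed, so
  the table is reproducible bit-for-bit from one seed.

## Calibration

`calibrate()` runs the exact solver over the known-radius sequence and
extracts the range $[D_l, D_u]$ with a histogram rule: build an
equal-width histogram (default 10 bins), and in a *single pass* drop the
members of the lowest and/or highest bin if that bin's count is below
half of the average frequency; the surviving minimum and maximum become
the range.  Ten bins keeps the average frequency meaningful for typical
episodes of fewer than 100 frames.  The rule is deliberately not
iterated: re-binning survivors of heavy-tailed data could trim again,
and the single pass is what keeps at least half of the data by
construction.  When both extreme bins jointly hold most of the data the
rule is ill-posed; the package applies it literally and the trim-failure
error surfaces the pathology rather than guessing.

## Estimating an unknown plate

For a new sequence and each candidate radius $R_t$ on the grid, two
distance sets are pooled (doubling the data): the line prediction
$D^1_i = m/a_i + n$ and the exact solution $D^2_i$ of the cone
inversion at $R_t$.  The inclusion index

$$P(R_t) = \frac{\left|\{D_i \in [D_l, D_u]\}\right|}{\left|\{D_i\}\right|}$$

is the fraction of pooled distances inside the calibrated range (closed
interval — the bounds are themselves data values).  $P$ rises to a peak
near the true radius and decays on both sides; `fit_gaussian_peak()`
fits $A\exp(-(R_t-\mu)^2/2\sigma^2)$ by Levenberg–Marquardt and the
estimated radius is $\mu$, clamped to the grid extent (extrapolating
beyond the simulated lines is unsupported, and a clamped estimate
carries a warning).  No baseline term is used by default because the
curve decays to zero away from the peak; a constant-offset variant is
available.  The fit is initialized at the argmax with the half-maximum
width; because the pooled distances are a finite multiset, $P$ is a step
function and ties at the maximum are common — a *contiguous* plateau
initializes at its center, while non-contiguous equal maxima (genuine
multimodality) emit a warning and converge in the initializer's basin.
Internally the exact distances are computed once at unit radius and
scaled per candidate (the solver is exactly homogeneous in $R$), which
turns 136 × frames cone inversions into just one per frame.

Before any of this, `filter_outliers()` drops non-eating frames: a
frame is flagged when both its incoming and outgoing frame-to-frame
center displacement (or folded orientation change) exceed a robust
threshold, median + 4·MAD with absolute floors.  The floors (0.2 mm
center, 5° angle) guard the degenerate MAD = 0 case of a perfectly
steady sequence; 0.2 mm is about 5% of the default sensor width, small
relative to any genuine teleport of the plate in the frame yet far
above per-frame tracking jitter.

## The synthetic episode generator

No recordings accompany the method, so the package ships a
ground-truthed simulator (`generate_episode()`, `generate_study()`)
that defines the study conditions for all tests:

* distance: $D(t) = 450 + 120\sin(2\pi t/12) + \varepsilon(t)$ mm, with
  $\varepsilon$ a stationary AR(1) jitter (sd 15 mm, coefficient 0.8) —
  a lean-in cycle of roughly a minute at one image every 4–6 s, and
  enough irregularity that the motion is quasiperiodic rather than
  periodic;
* tilt: AR(1) drift around the middle of the 20–70° band, clipped to
  the band;
* 60 frames per episode (a 4–6 min capture at the device's frame
  interval);
* exact projection of the plate pose, then optional multiplicative
  noise on the semi-axes, center noise proportional to $a$ (additive —
  multiplicative center noise would be degenerate for the default
  on-axis pose family whose centers sit near the principal point), and
  outlier frames with teleported centers and random orientations;
* the default pose family keeps the optical axis through the plate
  center (so the simplified model holds exactly and estimator error can
  be separated from model error); `off_axis_deg > 0` shifts the plate
  laterally to stress the full cone-inversion path.

What the generator does **not** emulate: correlated ellipse-extraction
errors (occlusion by food, shadowing), partial plates at the image
border, lens distortion, or real biomechanics.  Passing tests therefore
demonstrate the estimator's correctness and its noise robustness under
this motion model, not performance on real recordings — on real data
the published experience is roughly a 10% mean absolute error, and
nothing here should be read as improving on that.

## Numerical choices

* Conic matrices are normalized to $Q_{33} = -1$ when that entry is
  nonzero (unit Frobenius norm otherwise), which keeps the
  geometric/conic round trip stable to $10^{-10}$.
* Transverse cone eigenvalues closer than $10^{-9}$ relative are
  treated as the frontal-view degenerate case.
* The ellipse fit from boundary points (`fit_ellipse_points()`) is the
  numerically stable partitioned form of the ellipse-constrained direct
  least-squares conic fit: the constraint $4AC - B^2 > 0$ is built into
  a 3×3 eigenproblem, so a hyperbola can never be returned even from
  noisy or partial arcs.  Points are centered and scaled before
  fitting, which also makes the fit exactly equivariant under rigid
  motions.  It is exact for points on an ellipse (five suffice) and,
  at 0.5% boundary noise with 100 points, recovers the semimajor axis
  to about 0.1% on average.

## Evaluation design

`cross_estimate_matrix()` reproduces the leave-one-plate-as-reference
design: each episode calibrates in turn and every other plate is
estimated, giving $M(M-1)$ estimates summarized by

$$\mathrm{mPE} = \overline{PE}, \qquad
  \mathrm{maPE} = \overline{|PE|}, \qquad
  \mathrm{mrRMSE} = \sqrt{\overline{PE^2}}, \qquad
  PE = \frac{R_{k,j} - R_j}{R_j}.$$

These obey $\mathrm{mrRMSE} \ge \mathrm{maPE} \ge |\mathrm{mPE}|$ (power
mean and triangle inequalities), which the tests assert on every
generated report.  Line tables are cached by configuration because they
depend on the candidate grid and bands, not on which plate calibrates.

On the default synthetic conditions — five plates of 60–150 mm sharing
one environment template — noise-free cross-estimation lands at a mean
absolute error of 2–4% depending on seed, and adding 1% ellipse noise
plus 5% outlier frames moves it only modestly (the test suite asserts
3% and 12% bounds at its fixed seeds; `scripts/acceptance.R` recomputes
both from scratch).  The dominant error source is not measurement noise
but the sampling variability of each 60-frame episode's realized
distance range — exactly the limitation one expects from a method whose
scale information lives in that range, and the reason longer captures
help more than better ellipse extraction.

## Worked example

```{r example, eval = FALSE}
cam <- camera_intrinsics(focal_length_mm = 3, pixel_pitch_mm = 0.003,
                         principal_point_px = c(640, 480),
                         image_size_px = c(1280, 960))

# calibration meal with a measured 100 mm plate
cal <- generate_episode(episode_config(true_radius = 100, seed = 1), cam)
prof <- calibrate(cal$observations, cam, R_ref = 100)
prof

# later meal, unknown plate (truth: 120 mm)
tab <- build_line_table(cam$focal_length_mm,
                        distance_band_mm = table_band_for_profile(prof),
                        seed = 2)
unk <- generate_episode(episode_config(true_radius = 120, seed = 3), cam)
est <- estimate_radius(unk$observations, cam, prof, tab)
est
plot(est)
```

## Limitations

* One profile per person, location and device position; any change
  requires recalibration.
* Circular plates only (a bowl of known rim radius can stand in, at the
  cost of a rim-height error); plate rim height is ignored throughout.
* Estimates are clamped to the candidate grid (30–165 mm by default);
  plates outside it cannot be recovered.
* The method degrades when the eating session's distance range differs
  from the calibrated one (unusual posture, relocated chair); the
  out-of-calibration-range error only catches gross mismatches.
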