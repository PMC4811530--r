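---
title: "Reconstructing 3D eye rotation vectors from 2D video-oculography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D eye rotation vectors from 2D video-oculography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vog3d)
```

## The measurement problem

A video camera sees the mouse eye as a 2D image: the pupil appears as an
ellipse and a pigmented iris landmark (a "freckle") as a dark blob. A single
landmark only constrains gaze direction (two degrees of freedom); torsion
about the line of sight is invisible without a second landmark. `vog3d`
recovers the full 3D orientation — expressed as a *rotation vector* `r` whose
direction is the rotation axis and whose magnitude is tan(θ/2) of the rotation
angle from a reference position — from the image trajectories of the pupil
center and one iris freckle.

Four geometric assumptions make this well-posed:

1. the eye rotates about a fixed point;
2. the pupil edge is a circle, and the edge and the freckle lie in one plane;
3. the distance from the rotation center to the pupil circle is constant;
4. the camera is orthographic (projection onto a plane perpendicular to the
   camera axis).

The coordinate frame is X toward the camera, Y to the right from the
examiner's view, Z up; angles at all public interfaces are degrees, radians
are internal.

## Geometric calibration

The projected center of eye rotation lies on the extension of the minor axis
of every eccentric pupil ellipse (the circle is foreshortened along the
direction of gaze tilt). During a calibration recording, the eye is swept in a
circle ("swirl") so minor axes of many directions are observed; the center
`(yc, zc)` is the minimizer of the summed squared distances to those lines, a
quadratic objective solved in closed form from its 2×2 normal equations.
`estimate_rotation_center()` refuses near-parallel bundles (condition-number
bound) — a sinusoidal rotation about a single axis, for instance, does not
calibrate.

With the center known, the tilt θ of each frame follows from
cos θ = minor/major, and the image eccentricity r of the pupil center from
sin θ = r/R, giving per-frame radii

\[ R = \frac{r}{\sqrt{1 - (\text{minor}/\text{major})^2}} , \qquad
   R' = \sqrt{R^2 + \left(\frac{a}{b}\cdot\frac{\text{major}}{2}\right)^2}, \]

where `a` and `b` are image distances from the ellipse center to the freckle
and to the pupil edge along the same ray (point *c*, computed by solving the
ellipse quadratic along the ray and taking the root toward the freckle). The
ratio a/b is invariant under foreshortening, which is what makes the in-plane
freckle offset recoverable from a single image. Per-frame radii are averaged
arithmetically (a median option exists for contaminated recordings).

**Eccentricity cutoff.** Near frontal gaze the minor-axis direction and the
radius formula are 0/0. Frames with minor/major > 0.995 are excluded from
center and radius estimation. They remain eligible as the *reference frame* —
the frame whose pupil center is nearest `(yc, zc)`, ties broken by earliest
index — because that frame is by construction the most frontal one.

## Reconstruction and kinematics

Each landmark lifts onto its rotation sphere with the positive (camera-facing)
root, `(sqrt(R^2 - dy^2 - dz^2), dy, dz)`. Radicands negative by at most
`1e-6 * R^2` (measurement noise) are clamped to zero; larger violations raise
an error naming the frame, because silently clamping would hide calibration
drift. Frames with missing landmarks are emitted as explicit gaps and never
interpolated; velocity estimation later splits at gaps and drops segments
shorter than three samples.

The pose matrix solves `M [p_ref f_ref p_ref×f_ref] = [p_cur f_cur p_cur×f_cur]`
exactly, as the product `A_cur A_ref^-1` with the raw (unnormalized) cross
product. For exact rigid input this M is an exact rotation; no
orthogonalization is applied by default, and an optional polar-decomposition
projection is available for noisy landmarks. The rotation vector is
`r = (R32-R23, R13-R31, R21-R12)/(1+trace)`, rejected when `1+trace` falls
below 1e-8 (rotations near 180°, far outside the oculomotor range). Angular
velocity uses `omega = 2 (dr/dt + r x dr/dt)/(1+|r|^2)` with central
differences and two-point one-sided stencils at the series endpoints; the
scalar *signed speed* is ‖ω‖ carrying the sign of the yaw (Z) component, so a
single trace encodes rotation direction.

## Image processing

Detection mirrors manual-threshold VOG practice: per-recording gray-value
thresholds and ROIs, set once per recording. Contrast is first stretched
linearly (1st–99th percentile to full range, unrounded, hence idempotent up to
the clamped tails and exactly invariant to affine intensity changes). The left
and right pupil edges are binarized inside separate rectangular ROIs with
*separate thresholds*: an off-axis infrared source leaves one side of the
pupil brighter, and a single threshold biases one edge. Within each ROI the
largest dark component is kept, and its boundary is localized at subpixel
threshold crossings (linear interpolation between the straddling pixel
centers); pixel pairs leaving the ROI are skipped so the artificial cut where
the ROI crops the pupil contributes no points. The pooled edge points are
fitted with the direct least-squares conic constrained to an ellipse
(Fitzgibbon's method in the numerically stable block form, on centered and
scaled coordinates).

The freckle is searched in an annulus that follows the ellipse's curvature at
a configured distance beyond its edge; components with area inside a
configured range are accepted and the largest one's *binary* centroid is
returned. Turntable markers are the two largest bright blobs; their
*intensity-weighted* centers of gravity define a line whose direction is the
table angle modulo 180°, disambiguated by continuity (unwrapping) and zeroed
at the first valid frame.

## VOR analysis

The table angle is differentiated with the same central-difference scheme as
the eye, fitted with `v*sin(2*pi*f*t + p)` with `f` free (linear quadrature
fit inside a 1D search bracketed by the periodogram peak and refined by
Brent's method), and the signed eye speed is then fitted *at the table
frequency* — the estimated, not nominal, stimulus frequency (a hand-driven
turntable does not hold its metronome rate exactly). Gain is the amplitude
ratio; phase is `p_e - (p_t - pi)` wrapped to (−π, π], positive when the eye
leads the ideal compensatory (anti-phase) response. There is no DC term in the
model by default. Degenerate (constant) signals return a flagged fit with zero
amplitude.

**Noise and the optional low-pass.** Differencing at 240 Hz multiplies
landmark noise by the sampling rate: 0.5 px of landmark noise becomes on the
order of 100°/s of velocity noise per component, and the signed-norm transform
*rectifies* the torsional and vertical components into a large positive
amplitude bias. `signed_eye_speed()` and `vor_analysis()` therefore accept
`lowpass_hz`: a second-order Butterworth applied forward and backward
(zero-phase) with reflection padding, applied *identically* to the table angle
and to the rotation-vector components. Because both streams pass the same
filter, its pass-band attenuation cancels in the gain ratio, and zero-phase
filtering adds no phase error. A cutoff of twice the stimulus frequency works
well; the default remains no filtering, which is exact for noise-free data.

## The simulator

The forward model generates the study conditions used throughout the tests:
an eye with pupil-center radius R = 40 px, pupil radius 15 px, and a freckle
22 px from the pupil center in the pupil plane (so R′ = √(40² + 22²) ≈ 45.65
px), imaged orthographically at 240 Hz. Motions are explicit angle lists
about a unit axis (the supplementary scenario: −30°…+30° in 1° steps about
(1,2,3)/√14), sinusoids, or calibration swirls (gaze sweeping a cone of
half-angle 15°, three turns, 720 frames — about the count a real calibration
uses per turn at 240 Hz). Every projected frame satisfies the foreshortening
relations exactly by construction, which is what makes 1e-9-level round-trip
assertions meaningful. Landmark noise is additive Gaussian, seeded. The
renderer draws the projected geometry with anti-aliased (linearly ramped)
edges on a background with a linear left-right illumination gradient,
emulating the brightness asymmetry that motivates per-side pupil thresholds;
rendered turntable frames carry two bright disks.

What the simulator does *not* emulate: eyelid occlusion, corneal reflections,
iris texture, pupil-size change, perspective distortion, motion blur, or
quick phases/saccades (the analysis assumes none, as holds for rotated mice).
Passing tests therefore validate the geometry and estimation chain, not
robustness to those artifacts.

## Numerical choices and problem sizes

- Condition-number bound 1e8 on landmark triads and minor-axis normal
  matrices; violations raise degeneracy errors rather than returning garbage.
- Lift clamping tolerance 1e-6·R²; trace guard 1e-8; eccentricity cutoff
  0.995.
- Free-frequency fits refine to `tol = 1e-12` (Brent), recovering a noise-free
  frequency to ~1e-9 Hz.
- Test problem sizes: 1000 random rotations for matrix↔vector round trips
  (1e-12), 720-frame swirls for calibration (1e-9), 100 rendered poses for
  ellipse recovery (≤0.5 px center, ≤1% axes, ≤1° orientation), 10-s
  recordings for noise-free VOR recovery (gain ±1%, phase ±0.5°) and 60-s
  recordings for the σ = 0.5 px stochastic case (±5%, ±2°) — the longer
  stochastic recording follows from the quadrature noise floor of the fit,
  which shrinks as 1/√N, sized before the tolerance was tested.
- The orientation tolerance applies to poses tilted ≥ 8° from frontal;
  orientation is intrinsically ill-conditioned as the ellipse approaches a
  circle, which is the same reason the eccentricity cutoff exists.

## Known limitations

- Thresholds and ROIs are per-recording manual settings (as in practice); no
  automatic threshold selection.
- The reference position is whatever frame is most frontal in the calibration
  recording; if the calibration never passes near frontal gaze, all rotation
  vectors are expressed relative to that slightly tilted reference. Angular
  velocity — and therefore VOR gain and phase — is invariant to this constant
  offset.
- Gain/phase analysis assumes a single dominant sinusoid; there is no
  multi-frequency decomposition and no quick-phase removal.
- A dilated pupil defeats the method twice over: partial edges bias the
  ellipse fit, and the freckle becomes invisible, removing the torsion
  constraint. The pipeline reports gaps rather than guessing.
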