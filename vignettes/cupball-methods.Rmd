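---
title: "Models and methods behind cupball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cupball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupball)
```

This vignette documents the models, numerical choices and design
decisions of the package — what is computed, under which assumptions,
and where the defaults come from. Empirical claims below are the ones
the test suite and `scripts/acceptance.R` compute; nothing is asserted
that the code does not measure.

## The measurement chain

The package analyses a tabletop motor task: a person slides a cup
across a rectangular whiteboard (long side along x), possibly with a
steel ball rolling in the cup's spherical dish, while a fixed overhead
RGB camera records the board. All downstream quantities — reach times,
tracing errors, ball-escape margins — are functions of the cup and ball
positions in board coordinates, so the chain is: register the camera
against the board, track the objects per frame, map to millimetres,
then compute metrics and (optionally) model-based ball state.

## Registration

The camera-to-board relation is a planar homography: the board is flat
and the camera fixed, so pixel coordinates map to board millimetres by
a 3×3 projective transform. `fit_planar_map()` estimates it from
matched point pairs with the normalized direct linear transform,
solved as an overdetermined least-squares problem via SVD. The
canonical protocol supplies five pairs — the four corners of the field
of view and the crossing of the diagonals — which overdetermines the 8
degrees of freedom and gives a residual that doubles as a registration
quality check. Degenerate configurations (collinear or coincident
points) are detected from the second-smallest singular value of the
design matrix.

Conventions: the board origin is the corner nearest the image origin,
x along the long side, y along the short side increasing downward in
the registered view, units mm. Pixel pitch is never hard-coded: it is
always derived from the fitted map (`mm_per_pixel()`), because the
nominal "board width / image width" figure is ambiguous for anisotropic
pixels and mildly perspective views.

Drawn **targets** are detected with a circular Hough transform on the
boundary pixels of an "ink" mask (pixels whose colour departs from the
per-channel median of the frame, the estimated board colour). The
radius search range (default 40–120 mm), accumulator bin (2 px) and
acceptance score (45% of a full outline's votes) are configurable;
accepted peaks are refined by an algebraic (Kåsa) circle fit of nearby
boundary pixels *in board coordinates*, so the reported centre and
radius are unbiased by perspective. Duplicates closer than half a
radius merge; circles return ordered by area. **Obstacles** are
connected components whose boundary, simplified by
Ramer–Douglas–Peucker at 2% of the perimeter, leaves between 3 and 8
vertices; components whose boundary fits a circle to better than 4%
radial spread are classified as targets, not obstacles. Morphological
opening is deliberately *not* applied before polygon extraction — a
5×5 opening rounds corners by 2–3 px (~4 mm), which was the dominant
vertex error in early testing; speckle is instead rejected by the
component area threshold.

## Colour tracking

Per frame: RGB→HSV (hexcone formula, hue in degrees 0–360 internally —
byte-dialect hue scales are an I/O concern), an HSV window mask per
object with hue-wrap support, a 5×5 morphological opening, connected
components, and an ellipse (moment) fit of the component maximizing a
circularity-weighted area score, `area × (minor/major)²`, with ties
broken by area then by boundary fit residual. The default opening is
one erosion + one dilation: a true opening is idempotent, which the
pipeline's invariant tests rely on, whereas an extra dilation grows
every blob by a one-pixel ring per application (about 25% of the ball
blob's area) and is therefore not a sensible default; iteration counts
remain configurable for noisy real footage.

The ball is searched first inside a window of twice the cup radius
around the detected cup — the ball cannot leave the dish without
escaping, and this also prevents green clutter elsewhere on the board
from stealing the detection — with a full-frame fallback.

Implementation notes: morphology is computed with summed-area tables
(erosion = "window count equals kernel area", dilation = "window count
positive"), which matches EBImage's `erode`/`dilate` exactly on box
kernels (a test asserts this) at a fraction of the cost; detection runs
coarse-to-fine (a stride-4 subsampled mask proposes a region of
interest, full resolution runs inside it, whole-frame when the coarse
pass finds nothing), which preserves the full-frame semantics while
keeping per-frame cost near 50 ms in pure R.

Measured on the synthetic renderer (the acceptance script recomputes
these): cup-centre error stays below 0.5 px on noiseless frames and
below 2 px median under per-channel Gaussian pixel noise of σ = 5/255,
across 200 random placements.

## The cup-and-ball model

The ball rolling in the spherical dish is modelled as a spherical
pendulum of length `l` suspended from a planar cart (the cup) of mass
`m_c` driven by a horizontal force. `l` defaults to the dish radius of
curvature minus the ball radius (70 − 12.7 = 57.3 mm for the reference
cup; 1-inch steel ball). With generalized coordinates
`q = (x_c, y_c, θ, φ)` — `θ` the polar angle from the downward
vertical, `φ` the azimuth from +x — the bob sits at
`x_b = x_c + l sinθ cosφ`, `y_b = y_c + l sinθ sinφ`, `z_b = −l cosθ`.

Rather than expanding Christoffel symbols, the implementation uses the
identity that for kinetic energies of the form `T = q̇ᵀM(q)q̇/2` with
`M = const + m_b JᵀJ` (J the bob-position Jacobian), the
Euler–Lagrange equations reduce to

```
M(q) q̈ = Q − ∇V − m_b Jᵀ (J̇ q̇),
```

a 4×4 linear solve per evaluation with `J̇q̇` available in closed form.
This form is validated four independent ways: against a separately
derived textbook planar cart-pendulum (agreement < 1e-14 per
derivative call), by energy and horizontal-momentum conservation of
unforced undamped runs (drift < 1e-9 relative over 10 s at dt = 1 ms
for release-from-rest initial conditions), by azimuthal equivariance
(rotating initial azimuth and force rotates the solution, < 1e-9), and
against `deSolve::lsoda` at tight tolerances. Optional viscous damping
adds generalized torques `−c·θ̇` and `−c·sin²θ·φ̇`; an optional 7/5
factor on the bob's effective inertia models a rolling solid sphere
(off by default — the reference model is a point bob). Magnet
attraction and table friction are not modelled; the cart is driven
only by the supplied force or prescribed motion.

**Coordinate singularity.** The azimuthal equation divides by `sin²θ`;
near a planar zero crossing, conservation of the vertical angular
momentum forces `φ̇ ∝ 1/sin²θ`, whose local growth rate `2 cotθ·θ̇`
exceeds any explicit integrator's stability region. Whenever
`|sinθ| < 0.01` the φ equation is frozen (φ̇ held, φ̈ = 0) for that
evaluation. The threshold is chosen so the rate stays inside RK4's
stability limit at millisecond steps; the angular momenta it suppresses
correspond to |θ| < 0.6°, far below anything the tracker can resolve.
A much smaller threshold (we tried 1e-8) lets numerically acquired
azimuthal momentum amplify without bound through each crossing and
destroys energy conservation. As a side effect of the planar chart, θ
may go negative (deflection at azimuth φ + π); all escape logic
therefore uses |θ|.

**Integration.** `simulate_forced()` uses fixed-step classical RK4
(halving dt shrinks endpoint error ~16×, as a test verifies). The
first sample with |θ| ≥ θ_esc is flagged as the ball escape; by
default the angular states freeze there (the dish no longer constrains
the ball, and the frozen angle preserves the escape geometry for
rendering), or integration can continue. `simulate_kinematic()`
integrates only the pendulum block with the cart acceleration
prescribed by central differences of a measured (filtered) cup
trajectory; because video-rate sampling (20–80 fps) is far too coarse
for a pendulum with a 0.48 s period, each sample interval is
sub-stepped internally at 1 ms with linear interpolation of the
acceleration. Gaps larger than 3 sampling intervals are an error, not
silently bridged.

**Escape geometry.** A spherical-cap dish of curvature radius R and
aperture radius a has rim angle `asin(a/R)`: a 70 mm dish with a 40°
rim has a = 45 mm, and the same aperture on a 140 mm dish gives
`asin(45/140) = 18.75°`, i.e. 19° after rounding — flatter dishes make
the task harder by shrinking the escape angle. The **safety margin**
of a trial is defined here as `θ_esc − |θ(t)|`, with the minimum over
the trial as the summary; a non-positive minimum means escape. (The
literature contains energy-based margins as well; the angular margin is
this package's definition and is labelled as such.)

## Task metrics

- **Filtering**: zero-phase (forward–backward) Butterworth, default
  6th order, 6 Hz cutoff — the standard kinematics setting. The double
  pass squares the magnitude response and cancels phase, so symmetric
  pulses keep their peak sample. Reflective padding absorbs the
  end transients of `signal::filtfilt`; tests that assert linearity
  properties compare away from the series ends.
- **Reach time**: time from go cue to the first sample at which the
  cup centre lies in the *closed* target disc (the protocol counts
  "centre in the circle" as reached). Success additionally requires
  the ball not to have escaped before entry (levels ≥ 2). Never
  entering is a failure result, not an error. Delaying the go cue by Δ
  (still before entry) shortens the reach time by exactly Δ.
- **Figure-eight error**: distance to the nearest point of the union
  of the two 25 cm template circle outlines — available in closed form
  as `| ‖p − c_i‖ − r |` minimized over the two circles — with RMS over
  the trial. Trajectories generated on the template have RMS 0 to
  machine precision.
- **Path variability** (no standard formula exists; this is the
  package's definition, documented as such): each path resampled to 50
  arc-length stations; variability = mean over stations of the mean
  distance to the station centroid. Identical paths give 0, two
  parallel paths offset by d give d/2, and the measure is invariant to
  rigid motions.
- **Trial segmentation**: trials start at go cues and end at the next
  cue or series end; point-to-point trials alternate
  outward/inward.

## Verification pipeline

Two recordings of one movement, from devices with independent clocks
and coordinate frames, are compared by: zero-phase filtering,
resampling each onto a uniform grid (linear interpolation), estimating
the clock offset as the difference of the global speed-peak sample
indices (sub-sample parabolic refinement exists but is off by default —
sample-resolution alignment is the reference behaviour), restricting to
the post-sync overlap, and Procrustes alignment: the closed-form
least-squares similarity transform from the SVD of the cross-covariance
matrix, reflection excluded unless requested. Both time axes are
re-zeroed before synchronization — absolute timestamps from two
unsynchronized devices must not participate in alignment.

The error is reported as the **mean Euclidean point error in mm**
(field convention for this verification, despite often being called
"MSE"); the RMS variant is reported alongside, as are per-axis Pearson
correlations next to the primary 2-D (flattened-array) correlation R.
Velocity-peak synchronization presumes a movement with one dominant
speed maximum (spirals, single reaches); on repetitive multi-reach
recordings the global peak is ambiguous between near-identical trials
and the alignment may lock onto a neighbouring repetition.

Since reference optical-mocap recordings are not publicly available,
the package's end-to-end accuracy claim is property-based: nine spiral
sessions (~310 mm arc each, ~2.8 m combined) rendered across the board
at 640×480, tracked, and aligned against ground truth must each stay
within 1.5 mm mean point error with R ≥ 0.999. Measured values are
around 0.08 mm and R > 0.9999 — the renderer omits several error
sources of real footage (below), so this validates the software chain,
not the physical camera.

## The synthetic scene generator

The renderer is the package's ground-truth instrument: filled discs
(targets, cup, ball — ball drawn last, on top) and polygons are
projected through the registration map and anti-aliased by 4×4
subsampling *in board coordinates* (each subsample is mapped through
the inverse homography and tested against the disc in mm), so the
rendered coverage is the true projected shape even under perspective.
Centroid bias from aliasing stays below 0.1 px. The default scene
mirrors the reference prototype: 914 × 609 mm board imaged at 640×480
through a mild fixed perspective (corner displacements ≤ 2% of image
width), 140 mm targets 52 cm apart placed on the board diagonal, orange
cup dish (radius 70 mm), green ball (radius 12.7 mm), near-white board;
object hues must be pairwise separated by ≥ 20°. Optional per-channel
Gaussian pixel noise; everything downstream of the scene seed is
deterministic (byte-identical frames and tables for a fixed seed).

Trajectory sources: minimum-jerk point-to-point reaches (quintic with
zero boundary velocity/acceleration; peak speed 1.875·d/T), Archimedean
spirals at constant angular rate, figure-eight traversals that lie
exactly on the two-circle template, and model-driven sessions in which
`simulate_kinematic()` infers the ball from the cup profile and the
renderer draws the model's ball position. Default session conditions
follow the task protocol: 30 point-to-point trials (15 outward + 15
inward), one go cue per trial, 14 cm targets 52 cm apart; the default
reach duration (1 s) and inter-trial hold (0.5 s) are a deliberately
brisk "as fast as possible" pace, and the figure-eight default period
(1.66 s) is the comfortable pace reported for neurotypical adults.

What the renderer does *not* emulate — and hence what passing tests do
not show about real data: lens distortion, hands and arms occluding the
cup, shadows and non-uniform lighting, motion blur, rolling-ball visual
offset in the dish, sensor noise correlation, and dropped-frame timing
jitter. Colour profiles that are trivially separable here must be tuned
per camera and lighting for real footage.

## Session I/O and the command line

Sessions are plain CSV in a fixed schema (frame index, timestamp,
per-object found flags, mm and pixel coordinates); missing values are
empty fields, never zeros, and a comment header can carry the absolute
session start time for alignment with external recordings (EMG, neural)
without implementing that alignment. Reading validates field counts and
numeric columns and reports offending line numbers. Registration, task
and model-parameter files are plain YAML. `run_pipeline()` chains
registration → tracking → metrics (→ verification when a reference is
supplied), writes session/results/report files plus a log with
per-stage counts, and aborts naming the failed stage. Frames decoded
always equals samples written plus logged drops — no silent loss.

The `cupball` executable (`inst/exec`) exposes the workflow as
subcommands (`register`, `detect-targets`, `track`, `simulate`,
`margin`, `metrics`, `verify`, `synth`) with exit codes 0 (success),
2 (configuration error), 3 (data error). Video input is a directory of
PNG frames with a `manifest.csv` (or an in-memory frame list in R);
container decoding is out of scope for the R build, which targets the
frame-stream contract.

## Problem sizes used in testing

The default test and acceptance runs use: 9 spiral sessions × 60
frames at 20 fps for the end-to-end verification; 200 random cup
placements per noise condition for tracker accuracy; 10 s at 1 ms
steps for conservation checks; 2000-point series for the jitter
calibration of the alignment error. These sizes make the full suite
run in about two minutes on one CPU while keeping every estimate's
sampling error well inside the asserted tolerances.

## Known limitations

- The tracker assumes exactly one cup-coloured and one ball-coloured
  blob of sufficient size; two similarly coloured objects resolve by
  the circularity-weighted score, not by temporal continuity (no
  Kalman/track association).
- The dynamics model omits rim contact (Level-2 cups), dish friction,
  magnet force and 3-D cup tilt; inferred ball angles are only as good
  as the twice-differentiated cup trajectory, so they depend on the
  filter settings.
- `simulate_forced()` leaves the step size to the caller; dt must
  resolve the pendulum period (defaults in the CLI use 1 ms).
- Velocity-peak synchronization is unreliable for periodic movements
  with several near-equal speed maxima.
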