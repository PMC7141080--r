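---
title: "Monocular gaze estimation: models, corrections and uncertainty maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monocular gaze estimation: models, corrections and uncertainty maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monogaze)
```

## The problem

A head-mounted monocular eye tracker records two synchronized video
streams: an IR-illuminated eye camera (640x480 px) watching the pupil, and
a forward-facing world camera (1920x1080 px) showing the scene.  Gaze
estimation maps the pupil centre, in eye-camera pixels, to the point being
looked at, in world-camera pixels.  The mapping is learned during a brief
calibration in which the user looks at the centre of a printed
concentric-ring marker while either the marker moves (smooth pursuit) or
the head rotates about a fixed marker (vestibulo-ocular calibration).
Both procedures sweep many paired observations — several per frame-pair at
an effective 114 Hz — rather than a handful of static fixation targets.

`monogaze` implements the full pipeline: pupil detection, marker
detection, the quadratic gaze mapping, two residual-based corrections of
the raw estimates, quantitative accuracy metrics, and qualitative
uncertainty visualizations.  A synthetic-session generator with known
ground truth makes every stage testable without recordings.

## Pupil detection and its uncertainty

The pupil is the darkest structure in the IR eye frame (the dark-pupil
regime).  `detect_pupil()` thresholds at the lowest occupied histogram
intensity plus a fixed offset (default +15), closes specular glint holes
with a 5x5 morphological closing, keeps the largest dark connected
component (minimum area 100 px^2), traces its contour, and fits an
ellipse by direct algebraic least squares (the numerically stable
Halir-Flusser formulation).  The reported centre is the ellipse centre,
which degrades more gracefully than the pixel centroid under partial
occlusion.  No corneal reflection is used, so the method tolerates free
head movement but offers no optical slippage compensation — that is what
the corrections below are for.

The detected contour constrains but does not pin down the true centre.
`compute_uncertainty_field()` expresses this with the Euclidean distance
transform: over the pupil's bounding box the field is
$1 - \mathrm{DT}(p)/\max \mathrm{DT}$, i.e. 0 at the deepest interior
point (most plausible centre) rising to 1 on the contour.  The polarity —
0 inside, 1 at the rim — is a convention of this package; for a circular
pupil of radius $R$ the field at radial distance $\rho$ is exactly
$\rho/R$.

## Marker detection

The calibration marker is a thick black ring containing a white ring
which encloses a filled black disk (radii 3:2:1 here; the exact
proportions are a rendering convention) with a small white cross at the
centre.  `detect_marker()` finds dark components whose hole-filled
interior again contains dark content separated by a light ring, and
requires the three centroids (filled outer shape, light ring, filled
inner disk) to agree within 10% of the outer radius.  The innermost-disk
centroid is the measured centre; the cross is neutralized by hole
filling.  Detection is scale- and rotation-invariant by construction, and
a frame with more than one confident candidate raises an
`AmbiguousMarker`-style condition rather than guessing.

## The gaze mapping

With paired observations $(u_i, v_i) \mapsto (x_i, y_i)$, `gaze_fit()`
fits two bivariate second-order polynomial surfaces over the basis

$$(1,\; u,\; v,\; uv,\; u^2,\; v^2),$$

one for $x$ and one for $y$, by SVD least squares (pseudo-inverse of the
design matrix).  Six coefficients per axis means six well-spread pairs
suffice; a rank-deficient geometry (e.g. pupils on a line) is refused
with the deficient basis direction named.  The basis stops at order two
with only the first-order cross term: higher orders interpolate the
calibration points better but extrapolate worse, which is precisely the
failure mode moving-target calibration must avoid.  Pupil coordinates
are standardized (zero mean, unit variance per axis) before the solve —
a pure conditioning measure; predictions are invariant to it, which the
test suite checks directly.

`predict()` flags points outside the calibration pupil bounding box:
outside the calibrated region a quadratic can fold the plane onto itself,
and `project_contour()` detects exactly this signature (a
self-intersecting projected pupil contour).

## Correcting the raw estimates

The fitted mapping reprojects each calibration pupil to an estimated
marker centre; the *residual* $v_i$ = marker − reprojection is known at
every calibration node.  Raw estimates of new gaze points are corrected
by interpolating these residuals.

**IDW.**  Shepard interpolation over all nodes:

$$v_p = \frac{\sum_i v_i \, d_i^{-r}}{\sum_i d_i^{-r}},$$

with $d_i$ the Euclidean distance in world pixels from the query to node
$i$ and $r > 0$ a power chosen arbitrarily; $r = 2$ is the default, the
value found most appropriate for this pipeline.  At $d_i = 0$ the weight
is undefined; this implementation returns the coincident node's vector
(their mean if several coincide), so a node's reprojection is corrected
exactly onto its marker.

**Modified IDW.**  Instead of all nodes, only those recorded within a
time window $T$ (default 200 ms, closed on both sides) of the node
spatially nearest to the query are used:

$$v_s = \{\, e \in v_i : |t_{Np} - t_e| \le T \,\}.$$

Because a calibration sweep visits each location briefly, spatial
neighbours are also temporal neighbours, and the window isolates the
locally coherent part of the residual field — the part produced by slow
drifts and local model mismatch — while excluding distant nodes whose
residuals are unrelated.  As $T$ grows beyond the session span, Modified
IDW reduces exactly to IDW (a subset identity the tests assert to
1e-12).  Ties in the nearest-node search break toward the earlier
timestamp; both tie-break and window closure are package conventions.

## Accuracy metrics

Per-point error is the Euclidean norm between estimated and actual gaze
position in world pixels; `evaluate_session()` converts it to
centimetres through the world-plane scale `px_per_cm` and to degrees of
visual angle through $\theta = \arctan(e_\mathrm{cm}/D)$ at viewing
distance $D$ (default 75 cm).  The Mean Angular Error is the mean of the
per-point degree conversions, and standard deviations are taken over
per-point errors within a session.  The arctangent form reproduces the
paired cm/degree columns of published accuracy tables at 75 cm to print
precision, which the test suite verifies.  Sessions shorter than 6 s
follow the short-time protocol, 6-12 s the long-time protocol, and
longer ones are excluded (`classify_session()`).

## Synthetic sessions: what they emulate

`generate_session()` is first-class, tested code, not a fixture.  It
draws a marker trajectory over the world frame — an inward-then-outward
spiral (the apparent path of a fixed marker under two head rotations), a
rectangular pursuit path, or a static 3x3 grid — samples it at 114 Hz,
and obtains true pupil centres by Newton inversion of a fixed
ground-truth quadratic map.  Observed pupil centres add two error
components:

* **Gaussian pixel noise**, sd `noise_sd_px` (default 1 px, a realistic
  centre-detection jitter; the literature rarely quantifies it);
* **slow drift**, two seeded low-frequency sinusoids of amplitude
  `drift_px` (default 5 px) emulating headset slippage over the session.

The drift is what makes the corrections meaningful: with white noise
alone the quadratic fit is already near-optimal and residual
interpolation could only chase noise.  Real recordings err with exactly
such temporally coherent structure, and the Modified IDW's time window
is designed to capture it.  Marker positions are treated as exact
stimulus ground truth (noise-free), so the session's marker columns
double as the evaluation truth.

Because the generating family equals the fitted family, noiseless
sessions admit exact-recovery tests (evaluation MAE below 1e-6 px).  An
optional projective `distortion` mode places the true relation outside
the quadratic family to exercise model mismatch; it is off by default.
What these synthetic conditions do **not** emulate: saccades and pursuit
lag, blinks and eyelid occlusion, illumination changes, or the
perspective geometry of a real scene camera — so passing tests certify
the algorithms, not field accuracy on human data.

Default problem sizes were chosen at desk scale: 2-10 s sessions
(228-1100 pairs), 640x480 eye frames, and factor-4 downsampled world
rasters.  All are parameters, not limits.

## Uncertainty maps

`uncertainty_map()` accumulates gaze evidence over a downsampled
world-camera raster (default factor 4):

* **Gaussian kernel** — each gaze point deposits a unit-mass isotropic
  Gaussian (sd 20 world px, about 1% of the frame width; the bandwidth
  is a visualization choice).  Total mass equals the sample count, so
  regions compare by dwell.
* **Pupil-polygon kernel** — each pupil contour is projected through the
  fitted mapping and deposits its interior distance-transform kernel
  (1 at the deepest point, 0 at the edge), *unnormalized*: larger or
  more elongated projected pupils spread more mass over more support,
  which is exactly the visual contrast between certain and uncertain
  samples that an isotropic kernel hides.

`bump_render()` relights either map as a height field (central-difference
gradients, Lambertian shading, min-max scaled) to emphasize gradient
structure; a constant map renders flat mid-gray.  `error_map()`
interpolates the residual *norms* by the same IDW machinery over the
whole raster, giving a per-location estimate of mapping error; node
cells carry their own $|v_i|$ by the $d = 0$ rule, and the convex-weight
structure bounds adjacent-cell jumps by $\max |v_i|$.

## Numerical conventions and edge cases

* Coordinates are 0-based, origin at the top-left pixel centre, x
  rightward, y downward; images are matrices with rows indexing y.
* Timestamps are integer milliseconds from session start; the 114 Hz
  grid (8.77 ms steps) remains strictly increasing after rounding.
* Sessions are cleansed by removing rows duplicated in all four
  coordinates at 6-decimal precision — the pupil entry and its marker
  pair leave together — keeping first occurrences; cleansing is
  idempotent.
* The calibration/evaluation split is a seeded uniform draw (default
  fraction 0.5); `round(n * fraction)` pairs calibrate, and at least 6
  are required.
* Rank decisions in `gaze_fit()` use a singular-value tolerance of
  `max(dim) * eps * d_max`; ellipse fits require at least 5 contour
  points; polygons with area below 4 px^2 are degenerate.
* The grid-9 trajectory produces exactly 9 distinct noiseless positions,
  so a cleansed noiseless grid-9 session collapses to 9 pairs — by
  design: duplicate removal treats repeated identical observations as
  redundant.  Use the moving-target trajectories when a cleansed
  noiseless session must retain its pairs.

## A worked example

```{r example, eval = FALSE}
library(monogaze)

s <- generate_session("head-rotation", duration_s = 4.7, seed = 2)
ev <- evaluate_session(s, gaze_config(seed = 2))
ev
#> Gaze evaluation on 267 evaluation points:
#>  method mae_px mae_cm  sd_cm mae_deg sd_deg n_eval reduction_vs_raw_percent
#>     raw 7.3473 0.2939 0.1886  0.2245 0.1441    267                   0.0000
#>     idw 5.3059 0.2122 0.1610  0.1621 0.1230    267                  27.7837
#>    midw 4.5781 0.1831 0.1573  0.1399 0.1202    267                  37.6897
```

Raw error reflects the injected drift plus noise; IDW recovers part of
it and Modified IDW the most, mirroring the ordering that motivates the
method.  The magnitudes are those of the synthetic conditions above, not
of any human recording.

## Known limitations

* Pupil detection assumes the dark-pupil regime (pupil mode at intensity
  <= 100) and a single pupil; it has no eyelid/eyelash model.
* The corrections interpolate residuals; they cannot fix errors outside
  the span of the calibration nodes, and IDW's global weights dilute
  under strong drift.
* Degree conversion assumes a flat target plane orthogonal to the line
  of sight at known distance.
* One marker per frame is assumed; two confident candidates raise an
  error rather than invoking a tracker.
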