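---
title: "From marker trajectories to mouth-expansion power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From marker trajectories to mouth-expansion power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

suctionpower implements the computational chain used in marker-based X-ray
(XROMM-style) studies of suction feeding in fishes: from tracked 3D marker
coordinates and an intra-oral pressure trace to skeletal joint kinematics,
axial-muscle strain, dynamic mouth-cavity volume, and instantaneous
mouth-expansion power. This vignette describes each stage's model and
assumptions, the tunable parameters, the numerical choices, and what the
bundled synthetic-strike generator does and does not emulate.

## The measurement model

A strike is observed as a `trajectory_set`: per-frame 3D positions of named
markers at a fixed video rate (300 frames/s by default), in centimetres.
Three kinds of markers occur:

* **bone markers** implanted in rigid bones (neurocranium, cleithrum, lower
  jaw) and in the trunk (the 6-marker *body plane*, a virtual rigid body
  that serves as the reference frame so cranial motions are measured
  relative to the body);
* **intramuscular markers** forming ordered chains through the epaxial and
  hypaxial muscles (fluoromicrometry);
* **endocast landmarks** on the medial surfaces of the left-side cranial
  skeleton, the midsagittal plane, and the caudal closure plane, which
  together enclose the mouth cavity.

A separate pressure channel records intra-oral pressure at 1000 Hz.

## Rigid-body pose estimation

Each bone's per-frame pose is the orthogonal least-squares (Kabsch/Umeyama,
no scaling) fit of its reference (CT-space) marker coordinates onto the
tracked positions, computed from the cross-covariance SVD with a determinant
correction so a proper rotation (never a reflection) is returned even for
near-planar marker sets. Frames with fewer than 3 usable markers are flagged
missing; collinear reference geometry is rejected. The per-frame RMS
residual is retained so suspect frames can be audited rather than silently
dropped.

Tracking precision is summarized as the mean over intra-bone marker pairs of
the standard deviation of their inter-marker distance: on a truly rigid bone
that distance is constant, so its spread is pure tracking noise. For
isotropic per-coordinate noise of s.d. sigma on both markers the expected
value is close to sigma * sqrt(2); the test suite verifies this against a
Monte-Carlo oracle.

## Filtering

All kinematic signals are low-pass filtered with a 2nd-order Butterworth
applied forward and backward (zero phase, effective 4th order), cutoff 40 Hz
for kinematics and 300 Hz for pressure. These cutoffs are configuration
values (`filters$cutoff_kinematics_hz`, `filters$cutoff_pressure_hz`).
Numerical details:

* Edges are stabilized by odd-reflection padding of about six filter time
  constants, so constants pass through to ~1e-12 and the forward-backward
  transients decay inside the pad.
* Marker coordinates are filtered per axis *before* any distance
  computation (muscle lengths, endocast landmarks). Bone poses are filtered
  as rigid motions: rotations are converted to sign-continuous unit
  quaternions, the four quaternion and three translation components are
  filtered, and quaternions are renormalized. Filtering rotation-matrix
  entries directly would break orthogonality; which representation the
  upstream tracking tools filter is not documented, so this is a
  package-level design choice, stated here.
* Gap policy: interior runs of missing samples of at most 5 frames are
  linearly interpolated before filtering; longer gaps stay missing and
  propagate to everything computed from them. This avoids filter ringing
  across tracking holes.
* `analyze_strike(filter_kinematics = FALSE)` bypasses filtering entirely.
  This is how the zero-noise fixed point of the pipeline is tested: on
  noiseless data the geometric chain (pose fit, joint decomposition,
  lengths, volumes, power) is exact to machine precision, whereas even an
  ideal low-pass filter perturbs a smooth pulse at the 1e-5 level.

## Joint coordinate systems and sign conventions

Joint motion is measured with a duplicated anatomical coordinate system
(ACS): one copy fixed to the proximal body (the body plane), one to the
mobile bone, coinciding at the setup pose. The per-frame relative transform
of the distal copy in the proximal copy's frame is decomposed as intrinsic
z-then-y-then-x rotations plus translations along the proximal axes.

The axis triad is right-handed with +x rostral, +z toward the animal's
right, and +y = z cross x (dorsal). This is the unique assignment under
which "rotation dorsally is positive z" and "translation to the right is
positive z" hold simultaneously: cranial elevation is +rz, cranial
depression and pectoral-girdle retraction are -rz. The middle (y) angle is
returned in [-90, 90] degrees; frames within 1e-3 rad of gimbal lock are
flagged but still reported.

Gape is the Euclidean distance between jaw-tip landmarks animated on the
neurocranium and lower jaw; the frame of its (filtered) global maximum
defines t = 0 for all traces, with ties broken to the earliest frame.
Traces are re-zeroed by subtracting the mean over a pre-strike baseline
window — by default the 0.1 s window ending 0.2 s before peak gape. The
source protocols say only "relative to initial values"; a window mean is
used rather than a single frame because it is robust to single-frame noise,
and both the width and the gap are configurable.

## Muscle strain

Axial muscle length is the distance between successive intramuscular
markers (subregions) and between the first and last marker (whole region).
Whole-region length uses the straight-line distance, not the summed chain;
for a straight chain the two are identical, and a `whole = "chain"` switch
is provided. Strain is expressed relative to the mean initial length L_i —
the mean over strikes of the baseline-window mean length:

* strain [%] = 100 (L_i - L) / L_i, positive = shortening;
* strain rate [L_i/s] = -(dL/dt) / L_i, positive = shortening.

Derivatives are central differences on the already-filtered lengths, with
one-sided differences at the ends and no additional smoothing. Cranial
muscles are measured from bone-attached virtual landmarks at the origin and
insertion of three fibers; whole-muscle length is the per-frame mean of the
three fiber lengths (for tendinous muscles this is muscle-tendon-unit
length, not fiber length). The synthetic sternohyoideus carries both an
intramuscular marker pair and fiber landmarks so the two measurement paths
can be cross-validated against each other.

## Dynamic endocast volume

Mouth volume is the volume of the 3D alpha shape of the endocast landmark
cloud at each frame, doubled under the bilateral-symmetry assumption
(`bilateral_factor = 2`). Alpha semantics follow the "alpha radius"
convention: Delaunay tetrahedra whose circumsphere radius exceeds alpha are
discarded; volume is the sum of kept tetrahedra and the boundary mesh
(faces on exactly one kept tetrahedron, oriented outward) can be exported
per frame as OBJ for visual inspection. The default alpha is 2 in scene
units; the scene unit is centimetres by default and is a configuration key,
because the upstream animation scenes do not document their unit.

The Delaunay tetrahedralization is computed in compiled code by an
incremental Bowyer-Watson construction written for this package. Numerical
robustness choices, all of which are exercised by tests against analytic
hull volumes:

* input is rescaled to the unit box and deterministically jittered (~1e-6
  of the cloud extent) so cospherical/coplanar degeneracies — ubiquitous in
  grid-like landmark sets — break consistently; volumes and circumradii are
  measured on the *original* coordinates, and any valid triangulation of
  the jittered points tiles the same hull, so total volume is unaffected;
* the four bootstrap vertices are treated as points at infinity: predicates
  involving them are evaluated as polynomials in the bootstrap scale and
  decided by the leading coefficient, which makes the finite part of the
  triangulation the true Delaunay tetrahedralization (a finite bootstrap
  tetrahedron of any size distorts near-hull topology);
* in-circumsphere tests use a cached circumcenter with a guard band,
  falling back to a long-double determinant near ties;
* tetrahedra with volume below 1e-12 of the bounding-box volume are
  dropped before the circumradius test.

dV/dt is computed by central differences on the (bilateral) volume series
without extra smoothing, since the landmarks derive from already-filtered
coordinates. Degenerate frames (missing landmarks, coplanar cloud) yield
missing volume samples and are logged.

## Pressure and expansion power

The raw pressure channel (mV) is converted to Pa with the probe
calibration, low-pass filtered at 300 Hz *at its native 1000 Hz rate*, then
re-referenced so the pre-strike ambient mean is 0 Pa (sub-ambient pressure
is negative). Only after filtering is it linearly interpolated onto the
video frame times — filtering after downsampling would alias. The
synchronization offset defaults to 0 (the source recordings verified no
offset between pressure and video) and is configurable.

Instantaneous expansion power is `(-p) * dV/dt` with p in Pa and dV/dt in
m^3/s, so sub-ambient pressure during expansion gives positive watts. The
signed product is kept at every frame rather than zeroing non-sub-ambient
frames: it reduces to the conventional value whenever p <= 0 and preserves
information elsewhere. The peak-power window is all frames with power at
least 0.75 of the maximum; because that set can be non-contiguous, the
contiguous block containing the peak is reported alongside the full mask,
and windowed extrema (peak rotations, strains, shortening velocities during
peak power) use the full mask. Peak power is normalized by hypaxial muscle
mass, summed cranial-muscle mass, body mass (W/kg; dissected unilateral
masses should be doubled before entry) and by the maximum change in mouth
volume (W/cm^3). Per-individual tables report mean and s.e.m. = sd/sqrt(n)
over strikes, with n = 1 groups reported as s.e.m. 0 and flagged.

## The synthetic-strike generator

`simulate_strike()` produces a complete strike with analytically known
truth so every stage has a recovery test without any external data. It
emulates: rigid bones driven by prescribed raised-cosine joint-angle pulses
about the defined ACS axes (elevation 5 deg, retraction 8 deg, jaw
depression 18 deg by default — magnitudes on the scale reported for channel
catfish, where cranial elevation is small and girdle retraction is 6-11
deg); muscle chains whose subregion lengths follow L0(1 - strain/100) with
default peak strains of 4, 8, 6 and 3% (hypaxial) and 0% (epaxial); an
endocast cloud built as a half-ellipsoid shell plus midsagittal wall and
half-depth inner shell (about 290 landmarks) scaled so total volume follows
an analytic V(t) rising 80% above its ~30 cm^3 rest value; a pressure trace
constructed by inverting the power product so that peak expansion power
equals a prescribed target (5 W default, inside the reported 0.07-29.3 W
range) exactly, with a kilopascal-scale sub-ambient pulse; and isotropic
Gaussian marker noise of 0.08 mm, the tracking-precision scale of the
source recordings, plus 1% pressure noise. The same seed reproduces a
bundle bit for bit.

It does **not** emulate: soft tissue (the endocast bounds the skeletal
cavity, so absolute volumes overestimate the anatomical mouth volume in
real data); marker dropout or tracking outliers beyond an optional gap
test; spatial pressure gradients within the mouth (a single probe site);
inertial and drag contributions to power; or deformable bones. Passing
recovery tests therefore demonstrates the correctness of the computational
chain under the stated noise model, not the fidelity of any biological
inference from real recordings.

Two interior points of the generator are worth noting. The inner endocast
shell and filled midsagittal wall exist so that no interior Delaunay
tetrahedron has a circumradius near the default alpha of 2 cm — a purely
surface-sampled convex cloud would be hollowed out by the alpha criterion.
And the sampled half-ellipsoid underestimates the analytic volume by about
2% at the default 200-point shell (an inscribed polyhedron is always
smaller); tests compare against the analytic value with a 3% band rather
than calibrating the cloud to hit it.

## Problem sizes and runtime

The default synthetic strike is 0.8 s at 300 frames/s (241 frames) with
~290 endocast landmarks, chosen so a full noiseless-plus-noisy validation
pass, including per-frame alpha shapes, completes in about a minute on one
core. The endocast stage dominates (~0.1 s per frame); longer recordings
scale linearly.

## Known limitations

* The Euler decomposition is reported through gimbal lock (flagged) rather
  than switching representations; joints approaching |ry| = 90 deg need a
  different axis assignment.
* L_i couples strikes of one individual through the baseline mean; strikes
  lacking a valid pre-strike window are excluded from L_i rather than
  imputed.
* The alpha-shape convention (circumradius threshold) matches the common
  "alpha radius" meaning; tools using the inverse-alpha convention will
  need the parameter translated.
* Power is an estimate bounded below by construction: it excludes inertia
  and drag and uses one pressure site, as in the source protocol.
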