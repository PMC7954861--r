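---
title: "Root morphokinetics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root morphokinetics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkin)
```

`rootkin` analyses 4D (X, Y, Z over time) nucleus-tracking data from growing
plant roots and ships a simulator that generates such data with known ground
truth. This vignette is the package's account of the underlying science: the
models and their assumptions, the parameters that matter, what a green test
does and does not establish, and the numerical choices made where the design
was genuinely open.

## Coordinate and time conventions

Positions are in micrometres in a right-handed frame with the root axis
along +Y pointing shootward and the root tip at the origin. Time is in
hours internally; the frame interval is configured in minutes (default
8.75 min, 40 frames ≈ 6 h, matching typical confocal time-lapse settings
for whole-root imaging).

The analysis frame is **tip-registered**: the tip is held at the origin and
nuclei flow shootward through the field. This is the only frame in which an
elongation-zone axial velocity equal to the growth plateau (~50 µm/h) is
observed directly; in a dish-anchored frame the differentiation zone is
static and the tip advances instead. Published velocity maps that show
elongation-zone nuclei moving steadily at the plateau are implicitly
tip-registered, which is why this is the default. A moving tip trajectory
can be supplied via `tip_position` to reconstruct a lab frame; the choice
matters for interpreting differentiation-zone statistics (see
*Limitations*).

## The simulated root

`simulate_root()` seeds `n_nuclei` (default 1000) uniformly over a cylinder
of radius `root_radius` (50 µm) and length `root_length` (1200 µm) and
advects them with a velocity field composed of three parts:

1. **Axial growth.** `v(y) = v_plateau · plogis((y − y_mid)/width)` with
   plateau 50 µm/h, midpoint 150 µm and width 35 µm. The sigmoid is ~0 at
   the tip and saturates before the elongation zone begins (250 µm), so the
   time-averaged elongation-zone axial velocity is within 2% of the
   plateau. Zone boundaries (meristem end 250 µm, elongation end 700 µm)
   are configuration, not biology: real roots do not expose sharp
   boundaries, and published maps do not state theirs.
2. **Meristem skewing.** Nuclei within `meristem_extent` of the tip
   additionally rotate rigidly at `omega` (rad/h) about an axis tilted
   `axis_tilt` = 10° from the root axis, with a smooth roll-off
   (`taper` = 20 µm) at the meristem edge to keep the ODE well behaved.
   Rigid rotation is the minimal model producing the observed signature:
   anti-parallel lateral velocities on opposite flanks of the root
   diameter, hence low coordinated motility in the meristem.
3. **Whole-root lateral drift.** A gentle common lateral velocity (default
   5 µm/h, direction rotating with a 4-h period) models circumnutation-like
   sway. It exists because the reported meristem lateral-speed excess is
   *relative to the elongation zone* ("~10 µm/h faster in X and Z than the
   elongation zone"), i.e. the elongation zone has a nonzero lateral
   baseline. Without it, the pipeline estimate of the excess would be
   biased low by the Rayleigh noise floor of the zero-signal zone
   (measured lateral speed of a truly static cell is
   `σ·sqrt(π/2)` where σ is the velocity noise), and the comparison with
   the reported excess would measure the noise model rather than the
   kinematics. The value was fixed a priori at a realistic sway amplitude
   and is not fitted.

Positions are integrated with RK4 at 5 substeps per frame; stored true
velocities are the field evaluated at the stored positions, and a test
asserts they agree with finite differences of positions to within the
integration tolerance.

**Division** is a Poisson process (default 0.05 events/cell/h, roughly a
20-h cell cycle) restricted to the meristem. A division ends the parent's
trajectory; two children appear at the next frame at the parent's last
position ± 1.5 µm along a random direction. The tracker deliberately has no
division model (as is typical for surface-based instrument trackers), so
divisions appear downstream as one track continuing into a child plus one
new track; `match_to_truth()` reports link accuracy both strictly and
counting such continuations as correct.

**Reporter dynamics** are phenomenological: intensity
`baseline + amplitude · T(t) · S(y)` with `T(t) = 1 − exp(−(t − delay)/rise)`
after an onset `delay` (default 2.5 h, the reported lag of a
transcriptional auxin reporter) and a Gaussian spatial profile centred
450 µm from the tip. A separate auxin level drives the ratiometric (DII-like)
channel pair as `DII = mDII · exp(−auxin)`. These are delays and saturations,
not signalling models.

**Scenarios** (`apply_scenario()`) modulate the same world over time:
`auxin_induction` multiplies axial speed by a profile rising ~20% to a peak
at 0.5 h and then declining exponentially (`decay_rate`), optionally
decaying `omega` to zero (skew suppression — observed when auxin rises);
`exogenous_IAA` scales the decline with dose. A scenario re-runs the
simulation with the same seed, so `control` is bit-identical to the input.

## Acquisition model

`render_frames()` (point mode) perturbs true positions with isotropic
Gaussian jitter (default 0.5 µm, sub-voxel localisation error), drops each
nucleus independently (2%), adds spurious detections (1% per true nucleus,
uniform over the volume), and adds Gaussian channel noise. Per-frame
bookkeeping (true/dropped/spurious counts) is recorded so conservation is
asserted exactly, not approximately. `render_voxels()` paints 3D Gaussian
blobs into a voxel grid for exercising the image-detection stage, and
minimal uncompressed 16-bit multi-page TIFF I/O is provided (round-trip
verified against an independent implementation in the test suite).

## Detection

The image pipeline mirrors a surface-based instrument pipeline: Gaussian
smoothing with σ = grain_size/2 (the grain size, default 1.5 µm, is a
length scale, not a σ); background elimination by grey opening with a ball
of diameter 6.23 µm; a manual global threshold (20); connected components;
seeded region growing (local maxima separated by at least the estimated
nucleus diameter, 8.30 µm; voxels join the nearest seed); then quality and
voxel-count filters. "Quality" in the instrument is proprietary; here it is
defined transparently as the integrated background-corrected intensity of
the object. The instrument-scale filter values (quality above 5,000–15,000,
voxel count above 10,000) are preserved verbatim in
`imaris_reference_params()` but are not defaults, because they presuppose
that instrument's intensity scale and supersampled surfaces; the
*rule* (threshold on quality and size) is what the configuration fixes.
Second-moment morphology subtracts the within-voxel variance
(`voxel_size²/12`) so digitised shapes are not inflated by half-voxel
smearing; a 2:1 digital ellipsoid then recovers eccentricity √3/2 to
within 1%.

## Tracking

Linking is frame-to-frame minimum-cost assignment where the cost is the
Euclidean distance between a detection and a track's predicted position.
Prediction is order-1 constant velocity from the last two linked samples
(the conventional reading of an "autoregressive motion" tracker); tracks
with one sample predict their last position. Links beyond `max_distance`
(12 µm, the midpoint of the instrument's automatic 9–15 µm range) are
forbidden. Unlinked tracks stay open up to `max_gap` = 3 frames with the
prediction extrapolated and the search radius scaled by (gap + 1); bridged
frames get linearly interpolated samples flagged `gap`. The assignment is
solved exactly per frame with a shortest-augmenting-path LAP solver (Rcpp)
on a padded matrix whose death/birth costs equal the (gap-scaled) radius,
after decomposing the candidate graph into connected components; tests
verify equality with exhaustive enumeration on small frames and invariance
to detection order. Track *duration* is the time span
`(last − first frame) · Δt`, and the duration filter (default 3600 s)
removes short tracks — including most tracks seeded by false positives.

Gap-flagged samples exist so that analyses can exclude them: velocities
differenced through interpolated positions are not measurements. The
recovery analyses in this package exclude `from_gap` samples (the flag also
marks samples whose difference stencil touches a gap).

## Kinematics and coordinated motility

Velocities use central differences by default (forward is available);
acceleration is the difference of successive velocities; displacement² is
referenced to each track's first sample; the instantaneous angle is
`acos(vy/‖v‖)` to the shootward axis. `velocity_total` is the *sum of the
absolute per-axis components* — deliberately not the Euclidean speed, which
is reported separately: only this reading makes a total of ~60 µm/h
consistent with an axial speed of ~50 µm/h in the same zone.

Coordinated motility (CM) of a centre cell is the mean cosine between its
velocity and the velocities of all other cells within 200 µm (3D distance,
3D angles). The centre is excluded; zero-norm neighbours are excluded but
counted; fewer than 3 usable neighbours yields an undefined value. Under
uniform translation CM is exactly 1 for every centre; under isotropic random
directions the mean cosine between two directions has sd 1/√3, so
|CM| stays below 3/√n for n neighbours.

The per-cell feature vector (37 entries, `feature_manifest()`) takes
{mean, sd, max} over time of the velocity components, speed, velocity
total, acceleration magnitude, angle, CM, displacement² and lateral speed,
plus duration, net displacement, path length, directionality ratio, MSD
log–log slope, and mean eccentricity/area when morphology is available.
The MSD slope is fitted over the first quarter of lags **capped at 10**:
time-averaged MSD estimates at long lags have few effective degrees of
freedom and bias a log–log fit downward (a 1500-step random walk fits
~0.87 without the cap); for 40-frame movies the cap is inactive. Ballistic
tracks give slope 2 exactly, diffusive tracks 1 within ±0.1 at the tested
sizes.

## Maps, skewing fits, reporters, cohorts

Spatiotemporal maps average any per-sample statistic in (axial bin × frame)
cells (default 25 µm × 1 frame), tip up; empty bins are missing, and bin
counts sum exactly to the number of samples. The tip is either configured
or estimated per frame as the 2nd percentile of axial positions (robust to
stray detections); positions tipward of the tip are clamped into the
meristem with a warning.

`skewing_rotation_fit()` solves `v ≈ ω × p + t` by least squares (SVD;
condition number above 1e8 is an error naming the degeneracy) and reports
‖ω‖, a centre, and the residual RMS. On meristem samples the residual also
absorbs the axial velocity gradient, so the model-free alternative — the
meristem-minus-elongation mean lateral-speed difference — is reported
alongside and is what the acceptance analysis uses.

Reporter onset is operationalised as the first time a series exceeds its
baseline mean + 3 sd for 2 consecutive frames. The baseline window default
is 8 frames: long enough for a stable sd estimate (5 frames produced
occasional early false crossings purely from threshold noise), short
relative to a 2.5-h delay at 8.75-min sampling. With the simulator's
signal-to-noise (≥ 5) the onset is recovered within one frame across 100
seeds.

Cohort analysis pools replicate movies sample-weighted (every cell-frame
sample counts equally, matching concatenated-data averaging), builds a
line × parameter matrix of means, z-scores columns over lines (zero-variance
columns are dropped with a warning), and clusters lines with Euclidean
distance and average linkage — both configurable, since the reference
analysis names neither. Determinism: lines are sorted by label before
clustering.

## Parameter recovery and calibration

Two headline quantities are recomputed end-to-end by
`scripts/acceptance.R`:

* the elongation-zone mean axial velocity on a non-skewing root whose
  plateau is 50 µm/h, recovered through jitter, dropouts, tracking and
  central differencing (tolerance 5%);
* the meristem-minus-elongation mean lateral-speed excess, with `omega`
  calibrated by secant iteration **on the noiseless ground truth** so the
  true excess is 10 µm/h, then measured through the noisy pipeline
  (tolerance 20%). The calibration target is a property of the stated
  world, not of the pipeline output; nothing is tuned against the measured
  value.

## What a green test establishes — and what it does not

The simulator emulates the *kinematic structure* of a growing root
(zone-dependent axial flow, rigid-rotation skewing, division, delayed
reporters) and an idealised acquisition (isotropic Gaussian jitter,
independent dropouts, uniform false positives). It does not emulate:
optical anisotropy in Z, intensity-dependent localisation error, drift or
registration error between tiles, nucleus shape changes, crowding-dependent
detection failure, or biomechanics (no cell walls, no transport, no
signalling). Recovery within tolerance therefore validates the analysis
chain's correctness on data of known structure — it does not certify
instrument-specific performance. Two consequences worth naming: in the
tip-registered frame the differentiation zone translates coherently and so
shows *high* coordinated motility, whereas lab-frame analyses of real data
show low coordination there (near-static nuclei whose measured directions
are noise); and the 6-fold elongation-vs-differentiation coordination
contrast in real data depends on that uncalibrated noise floor, so tests
assert only the zone *ordering* that is frame-independent (elongation above
meristem, at every frame).

## Numerical and interface choices

* Assignment ties are broken by processing tracks in id order and columns
  by index; all randomness flows from a single configured seed, restored
  after use, so identical configs are bit-identical.
* Pipeline configuration is JSON (`jsonlite`), one block per stage plus a
  mandatory global seed; unknown keys are rejected; the run manifest
  records seed, config hash and per-stage counts. (TOML was considered but
  no TOML parser is available in the supported R stack, and a hand-rolled
  parser for a standard format was ruled out.)
* Track tables round-trip through CSV at full double precision (`%.17g`),
  so stage-wise reruns reproduce downstream artifacts bit-identically.
* Degenerate inputs: empty images yield zero detections (not an error);
  single-sample tracks cannot be differenced (error); constant intensity
  series have undefined onset; zero-variance feature columns are dropped
  before z-scoring; collinear point sets fail the rotation fit with the
  condition number reported.

## Known limitations

* The tracker is a frame-pair LAP with constant-velocity prediction; no
  multi-hypothesis or global (all-frames) optimisation, no lineage
  reconstruction, no drift registration.
* The root axis is assumed straight within a movie; no midline spline or
  curvature handling.
* The "36 morphokinetic features" of the reference analysis are not
  published as a list; `feature_manifest()` is this package's documented,
  versioned stand-in (37 entries) and would need reconciliation against the
  original supplementary table to claim equivalence.
* Whether published coordinated-motility values use 3D or projected 2D
  angles is unstated; this package uses 3D.
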