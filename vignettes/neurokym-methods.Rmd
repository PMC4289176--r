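---
title: "Methods: volumetric kymographs, organelle kinetics and FRAP fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric kymographs, organelle kinetics and FRAP fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurokym)
```

## What the package computes

Radially migrating cerebellar granule neurons (CGNs) move with a two-stroke
cadence: organelles (centrosome, Golgi, primary cilium) advance into the
actin-rich proximal leading process first, and the nucleus follows.
`neurokym` quantifies this choreography from multi-channel 3D time-lapse
stacks:

* **Seeded 3D segmentation** — the cell is the 6-connected component of
  voxels at or above a per-cell intensity threshold that contains a soma
  seed. User-supplied *walls* (polylines rasterized to zero intensity and
  extruded through z) stop the component from bleeding into neighbors.
* **Adaptive volumetric kymographs** — masked fluorescence is accumulated
  in cross-sections one x-y pixel apart along the migration axis (soma
  centroid toward the leading-process tip at frame 0), with sum or max
  statistics and soma/organelle overlays.
* **Local concentration** — mean marker intensity in the intersection of
  the mask with a cylinder of radius 1, 2 or 4 um around a tracked object,
  against the whole-cell mean as baseline.
* **Compartment fractions** — the share of a channel's masked fluorescence
  in the leading process, soma and trailing process along the axis.
* **Velocity kinetics** — per-track mean step speeds with the assay's
  inclusion rules and pre/post drug-addition splits, compared by Welch
  tests.
* **FRAP fitting** — single-exponential recovery fits yielding a half-life
  and mobile fraction.

A fully ground-truthed synthetic scene generator stands in for raw
microscopy data, so every stage is testable end to end.

## Coordinate and binning conventions

One set of conventions is used everywhere to avoid off-by-one drift: voxel
indices are 0-based, a voxel's physical coordinate is `index * voxel size`
(voxel-center convention), and all ranges are half-open. Kymograph bins
are the half-open intervals `[i*delta, (i+1)*delta)` of the projected
coordinate `s = (center - origin) . direction`, with `delta` equal to the
x-y pixel size; a voxel belongs to bin `floor(s/delta)`. Negative `s` is
retained through a recorded bin-0 offset. With the sum statistic, column
totals equal the frame's total masked fluorescence exactly — the invariant
the test suite checks against a brute-force voxel loop.

The migration axis stays anchored at the frame-0 soma centroid. A
per-frame re-anchored variant was considered and rejected as the default:
re-anchoring conflates cell translation with internal rearrangement, which
is exactly what the kymograph is supposed to separate.

## Segmentation choices

Connectivity is fixed at 6 (in-plane 4-neighborhood plus the two
z-neighbors). This is what makes one-pixel-wide 8-connected walls provable
separators: no 6-connected path can step across an 8-connected polyline
extruded through z. The property suite verifies this on randomized
two-blob fixtures against an independent flood fill.

The threshold is per cell and constant over the sequence, supplied by
configuration; nothing re-chooses it mid-sequence. Seeds for later frames
default to the previous mask's intensity-weighted centroid; a frame whose
propagated seed falls below threshold is flagged and skipped rather than
silently returning an empty mask.

## Cylinder orientation for local concentration

The local-concentration region is a disk in x-y extruded through all z
(cylinder axis parallel to z), intersected with the cell mask. An in-plane
cylinder orientation was the plausible alternative reading; the z-parallel
choice was adopted because axial sampling is strongly anisotropic (0.83 um
sections against 0.25 um pixels) and the measurement is meant to probe
in-plane proximity to the tracked object at multiple scales. Distances are
physical (micrometres), voxel center to point. Empty regions return a
flagged `NA`, never a silent zero.

## Velocity estimator and inclusion rules

"Average velocity" is the mean over consecutive-frame pairs of the 3D step
length divided by the frame interval; frame gaps contribute no step. The
alternative (net displacement over total time) underestimates speed for
saltatory motion, and per-frame tracking tools conventionally report step
means. Tracks enter a group only if some run of at least five consecutive
frames exists, and neurons count as migrating only if net displacement
exceeds two cell body lengths (strict inequality; the cell body length
defaults to the frame-0 soma extent along the axis).

Drug-addition experiments split each track into pre (`t <= drug time`),
an excluded settling window (`drug time < t <= window end`, discarded for
focus loss and bath-addition motion) and post (`t > window end`). With the
migration-assay defaults (2-minute frames, drug at 24 min, window ending
at 32 min) this reproduces the published frame sets: pre 0–24 min,
excluded 26–32 min, post 34–60 min. Group comparisons use Welch's
unequal-variance t-test — group spreads in this kind of data differ
severalfold, making the pooled-variance test inappropriate.

Note that the mean-step estimator is biased upward by localization noise:
with per-coordinate noise `s`, a step of true length `d` is measured as
roughly `sqrt(d^2 + 2*s^2)` per in-plane axis pair. At the basal assay's
settings (0.195 um steps, 0.05 um noise) this bias is about +6%; at the
migration assay's settings it is under +1%. The estimator-recovery tests
bound it explicitly.

## FRAP model

Recovery traces are fit to the standard minimal model
`I(t) = I_post + (I_plateau - I_post) * (1 - exp(-k t))` with the bleach
floor fixed at the first post-bleach sample and `(I_plateau, k)` free.
The half-life is `ln(2)/k`; the mobile fraction is
`(I_plateau - I_post) / (I_pre - I_post)`, clipped into `[0, 1]` with a
flag when the fit overshoots. `k` is initialized from a log-linear fit of
the normalized recovery deficit and refined by Levenberg–Marquardt under a
positivity bound. Traces with no increasing trend are reported as
non-converged with a diagnostic instead of being forced through the
optimizer. The fit is invariant to affine intensity rescaling, exact in
the noiseless limit over a grid of `(k, mobile fraction)`, and recovers
group-mean half-lives to within a few percent at 2-s sampling with 2%
noise — all properties the test suite asserts.

## The synthetic scene generator

`scene_config()` / `render_scene()` emulate the acquisition geometry of
the assays: 13 z-sections spanning 10 um, 0.25 um x-y pixels, 2-minute
frames for migration assays and 15-second frames for basal-motility
assays. The rendered cell is a soma sphere with a tapered leading process
ahead and a thin trailing process behind; channels are (0) nucleus, (1) a
punctate organelle, (2) a cytoplasmic actin marker with a Gaussian hotspot
riding on the organelle, and (3) adhesion puncta fixed in the lab frame
that the advancing soma slides past. The trailing process is what keeps
passed adhesion sites inside the segmented cell, so the
leading-to-trailing signal handover is observable in compartment
fractions, as it is in the real cells.

Two-stroke kinematics follow a square-wave phase model: during the first
half-cycle the organelle advances (its lead over the nucleus rises from 0
to the lead amplitude along a triangular wave) while the nucleus is
stationary; during the second half the nucleus advances at twice its mean
speed. Per cycle the nucleus advances exactly `speed x period`. Setting
the lead amplitude to zero selects a constant-speed degenerate mode with
analytically exact step lengths, used for estimator-recovery tests. The
magnitudes are not published quantities; the defaults (5 um lead, 20 min
cycle) are plausible for CGNs and are fixed once here.

Rendering voxelizes the cell body once at frame 0, blurs it with a
Gaussian point-spread proxy (sigma 0.3/0.3/0.8 um — not an optics model,
just enough to exercise centroid and segmentation code), and translates it
to later frames by linear-interpolation sub-voxel shifts. Linear
interpolation is a partition of unity, so total component intensity is
conserved exactly while the support stays inside the grid — the
conservation invariant the tests assert at 1e-8. Point-like structures are
sampled analytically as Gaussians. Noise is Poisson on the signal, then
additive Gaussian, both optional, applied after geometry under the config
seed: identical configs give byte-identical stacks, and configs differing
only in seed share identical ground truth.

Synthetic tracks for estimator recovery lie in the imaging plane
(constant z) with Gaussian localization noise applied per in-plane
coordinate. CGNs migrating along glial fibers on a coverslip move
essentially in-plane, and axial localization error is dominated by the
0.83-um section spacing, which an isotropic in-plane sigma does not
describe; modeling z noise with the in-plane sigma would misstate both.

What the generator does *not* emulate: optics-accurate point spread,
glial-fiber substrate, crowded multi-cell fields, photobleaching decay,
or motion blur. Passing tests therefore demonstrate correctness of the
*computations* under the stated statistical structure, not robustness to
every artifact of real microscopy.

## Problem sizes used in the checks

The packaged checks run on deliberately small grids (roughly 9–13
z-sections, 40 x 140–250 x-y pixels, 6–10 frames), chosen so the whole
suite executes in seconds while still containing a full soma, both
processes and several organelle strokes. Parameter-recovery runs use the
published group sizes (36–120 tracks, 25–30 FRAP traces per condition).

## Numerical details and degenerate inputs

* TIFF storage uses 32-bit integer samples; non-negative integer
  intensities round-trip bit-exactly, other data are quantized at `2^-32`
  relative precision with the scale recorded in the JSON sidecar.
* Welch tests on two zero-variance groups are reported (`t = 0, p = 1`
  for equal means) and flagged degenerate instead of erroring.
* Compartment boundary voxels (`s` exactly at the soma interval edge)
  count as soma; the interval is closed. Fractions are intensity-weighted
  and normalized per frame; frames with zero total signal are flagged.
* Empty kymograph bins hold 0, with an explicit emptiness flag for the
  max statistic.
* The soma overlay takes the largest above-threshold nucleus component
  inside the mask (default threshold: half the frame's maximum nucleus
  intensity in the mask), dilated by a 1-um margin along the axis.

## A worked example

```{r example, eval = FALSE}
cfg <- scene_config(n_frames = 6, n_z = 9, n_y = 40, n_x = 140,
                    voxel_z_um = 1, soma_radius_um = 3,
                    process_length_um = 14, nucleus_speed_um_s = 0.01,
                    lead_amplitude_um = 4, cycle_period_s = 480,
                    start_x_um = 10, seed = 11)
scene <- render_scene(cfg)
seg <- segment_sequence(scene$stack, "actin", threshold = 50,
                        seed_voxel = c(40, 19, 4))
axis <- migration_axis(scene$truth$axis_origin_um,
                       mask = seg$masks[[1]],
                       voxel_size_um = scene$stack$voxel_size_um)
kymo <- volumetric_kymograph(scene$stack, "actin", seg, axis, "sum")
soma <- soma_overlay(scene$stack, "nucleus", seg, axis)
frac <- compartment_fractions(scene$stack, "adhesion", seg, axis, soma)
```

## Known limitations

* Segmentation is thresholding plus connectivity; dim or fragmented cells
  need a well-chosen threshold and, in crowded fields, walls. An Otsu
  initializer could be added but is deliberately never applied silently.
* The kymograph axis is straight; strongly curved migration paths would
  need a spline axis, which is out of scope.
* Tracks are inputs: the package quantifies but does not detect or link
  organelles.
* The FRAP model is the minimal single-exponential with a fixed floor; it
  reports apparent recovery kinetics and does not separate diffusion from
  binding.
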