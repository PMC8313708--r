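---
title: "Vascular brain positioning for functional ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular brain positioning for functional ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusbps)
```

## The problem

Functional ultrasound (fUS) maps cerebral blood volume through the skull of
a mouse at a spatial resolution where anatomy is hard to read, but the
vascular network itself is highly informative: each brain presents a dense,
individually varying but globally conserved "vascular fingerprint" in Power
Doppler contrast. `fusbps` implements a neuronavigation workflow built on
that fingerprint:

1. acquire a 3D Power Doppler scan of the subject at the start of a session;
2. register it (affine, monomodal, mutual-information metric) to a Doppler
   *reference* volume that was aligned beforehand to a labelled brain atlas;
3. compose the two transforms to overlay atlas structures on the live
   subject, extract regions of interest, and drive a motorized probe to any
   vertical imaging plane through two user-placed markers;
4. audit the residual misalignment at micrometre scale with ultrasound
   localization microscopy (ULM), i.e. super-resolved microbubble maps;
5. analyze task-evoked activation (GLM Z-scores, Bonferroni) and
   resting-state connectivity (0.1 Hz low-pass, ROI Pearson matrices,
   seed maps) in atlas coordinates.

Everything is exercised end-to-end on synthetic phantoms; no animal data
ships with the package.

## Coordinate conventions

All world coordinates are millimetres: x lateral (left to right), y the
antero-posterior axis with the first slice of an assembled volume the most
anterior (so slice index increases as Bregma-referenced labels decrease),
z depth, positive downward. Voxel indices are 0-based and the world position
of voxel $i$ is $\mathrm{origin} + i \cdot \mathrm{spacing}$ (voxel
centres). An `affine3d` acts as $y = L(x - c) + c + t$ and is always the
forward map from moving (subject) space into fixed (reference or atlas)
space; resampling pulls intensities through its inverse.

## Doppler processing

A Power Doppler image is the per-pixel temporal mean of squared magnitude of
a clutter-filtered ensemble of compounded frames. The clutter filter is the
standard spatiotemporal SVD: the ensemble is reshaped to a Casorati matrix
(rows = flattened space, x fastest; columns = time) and the leading
`cutoff_rank` singular components — slow, spatially coherent tissue motion —
are subtracted. The number of rejected components is a free parameter
(`default_cutoff_rank()` suggests 30% of the ensemble, 60 of a 200-frame
block, a common choice for transcranial rodent fUS); validation uses
explicit ranks, so nothing in the pipeline depends on the default.

The acquisition arithmetic is kept explicit because it anchors several exact
checks: 11 tilted plane waves at a 5500 Hz pulse repetition frequency
compound to 500 Hz; blocks of 200 compounded frames give one Doppler image
per 400 ms, a 2.5 Hz Doppler frame rate; 2D slices 0.2 mm apart assemble
into volumes with $(100 \times 100 \times 400)\,\mu m^3$ voxels.

## Registration

### Metric

Similarity is Mattes-style mutual information: the fixed volume's voxels
are binned hard into 50 intensity bins; the moving volume is sampled with
trilinear interpolation at the transformed sample positions and its
intensity spread over the moving-axis bins by a Parzen window; MI is
computed from the joint density in nats. All spatial samples are used by
default. Bins span each volume's $[\min,\max]$ with half-bin padding, so
intensities quantized to bin centres land exactly on them.

The Parzen window on the moving axis is the *first-order* (linear)
B-spline by default, not the cubic one that larger registration toolkits
use. The choice is deliberate: with bin-centred data the linear window
reduces exactly to the hard joint histogram, which makes the metric
directly verifiable against a brute-force oracle (and makes
$\mathrm{MI}(A,A) = \ln 50$ for a 50-level volume, a property the test
suite asserts). A cubic window (available via `mi_config(kernel =
"cubic")`) smooths the joint density along the moving axis, which costs
about $-\sum_k w_k \ln w_k \approx 0.87$ nats of self-information — harmless
for optimization, but it breaks the exact oracle equivalence, so it is not
the default. Samples that land outside the moving volume are dropped; if
fewer than 10% remain the metric raises a degenerate-overlap error, which
is what prevents the optimizer from drifting off the brain entirely.

### Optimizer

The search runs over 12 parameters — three rotations (radians), three
log-scales, three shears, three translations (mm), rotation centre at the
fixed volume's geometric centre — conditioned so that 0.1 rad, 0.1
log-scale and 0.1 shear count as 1 mm of translation. The optimizer is a
(1+1) evolution strategy: perturb the current best isotropically in the
scaled space, accept improvements, grow the search radius by 1.05 on
success and shrink it by $1.05^{-1/4}$ on failure, stop at radius
$1.5\cdot10^{-6}$ or 300 iterations per level. It runs coarse-to-fine over
a 3-level Gaussian pyramid (shrink factors 4/2/1 with smoothing sigmas
2/1/0 voxels — the familiar pairing; heavier smoothing visibly degrades
16-voxel axes on desk-scale volumes). The translation is initialized from
the intensity centres of mass. Because the ES plateaus within a few tenths
of a degree of the optimum on a 12-dimensional landscape, a deterministic
Nelder–Mead refinement (300 evaluations, kept only if it improves the
metric) follows at the finest level; and the registration never returns a
transform scoring below its own starting point at full resolution. The
whole procedure is deterministic given `mi_config(seed=)`.

On 64 × 48 × 32 phantom pairs (0.1/0.1/0.2 mm voxels) perturbed by random
rigid+scale transforms (up to 1 mm translation, 10° rotation, ±5% scale),
`registration_recovery()` recovers the applied transform with median
per-axis translation errors of a few micrometres and median rotation error
of about a quarter of a degree; the acceptance suite asserts ≤ 50 µm and
≤ 0.5°. These phantom numbers measure algorithmic recovery on a perturbed
copy of the same scan — the favourable case; with independently re-rendered
noise the information limit of the metric itself (not the optimizer)
dominates and rotational accuracy degrades to the degree scale.

### Audit metrics

`normalized_xcorr3()` computes the zero-mean, globally normalized 3D
cross-correlation over all voxel lags (FFT), and `xcorr_metrics()` extracts
the peak value, the peak lag (equal to the displacement of the second
volume relative to the first) and the per-axis full width at half maximum
with linearly interpolated half-crossings; ties break to the first maximum
in scan order. Because the correlation is computed on mean-subtracted
volumes, the baseline sits slightly below zero and FWHM estimates are only
asymptotically equal to the closed form for isolated blobs — the test suite
uses a domain much larger than the blob for that reason.
`landmark_discrepancy()` reports 3D distance shifts between two named
landmark annotations in micrometres, the same summary used to compare
automatic registration with expert annotation.

## Navigation

Atlas labels are propagated by nearest-neighbour sampling only — labels are
categorical and never averaged — through the composed
subject→reference→atlas transform; the output label set is provably a
subset of the atlas labels plus background. The imaging plane is defined
from two markers as the unique vertical plane (containing the depth axis)
through both; the horizontal component of the marker separation gives the
in-plane lateral axis, and markers stacked within 0.1 mm horizontally are
rejected as under-determined. The stage model has 4 degrees of freedom
(x, y, z, yaw about the vertical axis), which reaches exactly that vertical
family — coronal, sagittal and vertical oblique planes like an
S1-barrel-field-to-V1 trajectory. Non-vertical planes raise an explicit
unsupported-orientation error rather than being silently approximated,
since the real platform's kinematic envelope is not part of this package's
contract; `solve_stage_pose()` inverts `forward_kinematics()` exactly on
the supported family.

The bundled `synthetic_atlas()` (ellipsoidal brain, Voronoi regions, toy
ontology with isocortex/thalamus/hypothalamus groups by depth) is a
geometric stand-in for a real labelled atlas: sufficient to test label
propagation, ROI extraction and plane targeting, with no anatomical claim.
A real atlas volume in NIfTI with an `id,acronym,name,parent_id,group`
ontology CSV drops in unchanged.

## Ultrasound localization microscopy

Bubbles are detected as local maxima above threshold, merged within
`psf_radius` to the brighter peak, and localized sub-pixel by an
intensity-weighted centroid over a $(2r+1)^2$ window after subtracting the
window minimum. The plain windowed centroid carries a pixel-phase
("pixel-locking") bias of up to ~0.3 px, so positions are refined by a
per-axis 3-point parabolic fit on log intensity, which is exact for
Gaussian spots and reduces noise-free localization error to numerical
precision; the centroid remains the fallback where the fit is undefined.

Frame-to-frame linking solves a minimum-cost bipartite assignment
(Hungarian method, shortest augmenting paths with potentials — verified
against exhaustive permutation enumeration up to 6×6) on Euclidean costs,
augmented with birth/death dummies priced at the gating distance; candidate
links beyond the gate (default 50 mm/s divided by the frame rate, per
elapsed frame) are infeasible. Tracks shorter than 4 points are discarded.
Tracks are smoothed by a sliding average whose window shrinks symmetrically
at the ends (so straight tracks map onto themselves), linearly interpolated
tenfold, and accumulated on a 5 µm grid: density is the point count per
pixel, velocity the density-weighted mean speed from finite differences.

Repositioning accuracy between two acquisitions is measured exactly as in
the imaging workflow: a Thirion-style demons displacement field (internal
4/2/1 pyramid, Gaussian field regularization, inputs pre-blurred with
σ = 2 px because near-binary super-resolved maps carry no usable gradients)
is averaged over the dilated intersection of the two vascular masks and
converted to micrometres per direction. A constructed 40 µm lateral offset
between rendered map pairs is recovered within the 10 µm the acceptance
suite demands.

The bubble-movie generator places each bubble on a root-to-leaf centreline
of the synthetic vascular tree at constant speed and returns the exact
ground-truth track set. Placements are rejection-sampled so that co-visible
bubbles stay at least 4 PSF sigmas apart: two bubbles within a PSF are one
spot — no tracker could recover them — so resolvability is a property the
phantom must provide, not a parameter to tune. When a tree cannot host the
requested number of fully co-visible bubbles at that separation, later
placement attempts stagger the bubble's wash-in frame (bubbles entering
the field mid-movie, as they do in vivo); the generator warns if even that
fails.

## Functional statistics

The design matrix is an intercept plus a boxcar regressor sampled at the
Doppler frame rate (the canonical protocol: 30 s baseline, three 30 s
ON / 30 s OFF trials, 210 s, 525 samples at 2.5 Hz). No hemodynamic
convolution is applied by default — CBV tracks the stimulus closely at
these time scales — but a gamma-kernel flag exists. Each voxel is fitted by
ordinary least squares; $t = \hat\beta_1/SE$ is mapped to a Z-score through
the t distribution function (tail-stable via log-probabilities, capped at
|z| = 38; voxels with numerically zero residual variance report ±38 or 0).
Significance uses the Bonferroni-corrected per-voxel level α divided by the
voxel count (0.05 over 5000 voxels gives the 10⁻⁵ per-voxel level). Null
simulations confirm mean ≈ 0, variance ≈ 1 and family-wise error within
the binomial margin of 5%; note that for strong effects the t→z mapping
compresses the far tail, so the mean Z matches the closed-form
noncentrality only at moderate effect sizes.

The connectivity path low-pass filters at 0.1 Hz with a 4th-order
Butterworth applied forward and backward (zero phase, unit DC gain) around
reflection padding — plain forward-backward filtering without padding
leaves O(1) edge transients. ROI signals are spatial means over propagated
atlas labels; matrices are Pearson correlations, symmetric with unit
diagonal and invariant to per-ROI affine rescaling. Filtering white noise
to 0.1 Hz at a 2.5 Hz sampling rate leaves roughly one independent sample
per 12, so correlation estimates on filtered data have inflated variance —
the generator-truth recovery checks therefore run on unfiltered ROI noise,
where the Fisher interval at n = 1500 applies.

## What the phantoms do and do not show

The synthetic generators close the loop from ground truth to estimate:
every generator returns the latent truth (applied transform, bubble tracks,
effect sizes, correlation structure) that downstream checks compare
against. They emulate tree-like vascular intensity volumes (intensity
∝ radius², a blood-volume proxy, with a Gaussian radial profile so the
metric sees gradients), rank-structured tissue+blood frame ensembles,
sparse point-scatterer movies and stimulus-locked or correlated CBV series.
They do not emulate speckle statistics, skull aberration, breathing or
motion artifacts, bubble concentration dynamics, or real vascular topology;
passing phantom tests therefore demonstrates algorithmic correctness and
calibration, not in-vivo performance. Problem sizes in the test and
acceptance suites (64 × 48 × 32 volumes, 20 registration pairs, 60-frame
movies with 12 bubbles, 500 null GLM runs of 2000 voxels, n = 1500
connectivity samples) are the package's chosen desk-scale study conditions.

## Numerical choices worth knowing

- Volume grids follow dimension = ⌊extent/spacing⌋ + 1 with voxel-centre
  sampling; boundary coordinates are accepted within a 10⁻⁶-voxel epsilon
  so exact voxel-centre sampling survives floating-point round-off.
- Resampling out-of-support voxels are 0; label sampling is strictly
  nearest-neighbour.
- The cross-correlation peak and detection maxima break ties to the first
  occurrence in scan order.
- `normalize_for_registration()` log-compresses (`log1p`), clips to the
  (1, 99) percentiles and rescales to [0, 1]; a constant volume normalizes
  to zeros with a warning.
- All stochastic components take explicit seeds and restore the caller's
  RNG state; rerunning any pipeline with the same configuration reproduces
  outputs bit-exactly.

## Known limitations

Non-rigid volume registration is out of scope (the affine model is the
deliberate baseline; demons is used only on 2D ULM maps). The stage model
cannot tilt out of the vertical-plane family. The frame-stack external
format is NIfTI + JSON sidecar rather than HDF5. MI-based registration of
genuinely different subjects (inter-animal) is information-limited on
sparse synthetic trees; the phantom acceptance numbers characterize the
intra-scan (perturbed copy) regime.
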