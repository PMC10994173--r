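---
title: "Automated tilt-series processing with tiltflow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tilt-series processing with tiltflow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tiltflow` reconstructs cryo-electron tomograms from tilt series without
fiducial markers and without manual interaction, the way on-the-fly
processing must run during an acquisition session. This vignette is the
package's own account of the science: the models each stage assumes, the
tunable parameters and why their defaults are what they are, what the
synthetic ground-truth generator does and does not emulate, and the design
choices made where more than one reasonable implementation exists. No
empirical claim is made here beyond what the package's tests and the
acceptance script themselves compute.

## The processing chain

A tilt series is an ordered set of projection images of one specimen area
recorded at stage tilts `a_1 .. a_n` (here the dose-symmetric scheme
0, +3, -3, -6, +6, ... up to &pm;60&deg; with a 3&deg; step and group size
2, i.e. 41 images). The pipeline transforms a raw `tilt_series` through:

1. **Frame preprocessing** (`group_frames`, `correct_motion`) — movie
   frames are grouped into fractions of about one electron per pixel and
   drift-corrected with rigid per-fraction shifts refined on a 3&times;3
   patch grid, summed without dose weighting.
2. **Stack cleaning** (`clean_stack`) — images ruined by grid bars or
   shutter failures are detected from the pairwise similarity of their
   gray-value histograms and flagged non-usable.
3. **Coarse (pair) alignment** (`align_pairs`) — large X/Y shifts are
   measured by filtered cross-correlation between successive images,
   walking outward from the 0&deg; image, skipping ahead when no robust
   peak exists.
4. **Tomogram positioning** (`estimate_pretilt`,
   `apply_pretilt_correction`) — the static inclination of the specimen
   slab (common for FIB-milled lamellae) is estimated from feature flow;
   the Y component corrects the tilt angles, the X component enters the
   reconstruction geometry.
5. **Fine alignment** (`track_patches`, `solve_alignment`,
   `apply_alignment`) — patches are tracked across the series and a
   parallel-projection model is solved for the tilt-axis angle and
   per-image rotations and shifts; the raw stack is resampled once with
   the composed transform.
6. **CTF determination** (`fit_ctf_2d`, `fit_tilted_defocus`) — defocus
   and astigmatism are fitted on the horizontal-sample image; tilted
   images get strip-based defocus with the astigmatism held
   series-constant.
7. **Reconstruction** (`estimate_thickness`, `final_reconstruct`) — SIRT
   with automatic thickness determination, on the 4&times; binned aligned
   stack, with the X tilt in the geometry.
8. **Export** (`export_all`) — IMOD (.rawtlt/.tlt/.xf/.tltxf,
   newst.com/tilt.com, clean stack), Ctfplotter-style .defocus, RELION
   order list and STAR file, and a JSON quality report.

## Conventions

Coordinates are x = column, y = row, with transforms acting on centred
coordinates; shifts are in pixels at the stated working binning. Angles
are degrees throughout. The tilt-axis angle is measured counter-clockwise
from the image Y axis, so rotating an image by minus the axis angle makes
the axis vertical; in that frame features move along x as the stage
tilts. The stage tilts about Y; a feature at sample position (X, Y, Z)
projects to `x = X cos a + Z sin a`, `y = Y` (plus the in-plane transform
of the recording). Defocus is positive for underfocus.

Rotations near quarter turns are applied as an exact 90&deg; pixel
permutation plus a small residual interpolation, so an 85&deg; axis
correction costs only the fill of a ~5&deg; rotation.

## Stage models and parameter choices

### Frame grouping and drift correction

Frames are grouped into blocks of `g = max(1, round(1/dose_per_frame))`
so each fraction carries about 1 e-/px; remainder frames fold into the
last fraction (the rounding rule is a documented choice — the target is
the per-fraction dose, not an exact block count). Drift correction is a
deliberately simplified stand-in for the full multi-patch polynomial
approach used on raw movies: rigid per-fraction shifts against a running
average (two passes), a 3&times;3 patch refinement interpolated
bilinearly, a single bilinear resampling, and a plain sum (no dose
weighting). The contribution of this package lies downstream; the
preprocessing target is functional, not numerical, equivalence to
dedicated motion-correction software.

### Stack cleaner

Histograms (256 bins over the series-wide robust 1st–99th percentile
range) are compared pairwise; image i stays usable when its similarity
with more than 4 other images exceeds a threshold derived from the matrix
statistics. Two implementation choices deserve explanation:

* **Similarity metric.** The default is histogram *intersection* (the
  summed bin-wise minimum of the two L1-normalised histograms). Pearson
  correlation is available (`cleaner_config(method = "pearson")`), but on
  images in the counting regime the correlation of two histograms is
  dominated by the shared comb of discrete intensity levels and saturates
  near 1 even for grossly different exposures; intersection keeps its
  dynamic range.
* **Threshold.** The mean-plus-one-sigma level computed from a bounded
  similarity matrix can exceed every entry when the clean-stack
  distribution is left-skewed and saturated near its maximum — in that
  regime it would flag perfect data. The threshold is therefore capped at
  the median of the off-diagonal values; for matrices with a wide spread
  the classic mean + 1&sigma; level applies unchanged. With
  identical histograms (sigma exactly zero) the threshold drops just
  below the mean so a perfect stack is fully usable.

Because histograms are position-free, high-contrast features present in
every image (fiducials, ice crystals) do not trigger removal; an image of
a *different* area with similar statistics is likewise not caught here —
that failure mode is handled later by pair alignment.

### Pair alignment

Cross-correlation runs at 4&times; binning on axis-vertical images. For
each pair an annular band-pass (grid over low cut 0–0.1 and high cut
0.15–1.0 of Nyquist) is chosen to maximise the peak-quality score — peak
height over the mean absolute level of an annulus around the peak. The
"no robust peak" threshold (7.2) is the upper envelope of the 99th
percentile of that score on independent-noise image pairs across window
sizes, calibrated once (`calibrate_peak_null()`). On failure the walk marks the farther-from-0&deg;
image non-usable and re-pairs across it; cumulative shifts are summed
from the anchor (any slow drift this accumulates is absorbed by the fine
alignment). Shifts are scaled back to unbinned pixels.

### Tomogram positioning

Feature flow between consecutive images is measured by block matching on
a grid of Hann-tapered, 4&times;-overlapping windows (the taper matters:
content drifting over the window border otherwise biases the correlation
toward contraction). A second pass warps the next image back by the
affine flow fitted in the first pass and re-measures the small residual.
Windows overlapping regions filled in by the axis rotation are skipped.

Parallel projection of a *planar* specimen makes the per-pair flow field
exactly affine in image position, and its gradients are clean
observables: `dvx/dx = cos(a_j)/cos(a_i) - 1` pins the Y pre-tilt, and
the symmetrised cross gradient `dvx/dy + dvy/dx =
tan(x_tilt) sin(a_j - a_i)/cos(a_i)` pins the X tilt while cancelling
in-plane rotation. The module triangulates patch trajectories (affine
maps composed outward from the 0&deg; image) and fits a plane with
iterated 3-MAD outlier rejection — that fit provides the inlier report —
and then refines both angles in the slope domain, which is immune to the
error accumulation of chained trajectories. Sign convention: the angles
are *additive corrections*; adding the Y tilt to the nominal angles (and
rotating the reconstruction geometry by the X tilt) levels the sample.

The precision of this stage is feature-statistics-limited: each window
averages the parallax of the features it contains, so a thick sparse
specimen leaves the mid-plane genuinely ambiguous. With the default
synthetic conditions (6000 features in a 100 px slab) both angles are
recovered to a few tenths of a degree.

### Patch tracking and the projection model

The 0&deg; image is divided into 16 patches of 30% of the image
dimensions (a 4&times;4 overlapping grid). Tracking walks outward pair by
pair at 2&times; binning: each patch is correlated (per-patch auto
band-pass, chosen at trajectory birth) against its theoretical position
in the next image, where the theoretical x displacement of a sample-plane
feature is `(x - w/2) (cos a_j / cos a_i - 1)`. A measurement deviating
from theory by more than 2% of `max(width, height)`, or lacking a robust
peak, triggers relocation: the image is divided into 200 subpatches
(20&times;10), their contrast (local standard deviation) sorted, and the
best subpatch not occupied by the core (2/3 of the surface) of any
current patch becomes a new trajectory. If more than 75% of patches on an
image need relocation the image is dropped and tracking continues across
it.

The solver fits the classical projection model: marker k on image i sits
at `scale * R(rot_i) * P(a_i) * X_k + shift_i`, with `P(a)` the 2x3
parallel projection (optionally with the static X tilt), tilt angles held
fixed, and marker positions free. Three stages: a Brent scalar search for
the common tilt-axis offset (5 inner alternations per evaluation, bracket
nominal &pm;10&deg;); blockwise alternation to convergence (markers by
linear least squares, per-image rotation/shift by 2D Procrustes, relative
residual change < 1e-4 or 50 iterations); and repeated trajectory pruning
at mean + 3 sd of the per-trajectory residuals (computed with the worst
trajectory excluded so a single gross outlier cannot mask itself),
refitting until stable. Gauge fixing: the marker centroid is pinned to
the origin. A single global magnification is *not* solved: it is exactly
degenerate with the scale of the marker cloud (`P(a)(sX) = s P(a)X`);
per-image scale can be enabled for relative magnification changes.

Two less obvious solver details. First, the objective is nearly flat
along a joint rotation of the marker cloud against the per-image
rotations (`rot_i ~ gamma cos a_i`); block alternation stalls in that
valley, so it is resolved by an explicit line search over gamma. Second,
tracking is run twice: the first solve provides a predicted plane-affine
map between consecutive images, the second tracking pass warps each next
image back by that prediction and measures only small, gradient-free
residuals. Without this, the expansion and rotation gradients inside
correlation windows attenuate the measured displacements by several
percent and bias the solved axis by up to a degree.

`apply_alignment` composes the axis rotation, pair shifts and solved
per-image transform into one affine map and resamples each raw image
once (bilinear; a single interpolation preserves more high-frequency
signal than sequential resampling, which the tests assert via the power
spectra of the two paths).

### CTF determination

The horizontal-sample image — after pre-tilt correction the image whose
corrected tilt is nearest zero — is fitted following the classical 2D
approach: tiled Hann-windowed periodogram (256 px tiles, half-tile
overlap), smooth radial background removal in the log domain, then
maximisation of the correlation between |CTF|^2 and the spectrum over the
fit band (40 &Aring; to just above Nyquist by default). The defocus
search starts from the applied (microscope) value; astigmatism is seeded
on a coarse magnitude &times; angle grid before simplex refinement, since
the correlation surface has local optima in the angle. The confidence
range is the highest resolution up to which the ring-windowed correlation
between model and spectrum stays above 0.3.

Optical constants default to 300 kV, Cs 2.7 mm, amplitude contrast 0.07
— ordinary practice for the instruments this pipeline targets — and are
configurable. When the pixel size is much finer than needed to sample the
first CTF oscillation, the image is resampled by
`R = round_to_half(N_ref/N_exp)` (ties round up, clamped at 1), where
`N_exp` counts spectrum samples to the first model zero at the native
sampling and `N_ref` the same count at the reference sampling. Because
both counts are proportional to the pixel size, R reduces to the
half-integer-rounded ratio of reference to native pixel size; the
reference is 1.5 &Aring; by default and configurable, since published
descriptions of this rule mix nanometre and &aring;ngstr&ouml;m
conventions.

Tilted images are handled strip-wise: the axis-vertical image is divided
into 9 vertical strips, square 128 px patches tiled along each strip are
averaged into a per-strip power spectrum, and each strip's
equiphase-averaged 1D curve — averaged along the iso-phase ellipses of
the series astigmatism, so zeros stay sharp; with zero astigmatism this
is exactly the rotational average — is background-subtracted with a
smoothing spline through its minima and high-frequency tail, then
rescaled along frequency to match the on-axis curve. A rescaling factor
s corresponds to defocus `f_axis / s^2`. The image defocus is the
refined on-axis value; the slope of strip defocus versus offset is
checked against the geometric expectation `pixel_size * tan(tilt)` and
inconsistent images are flagged low-confidence. Astigmatism is held
series-constant by construction.

### Reconstruction and thickness

The projector pair is a native ray-driven parallel-beam implementation
(unit steps along the beam, trilinear interpolation) whose back projector
scatters with identical weights, making the pair an exact adjoint — the
property the tests verify directly, and the reason SIRT behaves. The
geometry composes the tilt about Y with the static X tilt, so a
correctly positioned slab reconstructs level in the XZ and YZ cross
sections. A `backend` field in the configuration marks where an external
tomography engine could be slotted in; only the native backend ships.

SIRT iterates `x <- x + relaxation * C A^T R (b - A x)` with row and
column sum normalisers and clips the volume to non-negative densities
each iteration (density is non-negative; the constraint partially
compensates the missing wedge). Defaults are 50 iterations and
relaxation 1.4, chosen as the point where in-slab fidelity on noiseless
&pm;60&deg; phantom projections saturates; both are configurable and the
residual trace is returned (it must not increase on noiseless data — an
asserted property — and an increase over three consecutive iterations
stops the run early).

Thickness is estimated from a quick reconstruction — the stack binned to
a small lateral working size (128 px; the synthetic frames already stand
in for 4k acquisitions, so this matches the customary few-hundred-pixel
quick pass at acquisition scale), at most 21 views, a z extent of 0.95
of the binned lateral size, and a dozen iterations: the standard deviation of each XY plane forms a contrast
profile, modelled as a top hat convolved with a Gaussian edge. The
primary width estimate is the distance between the outermost crossings of
a low threshold (baseline plus 0.3 of the amplitude, with the Gaussian
edge's outward push subtracted); the plateau-model fit refines it when
the two agree. A flat profile (no specimen) falls back to a third of the
z extent with a warning. The final reconstruction runs on the 4&times;
binned aligned stack with z set to the estimated thickness plus a 10%
margin. Note one geometric caveat the tests make visible: when the slab
thickness approaches the lateral field of view, high-tilt rays no longer
cover the top and bottom of the volume and the contrast profile tapers
early, biasing the estimate low by a few voxels; at realistic aspect
ratios (field of view comfortably wider than the specimen is thick) the
estimator stays within 10%.

### Quality metrics and export

The per-series report carries the alignment accuracy (mean model
residual, px), number of deleted slices (union of cleaner, pair-alignment
and tracking removals), tilt-axis correction (solved minus nominal,
degrees), defocus of the horizontal image, CTF confidence range and
astigmatism. IMOD transforms are written one 2&times;3 line per usable
image (`a11 a12 a21 a22 dx dy`, shifts in unbinned pixels); `newst.com`
and `tilt.com` are templates following current IMOD syntax, not
guaranteed runnable without IMOD. The Ctfplotter-style `.defocus` file
carries view and tilt ranges plus the two astigmatic defocus values in
nanometres with the format version flag on the first row. RELION export
targets the tomography STAR layout (field names collected in one place in
the source) plus the acquisition-order CSV; the exact column dialect of
other tools' exports varies, so the STAR fields may need renaming for a
given downstream version.

## The synthetic ground-truth generator

Every stage is tested by parameter recovery, so the generator is
first-class code. `simulate_tilt_series()` draws a ground truth
(per-image shifts up to 30 px, per-image rotations up to 2&deg;, tilt
axis uniform in 80–95&deg;, lamella pre-tilts up to 10&deg;) and renders
Gaussian features confined to a slab, projected *analytically* — each
feature's recorded position follows the exact forward model, so recovered
parameters can be compared against truth at sub-pixel precision without
voxelisation error. The voxel-space twin (`make_phantom` +
`project_tilt_series`) renders slab phantoms with spheres, rods and
shells (anti-aliased edges, band-limited granular texture, features
clipped at the ice surfaces) through the compiled projector, and is the
basis of the reconstruction tests; the two projectors are checked against
each other on point sources.

Conditions the generator fixes, and why:

* **41 images, dose-symmetric &pm;60&deg;, 3&deg; step, group 2; 3
  e-/&Aring;&sup2; per image** — the acquisition scheme this pipeline is
  built around.
* **512 px frames standing in for 4k acquisitions.** The working pixel is
  therefore 8 &Aring; and one image deposits roughly 190 electrons per
  (working) pixel at 0&deg;. Simulating at acquisition sampling would
  put a handful of counts in each pixel of a small test image, a regime
  real processing stacks avoid by working on binned previews.
* **Specimen larger than the field of view** (&pm;1.5 image widths along
  x, slightly beyond the frame in y): at high tilt the projection
  compresses along x and material from outside the 0&deg; field enters —
  without this the high-tilt frames would be mostly empty, which no real
  stage position produces.
* **6000 features in a 100 px slab.** Positioning precision is limited by
  how well window-averaged flow pins the slab mid-plane; the plane of a
  sparse cloud is genuinely ambiguous at the half-degree level
  (its own sampled Z-vs-x slope wanders), so the density is chosen at
  the crowded-cytoplasm end.
* **Beer–Lambert attenuation** `exp(-t/lambda / cos a)` with one
  inelastic mean free path at zero tilt, plus a light detector
  point-spread blur: these give images the smooth tilt-dependent
  intensity progression and continuous gray values on which
  histogram-based cleaning operates.
* **CTF simulations use a separate broadband specimen** (white-noise
  object, mildly low-passed, 4 &Aring; pixels): smooth blob specimens
  carry no power at Thon-ring frequencies, so CTF recovery must be
  exercised on a textured object.
* Shot noise is Poisson only; detector DQE modelling, beam-induced
  doming, radiation damage and multislice image formation are out of
  scope. Passing recovery tests on these synthetics therefore
  demonstrates the geometry, estimation and bookkeeping machinery — not
  robustness to every pathology of real data.

## Numerical choices and degenerate inputs

* Correlation peaks are localised with a 3&times;3 parabolic fit;
  fftshift centring is exact for even and odd sizes.
* Block-mean binning is exact for integer factors; non-integer factors
  use Fourier cropping (mean-preserving).
* The robust-peak threshold (7.17) is a frozen build-time calibration;
  `calibrate_peak_null()` reproduces it.
* Degenerate inputs: identical histograms keep all images usable; a
  series shorter than the support count warns and keeps everything; an
  unusable 0&deg; image is a fatal pair-alignment error (the walk has no
  anchor); all-constant movie frames raise a zero-signal error; a flat
  contrast profile falls back to z/3 with a warning; SIRT with zero
  iterations returns the zero volume.
* Determinism: every stochastic generator takes a seed and restores the
  caller's RNG state; the pipeline itself is deterministic given its
  inputs, so repeated runs produce identical metrics and exports.

## Problem sizes used by the test and acceptance suites

The packaged suites run the full chain on 512&sup2; 41-image series (20
seeded cases for alignment recovery), 21-image 512&sup2; tilted CTF
series, 64&sup3; reconstruction phantoms with a 10-case thickness suite
at 96&times;96&times;64, and 128&sup2; 41-image series for the 50-seed
cleaner suite — sizes chosen so the whole suite completes in tens of
minutes on one CPU while every stage still operates in its intended
regime.

## Known limitations

* Magnification is assumed constant (global scale unidentifiable;
  per-image scale optional but off by default).
* The positioning model is a plane; doming or per-region Z maps are out
  of scope, as is local (non-rigid) fine alignment.
* Tilt angles are taken as read from the stage and never refined.
* CTF fitting assumes visible Thon rings; at very low dose or strong
  drift the confidence range collapses and results are flagged, not
  rescued. Phase plates are not modelled.
* The thickness estimate biases low when the specimen thickness
  approaches the lateral field of view (ray coverage, discussed above).
* Exports are format-conformant by construction and round-trip under the
  package's own parsers; they are not guaranteed byte-compatible with
  every downstream version.
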