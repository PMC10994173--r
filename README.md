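# tiltflow

Automated, fiducial-free processing of cryo-electron tomography tilt
series in R: stack cleaning, coarse and fine alignment, sample
positioning, tilted-specimen CTF estimation, SIRT reconstruction with
automatic thickness determination, and export to IMOD-, Ctfplotter- and
RELION-compatible files. The package targets the workflow of on-the-fly
tomogram screening — every stage runs without manual interaction — and
ships a forward simulator with known ground truth so that each stage is
testable by parameter recovery.

## Who this is for

Cryo-ET practitioners and method developers who want an open, scriptable,
fully tested implementation of the standard automatic processing chain:
from a raw tilt series (MRC stack or per-tilt files, plus acquisition
metadata) to an aligned stack, per-image CTF parameters, a reconstructed
tomogram and the export files downstream packages expect.

## The models at the core

* **Stack cleaning.** Unusable images (grid bars entering the field of
  view) are detected from the pairwise similarity of gray-value
  histograms: image *i* is kept iff its similarity with more than 4 other
  images exceeds a threshold derived from the matrix mean and spread.
* **Coarse alignment.** Large shifts are measured by band-pass-filtered
  cross-correlation between successive images of the tilt-ordered,
  axis-vertical stack, walking outward from the 0° image; images without
  a robust peak (calibrated against a noise null) are skipped and
  flagged.
* **Positioning.** For a planar specimen, parallel projection makes the
  feature flow between tilts *a_i → a_j* an affine field whose gradients
  are `dvx/dx = cos a_j / cos a_i − 1` (fixes the Y pre-tilt) and
  `dvx/dy + dvy/dx = tan(x_tilt)·sin(a_j − a_i)/cos a_i` (fixes the X
  tilt). The Y tilt corrects the tilt angles; the X tilt enters the
  reconstruction geometry.
* **Fine alignment.** 16 patches (30 % of the image size) are tracked by
  cross-correlation against their theoretical positions
  `dx = (x − w/2)(cos a_j/cos a_i − 1)`, with automatic relocation via
  200 contrast-sorted subpatches; the projection model
  `p_ik = s·R(rot_i)·P(a_i)·X_k + t_i` is then solved for the tilt-axis
  angle, per-image rotations and shifts, and free 3D marker positions,
  with 3σ trajectory pruning.
* **CTF.** Classical 2D power-spectrum fitting (defocus + astigmatism) on
  the horizontal-sample image; tilted images get strip-based defocus —
  per-strip equiphase-averaged 1D curves rescaled in frequency onto the
  on-axis curve (`f_strip = f_axis / s²`) — with astigmatism held
  series-constant.
* **Reconstruction.** SIRT (`x ← x + λ·C·Aᵀ·R·(b − Ax)`) on an exact
  adjoint ray-driven projector pair, with non-negativity, automatic
  thickness from the per-plane contrast profile of a quick binned
  reconstruction, and the X tilt in the geometry.

Details, parameter defaults and design rationale are in the methods
vignette (`vignettes/tiltflow-methods.Rmd`).

## Worked example

Simulate a tilt series with known ground truth and run the whole chain:

```r
library(tiltflow)

sim <- simulate_tilt_series(seed = 11, size = 512)   # 41 images, +-60 deg
sim$truth$tilt_axis_deg
#> [1] 82.55802
res <- run_pipeline(sim$series,
                    pipeline_config(do_ctf = FALSE,
                                    reconstruction = reconstruction_config(
                                      n_iterations = 15, binning = 8)))
res$metrics
#> Alignment accuracy: 0.229 px | Deleted slices: 2 | Tilt-axis correction: -0.93 deg
#> Defocus: NA um | CTF confidence: NA A | Astigmatism: NA um
res$model$tilt_axis_deg
#> [1] 82.07092
res$tomogram
#> <tomogram> 64x64x15 voxels, 64.000 A/voxel, x-tilt -0.68 deg
files <- export_all(res, "results/")
```

The alignment accuracy is the mean residual between tracked patch
trajectories and the solved projection model; the solved axis (82.07°)
recovers the injected 82.56° to half a degree on this case (0.28° RMS
over the packaged 20-case suite), the correction is reported relative to
the nominal (microscope) axis of 83°, and the two deepest-tilt images
were dropped as untrackable. CTF estimation needs a specimen with
broadband contrast; `simulate_ctf_series()` provides one:

```r
ctf_sim <- simulate_ctf_series(seed = 9, angles_deg = c(0, 45),
                               truth = ground_truth(2, defocus_um = 3))
central <- fit_ctf_2d(ctf_sim$series$images[[1]], applied_defocus_um = 2.9,
                      pixel_size_A = 4)
central$defocus_um
#> [1] 2.999353
strips <- strip_spectra(ctf_sim$series$images[[2]], pixel_size_A = 4)
fit_tilted_defocus(strips, central, tilt_angle_deg = 45)$defocus_um
#> [1] 3.003754
```

A thin command-line front end over the same functions is installed at
`inst/cli/tiltflow.R` (`synth`, `clean`, `run` subcommands).

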