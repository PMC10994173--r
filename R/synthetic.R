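# Forward simulator: slab phantoms, parallel-beam tilt projections with
# injected misalignments, defocus-gradient CTF, Poisson noise, grid-bar
# occlusions and dose-fractionated movies.  Everything is deterministic per
# seed so pipeline stages are tested by parameter recovery.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Dose-symmetric acquisition order
#'
#' Alternating-sides scheme: starting at 0 degrees, groups of `group` images
#' are recorded on one side before switching, keeping low-dose images at low
#' tilt (e.g. 0, +3, -3, -6, +6, +9, -9, ...).
#'
#' @param max_tilt_deg maximum |tilt| (degrees).
#' @param step_deg tilt increment (degrees).
#' @param group group size before switching sides.
#' @return numeric vector of angles in acquisition order.
#' @export
dose_symmetric_scheme <- function(max_tilt_deg = 60, step_deg = 3,
                                  group = 2) {
  pos <- seq(step_deg, max_tilt_deg, by = step_deg)
  neg <- -pos
  out <- 0
  i_pos <- 1L; i_neg <- 1L; side <- 1L
  remaining_first <- group - 1L  # the 0 image counts into the first group
  take <- function(side, k) {
    if (side > 0) {
      idx <- seq.int(i_pos, length.out = min(k, length(pos) - i_pos + 1L))
      i_pos <<- i_pos + length(idx); pos[idx]
    } else {
      idx <- seq.int(i_neg, length.out = min(k, length(neg) - i_neg + 1L))
      i_neg <<- i_neg + length(idx); neg[idx]
    }
  }
  out <- c(out, take(1L, remaining_first))
  side <- -1L
  while (i_pos <= length(pos) || i_neg <= length(neg)) {
    out <- c(out, take(side, group))
    side <- -side
  }
  out
}

#' Ground truth for a simulated tilt series
#'
#' @param n image count.
#' @param per_image_shift_px n x 2 matrix (dx, dy) of injected shifts.
#' @param per_image_rotation_deg per-image in-plane rotation residuals.
#' @param tilt_axis_deg global tilt-axis angle (CCW from image Y).
#' @param pre_tilt_x_deg,pre_tilt_y_deg static sample pre-tilts.
#' @param defocus_um per-image defocus (positive = underfocus).
#' @param astigmatism_um,astig_angle_deg series-constant astigmatism.
#' @param slab_thickness_voxels thickness of the supporting slab.
#' @param bad_image_indices indices meant to be flagged unusable downstream.
#' @param scale global magnification factor applied to projections.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(n, per_image_shift_px = matrix(0, n, 2),
                         per_image_rotation_deg = numeric(n),
                         tilt_axis_deg = 0, pre_tilt_x_deg = 0,
                         pre_tilt_y_deg = 0, defocus_um = rep(3, n),
                         astigmatism_um = 0, astig_angle_deg = 0,
                         slab_thickness_voxels = 40,
                         bad_image_indices = integer(0), scale = 1) {
  per_image_shift_px <- matrix(per_image_shift_px, n, 2)
  stopifnot(length(per_image_rotation_deg) == n,
            length(defocus_um) %in% c(1L, n), slab_thickness_voxels >= 1)
  structure(list(per_image_shift_px = per_image_shift_px,
                 per_image_rotation_deg = per_image_rotation_deg,
                 tilt_axis_deg = tilt_axis_deg,
                 pre_tilt_x_deg = pre_tilt_x_deg,
                 pre_tilt_y_deg = pre_tilt_y_deg,
                 defocus_um = rep_len(defocus_um, n),
                 astigmatism_um = astigmatism_um,
                 astig_angle_deg = astig_angle_deg,
                 slab_thickness_voxels = slab_thickness_voxels,
                 bad_image_indices = bad_image_indices,
                 scale = scale),
            class = "ground_truth")
}

#' Phantom specification
#'
#' @param volume_shape c(nx, ny, nz) voxel dimensions.
#' @param slab_thickness_voxels thickness of the central horizontal slab.
#' @param n_features number of randomly placed features.
#' @param kinds feature kinds drawn from `"sphere"`, `"rod"`, `"shell"`.
#' @param contrast feature density above background.
#' @param background mean density inside the slab.
#' @param texture_sd standard deviation of the granular density texture
#'   filling the slab (vitreous ice / cytoplasm is not featureless).
#' @param seed RNG seed (feature placement is deterministic per seed).
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 64),
                         slab_thickness_voxels = 24, n_features = 150,
                         kinds = c("sphere", "rod", "shell"), contrast = 1,
                         background = 0.1, texture_sd = 0.25, seed = 1) {
  stopifnot(length(volume_shape) == 3, n_features >= 0,
            slab_thickness_voxels >= 1,
            slab_thickness_voxels <= volume_shape[3])
  structure(list(volume_shape = volume_shape,
                 slab_thickness_voxels = slab_thickness_voxels,
                 n_features = n_features, kinds = kinds,
                 contrast = contrast, background = background,
                 texture_sd = texture_sd, seed = seed),
            class = "phantom_spec")
}

#' Build a slab phantom volume
#'
#' Features (spheres, rods, spherical shells) are confined to a horizontal
#' slab centred in z; the slab itself carries a small constant background
#' density and the outside is zero.
#'
#' @param spec a [phantom_spec()].
#' @return 3D array dim c(nx, ny, nz) (x fastest, z = depth).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$volume_shape[1]; ny <- spec$volume_shape[2]
  nz <- spec$volume_shape[3]
  th <- spec$slab_thickness_voxels
  vol <- array(0, dim = c(nx, ny, nz))
  cz <- (nz - 1) / 2
  zlo <- cz - th / 2; zhi <- cz + th / 2
  z_in <- which(seq(0, nz - 1) >= zlo & seq(0, nz - 1) <= zhi)
  vol[, , z_in] <- spec$background
  if (spec$texture_sd > 0) {
    # band-limited granularity (correlation length ~2 voxels) so the
    # texture survives a binned reconstruction
    with_seed(spec$seed + 1L, {
      tex <- array(rnorm(nx * ny * length(z_in)),
                   dim = c(nx, ny, length(z_in)))
      for (zz in seq_along(z_in)) {
        f <- fft(tex[, , zz])
        fg <- freq_grid(nx, ny)
        f <- f * exp(-((fg$fx^2 + fg$fy^2) / (2 * 0.08^2)))
        tex[, , zz] <- Re(fft(f, inverse = TRUE)) / (nx * ny)
      }
      tex <- tex * spec$texture_sd / max(sd(tex), 1e-12)
      vol[, , z_in] <- pmax(vol[, , z_in] + tex, 0)
    })
  }
  if (spec$n_features > 0) {
    max_r <- max(2, min(th / 3, min(nx, ny) / 10))
    if (max_r < 1) stop("slab too thin to fit features")
    xs <- seq(0, nx - 1) - (nx - 1) / 2
    ys <- seq(0, ny - 1) - (ny - 1) / 2
    zs <- seq(0, nz - 1) - (nz - 1) / 2
    soft <- function(d2, r) {
      # anti-aliased (band-limited) edge over ~1.5 voxels
      pmin(pmax((r - sqrt(d2)) / 1.5 + 0.5, 0), 1)
    }
    with_seed(spec$seed, {
      for (f in seq_len(spec$n_features)) {
        kind <- sample(spec$kinds, 1)
        r <- runif(1, 2, max_r)
        cx <- runif(1, -nx / 2 + r + 1, nx / 2 - r - 1)
        cy <- runif(1, -ny / 2 + r + 1, ny / 2 - r - 1)
        # features fill the slab up to its faces (clipped below, like
        # molecules at the ice surface)
        czf <- runif(1, -th / 2, th / 2)
        dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2; dz2 <- (zs - czf)^2
        d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
        add <- switch(kind,
          sphere = spec$contrast * soft(d2, r),
          shell = spec$contrast *
            pmin(soft(d2, r), 1 - soft(d2, 0.7 * r)),
          rod = {
            len <- runif(1, r, 3 * r)
            dxl <- pmin(pmax(abs(xs - cx) - len, 0), Inf)^2
            d2r <- outer(outer(dxl, dy2, "+"), dz2, "+")
            spec$contrast * soft(d2r, 0.5 * r)
          })
        vol <- vol + add
      }
    })
    # the ice surfaces clip everything outside the slab
    vol[, , -z_in] <- 0
  }
  vol
}

# beam-frame (u, v) detector coordinates of sample-frame points under stage
# tilt alpha (about Y), sample pre-tilts and per-image transform from truth
project_point_one <- function(P, alpha_deg, truth, i) {
  a <- deg2rad(alpha_deg + truth$pre_tilt_y_deg)
  b <- deg2rad(truth$pre_tilt_x_deg)
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  u <- ca * P[, 1] + sa * sb * P[, 2] + sa * cb * P[, 3]
  v <- cb * P[, 2] - sb * P[, 3]
  th <- deg2rad(truth$tilt_axis_deg + truth$per_image_rotation_deg[i])
  s <- truth$scale
  x <- s * (cos(th) * u - sin(th) * v) + truth$per_image_shift_px[i, 1]
  y <- s * (sin(th) * u + cos(th) * v) + truth$per_image_shift_px[i, 2]
  cbind(x, y)
}

#' Analytic projected positions of 3D points
#'
#' Applies the full forward model (pre-tilts, stage tilt about Y, tilt-axis
#' rotation, per-image rotation/scale/shift) to sample-frame points.
#'
#' @param points n x 3 matrix of (x, y, z) positions in voxels, origin at the
#'   volume centre.
#' @param angles_deg nominal tilt angles.
#' @param truth a [ground_truth()].
#' @return list of n x 2 matrices of centred image positions, one per angle.
#' @export
project_points <- function(points, angles_deg, truth) {
  points <- matrix(points, ncol = 3)
  lapply(seq_along(angles_deg), function(i)
    project_point_one(points, angles_deg[i], truth, i))
}

#' Forward-project a volume into a tilt series
#'
#' Parallel-beam line integrals about the Y axis after the ground-truth
#' pre-tilt rotations, followed by the recorded-frame transform (tilt-axis
#' plus per-image rotation, scale, shift) applied to each projection.
#'
#' @param volume 3D array dim c(nx, ny, nz) as from [make_phantom()].
#' @param angles_deg nominal tilt angles (one image per entry).
#' @param truth a [ground_truth()] consistent with `angles_deg`.
#' @param pixel_size_A pixel size recorded on the output series.
#' @return a `tilt_series` in the given (acquisition) order.
#' @export
project_tilt_series <- function(volume, angles_deg, truth,
                                pixel_size_A = 2) {
  n <- length(angles_deg)
  dims <- dim(volume)
  if (dims[1] * cos(deg2rad(max(abs(angles_deg)))) < dims[3] / 2)
    warning("volume may not cover the field of view at maximum tilt")
  images <- vector("list", n)
  for (i in seq_len(n)) {
    p <- .forward_project_cpp(as.numeric(volume), as.integer(dims),
                              angles_deg[i] + truth$pre_tilt_y_deg,
                              truth$pre_tilt_x_deg)
    img <- t(p)  # [u, v] -> [row = y, col = x]
    images[[i]] <- warp_image(img,
      rot_deg = truth$tilt_axis_deg + truth$per_image_rotation_deg[i],
      scale = truth$scale,
      shift = truth$per_image_shift_px[i, ], fill = 0)
  }
  tilt_series(images, angles_deg, pixel_size_A = pixel_size_A,
              nominal_tilt_axis_deg = truth$tilt_axis_deg)
}

# render Gaussian blobs at given centred positions into an image matrix
render_blobs <- function(size, pos, sigma, amp) {
  img <- matrix(0, size, size)
  c0 <- (size + 1) / 2
  for (k in seq_len(nrow(pos))) {
    x <- pos[k, 1] + c0; y <- pos[k, 2] + c0
    r <- ceiling(4 * sigma[k])
    if (x + r < 1 || x - r > size || y + r < 1 || y - r > size) next
    xs <- max(1, floor(x - r)):min(size, ceiling(x + r))
    ys <- max(1, floor(y - r)):min(size, ceiling(y + r))
    g <- amp[k] * exp(-(outer((ys - y)^2, (xs - x)^2, "+")) /
                        (2 * sigma[k]^2))
    img[ys, xs] <- img[ys, xs] + g
  }
  img
}

#' Simulate a blob-specimen tilt series with known ground truth
#'
#' Gaussian blobs confined to a slab are projected analytically (exact
#' forward model, no voxelisation), so recovered alignment parameters can be
#' compared against the injected truth at sub-pixel precision.
#'
#' @param seed RNG seed controlling blob layout, truth draws and noise.
#' @param size image side in pixels.
#' @param angles_deg nominal tilt angles; default dose-symmetric
#'   0..±60 at 3 degrees, group 2 (41 images).
#' @param truth optional [ground_truth()]; when `NULL` one is drawn with
#'   shifts up to `max_shift_px`, rotations up to `max_rot_deg`, tilt axis
#'   uniform in `axis_range_deg` and pre-tilts up to `max_pretilt_deg`.
#' @param n_blobs number of features.
#' @param slab_thickness_px slab thickness in pixels.
#' @param dose_e_per_A2 per-image dose for Poisson noise; `NA` disables
#'   noise.
#' @param pixel_size_A pixel size.
#' @param max_shift_px,max_rot_deg,axis_range_deg,max_pretilt_deg truth draw
#'   bounds used when `truth` is `NULL`.
#' @param contrast blob contrast relative to background in the noise model.
#' @param sample_extent_frac half-extent of the specimen along x as a
#'   fraction of the image size; larger than 0.5 so the field of view stays
#'   filled at high tilt where the projection compresses along x.
#' @param blob_sigma_px range of feature widths (Gaussian sigma, pixels);
#'   the default scales with the frame so a feature occupies the same
#'   fraction of the field of view at any simulation size.
#' @return list with `series` (a `tilt_series`), `truth`, and `points`
#'   (blob sample-frame positions).
#' @export
simulate_tilt_series <- function(seed = 1, size = 512,
                                 angles_deg = dose_symmetric_scheme(),
                                 truth = NULL, n_blobs = 6000,
                                 slab_thickness_px = 100,
                                 dose_e_per_A2 = 3, pixel_size_A = 8,
                                 max_shift_px = 30, max_rot_deg = 2,
                                 axis_range_deg = c(80, 95),
                                 max_pretilt_deg = 10, contrast = 1.2,
                                 sample_extent_frac = 1.5,
                                 blob_sigma_px = c(2.5, 6) * size / 512) {
  n <- length(angles_deg)
  with_seed(seed, {
    if (is.null(truth)) {
      truth <- ground_truth(
        n,
        per_image_shift_px = cbind(runif(n, -max_shift_px, max_shift_px),
                                   runif(n, -max_shift_px, max_shift_px)),
        per_image_rotation_deg = runif(n, -max_rot_deg, max_rot_deg),
        tilt_axis_deg = runif(1, axis_range_deg[1], axis_range_deg[2]),
        pre_tilt_x_deg = runif(1, -max_pretilt_deg / 2, max_pretilt_deg / 2),
        pre_tilt_y_deg = runif(1, -max_pretilt_deg, max_pretilt_deg),
        slab_thickness_voxels = slab_thickness_px)
    }
    # anchor the zero-tilt image so truth shifts are relative to it
    i0 <- which.min(abs(angles_deg))
    truth$per_image_shift_px[i0, ] <- 0
    truth$per_image_rotation_deg[i0] <- 0
    half_x <- sample_extent_frac * size
    half_y <- 0.55 * size  # specimen continues a little beyond the FOV
    pts <- cbind(runif(n_blobs, -half_x, half_x),
                 runif(n_blobs, -half_y, half_y),
                 runif(n_blobs, -slab_thickness_px / 2,
                       slab_thickness_px / 2))
    sigma <- runif(n_blobs, blob_sigma_px[1], blob_sigma_px[2])
    amp <- runif(n_blobs, 0.6, 1.5)
    proj <- project_points(pts, angles_deg, truth)
    images <- lapply(proj, function(p) render_blobs(size, p, sigma, amp))
    series <- tilt_series(images, angles_deg, pixel_size_A = pixel_size_A,
                          dose_e_per_A2 = dose_e_per_A2,
                          nominal_tilt_axis_deg = round(truth$tilt_axis_deg))
    if (!is.na(dose_e_per_A2))
      series <- add_poisson_noise(series, dose_e_per_A2,
                                  seed = seed + 10000L,
                                  contrast = contrast)
    list(series = series, truth = truth, points = pts)
  })
}

#' Add shot noise at a stated electron dose
#'
#' Images are mapped to expected counts `dose * pixel_size^2 *
#' (1 + contrast * standardized image)` (floored at 5% of the base rate)
#' and Poisson-sampled.  The base rate carries the tilt-dependent
#' attenuation of a slab specimen (electron path length grows as
#' 1/cos(tilt)), which is what gives real gray-value histograms their
#' smooth tilt-to-tilt progression.
#'
#' @param series a `tilt_series`.
#' @param dose_e_per_A2 dose per image in e-/A^2.
#' @param seed RNG seed.
#' @param contrast relative modulation of the expected rate by the image.
#' @param thickness_mfp specimen thickness in inelastic mean free paths at
#'   zero tilt (0 disables the attenuation).
#' @param mtf_blur apply a light separable detector point-spread kernel so
#'   recorded intensities are continuous rather than integer counts, as in
#'   motion-corrected detector averages.
#' @return the noisy `tilt_series`.
#' @export
add_poisson_noise <- function(series, dose_e_per_A2, seed = 1,
                              contrast = 1, thickness_mfp = 1,
                              mtf_blur = TRUE) {
  if (dose_e_per_A2 <= 0) stop("dose must be positive")
  base <- dose_e_per_A2 * series$pixel_size_A^2
  att <- exp(-thickness_mfp / cos(deg2rad(series$meta$tilt_angle_deg)))
  k <- c(0.15, 0.7, 0.15)
  blur <- function(m) {
    m2 <- k[1] * rbind(m[1, ], m[-nrow(m), ]) + k[2] * m +
      k[3] * rbind(m[-1, ], m[nrow(m), ])
    k[1] * cbind(m2[, 1], m2[, -ncol(m2)]) + k[2] * m2 +
      k[3] * cbind(m2[, -1], m2[, ncol(m2)])
  }
  with_seed(seed, {
    series$images <- lapply(seq_along(series$images), function(i) {
      img <- series$images[[i]]
      s <- (img - mean(img)) / max(sd(img), 1e-12)
      lam <- base * att[i] * pmax(1 + contrast * s, 0.05)
      out <- matrix(rpois(length(lam), lam), nrow(img), ncol(img))
      if (mtf_blur) out <- blur(out)
      out
    })
  })
  series$meta$dose_e_per_A2 <- dose_e_per_A2
  series
}

#' Apply a defocus-gradient CTF and shot noise to a tilt series
#'
#' Each image is filtered with a phase-contrast CTF whose defocus varies
#' linearly in the direction perpendicular to the tilt axis:
#' `defocus(d) = f0 + d * pixel_size * tan(tilt)` with `d` the signed
#' distance from the axis in pixels.  The variation is applied in smoothly
#' blended strips; Poisson noise at the stated dose follows.
#'
#' @param series a `tilt_series` (tilt axis angle taken from the series).
#' @param truth a [ground_truth()] carrying per-image defocus and series
#'   astigmatism.
#' @param dose_e_per_A2 per-image dose; `NA` skips the noise step.
#' @param seed RNG seed.
#' @param optics optical constants from [ctf_optics()].
#' @param strip_px width of the constant-defocus strips (pixels).
#' @param contrast rate modulation passed to [add_poisson_noise()].
#' @return the filtered (and optionally noisy) `tilt_series`.
#' @export
apply_ctf_and_noise <- function(series, truth, dose_e_per_A2 = 3, seed = 1,
                                optics = ctf_optics(), strip_px = 32,
                                contrast = 1) {
  if (any(truth$defocus_um <= 0)) stop("defocus must be positive underfocus")
  n <- n_images(series)
  d <- dim(series$images[[1]])
  ny <- d[1]; nx <- d[2]
  th <- deg2rad(series$nominal_tilt_axis_deg)
  # signed distance from the axis line through the image centre
  xs <- matrix(seq_len(nx) - (nx + 1) / 2, ny, nx, byrow = TRUE)
  ysm <- matrix(seq_len(ny) - (ny + 1) / 2, ny, nx)
  dist <- xs * cos(th) + ysm * sin(th)
  fg <- freq_grid(ny, nx)
  k2d <- sqrt(fg$fx^2 + fg$fy^2) / (series$pixel_size_A)  # 1/A
  az <- atan2(fg$fy, fg$fx)
  for (i in seq_len(n)) {
    alpha <- deg2rad(series$meta$tilt_angle_deg[i])
    grad_A_per_px <- series$pixel_size_A * tan(alpha)  # A of defocus per px
    img <- series$images[[i]]
    F0 <- fft(img)
    edges <- seq(min(dist) - strip_px, max(dist) + strip_px, by = strip_px)
    acc <- matrix(0, ny, nx)
    wsum <- matrix(0, ny, nx)
    for (e in edges) {
      w <- pmax(1 - abs(dist - e) / strip_px, 0)  # linear blend, sums to 1
      if (!any(w > 0)) next
      df_um <- truth$defocus_um[i] + e * grad_A_per_px * 1e-4
      ctf <- ctf_model(df_um, truth$astigmatism_um, truth$astig_angle_deg,
                       optics, k2d, az)
      filt <- Re(fft(F0 * ctf, inverse = TRUE)) / (ny * nx)
      acc <- acc + w * filt
      wsum <- wsum + w
    }
    series$images[[i]] <- acc / pmax(wsum, 1e-12)
  }
  if (!is.na(dose_e_per_A2))
    series <- add_poisson_noise(series, dose_e_per_A2, seed = seed,
                                contrast = contrast)
  series
}

#' Occlude images with a simulated grid bar
#'
#' A contiguous band of rows entering from the image edge is set to
#' near-zero intensity with a little read noise, emulating a grid bar coming
#' into the field of view at high tilt.
#'
#' @param series a `tilt_series`.
#' @param indices images to occlude.
#' @param coverage_fraction fraction of rows covered, in (0, 1]; 0 is a
#'   no-op.
#' @param seed RNG seed for the residual noise.
#' @return the modified `tilt_series`.
#' @export
occlude_grid_bar <- function(series, indices, coverage_fraction, seed = 1) {
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in [0, 1]")
  if (coverage_fraction == 0) return(series)
  if (any(indices < 1 | indices > n_images(series)))
    stop("occlusion index out of range")
  ny <- nrow(series$images[[1]])
  n_cov <- max(1L, round(coverage_fraction * ny))
  rows <- seq.int(ny - n_cov + 1L, ny)
  with_seed(seed, {
    for (i in indices) {
      img <- series$images[[i]]
      lvl <- 0.01 * max(abs(img))
      img[rows, ] <- abs(rnorm(length(rows) * ncol(img), 0, lvl))
      series$images[[i]] <- img
    }
  })
  series
}

#' Simulate a tilt series for CTF determination
#'
#' The specimen is broadband (white-noise object, mildly low-pass
#' filtered), so the contrast transfer function's zeros are visible in the
#' power spectra; each image is filtered with the defocus-gradient CTF of
#' its tilt angle via [apply_ctf_and_noise()].
#'
#' @param seed RNG seed.
#' @param size image side in pixels.
#' @param angles_deg tilt angles (default 0..60 in 3-degree steps).
#' @param truth a [ground_truth()] carrying defocus and astigmatism;
#'   default constant 3 um defocus, no astigmatism.
#' @param pixel_size_A pixel size (default 4).
#' @param dose_e_per_A2 dose per image for Poisson noise; NA disables.
#' @param optics a [ctf_optics()].
#' @return list with `series` (CTF-filtered `tilt_series`) and `truth`.
#' @export
simulate_ctf_series <- function(seed = 1, size = 512,
                                angles_deg = seq(0, 60, by = 3),
                                truth = NULL, pixel_size_A = 4,
                                dose_e_per_A2 = 3,
                                optics = ctf_optics()) {
  n <- length(angles_deg)
  if (is.null(truth)) truth <- ground_truth(n, defocus_um = 3)
  with_seed(seed, {
    images <- lapply(seq_len(n), function(i) {
      obj <- matrix(rnorm(size * size), size, size)
      # mild low-pass so the object resembles projected density rather
      # than pure pixel noise
      k <- freq_grid(size, size)
      env <- exp(-((k$fx^2 + k$fy^2) / 0.16))
      Re(fft(fft(obj) * env, inverse = TRUE)) / size^2
    })
    series <- tilt_series(images, angles_deg, pixel_size_A = pixel_size_A,
                          applied_defocus_um = truth$defocus_um,
                          nominal_tilt_axis_deg = 0)
    series <- apply_ctf_and_noise(series, truth, dose_e_per_A2,
                                  seed = seed + 5000L, optics = optics)
    list(series = series, truth = truth)
  })
}

#' Construct a dose-fractionated movie stack
#' @param frames 3D array dim c(ny, nx, n_frames) of counts.
#' @param dose_per_frame_e_per_px expected electrons per pixel per frame.
#' @param pixel_size_A pixel size.
#' @return object of class `fraction_stack`.
#' @export
fraction_stack <- function(frames, dose_per_frame_e_per_px,
                           pixel_size_A = 1) {
  stopifnot(length(dim(frames)) == 3, dose_per_frame_e_per_px > 0,
            min(frames) >= 0)
  structure(list(frames = frames,
                 dose_per_frame_e_per_px = dose_per_frame_e_per_px,
                 pixel_size_A = pixel_size_A),
            class = "fraction_stack")
}

#' Simulate a drifting dose-fractionated movie
#'
#' Each frame is the reference image shifted by the cumulative drift,
#' scaled to the per-frame dose and Poisson sampled.
#'
#' @param image reference image (matrix); internally normalised to mean 1.
#' @param dose_per_frame_e_per_px expected electrons per pixel per frame.
#' @param n_frames frame count.
#' @param drift_path n_frames x 2 matrix of cumulative (dx, dy) shifts in
#'   pixels (first row conventionally 0, 0); `NULL` means no drift.
#' @param seed RNG seed.
#' @return a `fraction_stack`.
#' @export
simulate_fraction_stack <- function(image, dose_per_frame_e_per_px,
                                    n_frames, drift_path = NULL, seed = 1) {
  if (dose_per_frame_e_per_px <= 0) stop("dose must be positive")
  if (is.null(drift_path)) drift_path <- matrix(0, n_frames, 2)
  drift_path <- matrix(drift_path, ncol = 2)
  if (nrow(drift_path) != n_frames)
    stop("drift_path must have n_frames entries")
  ref <- image / mean(image)
  ny <- nrow(ref); nx <- ncol(ref)
  frames <- array(0, dim = c(ny, nx, n_frames))
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      sh <- drift_path[f, ]
      img <- if (all(sh == 0)) ref else
        warp_image(ref, shift = sh, fill = 1)
      lam <- pmax(dose_per_frame_e_per_px * img, 0)
      frames[, , f] <- rpois(length(lam), lam)
    }
  })
  fraction_stack(frames, dose_per_frame_e_per_px)
}
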