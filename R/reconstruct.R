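# SIRT reconstruction on a native ray-driven projector pair (exact
# adjoint), with automatic thickness determination from the per-plane
# contrast profile of a quick low-resolution reconstruction.

#' Reconstruction configuration
#' @param n_iterations SIRT iteration count.
#' @param relaxation relaxation factor in (0, 2).
#' @param binning final-stack binning factor.
#' @param x_tilt_deg static X tilt from tomogram positioning.
#' @param nonneg clip the volume to non-negative densities after each
#'   update (partially compensates the missing wedge).
#' @param backend projector backend (only `"native"` is built in).
#' @return list of class `reconstruction_config`.
#' @export
reconstruction_config <- function(n_iterations = 50, relaxation = 1.4,
                                  binning = 4, x_tilt_deg = 0,
                                  nonneg = TRUE, backend = "native") {
  stopifnot(n_iterations >= 0, relaxation > 0, relaxation < 2,
            binning >= 1)
  structure(list(n_iterations = n_iterations, relaxation = relaxation,
                 binning = binning, x_tilt_deg = x_tilt_deg,
                 nonneg = nonneg, backend = backend),
            class = "reconstruction_config")
}

#' Parallel-beam forward projection of a volume
#'
#' Line integrals about the volume Y axis at the given angles, with a
#' static X-tilt pre-rotation; the adjoint of [back_project()].
#'
#' @param volume 3D array dim c(nx, ny, nz).
#' @param angles_deg tilt angles.
#' @param x_tilt_deg static X tilt.
#' @return list of projection matrices dim c(ny, nx) (image convention,
#'   row = y).
#' @export
forward_project <- function(volume, angles_deg, x_tilt_deg = 0) {
  dims <- as.integer(dim(volume))
  lapply(angles_deg, function(a)
    t(.forward_project_cpp(as.numeric(volume), dims, a, x_tilt_deg)))
}

#' Back projection (adjoint of [forward_project()])
#'
#' @param projections list of matrices dim c(ny, nx).
#' @param angles_deg tilt angles matching `projections`.
#' @param vol_dim c(nx, ny, nz) of the output volume.
#' @param x_tilt_deg static X tilt.
#' @return 3D array dim `vol_dim`.
#' @export
back_project <- function(projections, angles_deg, vol_dim,
                         x_tilt_deg = 0) {
  vol_dim <- as.integer(vol_dim)
  acc <- array(0, dim = vol_dim)
  for (i in seq_along(angles_deg))
    acc <- acc + .back_project_cpp(t(projections[[i]]), vol_dim,
                                   angles_deg[i], x_tilt_deg)
  acc
}

#' SIRT reconstruction of an aligned tilt series
#'
#' Simultaneous iterative reconstruction:
#' `x <- x + relaxation * C * A^T R (b - A x)` with row (`R`) and column
#' (`C`) sum normalisers.  Iterations stop early with a warning if the
#' data residual grows three times in a row.
#'
#' @param aligned_stack list of aligned images (or a `tilt_series`
#'   restricted to usable images), axis vertical.
#' @param angles_deg corrected tilt angles, one per image.
#' @param config a [reconstruction_config()] (binning is NOT applied here;
#'   see [final_reconstruct()]).
#' @param thickness_voxels z extent of the reconstruction volume.
#' @return list of class `tomogram`: `volume` (nx, ny, nz),
#'   `voxel_size_A`, `thickness_voxels`, `residuals` per iteration,
#'   `angles_deg`, `x_tilt_deg`.
#' @export
sirt_reconstruct <- function(aligned_stack, angles_deg, config =
                               reconstruction_config(),
                             thickness_voxels = NULL,
                             voxel_size_A = 1) {
  if (inherits(aligned_stack, "tilt_series")) {
    keep <- which(aligned_stack$meta$usable)
    angles_deg <- aligned_stack$meta$tilt_angle_deg[keep]
    voxel_size_A <- aligned_stack$pixel_size_A
    aligned_stack <- aligned_stack$images[keep]
  }
  stopifnot(length(aligned_stack) == length(angles_deg))
  ny <- nrow(aligned_stack[[1]]); nx <- ncol(aligned_stack[[1]])
  if (is.null(thickness_voxels)) thickness_voxels <- round(0.75 * nx)
  dims <- c(nx, ny, as.integer(thickness_voxels))
  x <- array(0, dim = dims)
  bx <- config$x_tilt_deg
  # normalisers from the projector applied to ones
  ones_v <- array(1, dim = dims)
  Rn <- forward_project(ones_v, angles_deg, bx)
  Rn <- lapply(Rn, function(m) 1 / pmax(m, 1e-6))
  ones_p <- lapply(seq_along(angles_deg), function(i) matrix(1, ny, nx))
  Cn <- back_project(ones_p, angles_deg, dims, bx)
  Cn <- 1 / pmax(Cn, 1e-6)
  residuals <- numeric(0)
  grow <- 0L
  for (it in seq_len(config$n_iterations)) {
    fp <- forward_project(x, angles_deg, bx)
    diffs <- lapply(seq_along(fp), function(i)
      (aligned_stack[[i]] - fp[[i]]) * Rn[[i]])
    res <- sqrt(sum(vapply(seq_along(fp), function(i)
      sum((aligned_stack[[i]] - fp[[i]])^2), numeric(1))))
    residuals <- c(residuals, res)
    if (it > 1 && res > residuals[it - 1]) grow <- grow + 1L else grow <- 0L
    if (grow >= 3L) {
      warning("SIRT residual grew 3 consecutive iterations; stopping early")
      break
    }
    x <- x + config$relaxation * Cn * back_project(diffs, angles_deg,
                                                   dims, bx)
    if (isTRUE(config$nonneg)) x[x < 0] <- 0
  }
  structure(list(volume = x, voxel_size_A = voxel_size_A,
                 thickness_voxels = dims[3], residuals = residuals,
                 angles_deg = angles_deg, x_tilt_deg = bx),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("<tomogram> %dx%dx%d voxels, %.3f A/voxel, x-tilt %.2f deg\n",
              d[1], d[2], d[3], x$voxel_size_A, x$x_tilt_deg))
  invisible(x)
}

# plateau-with-tails model of the per-plane contrast profile: a top hat of
# width T convolved with a Gaussian of width sigma
plateau_model <- function(z, z0, T, sigma, amp, base) {
  base + amp * (pnorm((z - z0 + T / 2) / sigma) -
                  pnorm((z - z0 - T / 2) / sigma))
}

#' Estimate tomogram thickness from a quick reconstruction
#'
#' The aligned stack is binned to a small working size, reconstructed
#' with a short SIRT run over a generous z range, and the standard
#' deviation of
#' each XY plane is fitted with a plateau-with-Gaussian-tails profile whose
#' plateau width, rescaled to the input sampling, is the thickness.
#'
#' @param aligned_stack list of aligned images or a `tilt_series`.
#' @param angles_deg corrected tilt angles (ignored for a `tilt_series`).
#' @param x_tilt_deg static X tilt for the quick geometry.
#' @param quick_size target lateral size of the quick reconstruction.
#' @param n_iterations quick SIRT iterations.
#' @return list: `thickness_voxels` (at input sampling), `profile`,
#'   `fit` (coefficients), `fallback` (TRUE when the profile carried no
#'   plateau and Z/3 was returned).
#' @export
estimate_thickness <- function(aligned_stack, angles_deg = NULL,
                               x_tilt_deg = 0, quick_size = 128,
                               n_iterations = 12) {
  if (inherits(aligned_stack, "tilt_series")) {
    keep <- which(aligned_stack$meta$usable)
    angles_deg <- aligned_stack$meta$tilt_angle_deg[keep]
    x_tilt_deg <- aligned_stack$extra$x_tilt_deg %||% x_tilt_deg
    aligned_stack <- aligned_stack$images[keep]
  }
  nx <- ncol(aligned_stack[[1]])
  bin <- max(1, floor(nx / quick_size))
  imgs <- if (bin > 1) lapply(aligned_stack, bin_image, factor = bin)
          else aligned_stack
  # the contrast profile does not need full angular sampling: a 21-view
  # subset carries the same per-plane contrast at a fraction of the cost
  if (length(imgs) > 21) {
    keep_v <- round(seq(1, length(imgs), length.out = 21))
    imgs <- imgs[keep_v]
    angles_deg <- angles_deg[keep_v]
  }
  nzq <- round(0.95 * ncol(imgs[[1]]))
  tom <- sirt_reconstruct(imgs, angles_deg,
                          reconstruction_config(n_iterations = n_iterations,
                                                x_tilt_deg = x_tilt_deg),
                          thickness_voxels = nzq)
  prof_raw <- apply(tom$volume, 3, sd)
  prof <- stats::filter(prof_raw, rep(1 / 3, 3))
  prof[is.na(prof)] <- prof_raw[is.na(prof)]
  prof <- as.numeric(prof)
  z <- seq_along(prof)
  outer_z <- c(seq_len(max(2, nzq %/% 8)),
               seq.int(nzq - max(2, nzq %/% 8) + 1, nzq))
  base0 <- median(prof[outer_z])
  amp0 <- max(prof) - base0   # prof is already smoothed
  # a specimen-free stack has a nearly flat profile (the mild doming of
  # backprojection density stays well under half the baseline)
  if (amp0 < 0.5 * base0 || !is.finite(amp0)) {
    return(list(thickness_voxels = round(nzq / 3) * bin, profile = prof_raw,
                fit = NULL, fallback = TRUE))
  }
  # outermost crossings of a low threshold are robust to uneven specimen
  # density inside the slab; the Gaussian edge of the reconstruction PSF
  # pushes each crossing outward by ~ half the edge width
  thr <- base0 + 0.3 * amp0
  above <- which(prof > thr)
  T0 <- max(diff(range(above)) + 1 - 2, 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(prof ~ plateau_model(z, z0, T, sigma, amp, base),
                      start = list(z0 = mean(range(above)), T = T0,
                                   sigma = 2, amp = amp0, base = base0),
                      lower = c(1, 1, 0.5, 0, 0),
                      upper = c(nzq, nzq, 5, Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  co <- if (is.null(fit)) NULL else as.list(coef(fit))
  # keep the refinement unless it disagrees grossly with the crossing
  # width (thin slabs: the Gaussian edge inflates the crossing width, so
  # the fit is the better estimate there)
  T_est <- if (!is.null(co) && co$T > 0.5 * T0 && co$T < 1.5 * T0)
    co$T else T0
  list(thickness_voxels = round(T_est * bin), profile = prof_raw,
       fit = co, fallback = FALSE)
}

#' Final SIRT reconstruction at the export binning
#'
#' Bins the aligned stack (default 4x), adds a 10% margin to the estimated
#' thickness, applies the X-tilt geometry and runs SIRT.
#'
#' @param aligned_stack list of aligned images or a `tilt_series`
#'   (usable images only are used).
#' @param angles_deg corrected tilt angles.
#' @param x_tilt_deg static X tilt.
#' @param thickness thickness estimate in unbinned voxels.
#' @param config a [reconstruction_config()].
#' @param voxel_size_A unbinned pixel size.
#' @return a `tomogram` (voxel size = pixel size x binning).
#' @export
final_reconstruct <- function(aligned_stack, angles_deg = NULL,
                              x_tilt_deg = 0, thickness = NULL,
                              config = reconstruction_config(),
                              voxel_size_A = 1) {
  if (inherits(aligned_stack, "tilt_series")) {
    keep <- which(aligned_stack$meta$usable)
    angles_deg <- aligned_stack$meta$tilt_angle_deg[keep]
    x_tilt_deg <- aligned_stack$extra$x_tilt_deg %||% x_tilt_deg
    voxel_size_A <- aligned_stack$pixel_size_A
    aligned_stack <- aligned_stack$images[keep]
  }
  if (is.null(thickness))
    thickness <- estimate_thickness(aligned_stack, angles_deg,
                                    x_tilt_deg)$thickness_voxels
  b <- config$binning
  imgs <- if (b > 1) lapply(aligned_stack, bin_image, factor = b)
          else aligned_stack
  nz <- max(8L, round(thickness / b * 1.1))
  cfg <- config
  cfg$x_tilt_deg <- x_tilt_deg
  tom <- sirt_reconstruct(imgs, angles_deg, cfg, thickness_voxels = nz,
                          voxel_size_A = voxel_size_A * b)
  tom$thickness_voxels <- round(thickness / b)
  tom
}
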