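# Tomogram positioning: estimate the static X/Y inclination of the sample
# plane from feature flow across the coarse-aligned series.  Patch-averaged
# flow vectors are chained into trajectories, triangulated against the
# parallel-projection model, and a plane is fitted robustly; the Y tilt
# corrects the tilt angles, the X tilt is used by the reconstruction
# geometry.

#' Patch-averaged feature flow across a coarse-aligned series
#'
#' Flow between consecutive usable images is measured on a fine grid of
#' small windows (block matching by filtered cross-correlation) and
#' averaged per patch; patches whose sub-window vectors disagree beyond
#' `max_spread_px` are dropped for that pair.
#'
#' @param series coarse-aligned `tilt_series` (see
#'   [apply_pair_alignment()]).
#' @param grid patches per side (default 8; sub-windows are 2x per side).
#' @param working_bin binning for the flow computation.
#' @param max_spread_px maximum allowed standard deviation among a patch's
#'   sub-window vectors, in unbinned pixels.
#' @return list of class `patch_flow_field`: `centers` (patch centres in
#'   centred unbinned pixels), `pairs` (by-tilt index pairs), `flow` (array
#'   patches x pairs x 2, unbinned px, NA where dropped).
#' @export
dense_flow_track <- function(series, grid = 8, working_bin = NULL,
                             max_spread_px = 3, two_pass = TRUE) {
  use <- which(series$meta$usable)
  if (length(use) < 2) stop("need at least two usable images")
  d <- dim(series$images[[1]])
  if (is.null(working_bin)) working_bin <- max(1, floor(min(d) / 128))
  imgs <- lapply(use, function(i)
    if (working_bin > 1) bin_image(series$images[[i]], working_bin)
    else series$images[[i]])
  ny <- nrow(imgs[[1]]); nx <- ncol(imgs[[1]])
  sub <- 2L * grid  # sub-window grid (cells; windows overlap 4x)
  wy <- floor(ny / sub); wx <- floor(nx / sub)
  # window side, centred on each cell; floor of 48 px so extended features
  # still fit with room for the scoring annulus on small images
  win <- min(max(4L * min(wy, wx), 48L), 2L * (min(ny, nx) %/% 4L))
  half <- win %/% 2
  n_pairs <- length(use) - 1L
  flow_sub <- array(NA_real_, dim = c(sub, sub, n_pairs, 2))
  # actual (clamped) window centres; border windows sit further in than
  # their nominal cell centres and must be attributed where they measured
  cy_act <- vapply(seq_len(sub), function(r)
    min(max(round((r - 0.5) * wy), half + 1L), ny - half), numeric(1))
  cx_act <- vapply(seq_len(sub), function(c)
    min(max(round((c - 0.5) * wx), half + 1L), nx - half), numeric(1))
  # Hann taper: content near the window border (which drifts out between
  # tilts and would bias the correlation toward contraction) is
  # down-weighted before the FFT
  hw <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  taper <- outer(hw, hw)
  # cache per-image window FFTs; each pair reuses the previous image's
  window_ffts <- function(img) {
    out <- vector("list", sub * sub)
    k <- 0L
    for (r in seq_len(sub)) {
      rows <- (cy_act[r] - half + 1):(cy_act[r] - half + win)
      for (c in seq_len(sub)) {
        cols <- (cx_act[c] - half + 1):(cx_act[c] - half + win)
        k <- k + 1L
        w <- img[rows, cols]
        out[k] <- if (sd(w) < 1e-12) list(NULL) else
          list(fft((w - mean(w)) * taper))
      }
    }
    out
  }
  # skip windows touching regions filled in by the coarse rotation
  win_ok <- matrix(TRUE, sub, sub)
  cov <- series$extra$coverage
  if (!is.null(cov)) {
    covb <- if (working_bin > 1) bin_image(cov, working_bin) else cov
    for (r in seq_len(sub)) {
      rows <- (cy_act[r] - half + 1):(cy_act[r] - half + win)
      for (c in seq_len(sub)) {
        cols <- (cx_act[c] - half + 1):(cx_act[c] - half + win)
        win_ok[r, c] <- min(covb[rows, cols]) > 0.95
      }
    }
  }
  mask <- band_mask(win, win, 0, 0.5)
  measure <- function(Fa, Fb, gate) {
    fl <- array(NA_real_, dim = c(sub, sub, 2))
    k <- 0L
    for (r in seq_len(sub)) {
      for (c in seq_len(sub)) {
        k <- k + 1L
        if (!win_ok[r, c] || is.null(Fa[[k]]) || is.null(Fb[[k]])) next
        pk <- xc_peak(xc_surface(Conj(Fa[[k]]) * Fb[[k]], mask))
        if (pk$quality > PEAK_QUALITY_NULL &&
            abs(pk$dx) < gate && abs(pk$dy) < gate)
          fl[r, c, ] <- c(pk$dx, pk$dy)
      }
    }
    fl
  }
  # centred (x, y) of every sub-window, binned pixels
  wxm <- matrix(cx_act - (nx + 1) / 2, sub, sub, byrow = TRUE)
  wym <- matrix(cy_act - (ny + 1) / 2, sub, sub)
  Fa <- window_ffts(imgs[[1]])
  for (p in seq_len(n_pairs)) {
    Fb <- window_ffts(imgs[[p + 1]])
    fl1 <- measure(Fa, Fb, win / 4)
    # second pass: remove the fitted affine flow by warping image p+1 back,
    # then re-measure the (nearly zero, gradient-free) residual flow
    ok <- which(!is.na(fl1[, , 1]))
    if (two_pass && length(ok) >= 6) {
      A <- cbind(1, wxm[ok], wym[ok])
      axc <- qr.solve(A, fl1[, , 1][ok])
      ayc <- qr.solve(A, fl1[, , 2][ok])
      M <- rbind(c(1 + axc[2], axc[3]), c(ayc[2], ayc[3] + 1))
      bwd <- warp_affine(imgs[[p + 1]], solve(M),
                         -solve(M) %*% c(axc[1], ayc[1]))
      fl2 <- measure(Fa, window_ffts(bwd), win / 8)
      # total flow = affine prediction at the window + measured residual
      pred_x <- axc[1] + axc[2] * wxm + axc[3] * wym
      pred_y <- ayc[1] + ayc[2] * wxm + ayc[3] * wym
      flow_sub[, , p, 1] <- pred_x + fl2[, , 1]
      flow_sub[, , p, 2] <- pred_y + fl2[, , 2]
    } else {
      flow_sub[, , p, ] <- fl1
    }
    Fa <- Fb
  }
  centers <- matrix(NA_real_, grid * grid, 2)
  flow <- array(NA_real_, dim = c(grid * grid, n_pairs, 2))
  k <- 0L
  for (r in seq_len(grid)) {
    for (c in seq_len(grid)) {
      k <- k + 1L
      rs <- (2 * r - 1):(2 * r); cs <- (2 * c - 1):(2 * c)
      centers[k, ] <- c(mean(cx_act[cs]) - (nx + 1) / 2,
                        mean(cy_act[rs]) - (ny + 1) / 2) * working_bin
      for (p in seq_len(n_pairs)) {
        vx <- flow_sub[rs, cs, p, 1]; vy <- flow_sub[rs, cs, p, 2]
        if (sum(!is.na(vx)) >= 2 &&
            sd(vx, na.rm = TRUE) * working_bin <= max_spread_px &&
            sd(vy, na.rm = TRUE) * working_bin <= max_spread_px)
          flow[k, p, ] <- c(mean(vx, na.rm = TRUE),
                            mean(vy, na.rm = TRUE)) * working_bin
      }
    }
  }
  structure(list(centers = centers, pairs = cbind(use[-length(use)],
                                                  use[-1]),
                 flow = flow, working_bin = working_bin,
                 tilt_angle_deg = series$meta$tilt_angle_deg[use]),
            class = "patch_flow_field")
}

#' Triangulate 3D patch positions from the flow field
#'
#' The measured patch flows are Eulerian (sampled at fixed image windows),
#' while triangulation needs material trajectories.  Parallel projection of
#' a planar specimen makes the per-pair flow field exactly affine in image
#' position, so an affine flow model is fitted per image pair (least
#' squares over the patch vectors) and the maps are composed outward from
#' the zero-tilt image to carry each patch centre along with the material.
#' Each resulting trajectory is then inverted against the projection
#' equations `x_i = X cos(a_i) + Z sin(a_i)`, `y_i = Y` by least squares.
#' Trajectories spanning fewer than three tilts are dropped.
#'
#' @param flow a `patch_flow_field`.
#' @param tilt_angles optional replacement tilt angles (degrees), one per
#'   tracked image.
#' @return matrix with columns X, Y, Z (centred unbinned pixels), one row
#'   per surviving patch.
#' @export
triangulate_positions <- function(flow, tilt_angles = NULL) {
  ang <- deg2rad(tilt_angles %||% flow$tilt_angle_deg)
  n_img <- length(ang)
  i0 <- which.min(abs(ang))
  K <- nrow(flow$centers)
  n_pairs <- dim(flow$flow)[2]
  tmaps <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    ok <- which(!is.na(flow$flow[, p, 1]))
    if (length(ok) < 6) next
    A <- cbind(1, flow$centers[ok, 1], flow$centers[ok, 2])
    tmaps[[p]] <- list(ax = qr.solve(A, flow$flow[ok, p, 1]),
                       ay = qr.solve(A, flow$flow[ok, p, 2]))
  }
  pos <- array(NA_real_, dim = c(K, n_img, 2))
  pos[, i0, ] <- flow$centers
  if (i0 < n_img) for (p in seq.int(i0, n_img - 1)) {
    tm <- tmaps[[p]]
    if (is.null(tm)) break
    x <- pos[, p, 1]; y <- pos[, p, 2]
    pos[, p + 1, 1] <- x + tm$ax[1] + tm$ax[2] * x + tm$ax[3] * y
    pos[, p + 1, 2] <- y + tm$ay[1] + tm$ay[2] * x + tm$ay[3] * y
  }
  if (i0 > 1) for (p in seq.int(i0 - 1, 1)) {
    tm <- tmaps[[p]]
    if (is.null(tm)) break
    # invert the affine step: pos_p solves pos_{p+1} = pos_p + v(pos_p)
    M <- rbind(c(1 + tm$ax[2], tm$ax[3]), c(tm$ay[2], 1 + tm$ay[3]))
    rhs <- cbind(pos[, p + 1, 1] - tm$ax[1], pos[, p + 1, 2] - tm$ay[1])
    pos[, p, ] <- t(solve(M, t(rhs)))
  }
  pts <- matrix(NA_real_, K, 3)
  for (k in seq_len(K)) {
    okp <- which(!is.na(pos[k, , 1]))
    if (length(okp) < 3) next
    A <- cbind(cos(ang[okp]), sin(ang[okp]))
    xz <- qr.solve(A, pos[k, okp, 1])
    pts[k, ] <- c(xz[1], mean(pos[k, okp, 2]), xz[2])
  }
  pts[complete.cases(pts), , drop = FALSE]
}

#' Robust plane fit through triangulated points
#'
#' Least-squares plane `z = a x + b y + c` with iterated outlier rejection
#' (points beyond 3 robust standard deviations of the residuals are dropped
#' and the plane refitted until stable).  The sample inclinations follow
#' from the slopes as `y_tilt = -atan(a)` and `x_tilt = atan(b)`, signed so
#' that both are additive corrections: adding `y_tilt` to the nominal tilt
#' angles (and rotating the reconstruction geometry by `x_tilt` about X)
#' levels the sample.  Under this convention a cloud whose +X edge sits
#' lower in z has a positive `y_tilt`.
#'
#' @param points n x 3 matrix of (x, y, z).
#' @param max_iter maximum rejection iterations.
#' @return list of class `plane_fit`: `x_tilt_deg`, `y_tilt_deg`,
#'   `inlier_mask`, `rms_residual`, coefficients `abc`.
#' @export
fit_plane_robust <- function(points, max_iter = 10) {
  points <- matrix(points, ncol = 3)
  if (nrow(points) < 3) stop("need at least three points for a plane")
  inl <- rep(TRUE, nrow(points))
  abc <- c(0, 0, 0)
  for (it in seq_len(max_iter)) {
    A <- cbind(points[inl, 1], points[inl, 2], 1)
    if (qr(A)$rank < 3) stop("degenerate (collinear) point configuration")
    abc <- qr.solve(A, points[inl, 3])
    res <- points[, 3] - cbind(points[, 1], points[, 2], 1) %*% abc
    s <- max(mad(res[inl]), 1e-9)
    new_inl <- abs(res) <= 3 * s
    if (sum(new_inl) < 3) break
    if (identical(new_inl, inl)) break
    inl <- new_inl
  }
  res <- points[, 3] - cbind(points[, 1], points[, 2], 1) %*% abc
  structure(list(x_tilt_deg = rad2deg(atan(abc[2])),
                 y_tilt_deg = -rad2deg(atan(abc[1])),
                 inlier_mask = inl,
                 rms_residual = sqrt(mean(res[inl]^2)),
                 abc = abc), class = "plane_fit")
}

#' Apply the pre-tilt correction to a tilt series
#'
#' Adds the fitted Y tilt to every nominal tilt angle (so the corrected
#' zero-angle image is the one where the sample is horizontal) and stores
#' the X tilt on the series for the reconstruction geometry.
#'
#' @param series a `tilt_series`.
#' @param fit a `plane_fit`.
#' @return the corrected `tilt_series` (`extra$x_tilt_deg` set,
#'   `extra$horizontal_index` = image with corrected angle nearest zero).
#' @export
apply_pretilt_correction <- function(series, fit) {
  series$meta$tilt_angle_deg <- series$meta$tilt_angle_deg + fit$y_tilt_deg
  series$extra$x_tilt_deg <- fit$x_tilt_deg
  series$extra$y_tilt_applied_deg <- fit$y_tilt_deg
  series$extra$horizontal_index <- zero_tilt_index(series)
  series
}

# per-pair affine fits of the patch flow field: v ~ 1 + x + y
affine_flow_fits <- function(flow) {
  n_pairs <- dim(flow$flow)[2]
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    ok <- which(!is.na(flow$flow[, p, 1]))
    if (length(ok) < 6) next
    A <- cbind(1, flow$centers[ok, 1], flow$centers[ok, 2])
    out[[p]] <- list(ax = qr.solve(A, flow$flow[ok, p, 1]),
                     ay = qr.solve(A, flow$flow[ok, p, 2]),
                     n = length(ok))
  }
  out
}

# Refine pre-tilt angles from the per-pair flow gradients.  For a planar
# specimen the x-flow between effective tilts a_i, a_j obeys
#   dvx/dx = cos(a_j)/cos(a_i) - 1            (fixes the Y pre-tilt)
#   dvx/dy + dvy/dx = tan(bx) sin(a_j - a_i)/cos(a_i)   (fixes the X tilt)
# where the symmetrised cross-gradient cancels in-plane rotation residuals.
# These statistics are invariant to per-image shifts, so no trajectory
# chaining noise enters.
refine_pretilt_slopes <- function(flow, seed_y = 0) {
  fits <- affine_flow_fits(flow)
  ok <- which(!vapply(fits, is.null, logical(1)))
  if (length(ok) < 5) return(NULL)
  ang <- flow$tilt_angle_deg
  gx <- vapply(fits[ok], function(f) f$ax[2], numeric(1))
  gy <- vapply(fits[ok], function(f) f$ax[3] + f$ay[2], numeric(1))
  w <- vapply(fits[ok], function(f) f$n, numeric(1))
  a_i <- ang[ok]; a_j <- ang[ok + 1]
  obj <- function(by) {
    m <- cos(deg2rad(a_j + by)) / cos(deg2rad(a_i + by)) - 1
    sum(w * (gx - m)^2)
  }
  by <- optimize(obj, seed_y + c(-15, 15))$minimum
  s <- sin(deg2rad(a_j - a_i)) / cos(deg2rad(a_i + by))
  bx <- rad2deg(atan(sum(w * gy * s) / sum(w * s^2)))
  list(x_tilt_deg = bx, y_tilt_deg = by)
}

#' Estimate sample pre-tilt of a coarse-aligned series
#'
#' Flow tracking, triangulation and robust plane fitting, followed by a
#' slope-domain refinement that re-estimates both angles directly from the
#' per-pair flow gradients (immune to trajectory chaining noise and to
#' per-image shift/rotation residuals).  A known FIB pre-tilt in the series
#' metadata seeds the tilt angles and is folded into the reported Y tilt.
#'
#' @param series coarse-aligned `tilt_series`.
#' @param grid patch grid per side.
#' @return list with `fit` (`plane_fit`, angles refined), `points`, `flow`.
#' @export
estimate_pretilt <- function(series, grid = 8) {
  seed_y <- series$pre_tilt_deg
  flow <- dense_flow_track(series, grid = grid)
  pts <- triangulate_positions(flow, flow$tilt_angle_deg + seed_y)
  if (nrow(pts) < 3) stop("too few triangulated patches for a plane fit")
  fit <- fit_plane_robust(pts)
  fit$y_tilt_deg <- fit$y_tilt_deg + seed_y
  ref <- refine_pretilt_slopes(flow, seed_y)
  if (!is.null(ref)) {
    fit$x_tilt_deg <- ref$x_tilt_deg
    fit$y_tilt_deg <- ref$y_tilt_deg
  }
  list(fit = fit, points = pts, flow = flow)
}
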