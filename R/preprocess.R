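# Movie preprocessing: frame grouping to a target dose of one electron per
# pixel per fraction, then simplified patch-based drift correction (rigid
# per-fraction shifts from cross-correlation against a running average,
# refined by a 3x3 patch grid, resampled and summed without dose
# weighting).

#' Group movie frames into ~1 e-/px fractions
#'
#' Frames are grouped into consecutive blocks of
#' `g = max(1, round(1 / dose_per_frame))` and summed, so each fraction
#' carries an expected dose of about one electron per pixel; trailing
#' remainder frames fold into the last fraction.
#'
#' @param stack a `fraction_stack`.
#' @return a `fraction_stack` of grouped fractions
#'   (`dose_per_frame_e_per_px` updated to the per-fraction dose).
#' @export
group_frames <- function(stack) {
  stopifnot(inherits(stack, "fraction_stack"))
  dose <- stack$dose_per_frame_e_per_px
  if (is.null(dose) || is.na(dose))
    stop("dose_per_frame_e_per_px unknown; fix the movie metadata")
  g <- max(1L, as.integer(round(1 / dose)))
  nf <- dim(stack$frames)[3]
  n_out <- max(1L, nf %/% g)
  d <- dim(stack$frames)[1:2]
  out <- array(0, dim = c(d, n_out))
  for (k in seq_len(n_out)) {
    from <- (k - 1L) * g + 1L
    to <- if (k == n_out) nf else k * g
    block <- stack$frames[, , from:to, drop = FALSE]
    out[, , k] <- rowSums(block, dims = 2)
  }
  fraction_stack(out, dose * g, stack$pixel_size_A)
}

# bilinear gather used for the spatially varying (patch-interpolated) remap
remap_bilinear <- function(img, map_x, map_y, fill) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(map_x); y0 <- floor(map_y)
  fx <- map_x - x0; fy <- map_y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 < nx & y0 < ny
  x0c <- pmin(pmax(x0, 1L), nx - 1L); y0c <- pmin(pmax(y0, 1L), ny - 1L)
  i00 <- (x0c - 1) * ny + y0c
  v <- (1 - fy) * ((1 - fx) * img[i00] + fx * img[i00 + ny]) +
    fy * ((1 - fx) * img[i00 + 1] + fx * img[i00 + ny + 1])
  v[!ok] <- fill
  matrix(v, ny, nx)
}

#' Drift-correct a dose-fractionated movie
#'
#' Global per-fraction shifts are estimated by cross-correlation of each
#' fraction against a running average (two passes), then refined on a 3x3
#' patch grid; fractions are resampled with the bilinearly interpolated
#' local shift field and summed with no dose weighting.
#'
#' @param stack a `fraction_stack` with at least two fractions (group first
#'   with [group_frames()]).
#' @param max_passes refinement passes over the running average.
#' @return list with `corrected` (summed image) and `drift` (a drift model:
#'   `global_shift_per_frame` n x 2, `patch_shifts` 3 x 3 x n x 2,
#'   `interpolation`).
#' @export
correct_motion <- function(stack, max_passes = 2) {
  nf <- dim(stack$frames)[3]
  if (nf < 2) stop("need at least two fractions for drift correction")
  frames <- lapply(seq_len(nf), function(k) stack$frames[, , k])
  if (all(vapply(frames, sd, numeric(1)) < 1e-12))
    stop("all-constant frames: no signal to align")
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  sh <- matrix(0, nf, 2)
  band <- bandpass_params(0, 0.5)
  for (pass in seq_len(max_passes)) {
    ref <- Reduce(`+`, lapply(seq_len(nf), function(k)
      if (all(sh[k, ] == 0)) frames[[k]] else
        warp_image(frames[[k]], shift = -sh[k, ], fill = mean(frames[[k]]))))
    for (k in seq_len(nf)) {
      ps <- pair_shift(ref / nf, frames[[k]], band)
      sh[k, ] <- c(ps$dx, ps$dy)
    }
    sh <- sweep(sh, 2, sh[1, ])  # first-frame shift is (0,0) by convention
  }
  # 3x3 patch refinement against the globally corrected average
  corr_glob <- lapply(seq_len(nf), function(k)
    if (all(sh[k, ] == 0)) frames[[k]] else
      warp_image(frames[[k]], shift = -sh[k, ], fill = mean(frames[[k]])))
  ref <- Reduce(`+`, corr_glob) / nf
  py <- round(seq(1, ny + 1, length.out = 4)); px <- round(seq(1, nx + 1, length.out = 4))
  patch_sh <- array(0, dim = c(3, 3, nf, 2))
  cy <- numeric(3); cx <- numeric(3)
  for (a in 1:3) {
    for (b in 1:3) {
      rows <- py[a]:(py[a + 1] - 1); cols <- px[b]:(px[b + 1] - 1)
      cy[a] <- mean(rows); cx[b] <- mean(cols)
      rp <- ref[rows, cols]
      if (sd(rp) < 1e-12) next
      for (k in seq_len(nf)) {
        ps <- pair_shift(rp, corr_glob[[k]][rows, cols], band)
        # trust only small local refinements
        if (abs(ps$dx) <= 4 && abs(ps$dy) <= 4 &&
            ps$quality > PEAK_QUALITY_NULL)
          patch_sh[a, b, k, ] <- c(ps$dx, ps$dy)
      }
    }
  }
  # resample each fraction with global + interpolated local shifts
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  gy <- matrix(seq_len(ny), ny, nx)
  corrected <- matrix(0, ny, nx)
  for (k in seq_len(nf)) {
    dxf <- interp_grid3(patch_sh[, , k, 1], cx, cy, ny, nx) + sh[k, 1]
    dyf <- interp_grid3(patch_sh[, , k, 2], cx, cy, ny, nx) + sh[k, 2]
    corrected <- corrected +
      remap_bilinear(frames[[k]], gx + dxf, gy + dyf,
                     fill = mean(frames[[k]]))
  }
  drift <- list(global_shift_per_frame = sh, patch_shifts = patch_sh,
                interpolation = "bilinear")
  list(corrected = corrected, drift = drift)
}

# bilinear interpolation of a 3x3 value grid (centres cx, cy) to ny x nx
interp_grid3 <- function(vals, cx, cy, ny, nx) {
  fx <- approx(cx, 1:3, xout = pmin(pmax(seq_len(nx), cx[1]), cx[3]))$y
  fy <- approx(cy, 1:3, xout = pmin(pmax(seq_len(ny), cy[1]), cy[3]))$y
  x0 <- pmin(floor(fx), 2L); y0 <- pmin(floor(fy), 2L)
  wx <- fx - x0; wy <- fy - y0
  out <- matrix(0, ny, nx)
  for (a in 0:1) {
    vy <- if (a == 0) 1 - wy else wy
    for (b in 0:1) {
      vx <- if (b == 0) 1 - wx else wx
      out <- out + outer(vy, vx) * matrix(vals[cbind(rep(y0 + a, nx),
                                                     rep(x0 + b, each = ny))],
                                          ny, nx)
    }
  }
  out
}
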