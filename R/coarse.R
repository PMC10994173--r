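# Pair alignment: sequential cross-correlation from the zero-tilt image
# outward in a tilt-axis-vertical frame, with automatic bandpass tuning and
# skip-ahead over images that yield no robust peak.

#' Coarse pair alignment of a tilt series
#'
#' The stack is reordered by tilt and each image rotated so the nominal tilt
#' axis is vertical; pairwise shifts are then measured by filtered
#' cross-correlation walking outward from the zero-tilt image and
#' accumulated into per-image shifts relative to it.  A pair whose peak
#' quality falls below the noise-calibrated threshold marks the
#' farther-from-zero image non-usable and the walk re-pairs across it
#' (i with i+2, i+3, ...).
#'
#' @param series a `tilt_series` (any order; unusable images are skipped).
#' @param working_bin binning factor for the correlation images.
#' @param quality_threshold minimum robust peak quality; default is the
#'   stored 99th percentile of the noise null ([calibrate_peak_null()]).
#' @return list with `shift_table` (data frame: by-tilt index, acquisition
#'   index, tilt angle, cumulative dx/dy in unbinned pixels in the
#'   axis-vertical frame, peak quality), `usable` (updated flags, by-tilt
#'   order), `skipped_pairs`, `series` (the reordered series with flags
#'   applied), and `working_bin`.
#' @export
align_pairs <- function(series, working_bin = NULL,
                        quality_threshold = PEAK_QUALITY_NULL) {
  series <- reorder_by_tilt(series)
  d <- dim(series$images[[1]])
  if (is.null(working_bin))
    working_bin <- max(1, floor(min(d) / 128))
  axis <- series$nominal_tilt_axis_deg
  n <- n_images(series)
  rot <- vector("list", n)
  for (i in seq_len(n)) {
    img <- if (working_bin > 1) bin_image(series$images[[i]], working_bin)
           else series$images[[i]]
    rot[[i]] <- warp_image(img, rot_deg = -axis)
  }
  usable <- series$meta$usable
  anchor <- zero_tilt_index(series)
  shifts <- matrix(NA_real_, n, 2)
  quality <- rep(NA_real_, n)
  shifts[anchor, ] <- c(0, 0)
  quality[anchor] <- Inf
  skipped <- list()

  walk <- function(idx_seq) {
    ref <- anchor
    for (j in idx_seq) {
      if (!usable[j]) next
      band <- auto_bandpass(rot[[ref]], rot[[j]])
      if (band$peak_quality < quality_threshold) {
        usable[j] <<- FALSE
        skipped[[length(skipped) + 1L]] <<- c(ref, j)
        next  # re-pair ref with the next image out
      }
      ps <- pair_shift(rot[[ref]], rot[[j]], band)
      shifts[j, ] <<- shifts[ref, ] + c(ps$dx, ps$dy)
      quality[j] <<- band$peak_quality
      ref <- j
    }
  }
  up <- seq_len(n)[seq_len(n) > anchor]
  dn <- rev(seq_len(n)[seq_len(n) < anchor])
  walk(up)
  walk(dn)
  if (n > 1 && all(is.na(shifts[-anchor, 1])))
    stop("pair alignment failed: no robust peak against the zero-tilt image")
  series$meta$usable <- usable
  tab <- data.frame(
    index = seq_len(n),
    acquisition_index = series$meta$acquisition_index,
    tilt_angle_deg = series$meta$tilt_angle_deg,
    dx = shifts[, 1] * working_bin,
    dy = shifts[, 2] * working_bin,
    peak_quality = quality)
  list(shift_table = tab, usable = usable,
       skipped_pairs = skipped, series = series,
       working_bin = working_bin)
}

#' Apply coarse alignment (axis rotation plus pair shifts) to a series
#'
#' Each usable raw image is rotated by minus the nominal tilt-axis angle and
#' shifted by minus its cumulative pair shift in a single resampling,
#' producing the axis-vertical coarse-aligned stack used by positioning and
#' patch tracking.
#'
#' @param pair result of [align_pairs()].
#' @return a `tilt_series` (by-tilt order, unusable images carried along
#'   untouched but flagged).
#' @export
apply_pair_alignment <- function(pair) {
  series <- pair$series
  tab <- pair$shift_table
  axis <- series$nominal_tilt_axis_deg
  d <- dim(series$images[[1]])
  ones <- matrix(1, d[1], d[2])
  coverage <- ones
  for (i in seq_len(n_images(series))) {
    if (!series$meta$usable[i] || is.na(tab$dx[i])) next
    # feature motion: p' = R(-axis) p - shift
    th <- deg2rad(-axis)
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    b <- c(-tab$dx[i], -tab$dy[i])
    series$images[[i]] <- warp_affine(series$images[[i]], A, b)
    coverage <- pmin(coverage, warp_affine(ones, A, b, fill = 0))
  }
  series$extra$coarse_applied <- TRUE
  # pixels that came from inside every source image (no rotation fill)
  series$extra$coverage <- coverage
  series
}
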