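# Parameter-recovery harness: run the alignment chain on a simulated case
# and score the result against the injected ground truth.  Comparisons are
# gauge-aware: a reconstruction is unchanged by a global translation of the
# specimen and by a rotation about the tilt axis (which re-labels the
# specimen inclination), so those degrees of freedom are resolved by least
# squares before per-image errors are measured.

#' Run the alignment pipeline on one simulated case
#'
#' Generates a blob-specimen tilt series with randomly drawn truth
#' (shifts, rotations, tilt axis, pre-tilts), then runs coarse pair
#' alignment, tomogram positioning, two-pass patch tracking and the
#' projection-model solution.
#'
#' @param seed case seed.
#' @param size image side in pixels.
#' @param ... further arguments to [simulate_tilt_series()].
#' @return list with `case` (simulation), `pair`, `pos`, `trk`, `model`,
#'   and `series` (by-tilt, pre-tilt-corrected).
#' @export
run_alignment_case <- function(seed, size = 512, ...) {
  case <- simulate_tilt_series(seed = seed, size = size, ...)
  pair <- align_pairs(case$series)
  coarse <- apply_pair_alignment(pair)
  pos <- estimate_pretilt(coarse)
  series <- apply_pretilt_correction(pair$series, pos$fit)
  coarse <- apply_pretilt_correction(coarse, pos$fit)
  trk <- track_patches(coarse)
  model <- solve_alignment(trk, series$meta$tilt_angle_deg,
                           series$nominal_tilt_axis_deg)
  trk <- tryCatch(track_patches(coarse, model = model),
                  error = function(e) trk)
  model <- solve_alignment(trk, series$meta$tilt_angle_deg,
                           series$nominal_tilt_axis_deg)
  series$meta$usable <- trk$usable
  list(case = case, pair = pair, pos = pos, trk = trk, model = model,
       series = series)
}

#' Score an alignment result against the simulation truth
#'
#' Applies the solved composed alignment to the true recorded feature
#' positions and compares with ideal axis-vertical projections of the true
#' 3D features, after resolving the inherent gauge freedoms (one global
#' specimen translation and one rotation about the tilt axis).  The
#' per-image shift error is the translation component of the residual;
#' images that ended non-usable or carry fewer than two trajectory
#' observations are excluded (they are not part of the aligned output).
#'
#' @param res result of [run_alignment_case()].
#' @return list: `tilt_axis_err_deg` (solved axis minus truth axis plus
#'   mean injected rotation, which is indistinguishable from it),
#'   `pre_tilt_err_deg` (x, y), `shift_rms_px`, `shift_max_px`,
#'   `mean_residual_px`, `n_images_scored`.
#' @export
alignment_recovery_metrics <- function(res) {
  case <- res$case; pair <- res$pair; model <- res$model
  tr <- case$truth
  o <- order(case$series$meta$tilt_angle_deg,
             case$series$meta$acquisition_index)
  truth_o <- tr
  truth_o$per_image_shift_px <- tr$per_image_shift_px[o, , drop = FALSE]
  truth_o$per_image_rotation_deg <- tr$per_image_rotation_deg[o]
  ang_sorted <- case$series$meta$tilt_angle_deg[o]
  # a subsample of features is plenty for the translation-error metric
  pts <- case$points
  if (nrow(pts) > 300)
    pts <- pts[round(seq(1, nrow(pts), length.out = 300)), , drop = FALSE]
  case$points <- pts
  pp <- project_points(pts, ang_sorted, truth_o)
  nom <- case$series$nominal_tilt_axis_deg
  n <- length(ang_sorted)
  obs_n <- vapply(seq_len(n), function(i)
    sum(vapply(res$trk$trajectories,
               function(t) !is.na(t$pos[i, 1]), logical(1))), integer(1))
  keep <- which(res$series$meta$usable & obs_n >= 2)
  aligned_pos <- lapply(seq_len(n), function(i) {
    phi <- deg2rad(model$rotation_deg[i])
    ps <- c(pair$shift_table$dx[i], pair$shift_table$dy[i])
    t(rot2(-phi) %*% (rot2(-deg2rad(nom)) %*% t(pp[[i]]) - ps -
                        model$shift[i, ])) / model$scale
  })
  ang_corr <- res$series$meta$tilt_angle_deg
  Pm <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0))
  per_image_err <- function(delta) {
    bigA <- NULL; bigb <- NULL
    for (i in keep) {
      Pi <- Pm(deg2rad(ang_corr[i] + delta))
      d <- aligned_pos[[i]] - t(Pi %*% t(case$points))
      bigA <- rbind(bigA, Pi[rep(1:2, nrow(case$points)), ])
      bigb <- c(bigb, as.numeric(t(d)))
    }
    Tt <- qr.solve(bigA, bigb)
    vapply(keep, function(i) {
      Pi <- Pm(deg2rad(ang_corr[i] + delta))
      q_id <- t(Pi %*% (t(case$points) + Tt))
      sqrt(sum(colMeans(aligned_pos[[i]] - q_id)^2))
    }, numeric(1))
  }
  dopt <- optimize(function(d) sqrt(mean(per_image_err(d)^2)),
                   c(-3, 3), tol = 0.02)$minimum
  e <- per_image_err(dopt)
  list(
    tilt_axis_err_deg = model$tilt_axis_deg -
      (tr$tilt_axis_deg + mean(tr$per_image_rotation_deg)),
    pre_tilt_err_deg = c(res$pos$fit$x_tilt_deg - tr$pre_tilt_x_deg,
                         res$pos$fit$y_tilt_deg - tr$pre_tilt_y_deg),
    shift_rms_px = sqrt(mean(e^2)),
    shift_max_px = max(e),
    mean_residual_px = model$mean_residual_px,
    n_images_scored = length(keep))
}

#' Alignment parameter-recovery suite
#'
#' Runs [run_alignment_case()] over a set of seeds and pools the recovery
#' errors.
#'
#' @param seeds case seeds.
#' @param size image side in pixels.
#' @param ... passed to [simulate_tilt_series()].
#' @return data frame with one row per case plus pooled RMS statistics in
#'   `attr(, "summary")`.
#' @export
alignment_recovery_suite <- function(seeds, size = 512, ...) {
  rows <- lapply(seeds, function(s) {
    m <- alignment_recovery_metrics(run_alignment_case(s, size, ...))
    data.frame(seed = s, tilt_axis_err_deg = m$tilt_axis_err_deg,
               pre_tilt_x_err_deg = m$pre_tilt_err_deg[1],
               pre_tilt_y_err_deg = m$pre_tilt_err_deg[2],
               shift_rms_px = m$shift_rms_px,
               shift_max_px = m$shift_max_px,
               mean_residual_px = m$mean_residual_px)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    axis_rms_deg = sqrt(mean(out$tilt_axis_err_deg^2)),
    pre_tilt_rms_deg = sqrt(mean(c(out$pre_tilt_x_err_deg,
                                   out$pre_tilt_y_err_deg)^2)),
    shift_rms_px = sqrt(mean(out$shift_rms_px^2)))
  out
}
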