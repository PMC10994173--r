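# Fiducial-free fine alignment: patch tracking by cross-correlation against
# theoretical patch positions, then joint solution of the parallel
# projection model (global tilt-axis angle, per-image rotation/shift, global
# scale, free 3D marker positions) with Brent initialisation and 3-sigma
# trajectory pruning.

#' Patch-tracker configuration
#'
#' Defaults: 16 patches sized at 30% of the image dimensions, relocation
#' when the measured-minus-theoretical shift exceeds 2% of the image size,
#' 200 candidate subpatches with a used core of 2/3 of the patch surface,
#' and an image declared non-usable when more than 75% of its patches need
#' relocation.
#'
#' @param n_patches number of patches (a square count; 16 = 4x4).
#' @param patch_frac patch side as a fraction of each image dimension.
#' @param abnormal_shift_frac relocation threshold as a fraction of
#'   `max(width, height)`.
#' @param n_subpatches candidate subpatches for relocation.
#' @param used_core_frac fraction of the patch surface whose subpatches are
#'   marked used.
#' @param removal_frac relocation fraction above which a tilt image is
#'   dropped.
#' @param min_span minimum tilts per trajectory for the solver.
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(n_patches = 16, patch_frac = 0.30,
                           abnormal_shift_frac = 0.02, n_subpatches = 200,
                           used_core_frac = 2 / 3, removal_frac = 0.75,
                           min_span = 5) {
  stopifnot(n_patches >= 4, patch_frac > 0, patch_frac <= 1,
            abnormal_shift_frac > 0, removal_frac > 0, removal_frac <= 1)
  structure(list(n_patches = n_patches, patch_frac = patch_frac,
                 abnormal_shift_frac = abnormal_shift_frac,
                 n_subpatches = n_subpatches,
                 used_core_frac = used_core_frac,
                 removal_frac = removal_frac, min_span = min_span),
            class = "tracker_config")
}

#' Initial patch layout on the zero-tilt image
#'
#' Patch centres form a square grid symmetric about the image centre; each
#' patch side is `patch_frac` of the corresponding image dimension, so
#' neighbouring patches overlap.
#'
#' @param zero_tilt_image matrix (only its dimensions are used).
#' @param config a [tracker_config()].
#' @return data frame with `x`, `y` centres (1-based pixels) and `width`,
#'   `height` of the patches.
#' @export
init_patches <- function(zero_tilt_image, config = tracker_config()) {
  d <- dim(zero_tilt_image)
  ny <- d[1]; nx <- d[2]
  g <- round(sqrt(config$n_patches))
  stopifnot(g * g == config$n_patches)
  pw <- round(config$patch_frac * nx)
  ph <- round(config$patch_frac * ny)
  if (pw >= nx || ph >= ny) stop("patch larger than image")
  cx <- (seq_len(g) - (g + 1) / 2) * (nx / g) + (nx + 1) / 2
  cy <- (seq_len(g) - (g + 1) / 2) * (ny / g) + (ny + 1) / 2
  data.frame(x = rep(cx, each = g), y = rep(cy, times = g),
             width = pw, height = ph)
}

#' Theoretical in-plane shift of a sample-plane patch between two tilts
#'
#' For a feature on the (levelled) sample plane at x-coordinate `x` in an
#' axis-vertical image of width `w`, the expected x-displacement from tilt
#' `alpha_i` to `alpha_j` is `(x - w/2) * (cos(alpha_j)/cos(alpha_i) - 1)`;
#' features on the tilt axis do not move.
#'
#' @param x patch x-coordinate in pixels.
#' @param w image width in pixels.
#' @param alpha_i,alpha_j tilt angles in degrees.
#' @return expected dx in pixels.
#' @export
theoretical_shift <- function(x, w, alpha_i, alpha_j) {
  (x - w / 2) * (cos(deg2rad(alpha_j)) / cos(deg2rad(alpha_i)) - 1)
}

# clamp a patch window inside the image; returns integer centre
clamp_center <- function(c0, half, n) {
  round(min(max(c0, half + 1), n - half))
}

extract_patch <- function(img, cx, cy, pw, ph) {
  hx <- pw %/% 2; hy <- ph %/% 2
  img[(cy - hy):(cy + hy - 1 + pw %% 2),
      (cx - hx):(cx + hx - 1 + pw %% 2)]
}

#' Pick a new patch position from contrast-sorted subpatches
#'
#' The image is partitioned into `n_subpatches` rectangles (near-square
#' grid, 20 x 10 for the default 200); their contrast (local intensity
#' standard deviation) is sorted descending and the best subpatch not in
#' the used set is returned.
#'
#' @param image matrix.
#' @param used integer vector of used subpatch ids.
#' @param config a [tracker_config()].
#' @param contrast optional precomputed contrast table (internal cache).
#' @return list with `center` (x, y), `subpatch` id, and `n_subpatches`.
#' @name relocate_patch
NULL

# contrast (local standard deviation) and centres of the subpatch grid,
# computed in one vectorised pass
subpatch_contrast <- function(image, config = tracker_config()) {
  ny <- nrow(image); nx <- ncol(image)
  gx <- 2L * as.integer(round(sqrt(config$n_subpatches / 2)))  # 20 for 200
  gy <- as.integer(config$n_subpatches / gx)                   # 10 for 200
  fy <- ny %/% gy; fx <- nx %/% gx
  sub <- image[seq_len(gy * fy), seq_len(gx * fx), drop = FALSE]
  dim(sub) <- c(fy, gy, fx, gx)
  m1 <- colMeans(aperm(sub, c(1, 3, 2, 4)), dims = 2)   # gy x gx means
  m2 <- colMeans(aperm(sub, c(1, 3, 2, 4))^2, dims = 2)
  contrast <- sqrt(pmax(m2 - m1^2, 0))
  cent_x <- (seq_len(gx) - 0.5) * fx
  cent_y <- (seq_len(gy) - 0.5) * fy
  # ids are column-fastest within a row (x fastest), matching
  # core_subpatches()
  list(contrast = as.numeric(t(contrast)),
       centers = cbind(rep(cent_x, times = gy), rep(cent_y, each = gx)),
       n = gx * gy)
}

#' @rdname relocate_patch
#' @export
relocate_patch <- function(image, used = integer(0),
                           config = tracker_config(), contrast = NULL) {
  if (is.null(contrast)) contrast <- subpatch_contrast(image, config)
  ord <- order(contrast$contrast, decreasing = TRUE)
  ord <- ord[!(ord %in% used)]
  if (!length(ord)) stop("relocation exhausted: all subpatches used")
  list(center = contrast$centers[ord[1], ], subpatch = ord[1],
       n_subpatches = contrast$n)
}

# ids of subpatches covered by the central core (used_core_frac of the
# patch surface) of a patch centred at (cx, cy)
core_subpatches <- function(cx, cy, pw, ph, nx, ny, config) {
  gx <- 2L * as.integer(round(sqrt(config$n_subpatches / 2)))
  gy <- as.integer(config$n_subpatches / gx)
  f <- sqrt(config$used_core_frac)
  x1 <- cx - f * pw / 2; x2 <- cx + f * pw / 2
  y1 <- cy - f * ph / 2; y2 <- cy + f * ph / 2
  cols <- which((seq_len(gx) - 0.5) * nx / gx >= x1 &
                  (seq_len(gx) - 0.5) * nx / gx <= x2)
  rows <- which((seq_len(gy) - 0.5) * ny / gy >= y1 &
                  (seq_len(gy) - 0.5) * ny / gy <= y2)
  as.integer(outer(cols, (rows - 1L) * gx, "+"))
}

#' Track patches across a positioned, coarse-aligned tilt series
#'
#' Walks outward from the zero-tilt image correlating each patch with its
#' theoretically shifted position in the next usable image.  A patch whose
#' measured shift deviates from theory by more than the abnormal-shift
#' threshold (or whose correlation peak is not robust) is relocated to a
#' fresh high-contrast subpatch and a new trajectory is born; an image
#' where more than `removal_frac` of patches need relocation is flagged
#' non-usable and tracking continues across it.
#'
#' @param series coarse-aligned, pre-tilt-corrected `tilt_series` (by-tilt
#'   order).
#' @param config a [tracker_config()].
#' @param working_bin binning for the correlation work (default 2 for
#'   images larger than 256, else 1).
#' @param quality_threshold robust-peak threshold (see
#'   [calibrate_peak_null()]).
#' @param model optional `alignment_model` from a previous solve; when
#'   given, tracking runs model-guided: each next image is warped back by
#'   the predicted plane-to-plane affine map before correlation, so the
#'   measured residuals are small and free of the expansion/rotation
#'   gradients that otherwise attenuate patch displacements.
#' @return list of class `trajectory_set`: `trajectories` (list; each has
#'   `patch_id`, `birth`, `status` and an n x 2 `pos` matrix of centred
#'   unbinned positions, NA off-trajectory), `usable` updated flags,
#'   `series` with flags applied, `relocation_frac` per image.
#' @export
track_patches <- function(series, config = tracker_config(),
                          working_bin = NULL,
                          quality_threshold = PEAK_QUALITY_NULL,
                          model = NULL) {
  d <- dim(series$images[[1]])
  if (is.null(working_bin)) working_bin <- if (min(d) > 256) 2 else 1
  n <- n_images(series)
  imgs <- lapply(series$images, function(m)
    if (working_bin > 1) bin_image(m, working_bin) else m)
  ny <- nrow(imgs[[1]]); nx <- ncol(imgs[[1]])
  ang <- series$meta$tilt_angle_deg
  usable <- series$meta$usable
  anchor <- zero_tilt_index(series)
  cfgp <- init_patches(imgs[[anchor]], config)
  pw <- cfgp$width[1]; ph <- cfgp$height[1]
  # patches must not overlap regions filled in by the coarse rotation: a
  # static fill corner anchors the correlation and drags the whole solution
  cov <- series$extra$coverage
  covb <- if (is.null(cov)) matrix(1, ny, nx) else
    if (working_bin > 1) bin_image(cov, working_bin) else cov
  cov_ok <- function(cx, cy) {
    hx <- pw %/% 2; hy <- ph %/% 2
    mean(covb[(cy - hy):(cy + hy), (cx - hx):(cx + hx)]) > 0.98
  }
  # model-guided pass: predicted affine map of sample-plane content from
  # frame i to frame j (binned pixels):  p_j = M p_i + tau
  pred_map <- function(i, j) {
    ca_i <- cos(deg2rad(ang[i])); ca_j <- cos(deg2rad(ang[j]))
    Ri <- rot2(deg2rad(model$rotation_deg[i]))
    Rj <- rot2(deg2rad(model$rotation_deg[j]))
    M <- Rj %*% diag(c(ca_j / ca_i, 1)) %*% t(Ri)
    ti <- model$shift[i, ] / working_bin
    tj <- model$shift[j, ] / working_bin
    list(M = M, tau = as.numeric(tj - M %*% ti))
  }
  abn <- config$abnormal_shift_frac * max(nx, ny)
  n_traj <- nrow(cfgp)
  traj <- lapply(seq_len(n_traj), function(k)
    list(patch_id = k, birth = anchor, status = "active",
         pos = matrix(NA_real_, n, 2), band = NULL))
  for (k in seq_len(n_traj)) traj[[k]]$pos[anchor, ] <- c(cfgp$x[k],
                                                          cfgp$y[k])
  slot <- seq_len(n_traj)  # active trajectory per patch slot
  contrast_cache <- vector("list", n)
  get_contrast <- function(j) {
    if (is.null(contrast_cache[[j]]))
      contrast_cache[[j]] <<- subpatch_contrast(imgs[[j]], config)
    contrast_cache[[j]]
  }
  # subpatches occupied by the cores of the currently active patches
  occupied_now <- function(j) {
    out <- integer(0)
    for (s in slot) {
      p <- traj[[s]]$pos[j, ]
      if (any(is.na(p))) {
        ok <- which(!is.na(traj[[s]]$pos[, 1]))
        if (!length(ok)) next
        p <- traj[[s]]$pos[ok[which.min(abs(ok - j))], ]
      }
      out <- union(out, core_subpatches(p[1], p[2], pw, ph, nx, ny,
                                        config))
    }
    out
  }
  reloc_frac <- rep(0, n)

  track_dir <- function(idx_seq) {
    i <- anchor
    for (j in idx_seq) {
      if (!usable[j]) next
      need_reloc <- logical(length(slot))
      prop <- vector("list", length(slot))
      guided <- !is.null(model)
      if (guided) {
        pm <- pred_map(i, j)
        c0 <- c((nx + 1) / 2, (ny + 1) / 2)
        # warp frame j back into frame i's geometry (centred convention)
        bwd <- warp_affine(imgs[[j]], solve(pm$M),
                           -as.numeric(solve(pm$M) %*% pm$tau))
      }
      for (s in seq_along(slot)) {
        tk <- slot[s]
        p_i <- traj[[tk]]$pos[i, ]
        if (any(is.na(p_i))) { need_reloc[s] <- TRUE; next }
        if (guided) {
          cA <- c(clamp_center(p_i[1], pw / 2, nx),
                  clamp_center(p_i[2], ph / 2, ny))
          pj_pred <- as.numeric(pm$M %*% (p_i - c0)) + pm$tau + c0
          cBchk <- c(clamp_center(pj_pred[1], pw / 2, nx),
                     clamp_center(pj_pred[2], ph / 2, ny))
          if (!cov_ok(cA[1], cA[2]) || !cov_ok(cBchk[1], cBchk[2])) {
            need_reloc[s] <- TRUE
            next
          }
          A <- extract_patch(imgs[[i]], cA[1], cA[2], pw, ph)
          B <- extract_patch(bwd, cA[1], cA[2], pw, ph)
          if (is.null(traj[[tk]]$band))
            traj[[tk]]$band <<- auto_bandpass(A, B)
          ps <- pair_shift(A, B, traj[[tk]]$band)
          m <- c(ps$dx, ps$dy)
          p_j <- as.numeric(pm$M %*% (p_i + m - c0)) + pm$tau + c0
          dev <- sqrt(sum(m^2))
          if (ps$quality < quality_threshold || dev > abn) {
            need_reloc[s] <- TRUE
          } else {
            prop[[s]] <- p_j
          }
          next
        }
        dx_th <- theoretical_shift(p_i[1], nx, ang[i], ang[j])
        cA <- c(clamp_center(p_i[1], pw / 2, nx),
                clamp_center(p_i[2], ph / 2, ny))
        cB <- c(clamp_center(p_i[1] + dx_th, pw / 2, nx),
                clamp_center(p_i[2], ph / 2, ny))
        if (!cov_ok(cA[1], cA[2]) || !cov_ok(cB[1], cB[2])) {
          need_reloc[s] <- TRUE
          next
        }
        A <- extract_patch(imgs[[i]], cA[1], cA[2], pw, ph)
        B <- extract_patch(imgs[[j]], cB[1], cB[2], pw, ph)
        if (is.null(traj[[tk]]$band)) {
          bp <- auto_bandpass(A, B)
          traj[[tk]]$band <<- bp
        }
        ps <- pair_shift(A, B, traj[[tk]]$band)
        p_j <- p_i + (cB - cA) + c(ps$dx, ps$dy)
        dev <- sqrt((p_j[1] - p_i[1] - dx_th)^2 + (p_j[2] - p_i[2])^2)
        if (ps$quality < quality_threshold || dev > abn) {
          need_reloc[s] <- TRUE
        } else {
          prop[[s]] <- p_j
        }
      }
      frac <- mean(need_reloc)
      reloc_frac[j] <<- max(reloc_frac[j], frac)
      if (frac > config$removal_frac) {
        usable[j] <<- FALSE   # drop the image, keep patches where they are
        next
      }
      used_now <- occupied_now(j)
      for (s in seq_along(slot)) {
        tk <- slot[s]
        if (!need_reloc[s]) {
          traj[[tk]]$pos[j, ] <<- prop[[s]]
        } else {
          traj[[tk]]$status <<- "replaced"
          new_c <- NULL
          repeat {  # skip candidate subpatches in rotation-fill regions
            cand <- tryCatch(relocate_patch(imgs[[j]], used_now, config,
                                            contrast = get_contrast(j)),
                             error = function(e) NULL)
            if (is.null(cand)) break
            used_now <- union(used_now, cand$subpatch)
            cx <- clamp_center(cand$center[1], pw / 2, nx)
            cy <- clamp_center(cand$center[2], ph / 2, ny)
            if (cov_ok(cx, cy)) { new_c <- cand; break }
          }
          if (is.null(new_c)) next
          used_now <- union(used_now,
                            core_subpatches(new_c$center[1],
                                            new_c$center[2], pw, ph, nx,
                                            ny, config))
          nt <- list(patch_id = length(traj) + 1L, birth = j,
                     status = "active", pos = matrix(NA_real_, n, 2),
                     band = NULL)
          nt$pos[j, ] <- new_c$center
          traj[[length(traj) + 1L]] <<- nt
          slot[s] <<- length(traj)
        }
      }
      i <- j
    }
  }
  track_dir(seq_len(n)[seq_len(n) > anchor])
  slot <- seq_len(n_traj)  # restart slots from the seed patches downward
  track_dir(rev(seq_len(n)[seq_len(n) < anchor]))

  # convert to centred unbinned coordinates
  for (k in seq_along(traj)) {
    p <- traj[[k]]$pos
    traj[[k]]$pos <- cbind((p[, 1] - (nx + 1) / 2),
                           (p[, 2] - (ny + 1) / 2)) * working_bin
    traj[[k]]$band <- NULL
  }
  spans <- vapply(traj, function(t) sum(complete.cases(t$pos)), integer(1))
  keep <- spans >= config$min_span
  if (sum(keep) < 4)
    stop("insufficient trajectories: fewer than 4 span the series")
  series$meta$usable <- usable
  structure(list(trajectories = traj[keep], usable = usable,
                 series = series, relocation_frac = reloc_frac,
                 working_bin = working_bin),
            class = "trajectory_set")
}

# --- projection-model solver -------------------------------------------

rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

# stack trajectory positions into obs[k, i, 2] with NA gaps
traj_matrix <- function(trajectories, n) {
  K <- length(trajectories)
  obs <- array(NA_real_, dim = c(K, n, 2))
  for (k in seq_len(K)) obs[k, , ] <- trajectories[[k]]$pos
  obs
}

# 2x3 parallel-projection matrices at the given tilt angles with a static
# X-tilt pre-rotation (beta); beta = 0 reduces to [cos a, 0, sin a; 0 1 0]
proj_mats <- function(ang, beta) {
  cb <- cos(beta); sb <- sin(beta)
  lapply(ang, function(a)
    rbind(c(cos(a), sin(a) * sb, sin(a) * cb), c(0, cb, -sb)))
}

solve_markers <- function(obs, P, phi, tvec, s) {
  K <- dim(obs)[1]
  X <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    ok <- which(!is.na(obs[k, , 1]))
    A <- do.call(rbind, P[ok])
    u <- vapply(ok, function(i)
      (t(rot2(phi[i])) %*% (obs[k, i, ] - tvec[i, ]) / s)[, 1], numeric(2))
    X[k, ] <- qr.solve(A, as.numeric(u))
  }
  X
}

predict_obs <- function(X, P, phi, tvec, s) {
  K <- nrow(X); n <- length(P)
  pred <- array(NA_real_, dim = c(K, n, 2))
  for (i in seq_len(n)) {
    q <- X %*% t(P[[i]])
    pred[, i, ] <- s * q %*% t(rot2(phi[i])) +
      matrix(tvec[i, ], K, 2, byrow = TRUE)
  }
  pred
}

mean_residual <- function(obs, pred) {
  d <- sqrt((obs[, , 1] - pred[, , 1])^2 + (obs[, , 2] - pred[, , 2])^2)
  mean(d, na.rm = TRUE)
}

solve_images <- function(obs, X, P, phi, tvec, s, update_rot = TRUE) {
  n <- length(P)
  for (i in seq_len(n)) {
    ok <- which(!is.na(obs[, i, 1]))
    if (length(ok) < 2) next
    q <- X[ok, , drop = FALSE] %*% t(P[[i]])
    p <- obs[ok, i, ]
    qm <- colMeans(q); pm <- colMeans(p)
    qc <- sweep(q, 2, qm); pc <- sweep(p, 2, pm)
    if (update_rot) {
      M <- t(qc) %*% pc
      phi[i] <- atan2(M[1, 2] - M[2, 1], M[1, 1] + M[2, 2])
    }
    tvec[i, ] <- pm - s * (rot2(phi[i]) %*% qm)[, 1]
  }
  list(phi = phi, tvec = tvec)
}

solve_scale <- function(obs, X, P, phi, tvec) {
  num <- 0; den <- 0
  n <- length(P)
  for (i in seq_len(n)) {
    ok <- which(!is.na(obs[, i, 1]))
    if (length(ok) < 2) next
    q <- X[ok, , drop = FALSE] %*% t(P[[i]])
    rq <- q %*% t(rot2(phi[i]))
    p <- sweep(obs[ok, i, ], 2, tvec[i, ])
    num <- num + sum(p * rq)
    den <- den + sum(rq^2)
  }
  min(max(num / den, 0.9), 1.1)
}

# NB: a single global magnification is gauge-degenerate with the marker
# radii (P(a)(sX) = s P(a)X), so the solver keeps scale = 1 unless asked;
# "scale" remains in the model for the per-image option and the exporters.
inner_solve <- function(obs, P, phi0, iters, update_rot = TRUE,
                        update_scale = FALSE, tol = 1e-4) {
  n <- length(P)
  phi <- phi0
  tvec <- matrix(0, n, 2)
  s <- 1
  last <- Inf
  for (it in seq_len(iters)) {
    X <- solve_markers(obs, P, phi, tvec, s)
    X <- sweep(X, 2, colMeans(X))  # centroid gauge
    up <- solve_images(obs, X, P, phi, tvec, s, update_rot)
    phi <- up$phi; tvec <- up$tvec
    if (update_scale) s <- solve_scale(obs, X, P, phi, tvec)
    res <- mean_residual(obs, predict_obs(X, P, phi, tvec, s))
    if (is.finite(last) && abs(last - res) / max(res, 1e-12) < tol) {
      last <- res
      break
    }
    last <- res
  }
  X <- solve_markers(obs, P, phi, tvec, s)
  X <- sweep(X, 2, colMeans(X))
  list(X = X, phi = phi, tvec = tvec, s = s, residual = last)
}

#' Solve the projection-model alignment from patch trajectories
#'
#' Fits the parallel-projection imaging model: the position of 3D marker k
#' on image i is `scale * R(rot_i) * [cos(a_i) X_k + sin(a_i) Z_k, Y_k] +
#' shift_i`, with tilt angles held fixed.  Three stages: (1) Brent scalar
#' search for the global tilt-axis offset (few inner iterations per
#' evaluation); (2) blockwise alternation (markers / per-image rotation and
#' shift / global scale) to convergence on the mean residual; (3) repeated
#' removal of trajectories whose residual exceeds three standard deviations,
#' refitting until stable.
#'
#' @param trajectories a `trajectory_set` or its `trajectories` list.
#' @param tilt_angles corrected tilt angles (degrees), one per image.
#' @param nominal_tilt_axis_deg the axis angle already removed from the
#'   tracked frame (reported axis = nominal + solved offset).
#' @param x_tilt_deg static sample X tilt from tomogram positioning,
#'   included in the projection geometry (its Y coupling otherwise leaks
#'   into the solved axis over an asymmetric tilt range).
#' @param axis_bracket_deg half-width of the Brent search bracket.
#' @param max_iter outer alternation cap.
#' @return list of class `alignment_model`: `tilt_axis_deg`, per-image
#'   `rotation_deg`, `shift` (n x 2), `scale`, `mean_residual_px`,
#'   `residual_sigma_px`, `markers`, `kept` (trajectory indices),
#'   `converged`.
#' @export
solve_alignment <- function(trajectories, tilt_angles,
                            nominal_tilt_axis_deg = 0, x_tilt_deg = 0,
                            axis_bracket_deg = 10, max_iter = 50) {
  trs <- if (inherits(trajectories, "trajectory_set"))
    trajectories$trajectories else trajectories
  n <- length(tilt_angles)
  if (length(trs) < 4) stop("need at least 4 trajectories")
  obs <- traj_matrix(trs, n)
  ang <- deg2rad(tilt_angles)
  P <- proj_mats(ang, deg2rad(x_tilt_deg))
  spread <- apply(obs[, , 1], 1, function(v) diff(range(v, na.rm = TRUE)))
  if (all(spread < 1e-6))
    stop("degenerate geometry: all markers coplanar with the tilt axis")
  # (1) tilt-axis offset by Brent search, few inner iterations
  f <- function(delta) inner_solve(obs, P, rep(deg2rad(delta), n),
                                   iters = 5, update_rot = FALSE,
                                   update_scale = FALSE)$residual
  br <- optimize(f, c(-axis_bracket_deg, axis_bracket_deg))
  delta0 <- br$minimum
  # (2) full alternation with per-image rotations free
  fit <- inner_solve(obs, P, rep(deg2rad(delta0), n), iters = max_iter)
  # The objective is nearly flat along a joint rotation of the marker
  # cloud against the per-image rotations (phi_i ~ gamma cos a_i); block
  # alternation stalls there, so the valley is resolved by an explicit
  # line search.
  ca <- cos(ang)
  gscan <- function(g) inner_solve(obs, P, fit$phi - g * ca,
                                   iters = 10)$residual
  gopt <- optimize(gscan, deg2rad(c(-2, 2)))$minimum
  if (abs(gopt) > 1e-6) {
    fit2 <- inner_solve(obs, P, fit$phi - gopt * ca, iters = max_iter)
    if (fit2$residual <= fit$residual) fit <- fit2
  }
  # (3) 3-sigma trajectory pruning
  kept <- seq_along(trs)
  converged <- TRUE
  pruning_residuals <- fit$residual
  repeat {
    pred <- predict_obs(fit$X, P, fit$phi, fit$tvec, fit$s)
    rk2 <- (obs[, , 1] - pred[, , 1])^2 + (obs[, , 2] - pred[, , 2])^2
    traj_res <- sqrt(rowMeans(rk2, na.rm = TRUE))
    # mean + 3 sd, with the worst trajectory excluded from the statistics
    # so a single gross outlier cannot mask itself
    ref <- traj_res[-which.max(traj_res)]
    thr <- mean(ref) + 3 * sd(ref)
    bad <- which(traj_res > thr)
    if (!length(bad) || length(kept) - length(bad) < 4) break
    kept <- kept[-bad]
    obs <- traj_matrix(trs[kept], n)
    fit2 <- inner_solve(obs, P, fit$phi, iters = max_iter)
    if (fit2$residual > fit$residual + 1e-9) { converged <- FALSE; break }
    fit <- fit2
    pruning_residuals <- c(pruning_residuals, fit$residual)
  }
  pred <- predict_obs(fit$X, P, fit$phi, fit$tvec, fit$s)
  d <- sqrt((obs[, , 1] - pred[, , 1])^2 + (obs[, , 2] - pred[, , 2])^2)
  structure(list(
    tilt_axis_deg = nominal_tilt_axis_deg + rad2deg(mean(fit$phi)),
    rotation_deg = rad2deg(fit$phi),
    shift = fit$tvec,
    scale = fit$s,
    mean_residual_px = mean(d, na.rm = TRUE),
    residual_sigma_px = sd(d, na.rm = TRUE),
    markers = fit$X,
    kept = kept,
    pruning_residuals = pruning_residuals,
    converged = converged), class = "alignment_model")
}

#' Apply the solved alignment to the raw tilt series
#'
#' Composes, per usable image, the coarse axis rotation and pair shift with
#' the solved rotation/scale/shift into a single affine transform and
#' resamples the raw image once (single-interpolation path).
#'
#' @param raw_series the original `tilt_series` (by-tilt order or
#'   reorderable).
#' @param model an `alignment_model`.
#' @param shift_table the `shift_table` from [align_pairs()] (cumulative
#'   coarse shifts, unbinned px, axis-vertical frame).
#' @return aligned `tilt_series` (axis vertical; unusable images carried
#'   but flagged).
#' @export
apply_alignment <- function(raw_series, model, shift_table = NULL) {
  series <- reorder_by_tilt(raw_series)
  n <- n_images(series)
  nominal <- series$nominal_tilt_axis_deg
  for (i in seq_len(n)) {
    if (!series$meta$usable[i]) next
    ps <- if (is.null(shift_table)) c(0, 0) else
      c(shift_table$dx[i], shift_table$dy[i])
    if (any(is.na(ps))) next
    phi <- deg2rad(model$rotation_deg[i])
    tv <- model$shift[i, ]
    # aligned = R(-phi) (R(-nominal) raw - ps - t) / s
    A <- t(rot2(phi + deg2rad(nominal))) / model$scale
    b <- -(t(rot2(phi)) %*% (ps + tv)) / model$scale
    series$images[[i]] <- warp_affine(series$images[[i]], A, b)
  }
  series$extra$aligned <- TRUE
  series
}
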