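test_that("patch initialisation follows the configured geometry", {
  img <- matrix(0, 4096, 4096)
  p <- init_patches(img)
  expect_equal(nrow(p), 16)
  expect_equal(p$width[1], round(0.30 * 4096))  # 1229 px
  # 4x4 grid symmetric about the image centre
  expect_equal(sort(unique(p$x)) + rev(sort(unique(p$x))),
               rep(2 * (4096 + 1) / 2, 4))
  expect_equal(length(unique(p$x)), 4)
  p2 <- init_patches(matrix(0, 100, 100))
  expect_equal(p2$width[1], 30)
  expect_error(init_patches(matrix(0, 10, 10),
                            tracker_config(patch_frac = 1)), "larger")
})

test_that("theoretical shifts follow the projection geometry", {
  expect_equal(theoretical_shift(2048, 4096, -30, 17), 0)  # on the axis
  expect_equal(theoretical_shift(3000, 4096, 25, 25), 0)   # same angle
  expect_equal(theoretical_shift(3072, 4096, 0, 3),
               1024 * (cos(deg2rad(3)) - 1), tolerance = 1e-9)
  expect_equal(1024 * (cos(deg2rad(3)) - 1), -1.40, tolerance = 0.01)
})

test_that("relocation picks contrast and never reuses a subpatch", {
  img <- matrix(rnorm(200 * 400, 0, 0.01), 200, 400)
  img[11:30, 361:392] <- rnorm(20 * 32, 0, 5)  # top-right contrast blob
  r1 <- relocate_patch(img)
  expect_equal(r1$n_subpatches, 200)
  expect_gt(r1$center[1], 340)
  expect_lt(r1$center[2], 45)
  r2 <- relocate_patch(img, used = r1$subpatch)
  expect_false(r2$subpatch == r1$subpatch)
  expect_error(relocate_patch(img, used = 1:200), "exhausted")
})

test_that("tracking a clean rigid series keeps all seed patches", {
  case <- small_clean_series()
  s <- reorder_by_tilt(case$series)
  trk <- track_patches(s)
  expect_true(all(trk$usable))
  seeds <- Filter(function(t) t$patch_id <= 16, trk$trajectories)
  seed_spans <- vapply(seeds, function(t) sum(complete.cases(t$pos)),
                       integer(1))
  # most seed trajectories survive the full series
  expect_gt(mean(seed_spans >= 15), 0.6)
  # tracked positions match projected truth to ~1 px
  ang <- s$meta$tilt_angle_deg
  errs <- c()
  for (tk in seeds[seq_len(min(8, length(seeds)))]) {
    ok <- which(!is.na(tk$pos[, 1]))
    if (length(ok) < 10) next
    i0 <- ok[which.min(abs(ang[ok]))]
    # a sample-plane point at the anchor position should follow x0 cos a
    x0 <- tk$pos[i0, 1] / cos(deg2rad(ang[i0]))
    errs <- c(errs, tk$pos[ok, 1] - x0 * cos(deg2rad(ang[ok])))
  }
  expect_lt(sqrt(mean(errs^2)), 3)
})

test_that("an image of pure noise is flagged by the 75% relocation rule", {
  case <- small_clean_series()
  s <- reorder_by_tilt(case$series)
  bad <- 5
  s$images[[bad]] <- matrix(rnorm(128 * 128), 128)
  trk <- track_patches(s)
  expect_false(trk$usable[bad])
  expect_gt(trk$relocation_frac[bad], 0.75)
})

test_that("the solver recovers a synthetic projection model exactly", {
  set.seed(11)
  n <- 31
  ang <- seq(-60, 60, by = 4)
  axis_true <- 85.4
  rot_true <- runif(n, -1.5, 1.5)
  sh_true <- cbind(runif(n, -12, 12), runif(n, -12, 12))
  X <- cbind(runif(12, -150, 150), runif(12, -150, 150),
             runif(12, -40, 40))
  phi <- deg2rad(axis_true - 85 + rot_true)
  trajs <- lapply(seq_len(12), function(k) {
    pos <- t(vapply(seq_len(n), function(i) {
      q <- c(cos(deg2rad(ang[i])) * X[k, 1] + sin(deg2rad(ang[i])) * X[k, 3],
             X[k, 2])
      c(cos(phi[i]) * q[1] - sin(phi[i]) * q[2],
        sin(phi[i]) * q[1] + cos(phi[i]) * q[2]) + sh_true[i, ]
    }, numeric(2)))
    list(patch_id = k, birth = 16, status = "active", pos = pos)
  })
  model <- solve_alignment(trajs, ang, nominal_tilt_axis_deg = 85)
  expect_lt(abs(model$tilt_axis_deg - (axis_true + mean(rot_true))), 0.1)
  expect_lt(model$mean_residual_px, 0.05)
  # per-image shifts match up to the 3D translation gauge of the marker
  # cloud: d_i = shift_i - true_i follows R(phi_i) P(a_i) C for one C
  derr <- model$shift - sh_true
  bigA <- NULL
  for (i in seq_len(n)) {
    Pi <- rbind(c(cos(deg2rad(ang[i])), 0, sin(deg2rad(ang[i]))),
                c(0, 1, 0))
    bigA <- rbind(bigA, tiltflow:::rot2(deg2rad(model$rotation_deg[i])) %*% Pi)
  }
  C <- qr.solve(bigA, as.numeric(t(derr)))
  resid <- matrix(as.numeric(t(derr)) - bigA %*% C, ncol = 2, byrow = TRUE)
  expect_lt(max(abs(resid)), 0.6)
})

test_that("a corrupted trajectory is pruned without moving the model", {
  set.seed(12)
  n <- 31
  ang <- seq(-60, 60, by = 4)
  X <- cbind(runif(10, -150, 150), runif(10, -150, 150),
             runif(10, -40, 40))
  make_traj <- function(k, noise = 0) {
    pos <- t(vapply(seq_len(n), function(i) {
      c(cos(deg2rad(ang[i])) * X[k, 1] + sin(deg2rad(ang[i])) * X[k, 3],
        X[k, 2]) + rnorm(2, 0, noise)
    }, numeric(2)))
    list(patch_id = k, birth = 16, status = "active", pos = pos)
  }
  trajs <- lapply(1:10, make_traj, noise = 0.05)
  clean <- solve_alignment(trajs, ang)
  walk <- make_traj(1)
  walk$pos <- walk$pos + cbind(cumsum(rnorm(n, 0, 3)),
                               cumsum(rnorm(n, 0, 3)))
  with_bad <- solve_alignment(c(trajs, list(walk)), ang)
  expect_lt(length(with_bad$kept), 11)   # the walker was pruned
  expect_lt(abs(with_bad$tilt_axis_deg - clean$tilt_axis_deg), 0.1)
  expect_lt(abs(with_bad$mean_residual_px - clean$mean_residual_px), 0.2)
})

test_that("identity model leaves the raw stack unchanged away from edges", {
  case <- small_clean_series()
  s <- reorder_by_tilt(case$series)
  n <- n_images(s)
  model <- structure(list(tilt_axis_deg = 0, rotation_deg = rep(0, n),
                          shift = matrix(0, n, 2), scale = 1,
                          mean_residual_px = 0, residual_sigma_px = 0),
                     class = "alignment_model")
  out <- apply_alignment(s, model)
  core <- 20:108
  expect_close(out$images[[3]][core, core], s$images[[3]][core, core],
               tol = 1e-9)
})

test_that("composed single-warp transform matches two sequential warps", {
  img <- bin_image(matrix(rnorm(512 * 512), 512), 2)
  rot <- 4; sh1 <- c(6.3, -2.7); sh2 <- c(-1.6, 4.9)
  two_step <- warp_image(warp_image(img, rot_deg = rot, shift = sh1),
                         shift = sh2)
  A <- tiltflow:::rot2(deg2rad(rot))
  one_step <- warp_affine(img, A, b = sh1 + sh2)
  core <- 40:216
  # single interpolation agrees with the double-interpolated control
  expect_lt(median(abs(one_step[core, core] - two_step[core, core])), 0.1)
  # ... and keeps more high-frequency power
  hf <- function(m) {
    sp <- Mod(fft(m - mean(m)))^2
    fg <- tiltflow:::freq_grid(nrow(m), ncol(m))
    sum(sp[sqrt(fg$fx^2 + fg$fy^2) > 0.3])
  }
  expect_gt(hf(one_step[core, core]), hf(two_step[core, core]))
})
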