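test_that("generators are reproducible for a fixed seed", {
  a <- make_phantom(phantom_spec(c(32, 32, 32), 12, 10, seed = 7))
  b <- make_phantom(phantom_spec(c(32, 32, 32), 12, 10, seed = 7))
  expect_identical(a, b)
  s1 <- simulate_tilt_series(seed = 3, size = 64, n_blobs = 50,
                             angles_deg = c(-30, 0, 30))
  s2 <- simulate_tilt_series(seed = 3, size = 64, n_blobs = 50,
                             angles_deg = c(-30, 0, 30))
  expect_identical(s1$series$images, s2$series$images)
  expect_identical(s1$truth, s2$truth)
})

test_that("phantom support is confined to the slab", {
  spec <- phantom_spec(c(48, 48, 128), slab_thickness_voxels = 40,
                       n_features = 15, seed = 2)
  vol <- make_phantom(spec)
  zmass <- apply(vol, 3, sum)
  expect_equal(sum(zmass > 0), 40)  # the 40-voxel slab band
  empty <- make_phantom(phantom_spec(c(32, 32, 32), 12, 0, seed = 1,
                                     texture_sd = 0, background = 0.2))
  expect_true(all(empty[, , 11:22] == 0.2))
  expect_true(all(empty[, , c(1:10, 23:32)] == 0))
})

test_that("dose-symmetric scheme alternates sides in groups of two", {
  sch <- dose_symmetric_scheme(60, 3, 2)
  expect_length(sch, 41)
  expect_equal(sch[1:7], c(0, 3, -3, -6, 6, 9, -9))
  expect_setequal(sch, seq(-60, 60, by = 3))
})

test_that("point projection matches analytic geometry and the voxel projector", {
  # point at (7.5, -0.5, 11.5) voxels from centre, 30 degree tilt
  vol <- array(0, dim = c(64, 64, 64))
  vol[40, 32, 44] <- 1
  tr <- ground_truth(1)
  s <- project_tilt_series(vol, 30, tr)
  idx <- arrayInd(which.max(s$images[[1]]), dim(s$images[[1]]))
  analytic <- project_points(c(7.5, -0.5, 11.5), 30, tr)[[1]]
  expect_equal(analytic[1], 7.5 * cos(pi / 6) + 11.5 * sin(pi / 6))
  expect_lt(abs((idx[2] - 1 - 31.5) - analytic[1]), 1)
  expect_lt(abs((idx[1] - 1 - 31.5) - analytic[2]), 1)
  # centre point is tilt-invariant
  ctr <- project_points(c(0, 0, 0), c(-60, 0, 45), ground_truth(3))
  expect_true(all(vapply(ctr, function(m) max(abs(m)), numeric(1)) < 1e-12))
  # an injected shift moves the spot by exactly that shift
  tr2 <- ground_truth(1, per_image_shift_px = c(12, -7))
  expect_equal(project_points(c(5, 5, 0), 0, tr2)[[1]] -
                 project_points(c(5, 5, 0), 0, tr)[[1]],
               cbind(x = 12, y = -7), ignore_attr = TRUE)
})

test_that("projected mass is tilt-independent for an untruncated phantom", {
  spec <- phantom_spec(c(96, 96, 96), 20, 10, seed = 4)
  vol <- make_phantom(spec)
  # zero the border so rotation cannot clip mass
  vol[c(1:24, 73:96), , ] <- 0
  vol[, c(1:8, 89:96), ] <- 0
  projs <- forward_project(vol, c(-60, -30, 0, 30, 60))
  masses <- vapply(projs, sum, numeric(1))
  expect_lt(max(abs(masses - masses[3])) / masses[3], 1e-3)
})

test_that("the simulated defocus gradient follows strip geometry", {
  # closed form: offset 1000 px from the axis at 2 A/px and 60 degrees
  # adds 1000 * 2 * tan(60 deg) = 3464 A = 0.346 um of defocus
  expect_equal(1000 * 2 * tan(deg2rad(60)) * 1e-4, 0.3464, tolerance = 1e-3)
  sim0 <- simulate_ctf_series(seed = 2, size = 256, angles_deg = 0,
                              truth = ground_truth(1, defocus_um = 2.5),
                              dose_e_per_A2 = NA)
  # at zero tilt the gradient term vanishes: left and right halves carry
  # the same first-zero position (compare half-image spectra)
  img <- sim0$series$images[[1]]
  sp_l <- tiltflow:::tile_power_spectrum(img[, 1:128], 128)
  sp_r <- tiltflow:::tile_power_spectrum(img[, 129:256], 128)
  ea_l <- equiphase_average(sp_l, 2.5, pixel_size_A = 4)
  ea_r <- equiphase_average(sp_r, 2.5, pixel_size_A = 4)
  expect_gt(cor(ea_l$value, ea_r$value, use = "complete"), 0.95)
})

test_that("grid-bar occlusion alters only the listed images", {
  case <- small_clean_series()
  s <- occlude_grid_bar(case$series, indices = c(1, 21),
                        coverage_fraction = 0.6)
  expect_false(identical(s$images[[1]], case$series$images[[1]]))
  expect_identical(s$images[[10]], case$series$images[[10]])
  s0 <- occlude_grid_bar(case$series, 1, 0)
  expect_identical(s0$images, case$series$images)
  sfull <- occlude_grid_bar(case$series, 5, 1)
  expect_lt(sd(sfull$images[[5]]), 0.15 * sd(case$series$images[[5]]))
  expect_error(occlude_grid_bar(case$series, 99, 0.5), "out of range")
})

test_that("fraction stacks conserve dose and follow the drift path", {
  img <- matrix(runif(64 * 64, 0.5, 1.5), 64)
  st <- simulate_fraction_stack(img, dose_per_frame_e_per_px = 50,
                                n_frames = 10, seed = 1)
  total <- sum(st$frames)
  expect_lt(abs(total - 10 * 50 * 64 * 64) / (10 * 50 * 64 * 64), 0.01)
  # 0.05 e-/px/frame for 20 frames integrates to 1 e-/px
  st2 <- simulate_fraction_stack(img, 0.05, 20, seed = 2)
  expect_equal(mean(apply(st2$frames, 3, mean)) * 20 / 1, 1,
               tolerance = 0.05)
  drift <- cbind(0.2 * (0:39), 0)
  expect_equal(drift[40, 1] - drift[1, 1], 7.8)
  expect_error(simulate_fraction_stack(img, 0, 5), "positive")
  expect_error(simulate_fraction_stack(img, 1, 5, drift_path = matrix(0, 3, 2)),
               "n_frames")
})
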