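test_that("flow on a static series is zero; rigid shifts are recovered", {
  img <- bin_image(matrix(rnorm(512 * 512), 512), 2)
  s <- tilt_series(list(img, img, img), c(-3, 0, 3))
  fl <- dense_flow_track(s, working_bin = 1)
  expect_lt(max(abs(fl$flow), na.rm = TRUE), 0.1)
  s2 <- tilt_series(list(img, warp_image(img, shift = c(5, 0))), c(0, 3))
  fl2 <- dense_flow_track(s2, working_bin = 1)
  fx <- fl2$flow[, 1, 1]
  expect_lt(max(abs(fx - 5), na.rm = TRUE), 0.3)
  expect_lt(max(abs(fl2$flow[, 1, 2]), na.rm = TRUE), 0.3)
})

test_that("flow magnitude grows with distance from the tilt axis", {
  case <- simulate_tilt_series(seed = 51, size = 512,
                               angles_deg = c(42, 45),
                               truth = ground_truth(2, tilt_axis_deg = 0),
                               dose_e_per_A2 = NA)
  fl <- dense_flow_track(case$series)
  v <- fl$flow[, 1, 1]
  x <- fl$centers[, 1]
  ok <- !is.na(v)
  slope <- coef(lm(v[ok] ~ x[ok]))[2]
  expect_equal(unname(slope), cos(deg2rad(45)) / cos(deg2rad(42)) - 1,
               tolerance = 0.25)
})

test_that("triangulation inverts the projection equations", {
  ang <- seq(-45, 45, by = 5)
  n <- length(ang)
  set.seed(14)
  centers <- cbind(runif(8, -120, 120), runif(8, -120, 120))
  # Eulerian flow field of a planar specimen z = a x + b y, sampled at
  # fixed window centres (the measurement dense_flow_track produces):
  # invert the window position to the plane, project at the next tilt
  plane_flow <- function(a, b) {
    fl <- array(NA_real_, dim = c(8, n - 1, 2))
    for (p in seq_len(n - 1)) {
      ca_p <- cos(deg2rad(ang[p])); sa_p <- sin(deg2rad(ang[p]))
      ca_q <- cos(deg2rad(ang[p + 1])); sa_q <- sin(deg2rad(ang[p + 1]))
      for (k in 1:8) {
        u <- centers[k, 1]; y <- centers[k, 2]
        X <- (u - b * sa_p * y) / (ca_p + a * sa_p)
        Z <- a * X + b * y
        fl[k, p, ] <- c(X * ca_q + Z * sa_q - u, 0)
      }
    }
    fl
  }
  fl <- structure(list(centers = centers,
                       pairs = cbind(seq_len(n - 1), seq_len(n - 1) + 1),
                       flow = plane_flow(0.3, -0.1), working_bin = 1,
                       tilt_angle_deg = ang),
                  class = "patch_flow_field")
  got <- triangulate_positions(fl)
  expect_equal(nrow(got), 8)
  # the anchor (0 degree) window centres correspond to plane points
  X_true <- centers[, 1]  # at 0 deg: u = X exactly
  Z_true <- 0.3 * X_true - 0.1 * centers[, 2]
  expect_close(got[, 1], X_true, tol = 0.5)
  expect_close(got[, 2], centers[, 2], tol = 0.5)
  expect_close(got[, 3], Z_true, tol = 0.5)
  expect_equal(sign(got[, 3]), sign(Z_true))
  # a flat specimen (z = 0) triangulates to z ~ 0
  fl0 <- fl; fl0$flow <- plane_flow(0, 0)
  got0 <- triangulate_positions(fl0)
  expect_lt(max(abs(got0[, 3])), 0.5)
})

test_that("robust plane fitting recovers slopes and rejects outliers", {
  set.seed(9)
  x <- runif(40, -100, 100); y <- runif(40, -100, 100)
  z <- tan(deg2rad(8)) * x
  fit <- fit_plane_robust(cbind(x, y, z))
  # documented convention: additive y correction is minus atan(slope_x)
  expect_equal(fit$y_tilt_deg, -8, tolerance = 1e-6)
  expect_equal(fit$x_tilt_deg, 0, tolerance = 1e-6)
  expect_equal(fit$rms_residual, 0, tolerance = 1e-9)
  # one gross outlier is excluded without moving the plane
  z2 <- z + c(rep(0, 39), 400)
  fit2 <- fit_plane_robust(cbind(x, y, z2 + rnorm(40, 0, 0.5)))
  expect_false(fit2$inlier_mask[40])
  expect_equal(fit2$y_tilt_deg, -8, tolerance = 0.15)
  # horizontal cloud
  fit3 <- fit_plane_robust(cbind(x, y, rnorm(40, 0, 0.1)))
  expect_lt(abs(fit3$x_tilt_deg) + abs(fit3$y_tilt_deg), 0.2)
  expect_error(fit_plane_robust(cbind(1:5, 2 * (1:5), rnorm(5))),
               "degenerate")
})

test_that("injected pre-tilts are recovered within tolerance", {
  for (cfg in list(c(seed = 61, x = 3, y = -5), c(seed = 62, x = -2, y = 8))) {
    tr <- ground_truth(41, tilt_axis_deg = 0, pre_tilt_x_deg = cfg["x"],
                       pre_tilt_y_deg = cfg["y"])
    case <- simulate_tilt_series(seed = cfg["seed"], size = 512,
                                 truth = tr, dose_e_per_A2 = 3)
    ep <- estimate_pretilt(reorder_by_tilt(case$series))
    expect_lt(abs(ep$fit$x_tilt_deg - cfg["x"]), 1,
              label = sprintf("seed %d x-tilt", cfg["seed"]))
    expect_lt(abs(ep$fit$y_tilt_deg - cfg["y"]), 1,
              label = sprintf("seed %d y-tilt", cfg["seed"]))
  }
})

test_that("pre-tilt correction levels the tilt angles", {
  tr <- ground_truth(41, tilt_axis_deg = 0, pre_tilt_y_deg = 8)
  case <- simulate_tilt_series(seed = 63, size = 512, truth = tr,
                               dose_e_per_A2 = NA)
  s <- reorder_by_tilt(case$series)
  ep <- estimate_pretilt(s)
  corrected <- apply_pretilt_correction(s, ep$fit)
  expect_equal(corrected$meta$tilt_angle_deg,
               s$meta$tilt_angle_deg + ep$fit$y_tilt_deg)
  expect_equal(corrected$extra$x_tilt_deg, ep$fit$x_tilt_deg)
  # the horizontal image is now the one nearest corrected zero: with +8
  # correction on a 3-degree raster that is the nominal -9 image
  hz <- corrected$extra$horizontal_index
  expect_equal(s$meta$tilt_angle_deg[hz], -9)
  # re-triangulating with corrected angles leaves a near-horizontal plane
  flow <- ep$flow
  pts2 <- triangulate_positions(flow, flow$tilt_angle_deg + ep$fit$y_tilt_deg)
  fit2 <- fit_plane_robust(pts2)
  expect_lt(abs(fit2$y_tilt_deg), 0.5)
  # zero correction is a no-op
  null_fit <- fit_plane_robust(cbind(runif(10, -50, 50),
                                     runif(10, -50, 50), 0))
  s0 <- apply_pretilt_correction(s, null_fit)
  expect_equal(s0$meta$tilt_angle_deg, s$meta$tilt_angle_deg)
})
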