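test_that("the projector pair is an exact adjoint", {
  set.seed(13)
  for (geom in list(c(0, 0), c(33, 5), c(-58, -3))) {
    v <- array(rnorm(16 * 12 * 10), c(16, 12, 10))
    p <- matrix(rnorm(16 * 12), 12, 16)
    Ax <- forward_project(v, geom[1], geom[2])[[1]]
    Aty <- back_project(list(p), geom[1], c(16, 12, 10), geom[2])
    lhs <- sum(Ax * p); rhs <- sum(v * Aty)
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-5)
  }
})

test_that("projection conserves mass and maps impulses to spots", {
  v <- array(0, c(16, 16, 16)); v[8, 9, 8] <- 1
  p0 <- forward_project(v, 0)[[1]]
  expect_equal(sum(p0), 1, tolerance = 1e-6)
  expect_equal(which(p0 > 0.2, arr.ind = TRUE)[1, ], c(row = 9, col = 8),
               ignore_attr = TRUE)
  spec <- phantom_spec(c(48, 48, 48), 16, 8, seed = 5)
  vol <- make_phantom(spec)
  vol[c(1:12, 37:48), , ] <- 0
  expect_equal(sum(forward_project(vol, 0)[[1]]), sum(vol),
               tolerance = 1e-6 * sum(vol))
})

test_that("zero iterations return the zero volume", {
  projs <- list(matrix(1, 8, 8))
  tom <- sirt_reconstruct(projs, 0, reconstruction_config(n_iterations = 0),
                          thickness_voxels = 8)
  expect_true(all(tom$volume == 0))
})

test_that("one SIRT iteration reproduces the dense-matrix update", {
  # tiny geometry: build A explicitly from impulse responses at 0 degrees
  dims <- c(8, 8, 8)
  b <- matrix(0, 8, 8); b[4, 5] <- 2
  cfg <- reconstruction_config(n_iterations = 1, relaxation = 1,
                               nonneg = FALSE)
  tom <- sirt_reconstruct(list(b), 0, cfg, thickness_voxels = 8)
  n <- prod(dims)
  A <- matrix(0, 64, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- as.numeric(forward_project(array(e, dims), 0)[[1]])
  }
  Rn <- 1 / pmax(rowSums(A), 1e-6)
  Cn <- 1 / pmax(colSums(A), 1e-6)
  x_ref <- Cn * as.numeric(t(A) %*% (Rn * as.numeric(b)))
  expect_close(as.numeric(tom$volume), x_ref, tol = 1e-8)
})

test_that("SIRT reconstructs a slab phantom faithfully inside the slab", {
  spec <- phantom_spec(c(64, 64, 64), 24, 30, seed = 3, background = 0,
                       texture_sd = 0)
  vol <- make_phantom(spec)
  angles <- seq(-60, 60, by = 3)
  projs <- forward_project(vol, angles)
  tom <- sirt_reconstruct(projs, angles, thickness_voxels = 26)
  r <- cor(as.numeric(vol[, , 20:45]), as.numeric(tom$volume))
  expect_gt(r, 0.9)
  expect_true(all(diff(tom$residuals) <= 1e-9))
})

test_that("thickness estimation is accurate and falls back on noise", {
  angles <- seq(-60, 60, by = 6)
  sp <- phantom_spec(c(96, 96, 64), 20, seed = 21)
  th <- estimate_thickness(forward_project(make_phantom(sp), angles),
                           angles, n_iterations = 10)
  expect_lt(abs(th$thickness_voxels - 20) / 20, 0.15)
  # doubling the slab roughly doubles the estimate
  sp2 <- phantom_spec(c(96, 96, 64), 40, seed = 21)
  th2 <- estimate_thickness(forward_project(make_phantom(sp2), angles),
                            angles, n_iterations = 10)
  expect_lt(abs(th2$thickness_voxels / th$thickness_voxels - 2), 0.4)
  # pure noise triggers the fallback
  noise <- lapply(angles, function(a) matrix(rnorm(32 * 32), 32))
  thn <- estimate_thickness(noise, angles, n_iterations = 4)
  expect_true(thn$fallback)
})

test_that("final reconstruction bins, pads thickness, applies the x-tilt", {
  spec <- phantom_spec(c(64, 64, 64), 24, 40, seed = 6, background = 0)
  vol <- make_phantom(spec)
  angles <- seq(-60, 60, by = 6)
  projs <- forward_project(vol, angles)
  tom <- final_reconstruct(projs, angles, thickness = 24,
                           config = reconstruction_config(
                             n_iterations = 15, binning = 2),
                           voxel_size_A = 2)
  expect_equal(dim(tom$volume)[1:2], c(32, 32))
  expect_equal(dim(tom$volume)[3], round(24 / 2 * 1.1))
  expect_equal(tom$voxel_size_A, 4)
})

test_that("an x-tilted slab reconstructs level under the corrected geometry", {
  spec <- phantom_spec(c(64, 64, 48), 16, 40, seed = 7)
  vol <- make_phantom(spec)
  angles <- seq(-60, 60, by = 6)
  truth <- ground_truth(length(angles), pre_tilt_x_deg = 5)
  series <- project_tilt_series(vol, angles, truth)
  projs <- series$images
  slab_com <- function(tom) {
    prof_by_y <- apply(tom$volume, c(2, 3), function(v) sd(v))  # ny x nz
    w <- pmax(sweep(prof_by_y, 1, apply(prof_by_y, 1, min)), 0)
    apply(w, 1, function(v) sum(v * seq_along(v)) / sum(v))
  }
  tom <- sirt_reconstruct(projs, angles,
                          reconstruction_config(n_iterations = 25,
                                                x_tilt_deg = 5),
                          thickness_voxels = 32)
  tom0 <- sirt_reconstruct(projs, angles,
                           reconstruction_config(n_iterations = 25),
                           thickness_voxels = 32)
  core <- 12:52
  tilt_of <- function(com) {
    # slope of the slab centre of mass across y, in degrees
    atan(coef(lm(com[core] ~ core))[2]) * 180 / pi
  }
  expect_lt(abs(tilt_of(slab_com(tom))), 2)
  expect_gt(abs(tilt_of(slab_com(tom0))), 3)
})
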