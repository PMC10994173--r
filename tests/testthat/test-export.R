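# helper: a solved result on a small synthetic case, shared by the export
# tests (kept deliberately small; the heavy end-to-end runs live in the
# acceptance suite)
export_fixture <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    case <- small_clean_series()
    s <- reorder_by_tilt(case$series)
    n <- n_images(s)
    s$meta$usable[c(1, 2, 21)] <- FALSE
    s$extra$nominal_tilt_deg <- s$meta$tilt_angle_deg
    model <- structure(list(
      tilt_axis_deg = 1.2, rotation_deg = rep(1.2, n),
      shift = matrix(rnorm(2 * n, 0, 3), n, 2), scale = 1,
      mean_residual_px = 0.4, residual_sigma_px = 0.2),
      class = "alignment_model")
    shift_table <- data.frame(dx = rnorm(n, 0, 5), dy = rnorm(n, 0, 5))
    ctf <- structure(list(defocus_um = rep(2.5, n), astig_um = 0.1,
                          astig_angle_deg = 30, confidence_range_A = 8,
                          horizontal_index = 11),
                     class = "ctf_series_fit")
    val <<- list(series = s, model = model, shift_table = shift_table,
                 ctf = ctf)
    val
  }
})

test_that("identity alignment exports IMOD identity transform lines", {
  case <- small_clean_series()
  s <- reorder_by_tilt(case$series)
  n <- n_images(s)
  ident <- structure(list(tilt_axis_deg = 0, rotation_deg = rep(0, n),
                          shift = matrix(0, n, 2), scale = 1,
                          mean_residual_px = 0, residual_sigma_px = 0),
                     class = "alignment_model")
  tab <- data.frame(dx = rep(0, n), dy = rep(0, n))
  out <- withr::local_tempdir()
  bundle <- export_imod(ident, s, tab, out)
  xf <- read_xf(bundle$xf)
  expect_equal(nrow(xf), n)
  expect_close(xf[, 1:4], matrix(c(1, 0, 0, 1), n, 4, byrow = TRUE),
               tol = 1e-6)
  expect_close(xf[, 5:6], matrix(0, n, 2), tol = 1e-3)
})

test_that("deleted-slice bookkeeping is consistent across files", {
  fx <- export_fixture()
  out <- withr::local_tempdir()
  bundle <- export_imod(fx$model, fx$series, fx$shift_table, out)
  n_usable <- sum(fx$series$meta$usable)
  expect_length(readLines(bundle$tlt), n_usable)
  expect_length(readLines(bundle$rawtlt), n_usable)
  expect_equal(nrow(read_xf(bundle$xf)), n_usable)
  expect_false(is.null(bundle$clean_mrc))
  expect_equal(dim(read_mrc(bundle$clean_mrc)$data)[3], n_usable)
  expect_true(file.exists(bundle$newst_com))
  expect_true(file.exists(bundle$tilt_com))
})

test_that("exported transforms re-apply identically to the package's own", {
  fx <- export_fixture()
  out <- withr::local_tempdir()
  bundle <- export_imod(fx$model, fx$series, fx$shift_table, out)
  xf <- read_xf(bundle$xf)
  keep <- which(fx$series$meta$usable)
  aligned <- apply_alignment(fx$series, fx$model, fx$shift_table)
  grid <- matrix(0, 128, 128)
  grid[seq(8, 120, by = 16), ] <- 1; grid[, seq(8, 120, by = 16)] <- 1
  for (r in c(1, length(keep))) {
    i <- keep[r]
    A <- matrix(xf[r, c(1, 3, 2, 4)], 2, 2)
    b <- xf[r, 5:6]
    via_file <- warp_affine(grid, A, b)
    phi <- deg2rad(fx$model$rotation_deg[i])
    A2 <- t(tiltflow:::rot2(phi + deg2rad(fx$series$nominal_tilt_axis_deg)))
    b2 <- -(t(tiltflow:::rot2(phi)) %*%
              (c(fx$shift_table$dx[i], fx$shift_table$dy[i]) +
                 fx$model$shift[i, ]))
    via_model <- warp_affine(grid, A2, as.numeric(b2))
    core <- 30:98
    expect_lt(max(abs(via_file[core, core] - via_model[core, core])), 0.1)
  }
})

test_that("defocus files round-trip with nanometre defocus columns", {
  fx <- export_fixture()
  f <- withr::local_tempfile(fileext = ".defocus")
  export_ctfplotter(fx$ctf, fx$series, f)
  df <- read_ctfplotter(f)
  expect_equal(nrow(df), sum(fx$series$meta$usable))
  expect_equal(df$defocus1_nm[1], (2.5 + 0.1) * 1e3, tolerance = 0.1)
  expect_equal(df$defocus2_nm[1], (2.5 - 0.1) * 1e3, tolerance = 0.1)
  expect_equal(df$astig_angle_deg[1], 30, tolerance = 0.01)
  expect_equal(df$tilt1, sort(fx$series$meta$tilt_angle_deg[
    fx$series$meta$usable]), tolerance = 0.01)
})

test_that("RELION export preserves the acquisition order and defocus", {
  fx <- export_fixture()
  out <- withr::local_tempdir()
  rel <- export_relion(fx$series, fx$model, fx$ctf, out)
  ord <- read.csv(rel$order_csv)
  keep_acq <- fx$series$meta$acquisition_index[fx$series$meta$usable]
  keep_tilt <- fx$series$meta$tilt_angle_deg[fx$series$meta$usable]
  expect_equal(ord$tilt_angle, keep_tilt[order(keep_acq)],
               tolerance = 0.01)
  star <- read_star(rel$star)
  expect_equal(nrow(star), sum(fx$series$meta$usable))
  expect_equal(star[["_rlnDefocusU"]][1], (2.5 + 0.1) * 1e4,
               tolerance = 1)
  expect_equal(star[["_rlnTomoNominalTiltAxisAngle"]][1], 1.2,
               tolerance = 0.01)
})

test_that("a dose-symmetric series exports its acquisition sequence", {
  ang <- dose_symmetric_scheme(15, 3, 2)  # 0 3 -3 -6 6 9 -9 -12 12 15 -15
  imgs <- lapply(seq_along(ang), function(k) matrix(rnorm(64), 8))
  s <- reorder_by_tilt(tilt_series(imgs, ang))
  n <- n_images(s)
  model <- structure(list(tilt_axis_deg = 0, rotation_deg = rep(0, n),
                          shift = matrix(0, n, 2), scale = 1,
                          mean_residual_px = 0, residual_sigma_px = 0),
                     class = "alignment_model")
  out <- withr::local_tempdir()
  rel <- export_relion(s, model, NULL, out)
  ord <- read.csv(rel$order_csv)
  expect_equal(ord$tilt_angle[1:5], c(0, 3, -3, -6, 6))
})
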