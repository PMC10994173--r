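test_that("the CTF model obeys its closed-form limits", {
  opt <- ctf_optics()
  expect_equal(ctf_model(2, 0, 0, opt, 0), -opt$amplitude_contrast)
  # zero astigmatism: azimuth independent
  k <- 0.03
  vals <- ctf_model(2, 0, 0, opt, k, seq(0, pi, length.out = 7))
  expect_lt(diff(range(vals)), 1e-12)
  # with astigmatism the defocus modulates as cos(2 theta)
  v0 <- ctf_model(2, 0.2, 0, opt, k, 0)
  expect_equal(ctf_model(2, 0.2, 0, opt, k, pi), v0)
  expect_false(isTRUE(all.equal(ctf_model(2, 0.2, 0, opt, k, pi / 2), v0)))
  # the first zero is a sign change of the model
  k1 <- ctf_first_zero(2, opt)
  expect_lt(abs(ctf_model(2, 0, 0, opt, k1)), 1e-6)
  expect_lt(ctf_model(2, 0, 0, opt, k1 - 0.002) *
              ctf_model(2, 0, 0, opt, k1 + 0.002), 0)
})

test_that("the resampling factor is the half-integer-rounded point ratio", {
  opt <- ctf_optics()
  # n_exp scales with pixel size, so r = round_to_half(ref_px / px)
  r1 <- auto_resample_factor(1.5, 2, opt, reference_pixel_A = 1.5)
  expect_equal(r1$r_factor, 1)
  expect_equal(r1$n_exp, r1$n_ref)
  r2 <- auto_resample_factor(0.75, 2, opt, reference_pixel_A = 1.5)
  expect_equal(r2$r_factor, 2)
  # ratio 1.3 rounds to 1.5 (ties toward the larger half-integer)
  r3 <- auto_resample_factor(1.5 / 1.3, 2, opt, reference_pixel_A = 1.5)
  expect_equal(r3$r_factor, 1.5)
  r4 <- auto_resample_factor(1.25, 2, opt, reference_pixel_A = 1.5)
  expect_equal(r4$r_factor, 1)  # ratio 1.2 -> nearest half is 1.0
  # coarse sampling never upsamples
  r5 <- auto_resample_factor(4, 2, opt, reference_pixel_A = 1.5)
  expect_equal(r5$r_factor, 1)
})

test_that("2D fitting recovers defocus and astigmatism from simulation", {
  opt <- ctf_optics()
  sim <- simulate_ctf_series(seed = 71, size = 512, angles_deg = 0,
                             truth = ground_truth(1, defocus_um = 2.5),
                             dose_e_per_A2 = 20)
  fit <- fit_ctf_2d(sim$series$images[[1]], 2.3, 4, opt)
  expect_lt(abs(fit$defocus_um - 2.5), 0.05)
  expect_lt(fit$astig_um, 0.05)
  tr2 <- ground_truth(1, defocus_um = 2.5, astigmatism_um = 0.3,
                      astig_angle_deg = 45)
  sim2 <- simulate_ctf_series(seed = 72, size = 512, angles_deg = 0,
                              truth = tr2, dose_e_per_A2 = 20)
  fit2 <- fit_ctf_2d(sim2$series$images[[1]], 2.3, 4, opt)
  expect_lt(abs(fit2$defocus_um - 2.5), 0.05)
  expect_lt(abs(fit2$astig_um - 0.3), 0.05)
  expect_lt(abs(fit2$astig_angle_deg - 45) %% 180, 5)
})

test_that("equiphase averaging reduces exactly to the rotational average", {
  sim <- simulate_ctf_series(seed = 73, size = 256, angles_deg = 0,
                             truth = ground_truth(1, defocus_um = 3))
  sp <- tiltflow:::tile_power_spectrum(sim$series$images[[1]], 256)
  ea <- equiphase_average(sp, 3, astig_um = 0, pixel_size_A = 4)
  # independent rotational average with the same binning
  g <- tiltflow:::spec_grids(256, 4)
  nb <- 128
  kedge <- seq(0, 0.5 / 4, length.out = nb + 1)
  bin <- findInterval(g$k, kedge, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= nb
  ra <- rep(NA_real_, nb)
  agg <- tapply(sp[ok], bin[ok], mean)
  ra[as.integer(names(agg))] <- agg
  same <- !is.na(ea$value) & !is.na(ra)
  expect_lt(max(abs(ea$value[same] - ra[same]) / pmax(ra[same], 1e-12)),
            1e-6)
})

test_that("equiphase averaging sharpens zeros under strong astigmatism", {
  tr <- ground_truth(1, defocus_um = 3, astigmatism_um = 0.4,
                     astig_angle_deg = 30)
  sim <- simulate_ctf_series(seed = 74, size = 512, angles_deg = 0,
                             truth = tr, dose_e_per_A2 = 20)
  sp <- tiltflow:::tile_power_spectrum(sim$series$images[[1]], 256)
  ea <- equiphase_average(sp, 3, 0.4, 30, pixel_size_A = 4)
  ra <- equiphase_average(sp, 3, 0, 0, pixel_size_A = 4)
  # contrast of the first oscillation: peak-to-trough around the mean zero
  k1 <- ctf_first_zero(3, ctf_optics())
  zone <- which(ea$k > 0.6 * k1 & ea$k < 1.5 * k1)
  contrast <- function(v) diff(range(v[zone], na.rm = TRUE)) /
    mean(v[zone], na.rm = TRUE)
  expect_gt(contrast(ea$value), contrast(ra$value))
})

test_that("strip spectra expose the defocus gradient of a tilted image", {
  opt <- ctf_optics()
  sim <- simulate_ctf_series(seed = 75, size = 512,
                             angles_deg = c(0, 45),
                             truth = ground_truth(2, defocus_um = 3),
                             dose_e_per_A2 = 10)
  central <- fit_ctf_2d(sim$series$images[[1]], 2.9, 4, opt)
  expect_lt(abs(central$defocus_um - 3), 0.05)
  st0 <- strip_spectra(sim$series$images[[1]], 9, 128, 4)
  ft0 <- fit_tilted_defocus(st0, central, 0)
  # untilted image: all strips agree with the central fit
  expect_lt(max(abs(ft0$strip_defocus_um - 3)), 0.1)
  st45 <- strip_spectra(sim$series$images[[2]], 9, 128, 4)
  expect_length(st45, 9)
  ft45 <- fit_tilted_defocus(st45, central, 45)
  expect_lt(abs(ft45$defocus_um - 3), 0.1)
  # strip defocus increases monotonically with signed offset
  expect_gt(cor(ft45$strip_offset_px, ft45$strip_defocus_um), 0.85)
  expect_false(ft45$low_confidence)
  expect_lt(abs(ft45$slope_um_per_px / ft45$expected_slope_um_per_px - 1),
            0.35)
})

test_that("series-level CTF keeps astigmatism constant across images", {
  tr <- ground_truth(5, defocus_um = 3, astigmatism_um = 0.2,
                     astig_angle_deg = 20)
  sim <- simulate_ctf_series(seed = 76, size = 512,
                             angles_deg = seq(0, 48, by = 12), truth = tr,
                             dose_e_per_A2 = 10)
  fit <- fit_ctf_series(sim$series)
  expect_length(fit$defocus_um, 5)
  expect_lt(max(abs(fit$defocus_um - 3), na.rm = TRUE), 0.12)
  # one astigmatism for the whole series, by construction
  expect_length(fit$astig_um, 1)
  expect_lt(abs(fit$astig_um - 0.2), 0.07)
})
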