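test_that("MRC stacks round-trip through write and read", {
  arr <- array(rnorm(24 * 32 * 5), dim = c(24, 32, 5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(arr, f, pixel_size_A = 1.96)
  r <- read_mrc(f)
  # mode-2 storage is float32: exact at single precision
  expect_close(r$data, arr, tol = 1e-5 * max(abs(arr)))
  expect_equal(r$pixel_size_A, 1.96, tolerance = 1e-6)
  # second round trip is bit-identical (data already float32-quantised)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(r$data, f2, pixel_size_A = 1.96)
  expect_identical(read_mrc(f2)$data, r$data)
})

test_that("int16 and half-precision MRC modes are readable", {
  # hand-build a little-endian mode-1 MRC
  f <- withr::local_tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(c(3, 2, 1, 1, 0, 0, 0, 3, 2, 1)); wf(c(3, 2, 1) * 2)
  wf(c(90, 90, 90)); wi(c(1, 2, 3)); wf(c(-5, 7, 1)); wi(1); wi(0)
  writeBin(raw(100), con); wf(c(0, 0, 0))
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con); wf(1); wi(0)
  writeBin(raw(800), con)
  writeBin(as.integer(c(-5, 0, 7, 100, -100, 32000)), con, size = 2,
           endian = "little")
  close(con)
  r <- read_mrc(f)
  expect_equal(dim(r$data), c(2, 3, 1))
  expect_equal(sort(as.numeric(r$data)),
               sort(c(-5, 0, 7, 100, -100, 32000)))
  expect_equal(r$pixel_size_A, 2)
  # half-precision decoding against hand-computed values
  expect_equal(tiltflow:::half_to_double(c(0x3C00L, 0xC000L, 0x0000L,
                                           0x7BFFL)),
               c(1, -2, 0, 65504))
})

test_that("tilt series construction validates its invariants", {
  imgs <- replicate(3, matrix(rnorm(16), 4), simplify = FALSE)
  expect_error(tilt_series(imgs, c(0, 3)), "metadata mismatch")
  expect_error(tilt_series(imgs, c(0, 3, 120)), "<= 90")
  expect_error(tilt_series(imgs, c(0, 3, -3),
                           acquisition_index = c(1, 1, 2)), "unique")
  imgs[[2]] <- matrix(0, 5, 4)
  expect_error(tilt_series(imgs, c(0, 3, -3)), "share dimensions")
})

test_that("read_tilt_series enforces metadata agreement and header fallback", {
  arr <- array(rnorm(16 * 16 * 5), dim = c(16, 16, 5))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(arr, f, pixel_size_A = 1.96)
  s <- read_tilt_series(f, list(tilt_angle_deg = seq(-6, 6, by = 3)))
  expect_equal(n_images(s), 5)
  expect_true(all(s$meta$usable))
  expect_equal(s$pixel_size_A, 1.96, tolerance = 1e-6)  # header fallback
  expect_error(read_tilt_series(f, list(tilt_angle_deg = 1:4)),
               "metadata mismatch")
})

test_that("writing excludes unusable images and orders by tilt", {
  imgs <- lapply(1:5, function(k) matrix(k, 8, 8))
  s <- tilt_series(imgs, c(0, 6, -6, 3, -3))
  s$meta$usable <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_tilt_series(s, f, include_unusable = FALSE)
  r <- read_mrc(f)
  expect_equal(dim(r$data)[3], 4)
  # sections ascend by tilt: -6, -3, 0, 3 -> constant values 3, 5, 1, 4
  expect_equal(as.numeric(r$data[1, 1, ]), c(3, 5, 1, 4))
  s$meta$usable[] <- FALSE
  expect_error(write_tilt_series(s, f, include_unusable = FALSE),
               "no usable")
})

test_that("reorder_by_tilt sorts, preserves indices, breaks ties stably", {
  ang <- dose_symmetric_scheme(12, 3, 2)  # 0 3 -3 -6 6 9 -9 -12 12
  imgs <- lapply(seq_along(ang), function(k) matrix(k, 4, 4))
  s <- tilt_series(imgs, ang)
  r <- reorder_by_tilt(s)
  expect_equal(r$meta$tilt_angle_deg, sort(ang))
  expect_setequal(r$meta$acquisition_index, seq_along(ang))
  expect_identical(reorder_by_tilt(r)$meta, r$meta)  # idempotent
  # duplicate angles keep acquisition order
  s2 <- tilt_series(list(matrix(1, 2, 2), matrix(2, 2, 2)), c(0, 0))
  expect_equal(reorder_by_tilt(s2)$meta$acquisition_index, c(1L, 2L))
})

test_that("bin_image pools blocks exactly and composes", {
  m <- matrix(rnorm(96 * 96), 96)
  expect_equal(dim(bin_image(m, 4)), c(24, 24))
  expect_equal(bin_image(matrix(7, 32, 32), 4), matrix(7, 8, 8))
  expect_close(bin_image(bin_image(m, 2), 3), bin_image(m, 6), tol = 1e-6)
  expect_equal(mean(bin_image(m, 4)), mean(m), tolerance = 1e-12)
  expect_error(bin_image(m, 200), "larger than image")
  # 4096 -> 256 uses factor 16
  expect_equal(dim(bin_image(matrix(0, 512, 512), 512 / 32)), c(32, 32))
})

test_that("rawtlt files read as plain angle lists", {
  f <- withr::local_tempfile(fileext = ".rawtlt")
  writeLines(c("-60.0", "-57.0", "0.0"), f)
  expect_equal(read_rawtlt(f), c(-60, -57, 0))
})
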