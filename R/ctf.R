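# CTF determination: classical 2D fitting on the horizontal-sample image,
# then strip-based defocus for tilted images (patch rows parallel to the
# tilt axis, equiphase averaging with the series astigmatism, spline
# background, frequency rescaling against the on-axis curve) and an
# automatic resampling decision for finely sampled data.

#' Optical constants for CTF computation
#' @param voltage_kV acceleration voltage.
#' @param cs_mm spherical aberration.
#' @param amplitude_contrast amplitude-contrast fraction.
#' @return list of class `ctf_optics` (includes the electron wavelength in
#'   Angstrom).
#' @export
ctf_optics <- function(voltage_kV = 300, cs_mm = 2.7,
                       amplitude_contrast = 0.07) {
  V <- voltage_kV * 1e3
  lambda_A <- 12.2639 / sqrt(V + 0.97845e-6 * V^2)
  structure(list(voltage_kV = voltage_kV, cs_mm = cs_mm,
                 amplitude_contrast = amplitude_contrast,
                 lambda_A = lambda_A), class = "ctf_optics")
}

#' Phase-contrast CTF amplitude
#'
#' `CTF(k, t) = -(sqrt(1 - A^2) sin(g) + A cos(g))` with phase
#' `g = pi * lambda * df(t) * k^2 - (pi/2) * Cs * lambda^3 * k^4` and
#' astigmatic defocus `df(t) = f + a cos(2 (t - t0))` (positive f =
#' underfocus, so the value at k = 0 is minus the amplitude-contrast
#' fraction).
#'
#' @param defocus_um mean defocus in micrometres.
#' @param astig_um astigmatism magnitude (half peak-to-peak) in
#'   micrometres.
#' @param astig_angle_deg astigmatism azimuth in degrees.
#' @param optics a [ctf_optics()].
#' @param k spatial frequency (1/Angstrom), any shape.
#' @param azimuth frequency-space azimuth in radians (same shape as `k`);
#'   ignored for zero astigmatism.
#' @return CTF amplitude, same shape as `k`.
#' @export
ctf_model <- function(defocus_um, astig_um = 0, astig_angle_deg = 0,
                      optics = ctf_optics(), k, azimuth = 0) {
  f_A <- defocus_um * 1e4
  a_A <- astig_um * 1e4
  cs_A <- optics$cs_mm * 1e7
  df <- f_A + a_A * cos(2 * (azimuth - deg2rad(astig_angle_deg)))
  g <- pi * optics$lambda_A * df * k^2 -
    (pi / 2) * cs_A * optics$lambda_A^3 * k^4
  A <- optics$amplitude_contrast
  -(sqrt(1 - A^2) * sin(g) + A * cos(g))
}

#' First zero of the CTF (zero astigmatism)
#'
#' Root of the phase argument reaching pi, found numerically.
#'
#' @param defocus_um defocus in micrometres.
#' @param optics a [ctf_optics()].
#' @return spatial frequency of the first zero in 1/Angstrom.
#' @export
ctf_first_zero <- function(defocus_um, optics = ctf_optics()) {
  f_A <- defocus_um * 1e4
  cs_A <- optics$cs_mm * 1e7
  A <- optics$amplitude_contrast
  phase0 <- atan2(A, sqrt(1 - A^2))
  g <- function(k) pi * optics$lambda_A * f_A * k^2 -
    (pi / 2) * cs_A * optics$lambda_A^3 * k^4 + phase0 - pi
  stats::uniroot(g, c(1e-6, sqrt(f_A / cs_A / optics$lambda_A^2)),
                 tol = 1e-10)$root
}

#' Automatic spectrum-resampling decision
#'
#' Counts the frequency samples `n_exp` describing the first CTF
#' oscillation at the native sampling, compares with the reference count
#' `n_ref` at the reference pixel size, and returns
#' `r = n_ref / n_exp` rounded to the nearest half-integer (ties round up),
#' clamped to at least 1.
#'
#' @param pixel_size_A native pixel size.
#' @param defocus_um defocus at which the first oscillation is evaluated.
#' @param optics a [ctf_optics()].
#' @param n_half one-sided spectrum sample count.
#' @param reference_pixel_A reference sampling (default 1.5 Angstrom).
#' @return list of class `resampling_decision` with `n_exp`, `n_ref`,
#'   `r_factor`.
#' @export
auto_resample_factor <- function(pixel_size_A, defocus_um = 2,
                                 optics = ctf_optics(), n_half = 128,
                                 reference_pixel_A = 1.5) {
  k1 <- ctf_first_zero(defocus_um, optics)
  n_exp <- k1 * (2 * pixel_size_A) * n_half        # samples to first zero
  n_ref <- k1 * (2 * reference_pixel_A) * n_half
  r <- max(1, floor(2 * (n_ref / n_exp) + 0.5) / 2)  # half-integer, ties up
  structure(list(n_exp = n_exp, n_ref = n_ref, r_factor = r),
            class = "resampling_decision")
}

# Hann-windowed tiled periodogram; returns the centred 2D power spectrum
tile_power_spectrum <- function(img, tile = 256) {
  ny <- nrow(img); nx <- ncol(img)
  tile <- min(tile, ny, nx)
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(tile) / (tile + 1))
  w <- outer(wy, wy)
  step <- max(tile %/% 2, 1)
  acc <- matrix(0, tile, tile)
  n <- 0L
  for (r0 in seq(1, ny - tile + 1, by = step)) {
    for (c0 in seq(1, nx - tile + 1, by = step)) {
      t0 <- img[r0:(r0 + tile - 1), c0:(c0 + tile - 1)]
      t0 <- (t0 - mean(t0)) * w
      acc <- acc + Mod(fft(t0))^2
      n <- n + 1L
    }
  }
  fftshift2(acc / n)
}

# frequency magnitude (1/A) and azimuth grids for a centred tile spectrum
spec_grids <- function(tile, pixel_size_A) {
  c0 <- floor(tile / 2) + 1
  f <- (seq_len(tile) - c0) / (tile * pixel_size_A)
  kx <- matrix(f, tile, tile, byrow = TRUE)
  ky <- matrix(f, tile, tile)
  list(k = sqrt(kx^2 + ky^2), az = atan2(ky, kx))
}

# subtract a smooth radial background from a centred 2D spectrum (log scale)
subtract_background_2d <- function(spec, k) {
  lk <- as.numeric(k); ls <- log(as.numeric(spec) + 1e-12)
  br <- seq(0, max(lk), length.out = 80)
  mid <- (br[-1] + br[-length(br)]) / 2
  bg <- vapply(seq_len(length(br) - 1), function(i) {
    v <- ls[lk >= br[i] & lk < br[i + 1]]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  ok <- !is.na(bg)
  sm <- smooth.spline(mid[ok], bg[ok], spar = 0.6)
  bgv <- predict(sm, pmin(pmax(lk, min(mid[ok])), max(mid[ok])))$y
  matrix(exp(ls - bgv) - 1, nrow(spec), ncol(spec))
}

#' Fit defocus and astigmatism on the horizontal-sample image
#'
#' Tiled-periodogram power spectrum, smooth radial background removal, then
#' maximisation of the correlation between the squared CTF model and the
#' spectrum over the fit band.  The defocus search is initialised at the
#' applied (microscope) defocus; astigmatism and its angle are refined
#' jointly afterwards.
#'
#' @param horizontal_image image where the sample is horizontal (no
#'   defocus gradient).
#' @param applied_defocus_um starting defocus (microscope value).
#' @param pixel_size_A pixel size.
#' @param optics a [ctf_optics()].
#' @param tile periodogram tile size.
#' @param fit_range_A resolution band (low, high) used for scoring, in
#'   Angstrom.
#' @param search_um one-sided width of the initial defocus grid search.
#' @return list of class `ctf_fit`: `defocus_um`, `astig_um`,
#'   `astig_angle_deg`, `confidence_range_A`, `score`, `low_confidence`,
#'   `optics`, `resampling`.
#' @export
fit_ctf_2d <- function(horizontal_image, applied_defocus_um,
                       pixel_size_A, optics = ctf_optics(), tile = 256,
                       fit_range_A = NULL, search_um = 1.5) {
  rd <- auto_resample_factor(pixel_size_A, applied_defocus_um, optics)
  img <- horizontal_image
  if (rd$r_factor > 1) {
    img <- bin_image(img, rd$r_factor)
    pixel_size_A <- pixel_size_A * rd$r_factor
  }
  if (is.null(fit_range_A))
    fit_range_A <- c(40, max(2.2 * pixel_size_A, 10))
  spec <- tile_power_spectrum(img, tile)
  tile <- nrow(spec)
  g <- spec_grids(tile, pixel_size_A)
  spec_bs <- subtract_background_2d(spec, g$k)
  band <- g$k >= 1 / fit_range_A[1] & g$k <= 1 / fit_range_A[2]
  sv <- spec_bs[band]; kv <- g$k[band]; av <- g$az[band]
  score1 <- function(f) {
    m <- ctf_model(f, 0, 0, optics, kv)^2
    suppressWarnings(stats::cor(m, sv))
  }
  fgrid <- seq(max(0.2, applied_defocus_um - search_um),
               applied_defocus_um + search_um, by = 0.02)
  s1 <- vapply(fgrid, score1, numeric(1))
  s1[is.na(s1)] <- -1
  f0 <- fgrid[which.max(s1)]
  obj <- function(p) {
    m <- ctf_model(p[1], abs(p[2]), p[3], optics, kv, av)^2
    v <- suppressWarnings(stats::cor(m, sv))
    if (is.na(v)) 1 else -v
  }
  # coarse astigmatism grid before the simplex refinement (the correlation
  # surface has local optima in the astigmatism angle)
  grid <- expand.grid(a = c(0.02, 0.1, 0.2, 0.35),
                      t = seq(0, 150, by = 30))
  gvals <- vapply(seq_len(nrow(grid)), function(i)
    obj(c(f0, grid$a[i], grid$t[i])), numeric(1))
  g0 <- grid[which.min(gvals), ]
  op <- optim(c(f0, g0$a, g0$t), obj, method = "Nelder-Mead",
              control = list(maxit = 400))
  fit_f <- op$par[1]; fit_a <- abs(op$par[2])
  fit_t <- ((op$par[3] + 90) %% 180) - 90
  score <- -op$value
  # ring-wise confidence: highest resolution with windowed correlation > 0.3
  conf <- confidence_range(spec_bs, g, fit_f, fit_a, fit_t, optics,
                           pixel_size_A, kmin = 1 / fit_range_A[1])
  structure(list(defocus_um = fit_f, astig_um = fit_a,
                 astig_angle_deg = fit_t,
                 confidence_range_A = conf, score = score,
                 low_confidence = score < 0.2,
                 optics = optics, pixel_size_A = pixel_size_A,
                 resampling = rd), class = "ctf_fit")
}

confidence_range <- function(spec_bs, g, f, a, t, optics, pixel_size_A,
                             kmin, window = 6, thr = 0.3) {
  m2 <- ctf_model(f, a, t, optics, g$k, g$az)^2
  nb <- floor(min(dim(spec_bs)) / 2) - 1
  kedge <- seq(0, 0.5 / pixel_size_A, length.out = nb + 1)
  bin <- findInterval(g$k, kedge, rightmost.closed = TRUE)
  cors <- rep(NA_real_, nb - window)
  for (b in seq_len(nb - window)) {
    sel <- bin >= b & bin < b + window & g$k >= kmin
    if (sum(sel) < 20) next
    cors[b] <- suppressWarnings(stats::cor(m2[sel], spec_bs[sel]))
  }
  valid <- which(!is.na(cors) & cors > thr)
  if (!length(valid)) return(Inf)
  # first window (from low resolution) where correlation drops below thr
  start <- valid[1]
  stop_b <- start
  for (b in seq.int(start, length(cors))) {
    if (is.na(cors[b]) || cors[b] <= thr) break
    stop_b <- b
  }
  kc <- kedge[stop_b + window]
  1 / kc
}

#' Per-strip power spectra of a tilted image
#'
#' The (axis-vertical) image is divided into `n_rows` vertical strips;
#' square patches tiled along each strip (centred on the strip's column)
#' are Hann-windowed and their periodograms averaged, giving one 2D power
#' spectrum per signed offset from the tilt axis.
#'
#' @param tilted_image matrix, tilt axis vertical through the centre.
#' @param n_rows number of strips (reduced with a warning if the image is
#'   too narrow).
#' @param patch_size patch side in pixels.
#' @param pixel_size_A pixel size.
#' @return list of class `strip_spectra`; each element has `row_offset_px`
#'   (signed distance of the strip centre from the axis), `spectrum`
#'   (centred 2D), `n_patches_averaged`.
#' @export
strip_spectra <- function(tilted_image, n_rows = 9, patch_size = 128,
                          pixel_size_A = 1) {
  ny <- nrow(tilted_image); nx <- ncol(tilted_image)
  patch_size <- min(patch_size, ny, nx)
  if (nx / n_rows < patch_size / 4) {
    n_rows <- max(3L, as.integer(nx / (patch_size / 4)))
    if (n_rows %% 2 == 0) n_rows <- n_rows - 1L
    warning("strips narrower than a quarter patch; reduced to ", n_rows,
            " rows")
  }
  centers <- (seq_len(n_rows) - (n_rows + 1) / 2) * (nx / n_rows) +
    (nx + 1) / 2
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(patch_size) / (patch_size + 1))
  w <- outer(wy, wy)
  half <- patch_size %/% 2
  ys <- seq(1, ny - patch_size + 1, by = max(half, 1))
  out <- lapply(seq_len(n_rows), function(s) {
    cx <- round(min(max(centers[s], half + 1), nx - half))
    acc <- matrix(0, patch_size, patch_size)
    for (y0 in ys) {
      p <- tilted_image[y0:(y0 + patch_size - 1),
                        (cx - half + 1):(cx - half + patch_size)]
      p <- (p - mean(p)) * w
      acc <- acc + Mod(fft(p))^2
    }
    list(row_offset_px = centers[s] - (nx + 1) / 2,
         spectrum = fftshift2(acc / length(ys)),
         n_patches_averaged = length(ys))
  })
  structure(out, class = "strip_spectra",
            pixel_size_A = pixel_size_A, patch_size = patch_size)
}

#' Equiphase average of a 2D power spectrum
#'
#' Averages along iso-phase contours of the astigmatic CTF: each frequency
#' sample is mapped to the equivalent mean-defocus frequency
#' `k_eq = k sqrt(df(theta) / f)` and binned radially, so the zeros of an
#' astigmatic spectrum stay sharp.  With zero astigmatism this reduces
#' exactly to the rotational average (identical code path).
#'
#' @param spectrum_2d centred 2D power spectrum.
#' @param defocus_um mean defocus defining the ellipses.
#' @param astig_um,astig_angle_deg astigmatism of the central tilt image.
#' @param pixel_size_A pixel size.
#' @return list with `k` (bin centres, 1/Angstrom) and `value`.
#' @export
equiphase_average <- function(spectrum_2d, defocus_um = 1, astig_um = 0,
                              astig_angle_deg = 0, pixel_size_A = 1) {
  tile <- nrow(spectrum_2d)
  g <- spec_grids(tile, pixel_size_A)
  ratio <- 1 + (astig_um / defocus_um) *
    cos(2 * (g$az - deg2rad(astig_angle_deg)))
  keq <- g$k * sqrt(pmax(ratio, 0))
  nb <- tile %/% 2
  kedge <- seq(0, 0.5 / pixel_size_A, length.out = nb + 1)
  bin <- findInterval(keq, kedge, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= nb
  sums <- tabulate(bin[ok], nb)
  tot <- vapply(split(spectrum_2d[ok], bin[ok]), sum, numeric(1))
  val <- rep(NA_real_, nb)
  val[as.integer(names(tot))] <- tot
  val <- val / pmax(sums, 1)
  list(k = (kedge[-1] + kedge[-(nb + 1)]) / 2, value = val)
}

# spline background through the minima of a 1D CTF curve plus the
# high-frequency tail; returns the background-subtracted curve
subtract_background_1d <- function(k, v) {
  ok <- which(!is.na(v) & k > 0)
  lv <- log(v[ok] + 1e-12)
  n <- length(ok)
  loc_min <- which(diff(sign(diff(lv))) > 0) + 1
  tail_idx <- seq.int(max(1, floor(0.9 * n)), n)
  idx <- sort(unique(c(1, loc_min, tail_idx)))
  if (length(idx) < 4) return(v - median(v, na.rm = TRUE))
  sm <- smooth.spline(k[ok][idx], lv[idx],
                      spar = 0.5, all.knots = TRUE)
  bg <- predict(sm, k[ok])$y
  out <- rep(NA_real_, length(v))
  out[ok] <- exp(lv) - exp(bg)
  out
}

#' Strip-based defocus of a tilted image
#'
#' Each strip's equiphase-averaged, background-subtracted 1D curve is
#' rescaled along frequency to best match the on-axis curve; the rescaling
#' factor converts to a per-strip defocus (`f_strip = f_axis / s^2`).  The
#' image defocus is the refined on-axis value; the fitted slope of strip
#' defocus versus offset is checked against the geometric expectation
#' `pixel_size * tan(tilt)`.
#'
#' @param strips a `strip_spectra`.
#' @param central_fit the `ctf_fit` of the horizontal image (supplies the
#'   series astigmatism and the defocus prior).
#' @param tilt_angle_deg tilt of this image (degrees), used for the
#'   consistency check.
#' @param fit_range_A scoring band in Angstrom.
#' @return list: `defocus_um`, `strip_defocus_um`, `strip_offset_px`,
#'   `slope_um_per_px`, `expected_slope_um_per_px`, `low_confidence`.
#' @export
fit_tilted_defocus <- function(strips, central_fit, tilt_angle_deg,
                               fit_range_A = NULL) {
  px <- attr(strips, "pixel_size_A")
  optics <- central_fit$optics
  if (is.null(fit_range_A))
    fit_range_A <- c(40, max(2.2 * px, 10))
  n <- length(strips)
  if (n < 3) stop("need at least three strips")
  curves <- lapply(strips, function(s) {
    ea <- equiphase_average(s$spectrum, central_fit$defocus_um,
                            central_fit$astig_um,
                            central_fit$astig_angle_deg, px)
    ea$value <- subtract_background_1d(ea$k, ea$value)
    ea
  })
  offs <- vapply(strips, `[[`, numeric(1), "row_offset_px")
  axis_i <- which.min(abs(offs))
  kv <- curves[[axis_i]]$k
  band <- kv >= 1 / fit_range_A[1] & kv <= 1 / fit_range_A[2]
  # refine the on-axis defocus against the 1D model
  sc <- function(f) {
    m <- ctf_model(f, 0, 0, optics, kv[band])^2
    v <- suppressWarnings(stats::cor(m, curves[[axis_i]]$value[band]))
    if (is.na(v)) -1 else v
  }
  fg <- seq(max(0.2, central_fit$defocus_um - 0.5),
            central_fit$defocus_um + 0.5, by = 0.01)
  f_axis <- fg[which.max(vapply(fg, sc, numeric(1)))]
  f_axis <- optimize(function(f) -sc(f),
                     c(f_axis - 0.02, f_axis + 0.02))$minimum
  axis_curve <- curves[[axis_i]]$value
  rescale_score <- function(curve, s) {
    shifted <- approx(kv, axis_curve, xout = kv * s, rule = 1)$y
    ok <- band & !is.na(shifted) & !is.na(curve)
    if (sum(ok) < 10) return(-1)
    v <- suppressWarnings(stats::cor(curve[ok], shifted[ok]))
    if (is.na(v)) -1 else v
  }
  f_strip <- numeric(n)
  for (i in seq_len(n)) {
    if (i == axis_i) { f_strip[i] <- f_axis; next }
    sg <- seq(0.8, 1.25, by = 0.005)
    sv <- vapply(sg, function(s) rescale_score(curves[[i]]$value, s),
                 numeric(1))
    sbest <- sg[which.max(sv)]
    sbest <- optimize(function(s) -rescale_score(curves[[i]]$value, s),
                      c(sbest - 0.01, sbest + 0.01))$minimum
    # axis curve evaluated at k*s matches a defocus f_axis / s^2;
    # the strip equals that defocus when its curve matches the rescaling
    f_strip[i] <- f_axis * sbest^2
  }
  co <- coef(lm(f_strip ~ offs))
  slope <- co[2]
  expected <- px * tan(deg2rad(tilt_angle_deg)) * 1e-4  # um per px
  low_conf <- abs(tilt_angle_deg) > 10 &&
    (sign(slope) != sign(expected) ||
       abs(abs(slope) - abs(expected)) > 0.5 * max(abs(expected), 1e-6))
  list(defocus_um = f_axis, strip_defocus_um = f_strip,
       strip_offset_px = offs, slope_um_per_px = unname(slope),
       expected_slope_um_per_px = expected,
       low_confidence = isTRUE(low_conf))
}

#' CTF parameters for a whole tilt series
#'
#' 2D fit (defocus + astigmatism) on the horizontal-sample image, then
#' strip-based defocus for every other usable image with the astigmatism
#' held series-constant.
#'
#' @param series aligned (axis-vertical) `tilt_series`; the horizontal
#'   image index is taken from the positioning step when present.
#' @param optics a [ctf_optics()].
#' @param n_rows strips per image.
#' @param patch_size strip patch size in pixels.
#' @param tile periodogram tile for the 2D fit.
#' @return list of class `ctf_series_fit`: per-image `defocus_um` (NA for
#'   unusable images), series `astig_um`, `astig_angle_deg`,
#'   `confidence_range_A`, `horizontal_index`, `per_image` details.
#' @export
fit_ctf_series <- function(series, optics = ctf_optics(), n_rows = 9,
                           patch_size = 128, tile = 256) {
  hi <- series$extra$horizontal_index %||% zero_tilt_index(series)
  applied <- series$meta$applied_defocus_um[hi]
  if (is.na(applied)) applied <- 3
  central <- fit_ctf_2d(series$images[[hi]], applied, series$pixel_size_A,
                        optics, tile = tile)
  n <- n_images(series)
  defocus <- rep(NA_real_, n)
  per_image <- vector("list", n)
  for (i in seq_len(n)) {
    if (!series$meta$usable[i]) next
    if (i == hi) { defocus[i] <- central$defocus_um; next }
    st <- strip_spectra(series$images[[i]], n_rows, patch_size,
                        series$pixel_size_A)
    ft <- fit_tilted_defocus(st, central, series$meta$tilt_angle_deg[i])
    defocus[i] <- ft$defocus_um
    per_image[[i]] <- ft
  }
  structure(list(defocus_um = defocus, astig_um = central$astig_um,
                 astig_angle_deg = central$astig_angle_deg,
                 confidence_range_A = central$confidence_range_A,
                 horizontal_index = hi, central = central,
                 per_image = per_image, optics = optics),
            class = "ctf_series_fit")
}
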