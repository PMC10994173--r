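# FFT cross-correlation with automatic bandpass tuning.  The peak-quality
# score (peak height over the mean absolute level of an annulus around the
# peak) is the robustness statistic used for the skip-ahead logic of pair
# alignment and the relocation logic of patch tracking.

# raised-cosine annular bandpass on normalised radius (1 = Nyquist),
# memoised because the same mask is rebuilt thousands of times during
# patch tracking
.band_mask_cache <- new.env(parent = emptyenv())

band_mask <- function(ny, nx, low_cut_frac, high_cut_frac, soft = 0.02) {
  key <- paste(ny, nx, low_cut_frac, high_cut_frac, soft, sep = "_")
  hit <- .band_mask_cache[[key]]
  if (!is.null(hit)) return(hit)
  fg <- freq_grid(ny, nx)
  r <- sqrt(fg$fx^2 + fg$fy^2) / 0.5
  m <- matrix(1, ny, nx)
  if (low_cut_frac > 0) {
    lo <- pmin(pmax((r - low_cut_frac) / soft, 0), 1)
    m <- m * (0.5 - 0.5 * cos(pi * lo))
  }
  hi <- pmin(pmax((high_cut_frac - r) / soft, 0), 1)
  m <- m * (0.5 - 0.5 * cos(pi * hi))
  if (length(.band_mask_cache) > 200)
    rm(list = ls(.band_mask_cache), envir = .band_mask_cache)
  .band_mask_cache[[key]] <- m
  m
}

# cross-correlation surface (zero shift at the centre pixel) given the
# conjugate cross spectrum and a band mask
xc_surface <- function(cross_spec, mask = NULL) {
  if (!is.null(mask)) cross_spec <- cross_spec * mask
  cc <- Re(fft(cross_spec, inverse = TRUE)) / length(cross_spec)
  fftshift2(cc)
}

# locate the correlation maximum with 3x3 parabolic sub-pixel refinement and
# score it against an annulus (sized relative to the image so the score is
# comparable across scales and clears the autocorrelation footprint of
# extended features)
xc_peak <- function(cc, annulus = NULL) {
  ny <- nrow(cc); nx <- ncol(cc)
  if (is.null(annulus))
    annulus <- c(0.25, 0.45) * min(ny, nx)
  idx <- arrayInd(which.max(cc), dim(cc))
  r <- idx[1]; c <- idx[2]
  pk <- cc[r, c]
  sub <- c(0, 0)
  if (r > 1 && r < ny) {
    den <- cc[r - 1, c] - 2 * pk + cc[r + 1, c]
    if (den < 0) sub[2] <- 0.5 * (cc[r - 1, c] - cc[r + 1, c]) / den
  }
  if (c > 1 && c < nx) {
    den <- cc[r, c - 1] - 2 * pk + cc[r, c + 1]
    if (den < 0) sub[1] <- 0.5 * (cc[r, c - 1] - cc[r, c + 1]) / den
  }
  cy <- floor(ny / 2) + 1L; cx <- floor(nx / 2) + 1L
  # annulus around the peak (clipped at the image border)
  rows <- matrix(seq_len(ny) - r, ny, nx)
  cols <- matrix(seq_len(nx) - c, ny, nx, byrow = TRUE)
  d <- sqrt(rows^2 + cols^2)
  ann <- abs(cc[d >= annulus[1] & d <= annulus[2]])
  quality <- pk / max(mean(ann), 1e-12)
  list(dx = c - cx + sub[1], dy = r - cy + sub[2],
       peak = pk, quality = quality)
}

norm_image <- function(img) {
  img - mean(img)
}

#' Bandpass parameters for cross-correlation
#' @param low_cut_frac,high_cut_frac cutoffs as fractions of Nyquist,
#'   `0 <= low < high <= 1`.
#' @param peak_quality score of the resulting correlation peak (filled by
#'   [auto_bandpass()]).
#' @return list of class `bandpass_params`.
#' @export
bandpass_params <- function(low_cut_frac = 0, high_cut_frac = 1,
                            peak_quality = NA_real_) {
  stopifnot(low_cut_frac >= 0, low_cut_frac < high_cut_frac,
            high_cut_frac <= 1)
  structure(list(low_cut_frac = low_cut_frac,
                 high_cut_frac = high_cut_frac,
                 peak_quality = peak_quality), class = "bandpass_params")
}

# default cutoff grid (fractions of Nyquist)
BANDPASS_GRID <- list(low = c(0, 0.01, 0.02, 0.05, 0.1),
                      high = c(0.15, 0.25, 0.5, 1.0))

#' Choose the bandpass that sharpens the correlation peak most
#'
#' Grid search over low/high cutoff pairs, maximising the peak-quality
#' score (peak height over mean annulus level) of the filtered
#' cross-correlation between the two images.
#'
#' @param imageA,imageB equal-sized matrices.
#' @param grid list with `low` and `high` cutoff candidates (fractions of
#'   Nyquist).
#' @return a [bandpass_params()] with `peak_quality` set.
#' @export
auto_bandpass <- function(imageA, imageB, grid = BANDPASS_GRID) {
  stopifnot(all(dim(imageA) == dim(imageB)))
  ny <- nrow(imageA); nx <- ncol(imageA)
  cs <- Conj(fft(norm_image(imageA))) * fft(norm_image(imageB))
  best <- bandpass_params(0, 1, -Inf)
  for (lo in grid$low) {
    for (hi in grid$high) {
      if (lo >= hi) next
      cc <- xc_surface(cs, band_mask(ny, nx, lo, hi))
      q <- xc_peak(cc)$quality
      if (q > best$peak_quality)
        best <- bandpass_params(lo, hi, q)
    }
  }
  best
}

#' Shift between two images from the cross-correlation peak
#'
#' Returns the displacement `(dx, dy)` such that `imageB` is `imageA` with
#' its features moved by `(dx, dy)` pixels (sub-pixel parabolic
#' refinement), plus the peak-quality score.
#'
#' @param imageA,imageB equal-sized matrices.
#' @param band a [bandpass_params()] (default: no filtering).
#' @return list with `dx`, `dy`, `quality`.
#' @export
pair_shift <- function(imageA, imageB, band = bandpass_params()) {
  stopifnot(all(dim(imageA) == dim(imageB)))
  ny <- nrow(imageA); nx <- ncol(imageA)
  cs <- Conj(fft(norm_image(imageA))) * fft(norm_image(imageB))
  cc <- xc_surface(cs, band_mask(ny, nx, band$low_cut_frac,
                                 band$high_cut_frac))
  p <- xc_peak(cc)
  list(dx = p$dx, dy = p$dy, quality = p$quality)
}

# Empirical null for the peak-quality score: upper envelope of the 99th
# percentiles over seeded independent-noise pairs at window sizes 48-512
# (see calibrate_peak_null(); the stored default covers the worst size).
PEAK_QUALITY_NULL <- 7.2

#' Null distribution of the peak-quality score
#'
#' Computes the quality score of [auto_bandpass()] on pairs of independent
#' Gaussian-noise images; its upper quantile defines the "no robust peak"
#' threshold used by [align_pairs()] and [track_patches()].
#'
#' @param n number of noise pairs.
#' @param size image side in pixels.
#' @param seed RNG seed.
#' @param probs quantiles to report.
#' @return quantiles of the null quality distribution.
#' @export
calibrate_peak_null <- function(n = 200, size = 128, seed = 42,
                                probs = c(0.5, 0.95, 0.99)) {
  q <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      a <- matrix(rnorm(size^2), size)
      b <- matrix(rnorm(size^2), size)
      auto_bandpass(a, b)$peak_quality
    }, numeric(1))
  })
  quantile(q, probs)
}
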