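deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Apply a similarity transform to an image
#'
#' Resamples `img` so that a feature at centred position `p` (x = column,
#' y = row, origin at the image centre) moves to
#' `scale * R(rot_deg) %*% p + shift`.  A single bilinear interpolation is
#' used however the transform was composed.
#'
#' @param img numeric matrix (row = y, column = x).
#' @param rot_deg in-plane rotation in degrees, counter-clockwise in (x, y).
#' @param scale isotropic magnification factor.
#' @param shift numeric length-2, (dx, dy) in pixels.
#' @param fill value used outside the source support (default: image mean).
#' @return transformed matrix of the same size.
#' @export
warp_image <- function(img, rot_deg = 0, scale = 1, shift = c(0, 0),
                       fill = NULL) {
  th <- deg2rad(rot_deg)
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  warp_affine(img, A, shift, fill)
}

# exact lossless rotation of square-image content by k * 90 degrees CCW
# in (x, y): feature (x, y) -> (-y, x) per step
rot90_content <- function(m, k) {
  k <- k %% 4L
  n <- nrow(m)
  for (i in seq_len(k)) m <- t(m[rev(seq_len(n)), , drop = FALSE])
  m
}

#' Apply a general 2x3 affine transform to an image
#'
#' Feature-motion convention: a feature at centred position `p` moves to
#' `A %*% p + b`.  For square images the rotation part is decomposed into
#' an exact 90-degree permutation plus a small residual, so a transform
#' near a quarter turn loses almost no field of view to interpolation
#' fill.
#' @param img numeric matrix.
#' @param A 2x2 matrix.
#' @param b length-2 shift (dx, dy) in pixels.
#' @param fill fill value outside the source support.
#' @return transformed matrix.
#' @export
warp_affine <- function(img, A, b = c(0, 0), fill = NULL) {
  if (is.null(fill)) fill <- mean(img)
  th <- atan2(A[2, 1], A[1, 1])
  k <- as.integer(round(th / (pi / 2))) %% 4L
  if (k != 0L && nrow(img) == ncol(img)) {
    img <- rot90_content(img, k)
    thk <- k * pi / 2
    Rk <- matrix(c(cos(thk), sin(thk), -sin(thk), cos(thk)), 2, 2)
    A <- A %*% t(Rk)
  }
  if (max(abs(A - diag(2))) < 1e-12 && max(abs(b)) < 1e-12)
    return(img)
  Minv <- solve(A)
  tvec <- -Minv %*% c(b[1], b[2])
  .warp_affine_cpp(img, as.numeric(Minv), as.numeric(tvec), fill)
}

#' Bin (downsample) an image
#'
#' Integer factors use exact block averaging (mean pooling: a constant image
#' stays constant and total intensity is preserved up to the 1/factor^2
#' normalisation); non-integer factors use Fourier cropping.
#'
#' @param pixels numeric matrix.
#' @param factor binning factor, `>= 1`.
#' @return matrix of dimension `floor(dim(pixels) / factor)`.
#' @export
bin_image <- function(pixels, factor) {
  stopifnot(is.matrix(pixels), factor >= 1)
  ny <- nrow(pixels); nx <- ncol(pixels)
  oy <- floor(ny / factor); ox <- floor(nx / factor)
  if (ox < 1 || oy < 1)
    stop("bin factor ", factor, " larger than image (", ny, "x", nx, ")")
  if (factor == round(factor)) {
    f <- as.integer(round(factor))
    if (f == 1L) return(pixels)
    sub <- pixels[seq_len(oy * f), seq_len(ox * f), drop = FALSE]
    # fold each f x f block and average (vectorised two-stage colMeans)
    dim(sub) <- c(f, oy, f, ox)
    m <- colMeans(sub)                # averages rows within blocks
    out <- colMeans(aperm(m, c(2, 1, 3)))  # then columns within blocks
    return(matrix(out, oy, ox))
  }
  # Fourier crop preserves mean intensity
  ft <- fftshift2(fft(pixels))
  cy <- floor(ny / 2) + 1L; cx <- floor(nx / 2) + 1L
  ry <- seq.int(cy - floor(oy / 2), length.out = oy)
  rx <- seq.int(cx - floor(ox / 2), length.out = ox)
  cr <- ft[ry, rx, drop = FALSE]
  out <- Re(fft(ifftshift2(cr), inverse = TRUE)) / (ny * nx)
  out * 1  # already mean-preserving at DC
}

#' Centre the zero-frequency component of a 2D spectrum
#' @param m matrix.
#' @return matrix with quadrants swapped.
#' @export
fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  sy <- ceiling(ny / 2); sx <- ceiling(nx / 2)
  m[c(seq.int(sy + 1, ny), seq_len(sy)), c(seq.int(sx + 1, nx), seq_len(sx))]
}

#' @rdname fftshift2
#' @export
ifftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  sy <- floor(ny / 2); sx <- floor(nx / 2)
  m[c(seq.int(sy + 1, ny), seq_len(sy)), c(seq.int(sx + 1, nx), seq_len(sx))]
}

# radial spatial-frequency magnitude (cycles/pixel, unshifted layout)
freq_grid <- function(ny, nx) {
  fy <- c(seq(0, floor(ny / 2)), seq(-(ceiling(ny / 2) - 1), -1)) / ny
  fx <- c(seq(0, floor(nx / 2)), seq(-(ceiling(nx / 2) - 1), -1)) / nx
  list(fy = matrix(fy, ny, nx), fx = matrix(fx, ny, nx, byrow = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
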