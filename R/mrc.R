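#' Read an MRC2014 image stack
#'
#' Little-endian MRC with data modes 1 (int16), 2 (float32) and 12 (half
#' precision) are supported.  The extended header, if any, is skipped for
#' pixel data but kept verbatim so a round trip preserves it.
#'
#' @param path file path.
#' @return list with `data` (3D array, dim = c(ny, nx, nz), image k at
#'   `data[, , k]`), `pixel_size_A`, `mode`, and `ext_header` (raw vector).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L) stop("truncated MRC header in ", path)
  int_at <- function(i) readBin(hdr[i:(i + 3)], "integer", 1, 4,
                                endian = "little")
  flt_at <- function(i) readBin(hdr[i:(i + 3)], "numeric", 1, 4,
                                endian = "little")
  nx <- int_at(1); ny <- int_at(5); nz <- int_at(9)
  mode <- int_at(13)
  mx <- int_at(29)
  cella_x <- flt_at(41)
  nsymbt <- int_at(93)
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("invalid MRC dimensions in ", path)
  ext <- if (nsymbt > 0) readBin(con, "raw", n = nsymbt) else raw(0)
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "12" = half_to_double(readBin(con, "integer", n = n, size = 2,
                                  signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", mode, " in ", path))
  if (length(vals) < n) stop("truncated MRC data in ", path)
  pix <- if (mx > 0 && cella_x > 0) cella_x / mx else NA_real_
  # MRC stores x fastest, then y, then section: reshape to [y, x, section]
  arr <- array(as.double(vals), dim = c(nx, ny, nz))
  arr <- aperm(arr, c(2, 1, 3))
  list(data = arr, pixel_size_A = pix, mode = mode, ext_header = ext)
}

#' Write an MRC2014 stack (mode 2, little-endian)
#'
#' @param data 3D array dim c(ny, nx, nz) or a matrix (written as one
#'   section).
#' @param path output path.
#' @param pixel_size_A physical pixel size written into the cell dimensions.
#' @param ext_header optional raw vector preserved from a previous read.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, pixel_size_A = 1, ext_header = raw(0)) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  ny <- dim(data)[1]; nx <- dim(data)[2]; nz <- dim(data)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz))            # NX NY NZ
  wi(2)                        # MODE
  wi(c(0, 0, 0))               # NXSTART..
  wi(c(nx, ny, nz))            # MX MY MZ
  wf(c(nx, ny, nz) * pixel_size_A)  # CELLA
  wf(c(90, 90, 90))            # CELLB
  wi(c(1, 2, 3))               # MAPC MAPR MAPS
  wf(c(min(data), max(data), mean(data)))  # DMIN DMAX DMEAN
  wi(1)                        # ISPG (image stack convention: 0/1)
  wi(length(ext_header))       # NSYMBT
  writeBin(raw(100), con)      # EXTRA
  wf(c(0, 0, 0))               # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(data))                 # RMS
  wi(0)                        # NLABL
  writeBin(raw(800), con)      # LABEL
  if (length(ext_header)) writeBin(ext_header, con)
  writeBin(as.numeric(aperm(data, c(2, 1, 3))), con, size = 4,
           endian = "little")
  invisible(path)
}

# IEEE 754 half-precision decode, vectorised over unsigned 16-bit integers.
half_to_double <- function(u) {
  sign <- ifelse(bitwAnd(u, 0x8000L) > 0L, -1, 1)
  expo <- bitwAnd(bitwShiftR(u, 10L), 0x1FL)
  frac <- bitwAnd(u, 0x3FFL)
  out <- numeric(length(u))
  norm <- expo > 0L & expo < 31L
  out[norm] <- sign[norm] * 2^(expo[norm] - 15) * (1 + frac[norm] / 1024)
  sub <- expo == 0L
  out[sub] <- sign[sub] * 2^-14 * (frac[sub] / 1024)
  inf <- expo == 31L
  out[inf] <- ifelse(frac[inf] == 0L, sign[inf] * Inf, NaN)
  out
}

#' Read a plain-text tilt-angle file (one angle per line)
#' @param path `.rawtlt`/`.tlt`-style file.
#' @return numeric vector of angles in degrees.
#' @export
read_rawtlt <- function(path) {
  as.numeric(readLines(path, warn = FALSE))
}
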