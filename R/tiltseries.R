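#' Construct a tilt series
#'
#' The central container every processing stage transforms: an ordered list
#' of tilt images plus per-image acquisition metadata and usability flags.
#'
#' @param images list of numeric matrices, all of equal dimension.
#' @param tilt_angle_deg nominal stage tilt per image (degrees, |a| <= 90).
#' @param pixel_size_A physical pixel size in Angstrom.
#' @param applied_defocus_um defocus requested at acquisition (positive =
#'   underfocus), recycled if scalar.
#' @param dose_e_per_A2 accumulated dose per image in electrons per square
#'   Angstrom, recycled if scalar.
#' @param acquisition_index integer recording order (unique); defaults to
#'   `seq_along(images)`.
#' @param nominal_tilt_axis_deg instrument tilt-axis angle, degrees
#'   counter-clockwise from the image Y axis.
#' @param pre_tilt_deg optional lamella pre-tilt in degrees.
#' @param usable logical per-image usability flags.
#' @param order `"acquisition"` or `"by_tilt"`.
#' @return object of class `tilt_series`.
#' @export
tilt_series <- function(images, tilt_angle_deg, pixel_size_A = 1,
                        applied_defocus_um = NA_real_,
                        dose_e_per_A2 = NA_real_,
                        acquisition_index = seq_along(images),
                        nominal_tilt_axis_deg = 0, pre_tilt_deg = 0,
                        usable = rep(TRUE, length(images)),
                        order = c("acquisition", "by_tilt")) {
  order <- match.arg(order)
  n <- length(images)
  if (n == 0L) stop("a tilt series needs at least one image")
  d <- dim(images[[1]])
  if (is.null(d) || any(d < 1)) stop("images must be non-empty matrices")
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("all images in a tilt series must share dimensions")
  if (length(tilt_angle_deg) != n)
    stop("metadata mismatch: ", n, " images but ", length(tilt_angle_deg),
         " tilt angles")
  if (any(abs(tilt_angle_deg) > 90)) stop("|tilt angle| must be <= 90 deg")
  if (anyDuplicated(acquisition_index))
    stop("acquisition_index must be unique")
  if (length(usable) != n) stop("usable flags must match image count")
  meta <- data.frame(
    tilt_angle_deg = as.numeric(tilt_angle_deg),
    applied_defocus_um = rep_len(as.numeric(applied_defocus_um), n),
    dose_e_per_A2 = rep_len(as.numeric(dose_e_per_A2), n),
    acquisition_index = as.integer(acquisition_index),
    usable = as.logical(usable))
  if (order == "by_tilt" && is.unsorted(meta$tilt_angle_deg))
    stop("order 'by_tilt' requires non-decreasing tilt angles")
  structure(list(images = images, meta = meta,
                 pixel_size_A = as.numeric(pixel_size_A),
                 nominal_tilt_axis_deg = as.numeric(nominal_tilt_axis_deg),
                 pre_tilt_deg = as.numeric(pre_tilt_deg),
                 order = order, extra = list()),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(paste0("<tilt_series> %d images (%dx%d px, %.3f A/px), ",
                     "tilt %g..%g deg, axis %g deg, %d usable, order=%s\n"),
              n_images(x), d[1], d[2], x$pixel_size_A,
              min(x$meta$tilt_angle_deg), max(x$meta$tilt_angle_deg),
              x$nominal_tilt_axis_deg, sum(x$meta$usable), x$order))
  invisible(x)
}

#' Number of images in a tilt series
#' @param series a `tilt_series`.
#' @return integer count.
#' @export
n_images <- function(series) length(series$images)

#' Read a tilt series from disk
#'
#' Accepts a single MRC stack or a directory of per-tilt MRC/TIFF files
#' (sorted by name).  `metadata` supplies per-image tilt angles (required)
#' and optional defocus/dose/pixel-size fields; pixel size falls back to the
#' MRC header when absent.
#'
#' @param path MRC stack path or directory.
#' @param metadata list with `tilt_angle_deg` (numeric, one per image) and
#'   optionally `pixel_size_A`, `applied_defocus_um`, `dose_e_per_A2`,
#'   `nominal_tilt_axis_deg`, `pre_tilt_deg`.  May also be a path to a JSON
#'   sidecar with those fields.
#' @return a `tilt_series` in acquisition order with all images usable.
#' @export
read_tilt_series <- function(path, metadata) {
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- jsonlite::read_json(metadata, simplifyVector = TRUE)
  angles <- metadata$tilt_angle_deg
  if (is.null(angles)) stop("metadata must supply tilt_angle_deg")
  hdr_pix <- NA_real_
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(mrc|st|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no MRC/TIFF files found in ", path)
    images <- lapply(files, function(f) {
      if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
        if (!requireNamespace("tiff", quietly = TRUE))
          stop("package 'tiff' is required to read TIFF tilt images")
        m <- tiff::readTIFF(f)
        if (length(dim(m)) == 3L) m <- m[, , 1]
        m
      } else {
        read_mrc(f)$data[, , 1]
      }
    })
  } else {
    mrc <- read_mrc(path)
    hdr_pix <- mrc$pixel_size_A
    images <- lapply(seq_len(dim(mrc$data)[3]), function(k) mrc$data[, , k])
  }
  if (length(images) != length(angles))
    stop("metadata mismatch: ", length(images), " images but ",
         length(angles), " tilt angles")
  pix <- metadata$pixel_size_A %||% hdr_pix
  if (is.na(pix)) pix <- 1
  tilt_series(images, angles, pixel_size_A = pix,
              applied_defocus_um = metadata$applied_defocus_um %||% NA_real_,
              dose_e_per_A2 = metadata$dose_e_per_A2 %||% NA_real_,
              nominal_tilt_axis_deg = metadata$nominal_tilt_axis_deg %||% 0,
              pre_tilt_deg = metadata$pre_tilt_deg %||% 0)
}

#' Write a tilt series as an MRC stack
#'
#' @param series a `tilt_series`.
#' @param path output MRC path.
#' @param include_unusable write all images (`TRUE`) or only usable ones in
#'   ascending-tilt order (`FALSE`, the "clean stack" convention).
#' @return `path`, invisibly.
#' @export
write_tilt_series <- function(series, path, include_unusable = TRUE) {
  keep <- if (include_unusable) seq_len(n_images(series)) else
    which(series$meta$usable)
  if (!length(keep)) stop("no usable images to write")
  if (!include_unusable) keep <- keep[order(series$meta$tilt_angle_deg[keep])]
  d <- dim(series$images[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(keep)))
  for (i in seq_along(keep)) arr[, , i] <- series$images[[keep[i]]]
  write_mrc(arr, path, pixel_size_A = series$pixel_size_A)
}

#' Reorder a tilt series by ascending tilt angle
#'
#' Ties (duplicate tilt angles) break deterministically by acquisition
#' index.  Per-image metadata, flags and acquisition indices travel with
#' their images.
#'
#' @param series a `tilt_series`.
#' @return the reordered `tilt_series` with `order == "by_tilt"`.
#' @export
reorder_by_tilt <- function(series) {
  o <- order(series$meta$tilt_angle_deg, series$meta$acquisition_index)
  series$images <- series$images[o]
  series$meta <- series$meta[o, , drop = FALSE]
  rownames(series$meta) <- NULL
  series$order <- "by_tilt"
  series
}

# index of the image whose tilt angle is closest to zero (usable preferred)
zero_tilt_index <- function(series, usable_only = TRUE) {
  a <- abs(series$meta$tilt_angle_deg)
  if (usable_only && any(series$meta$usable)) a[!series$meta$usable] <- Inf
  which.min(a)
}
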