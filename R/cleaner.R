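# Stack cleaner: flag obviously unusable tilt images (grid bars entering the
# field of view, shutter failures) from the pairwise correlation of their
# gray-value histograms.  Position-free by construction, so high-contrast
# features present in every image (e.g. fiducials) do not trigger removal.

#' Stack-cleaner configuration
#'
#' An image is kept when its histogram correlates above
#' `mean + sigma_multiplier * sigma` (matrix statistics over the
#' off-diagonal upper triangle) with more than `support_count` other
#' images.
#'
#' @param n_bins histogram bin count (>= 16).
#' @param sigma_multiplier threshold offset in matrix standard deviations.
#' @param support_count minimum number of supporting images (strictly
#'   exceeded).
#' @param method histogram similarity: `"intersection"` (overlap of the
#'   L1-normalised histograms, the default: it keeps its dynamic range when
#'   histograms are strongly dissimilar) or `"pearson"` correlation.
#' @return list of class `cleaner_config`.
#' @export
cleaner_config <- function(n_bins = 256, sigma_multiplier = 1,
                           support_count = 4,
                           method = c("intersection", "pearson")) {
  stopifnot(n_bins >= 16, support_count >= 1)
  structure(list(n_bins = n_bins, sigma_multiplier = sigma_multiplier,
                 support_count = support_count,
                 method = match.arg(method)), class = "cleaner_config")
}

#' Gray-value histogram of an image
#'
#' Binned over a robust intensity range (by default the image's own 1st-99th
#' percentile; the series-wide range is passed in by
#' [histogram_correlation_matrix()]), L1-normalised.  A constant image
#' yields a single occupied bin.
#'
#' @param pixels numeric matrix.
#' @param n_bins number of bins (>= 2).
#' @param range optional length-2 intensity range.
#' @return numeric vector of bin fractions summing to 1.
#' @export
gray_histogram <- function(pixels, n_bins = 256, range = NULL) {
  stopifnot(n_bins >= 2)
  if (is.null(range)) range <- quantile(pixels, c(0.01, 0.99), names = FALSE)
  if (diff(range) <= 0) {
    h <- numeric(n_bins)
    h[1] <- 1
    return(h)
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(pixels, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)
  h <- tabulate(idx, nbins = n_bins)
  h / sum(h)
}

safe_cor <- function(a, b) {
  if (sd(a) < 1e-15 || sd(b) < 1e-15)
    return(if (max(abs(a - b)) < 1e-12) 1 else 0)
  stats::cor(a, b)
}

#' Histogram correlation matrix of a tilt series
#'
#' Entry (i, j) is the correlation of the gray-value histograms of images i
#' and j, binned over the series-wide robust (1st-99th percentile)
#' intensity range.
#'
#' @param series a `tilt_series`.
#' @param config a [cleaner_config()].
#' @return list of class `correlation_matrix` with `values` (symmetric, unit
#'   diagonal), `mean` and `sigma` of the off-diagonal upper triangle.
#' @export
histogram_correlation_matrix <- function(series,
                                         config = cleaner_config()) {
  n <- n_images(series)
  if (n < 2) stop("need at least two images")
  all_range <- quantile(unlist(lapply(series$images, function(m)
    quantile(m, c(0.01, 0.99), names = FALSE))), c(0, 1), names = FALSE)
  H <- vapply(series$images, gray_histogram, numeric(config$n_bins),
              n_bins = config$n_bins, range = all_range)
  V <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      v <- if (config$method == "pearson") safe_cor(H[, i], H[, j])
           else sum(pmin(H[, i], H[, j]))
      V[i, j] <- V[j, i] <- v
    }
  }
  ut <- V[upper.tri(V)]
  structure(list(values = V, mean = mean(ut), sigma = sd(ut)),
            class = "correlation_matrix")
}

#' Flag non-usable tilt images from the correlation matrix
#'
#' Image i stays usable iff its correlation with more than `support_count`
#' other images exceeds the threshold `mean + sigma_multiplier * sigma`,
#' capped at the off-diagonal median: similarities live on a bounded,
#' often strongly left-skewed scale, where the uncapped mean-plus-sigma
#' level can exceed every entry of a perfectly clean matrix.  With a
#' degenerate sigma of zero (identical histograms) the threshold drops to
#' `mean - 1e-9` so perfect stacks are fully usable.
#'
#' @param matrix a `correlation_matrix`.
#' @param config a [cleaner_config()].
#' @return logical usability flags.
#' @export
flag_non_usable <- function(matrix, config = cleaner_config()) {
  V <- matrix$values
  n <- nrow(V)
  if (n < config$support_count + 2) {
    warning("series shorter than support_count + 2; keeping all images")
    return(rep(TRUE, n))
  }
  thr <- cleaner_threshold(matrix, config)
  vapply(seq_len(n), function(i) {
    sum(V[i, -i] > thr) > config$support_count
  }, logical(1))
}

cleaner_threshold <- function(matrix, config) {
  if (matrix$sigma < 1e-12) return(matrix$mean - 1e-9)
  ut <- matrix$values[upper.tri(matrix$values)]
  min(matrix$mean + config$sigma_multiplier * matrix$sigma,
      median(ut))
}

#' Run the stack cleaner on a tilt series
#'
#' @param series a `tilt_series`.
#' @param config a [cleaner_config()].
#' @return list with the updated `series` (flags ANDed in), the
#'   `correlation_matrix`, per-image `support` counts and the `usable`
#'   flags.
#' @export
clean_stack <- function(series, config = cleaner_config()) {
  m <- histogram_correlation_matrix(series, config)
  flags <- flag_non_usable(m, config)
  thr <- cleaner_threshold(m, config)
  support <- vapply(seq_len(nrow(m$values)), function(i)
    sum(m$values[i, -i] > thr), integer(1))
  series$meta$usable <- series$meta$usable & flags
  list(series = series, matrix = m, support = support, usable = flags)
}
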