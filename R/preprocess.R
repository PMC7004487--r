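#' Rolling-ball background subtraction
#'
#' Estimates a smooth background per z-slice as the grey-scale morphological
#' opening of the slice with a non-flat ball structuring element of the given
#' radius, and subtracts it.  The opening is a lower envelope of the image, so
#' the result is nonnegative and voxelwise no larger than the input.  Applied
#' independently to every channel and every slice (2D), matching how stack
#' processing is conventionally done before volumetric thresholding.
#'
#' @param stack an [image_stack()].
#' @param radius_px ball radius in pixels (default 50).
#' @param channels channels to process (default: all).
#' @return an `image_stack` with background-subtracted channels.
#' @export
subtract_background <- function(stack, radius_px = 50L, channels = NULL) {
  assert_that(is_count(radius_px), "`radius_px` must be a positive integer")
  d <- dim_stack(stack)
  assert_that(radius_px <= max(d[1], d[2]) ,
              "ball radius %d exceeds both in-plane dimensions (%d x %d)",
              radius_px, d[1], d[2])
  channels <- channels %||% names(stack$channels)
  out <- stack
  for (nm in channels) {
    arr <- get_channel(stack, nm)
    for (z in seq_len(d[3])) {
      bg <- cpp_ball_opening(arr[, , z], as.integer(radius_px))
      arr[, , z] <- pmax(arr[, , z] - bg, 0)
    }
    out$channels[[nm]] <- arr
  }
  out$bit_depth <- stack$bit_depth
  out
}

#' Disk median filter
#'
#' Per-slice 2D median over a disk neighbourhood (`dx^2 + dy^2 <= r^2`), with
#' edge handling by symmetric reflection.
#'
#' @inheritParams subtract_background
#' @param radius_px disk radius in pixels (default 2).
#' @return a filtered `image_stack`.
#' @export
median_filter <- function(stack, radius_px = 2L, channels = NULL) {
  assert_that(is_count(radius_px), "`radius_px` must be a positive integer")
  d <- dim_stack(stack)
  channels <- channels %||% names(stack$channels)
  out <- stack
  for (nm in channels) {
    arr <- get_channel(stack, nm)
    for (z in seq_len(d[3])) {
      arr[, , z] <- cpp_median_disk(arr[, , z], as.integer(radius_px))
    }
    out$channels[[nm]] <- arr
  }
  out
}

# Histogram-based Otsu threshold: given bin counts and bin representative
# values, returns the index of the last bin of the lower class at the split
# maximizing the between-class variance; smallest maximizer on plateaus.
otsu_split_from_counts <- function(counts, values) {
  n <- sum(counts)
  w <- cumsum(counts) / n
  mu <- cumsum(counts * values) / n
  mu_t <- mu[length(mu)]
  # between-class variance for the split after bin k (classes 1..k vs rest):
  # w0*w1*(mu0-mu1)^2 = (mu_t*w0 - mu)^2 / (w0*(1-w0))
  k <- seq_len(length(counts) - 1L)
  w0 <- w[k]
  valid <- w0 > 0 & w0 < 1
  assert_that(any(valid), "no threshold exists: channel is constant")
  bcv <- rep(-Inf, length(k))
  bcv[valid] <- (mu_t * w0[valid] - mu[k][valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  which(bcv == max(bcv))[1]   # smallest maximizing split
}

#' Otsu binarization on the stack histogram
#'
#' Computes a single Otsu threshold from the intensity histogram pooled over
#' all z-slices of a channel and returns the mask `intensity > threshold`.
#' The histogram has `n_bins` bins spanning the declared bit-depth range for
#' integer data (so 8-bit data with the default 256 bins is thresholded on
#' the exact integer histogram) or the min-max range for float data.  On
#' plateaus of the between-class variance, the smallest maximizing threshold
#' is chosen, making the result fully deterministic.
#'
#' @inheritParams subtract_background
#' @param channel channel name to binarize.
#' @param n_bins number of histogram bins (default 256).
#' @return a [binary_mask()] recording the threshold used.
#' @export
otsu_binarize <- function(stack, channel, n_bins = 256L) {
  arr <- get_channel(stack, channel)
  rng <- range(arr)
  assert_that(diff(rng) > 0, "no threshold exists: channel '%s' is constant",
              channel)
  integer_data <- !is.na(stack$bit_depth) && all(arr == floor(arr)) &&
    n_bins == 2^stack$bit_depth
  if (integer_data) {
    # one bin per representable integer; the threshold is the grey value of
    # the last lower-class bin, and the mask is the strict exceedance of it
    values <- seq(0, 2^stack$bit_depth - 1)
    counts <- tabulate(as.integer(arr) + 1L, nbins = length(values))
    best <- otsu_split_from_counts(counts, values)
    thr <- values[best]
  } else {
    if (!is.na(stack$bit_depth)) {
      lo <- 0
      hi <- 2^stack$bit_depth - 1
    } else {
      lo <- rng[1]
      hi <- rng[2]
    }
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    bin <- pmin(pmax(findInterval(arr, edges, rightmost.closed = TRUE), 1L),
                n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    mids <- (edges[-1L] + edges[-length(edges)]) / 2
    best <- otsu_split_from_counts(counts, mids)
    thr <- edges[best + 1L]   # boundary between lower and upper class bins
  }
  binary_mask(arr > thr, channel = channel, threshold = thr,
              params = list(n_bins = n_bins))
}

#' Full image conditioning chain
#'
#' Composes the conditioning chain in its fixed order -- rolling-ball
#' background subtraction, disk median filter, stack-histogram Otsu
#' binarization -- and records every parameter in the mask provenance.
#'
#' @inheritParams subtract_background
#' @param channels channels to binarize.
#' @param ball_radius_px rolling-ball radius (default 50).
#' @param median_radius_px median disk radius (default 2).
#' @param n_bins Otsu histogram bins (default 256).
#' @return named list of [binary_mask()] objects, one per channel.
#' @export
preprocess_stack <- function(stack, channels = NULL, ball_radius_px = 50L,
                             median_radius_px = 2L, n_bins = 256L) {
  channels <- channels %||% names(stack$channels)
  s <- subtract_background(stack, radius_px = ball_radius_px,
                           channels = channels)
  s <- median_filter(s, radius_px = median_radius_px, channels = channels)
  masks <- lapply(channels, function(nm) {
    m <- otsu_binarize(s, nm, n_bins = n_bins)
    m$params <- c(m$params, list(ball_radius_px = ball_radius_px,
                                 median_radius_px = median_radius_px))
    m
  })
  setNames(masks, channels)
}

#' Write / read a binary mask as an 8-bit TIFF plus JSON provenance
#'
#' @param mask a [binary_mask()].
#' @param path output TIFF path; the provenance sidecar is written next to it
#'   with extension `.json`.
#' @export
write_mask <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask$mask)[3]),
                  function(z) mask$mask[, , z] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(channel = mask$channel,
                            threshold = mask$threshold, params = mask$params),
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(FALSE, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]] > 0
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  binary_mask(arr, channel = meta$channel, threshold = meta$threshold,
              params = as.list(meta$params))
}
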