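#' Multichannel 3D image stack
#'
#' Container for a multichannel confocal z-stack.  Each channel is a 3D
#' numeric array indexed `[y, x, z]` of nonnegative intensities; all channels
#' share dimensions, physical voxel size, and a declared bit depth.
#'
#' @param channels named list of 3D numeric arrays, all with identical
#'   dimensions `c(y, x, z)`.
#' @param voxel_size named numeric vector `c(x =, y =, z =)` in micrometres.
#' @param bit_depth integer bit depth of the acquisition (commonly 8 or 16),
#'   or `NA` for unbounded floating-point data.
#' @return an object of class `image_stack`.
#' @examples
#' a <- array(0, dim = c(8, 8, 3))
#' s <- image_stack(list(DAPI = a), voxel_size = c(x = 0.2, y = 0.2, z = 1))
#' dim_stack(s)
#' @export
image_stack <- function(channels, voxel_size = c(x = 0.2, y = 0.2, z = 1.0),
                        bit_depth = 8) {
  assert_that(is.list(channels) && length(channels) >= 1,
              "`channels` must be a non-empty list of 3D arrays")
  assert_that(!is.null(names(channels)) && all(nzchar(names(channels))) &&
                !anyDuplicated(names(channels)),
              "channels must have unique non-empty names")
  dims <- lapply(channels, dim)
  assert_that(all(vapply(dims, length, 1L) == 3L),
              "every channel must be a 3D array (y, x, z)")
  assert_that(length(unique(dims)) == 1L, "channels must share dimensions")
  assert_that(all(dims[[1]] >= 1L), "all stack dimensions must be >= 1")
  voxel_size <- voxel_size[c("x", "y", "z")]
  assert_that(all(is.finite(voxel_size)) && all(voxel_size > 0),
              "voxel_size must have positive x, y, z components (um)")
  if (!is.na(bit_depth)) {
    hi <- 2^bit_depth - 1
    for (nm in names(channels)) {
      v <- channels[[nm]]
      assert_that(all(v >= 0) && all(v <= hi),
                  "channel '%s' has intensities outside [0, %d]", nm, hi)
    }
  } else {
    for (nm in names(channels)) {
      assert_that(all(channels[[nm]] >= 0),
                  "channel '%s' has negative intensities", nm)
    }
  }
  structure(list(channels = channels, voxel_size = voxel_size,
                 bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d (y,x,z), %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um (x,y,z), bit depth %s\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              as.character(x$bit_depth)))
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `image_stack`.
#' @export
dim_stack <- function(stack) dim(stack$channels[[1]])

#' @rdname image_stack
#' @param channel channel name.
#' @export
get_channel <- function(stack, channel) {
  assert_that(channel %in% names(stack$channels),
              "channel '%s' not present (have: %s)", channel,
              paste(names(stack$channels), collapse = ", "))
  stack$channels[[channel]]
}

#' Binary mask with provenance
#'
#' A boolean voxel mask matching one channel of a stack, carrying the source
#' channel name and the threshold (and any other parameters) that produced it.
#'
#' @param mask logical 3D array `[y, x, z]`.
#' @param channel source channel name.
#' @param threshold numeric threshold that produced the mask.
#' @param params list of additional provenance entries.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, channel, threshold, params = list()) {
  assert_that(is.logical(mask) && length(dim(mask)) == 3L,
              "`mask` must be a logical 3D array")
  structure(list(mask = mask, channel = channel, threshold = threshold,
                 params = params),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> channel '%s', threshold %.6g, %d/%d voxels positive\n",
              x$channel, x$threshold, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Region-of-interest set as a label volume
#'
#' Named regions (taste buds or cells) stored as an integer label volume:
#' 0 is outside every region, positive integers identify regions.
#'
#' @param labels integer 3D array `[y, x, z]` (or 2D matrix for planar ROIs,
#'   which is promoted to a single-slice volume).
#' @param kind `"bud"` or `"cell"`.
#' @param voxel_size physical voxel size copied from the source stack.
#' @param names optional character names for the labels (in label order).
#' @return object of class `roi_set`.
#' @export
roi_set <- function(labels, kind = c("bud", "cell"),
                    voxel_size = c(x = 0.2, y = 0.2, z = 1.0), names = NULL) {
  kind <- match.arg(kind)
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  assert_that(length(dim(labels)) == 3L, "`labels` must be a 2D or 3D array")
  assert_that(all(labels >= 0) && all(labels == floor(labels)),
              "labels must be nonnegative integers")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  assert_that(length(ids) >= 1L, "ROI set contains no regions")
  if (!is.null(names)) {
    assert_that(length(names) == length(ids), "one name per label required")
  } else {
    names <- paste0(kind, "_", ids)
  }
  structure(list(labels = labels, kind = kind,
                 voxel_size = voxel_size[c("x", "y", "z")],
                 ids = ids, region_names = setNames(names, ids)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> kind '%s', %d region(s): %s\n", x$kind,
              length(x$ids), paste(head(x$region_names, 8), collapse = ", ")))
  invisible(x)
}

# physical volume of one voxel in um^3
voxel_volume_um3 <- function(voxel_size) {
  unname(voxel_size["x"] * voxel_size["y"] * voxel_size["z"])
}

#' Write / read an image stack as multi-page TIFF files
#'
#' One multi-page TIFF per channel plus a JSON metadata sidecar
#' (`stack_meta.json`) holding channel names, voxel size, and bit depth.
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if missing).
#' @return `write_stack` returns `dir` invisibly; `read_stack` returns an
#'   `image_stack`.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bd <- if (is.na(stack$bit_depth)) 16L else as.integer(stack$bit_depth)
  scale <- 2^bd - 1
  for (nm in names(stack$channels)) {
    arr <- stack$channels[[nm]]
    pages <- lapply(seq_len(dim(arr)[3]), function(z) arr[, , z] / scale)
    tiff::writeTIFF(pages, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = min(bd, 16L))
  }
  meta <- list(channels = names(stack$channels),
               voxel_size = as.list(stack$voxel_size),
               bit_depth = stack$bit_depth)
  jsonlite::write_json(meta, file.path(dir, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"),
                              simplifyVector = TRUE)
  bd <- meta$bit_depth
  scale <- 2^(if (is.na(bd)) 16 else bd) - 1
  channels <- lapply(meta$channels, function(nm) {
    pages <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")), all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- pages[[z]] * scale
    round(arr)
  })
  names(channels) <- meta$channels
  image_stack(channels, voxel_size = unlist(meta$voxel_size), bit_depth = bd)
}
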