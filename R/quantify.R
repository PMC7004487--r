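#' Per-bud innervation density from a binary mask
#'
#' For each bud ROI, the innervation density is the labeled volume divided by
#' the total analyzed volume: `D = (# positive voxels inside the ROI) /
#' (# voxels inside the ROI)`, pooled over all optical sections the ROI
#' spans.  Per-section records (area, positive count, density) are retained.
#'
#' @param mask a [binary_mask()].
#' @param rois a [roi_set()] of kind `"bud"` sharing the mask geometry.
#' @return list of class `bud_measurements` with elements `per_bud` (one row
#'   per bud: voxel and physical volumes, labeled volume, density) and
#'   `per_section` (one row per bud per z-section).
#' @export
innervation_density <- function(mask, rois) {
  assert_that(identical(dim(mask$mask), dim(rois$labels)),
              "mask and ROI label volume must share dimensions")
  vv <- voxel_volume_um3(rois$voxel_size)
  per_bud <- list(); per_section <- list()
  for (id in rois$ids) {
    inroi <- rois$labels == id
    n_tot <- sum(inroi)
    assert_that(n_tot > 0, "ROI '%s' is empty", rois$region_names[as.character(id)])
    n_pos <- sum(mask$mask & inroi)
    zs <- which(apply(inroi, 3, any))
    sec <- data.frame(
      bud = id, z = zs,
      area_vox = vapply(zs, function(z) sum(inroi[, , z]), 0),
      positive_vox = vapply(zs, function(z) sum(mask$mask[, , z] & inroi[, , z]), 0))
    sec$density <- sec$positive_vox / sec$area_vox
    per_section[[as.character(id)]] <- sec
    per_bud[[as.character(id)]] <- data.frame(
      bud = id, channel = mask$channel,
      total_voxels = n_tot, labeled_voxels = n_pos,
      total_um3 = n_tot * vv, labeled_um3 = n_pos * vv,
      density = n_pos / n_tot)
  }
  structure(list(per_bud = do.call(rbind, per_bud),
                 per_section = do.call(rbind, per_section),
                 channel = mask$channel, threshold = mask$threshold),
            class = "bud_measurements")
}

#' Per-bud two-channel co-occupancy fraction
#'
#' For each bud ROI, reports the fraction of reference-channel fiber volume
#' that is co-labeled: `F = |A n B n ROI| / |B n ROI|`, where `A` is the
#' co-label mask (e.g. GFP) and `B` the reference mask (e.g. P2X3).  Buds
#' with no reference-positive voxels get `F = NA` and a flag rather than a
#' silent zero.  Volumes `|A n ROI|`, `|B n ROI|`, and `|(A u B) n ROI|` are
#' reported alongside.
#'
#' @param mask_a co-label [binary_mask()] (numerator channel).
#' @param mask_b reference [binary_mask()] (denominator channel).
#' @param rois a [roi_set()] of kind `"bud"`.
#' @return list of class `bud_measurements` with a `per_bud` table holding
#'   the overlap fraction and component volumes.
#' @export
coloc_fraction <- function(mask_a, mask_b, rois) {
  assert_that(identical(dim(mask_a$mask), dim(mask_b$mask)),
              "the two masks must share dimensions")
  assert_that(identical(dim(mask_a$mask), dim(rois$labels)),
              "masks and ROI label volume must share dimensions")
  vv <- voxel_volume_um3(rois$voxel_size)
  rows <- lapply(rois$ids, function(id) {
    inroi <- rois$labels == id
    assert_that(sum(inroi) > 0, "ROI '%s' is empty",
                rois$region_names[as.character(id)])
    a <- sum(mask_a$mask & inroi)
    b <- sum(mask_b$mask & inroi)
    ab <- sum(mask_a$mask & mask_b$mask & inroi)
    aub <- a + b - ab
    data.frame(bud = id, a_voxels = a, b_voxels = b, ab_voxels = ab,
               union_voxels = aub, a_um3 = a * vv, b_um3 = b * vv,
               fraction = if (b > 0) ab / b else NA_real_,
               undefined = b == 0)
  })
  structure(list(per_bud = do.call(rbind, rows),
                 channels = c(a = mask_a$channel, b = mask_b$channel)),
            class = "bud_measurements")
}

# z-planes at the 25/50/75% quantiles of a bud's z-extent (floor rounding)
quadrant_planes <- function(z_extent, quantiles = c(0.25, 0.5, 0.75)) {
  zmin <- z_extent[1]; zmax <- z_extent[2]
  n <- zmax - zmin + 1L
  unique(zmin + floor(quantiles * (n - 1L)))
}

#' Count marker-positive cell profiles on quadrant planes
#'
#' Emulates profile counting on three sampled optical sections per bud: the
#' planes at 25%, 50%, and 75% of each bud's z-extent are extracted and, on
#' each, marker-positive profiles (8-connected components of the binarized
#' marker channel with area at or above `area_floor_px`) containing at least
#' one nucleus-positive pixel are counted.  Sampling a plane per quadrant
#' rather than every section avoids re-counting elongate cells that persist
#' through many optical sections.
#'
#' By default the marker and nucleus channels are binarized with a median
#' filter followed by stack-histogram Otsu; precomputed masks can be supplied
#' instead via `marker_mask`/`nucleus_mask`.
#'
#' @param stack an [image_stack()].
#' @param rois a [roi_set()] of kind `"bud"`; every bud must span at least
#'   3 z-planes.
#' @param marker_channel,nucleus_channel channel names.
#' @param area_floor_px minimum profile area in pixels (default 20).
#' @param quantiles depth quantiles of the sampled planes.
#' @param median_radius_px median prefilter radius (default 2).
#' @param marker_mask,nucleus_mask optional [binary_mask()] overrides.
#' @return data.frame with one row per bud per sampled plane (`bud`, `z`,
#'   `count`) plus attribute `totals`, a per-bud data.frame of summed counts.
#' @export
count_profiles <- function(stack, rois, marker_channel = "SNAP25",
                           nucleus_channel = "DAPI", area_floor_px = 20,
                           quantiles = c(0.25, 0.5, 0.75),
                           median_radius_px = 2L,
                           marker_mask = NULL, nucleus_mask = NULL) {
  if (is.null(marker_mask) || is.null(nucleus_mask)) {
    sm <- median_filter(stack, radius_px = median_radius_px,
                        channels = c(marker_channel, nucleus_channel))
    marker_mask <- marker_mask %||% otsu_binarize(sm, marker_channel)
    nucleus_mask <- nucleus_mask %||% otsu_binarize(sm, nucleus_channel)
  }
  rows <- list()
  for (id in rois$ids) {
    inroi <- rois$labels == id
    zs <- which(apply(inroi, 3, any))
    assert_that(length(zs) >= 3L,
                "ROI '%s' spans %d z-plane(s); at least 3 required",
                rois$region_names[as.character(id)], length(zs))
    planes <- quadrant_planes(range(zs), quantiles)
    for (z in planes) {
      m <- marker_mask$mask[, , z] & inroi[, , z]
      lab <- cpp_label8(m)
      n <- 0L
      if (max(lab) > 0) {
        areas <- tabulate(lab[lab > 0], nbins = max(lab))
        nucl <- nucleus_mask$mask[, , z]
        for (cc in which(areas >= area_floor_px)) {
          if (any(nucl[lab == cc])) n <- n + 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(bud = id, z = z, count = n)
    }
  }
  out <- do.call(rbind, rows)
  totals <- stats::aggregate(count ~ bud, out, sum)
  attr(out, "totals") <- totals
  out
}

#' Tidy export of bud measurements
#'
#' @param x a `bud_measurements` object.
#' @param path CSV path.
#' @export
write_measurements <- function(x, path) {
  write.csv(x$per_bud, path, row.names = FALSE)
  invisible(path)
}
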