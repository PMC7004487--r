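# volumetric per-bud measurements

make_roi <- function(dims, sel) {
  lab <- array(0L, dims)
  lab[sel] <- 1L
  roi_set(lab, kind = "bud")
}

test_that("innervation density is the exact voxel ratio", {
  dims <- c(25, 25, 16)
  lab <- array(0L, dims)
  lab[1:20, 1:25, 1:16] <- 1L          # 20 * 25 * 16 = 8000 voxels
  rois <- roi_set(lab, kind = "bud")
  mask <- array(FALSE, dims)
  mask[1:10, 1:10, 1:5] <- TRUE        # 500 positive, all inside ROI
  bm <- binary_mask(mask, "P2X3", 10)
  got <- innervation_density(bm, rois)
  expect_equal(got$per_bud$density, 500 / 8000)
  expect_equal(got$per_bud$labeled_voxels, 500)
  # fully positive ROI
  bm2 <- binary_mask(array(TRUE, dims), "P2X3", 0)
  expect_equal(innervation_density(bm2, rois)$per_bud$density, 1)
  # per-section records sum to the totals
  expect_equal(sum(got$per_section$positive_vox), 500)
  expect_equal(sum(got$per_section$area_vox), 8000)
})

test_that("density and overlap match triple-loop counting on small stacks", {
  set.seed(8)
  dims <- c(9, 9, 9)
  lab <- array(as.integer(runif(prod(dims)) < 0.5), dims)
  if (all(lab == 0)) lab[1] <- 1L
  rois <- roi_set(lab, kind = "bud")
  a <- array(runif(prod(dims)) < 0.3, dims)
  b <- array(runif(prod(dims)) < 0.4, dims)
  ma <- binary_mask(a, "GFP", 0); mb <- binary_mask(b, "P2X3", 0)

  n_roi <- 0; n_pos <- 0; n_ab <- 0; n_b <- 0
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    if (lab[i, j, k] == 1) {
      n_roi <- n_roi + 1
      if (b[i, j, k]) n_b <- n_b + 1
      if (b[i, j, k]) n_pos <- n_pos + 1
      if (a[i, j, k] && b[i, j, k]) n_ab <- n_ab + 1
    }
  }
  expect_equal(innervation_density(mb, rois)$per_bud$density, n_pos / n_roi)
  got <- coloc_fraction(ma, mb, rois)$per_bud
  expect_equal(got$fraction, n_ab / n_b)
})

test_that("overlap fraction handles supersets, empty references, and counts", {
  dims <- c(10, 10, 4)
  rois <- make_roi(dims, TRUE)
  b <- array(FALSE, dims); b[1:10, 1:10, 1] <- TRUE    # 100 voxels
  a <- array(FALSE, dims); a[1:5, 1:5, 1] <- TRUE      # 25, all inside b
  got <- coloc_fraction(binary_mask(a, "GFP", 0), binary_mask(b, "P2X3", 0),
                        rois)$per_bud
  expect_equal(got$fraction, 0.25)
  expect_equal(got$union_voxels, 100)

  # A superset of B gives F = 1
  got2 <- coloc_fraction(binary_mask(b, "GFP", 0),
                         binary_mask(a, "P2X3", 0), rois)$per_bud
  expect_equal(got2$fraction, 1)

  # empty reference channel: flagged NA, not silently 0
  empty <- binary_mask(array(FALSE, dims), "P2X3", 0)
  got3 <- coloc_fraction(binary_mask(a, "GFP", 0), empty, rois)$per_bud
  expect_true(is.na(got3$fraction))
  expect_true(got3$undefined)
})

test_that("measurements are invariant to ROI relabeling and joint z-permutation", {
  set.seed(13)
  dims <- c(12, 12, 6)
  lab <- array(0L, dims); lab[3:10, 3:10, 2:5] <- 7L
  mask <- array(runif(prod(dims)) < 0.3, dims)
  bm <- binary_mask(mask, "P2X3", 0)
  d1 <- innervation_density(bm, roi_set(lab, "bud"))$per_bud$density
  lab2 <- lab; lab2[lab == 7L] <- 2L
  d2 <- innervation_density(bm, roi_set(lab2, "bud"))$per_bud$density
  expect_equal(d1, d2)
  perm <- sample(6)
  d3 <- innervation_density(binary_mask(mask[, , perm], "P2X3", 0),
                            roi_set(lab[, , perm], "bud"))$per_bud$density
  expect_equal(d1, d3)
})

test_that("adding positive voxels never decreases density or overlap", {
  set.seed(21)
  dims <- c(8, 8, 4)
  rois <- make_roi(dims, TRUE)
  mask <- array(runif(prod(dims)) < 0.2, dims)
  d1 <- innervation_density(binary_mask(mask, "m", 0), rois)$per_bud$density
  mask2 <- mask; mask2[which(!mask2)[1:10]] <- TRUE
  d2 <- innervation_density(binary_mask(mask2, "m", 0), rois)$per_bud$density
  expect_gte(d2, d1)

  b <- array(runif(prod(dims)) < 0.5, dims)
  a1 <- array(runif(prod(dims)) < 0.2, dims)
  a2 <- a1; a2[which(!a2)[1:15]] <- TRUE
  f1 <- coloc_fraction(binary_mask(a1, "a", 0), binary_mask(b, "b", 0),
                       rois)$per_bud$fraction
  f2 <- coloc_fraction(binary_mask(a2, "a", 0), binary_mask(b, "b", 0),
                       rois)$per_bud$fraction
  expect_gte(f2, f1)
})

test_that("empty ROI errors name the offending region", {
  dims <- c(6, 6, 3)
  lab <- array(0L, dims); lab[1:2, 1:2, 1] <- 1L
  rois <- roi_set(lab, "bud")
  rois$ids <- c(1L, 2L)  # a region with no voxels
  rois$region_names <- c(`1` = "bud_1", `2` = "bud_2")
  bm <- binary_mask(array(FALSE, dims), "m", 0)
  expect_error(innervation_density(bm, rois), "bud_2")
})

test_that("quadrant planes follow the 25/50/75% floor rule", {
  expect_equal(quadrant_planes(c(1, 5)), c(2, 3, 4))
  expect_equal(quadrant_planes(c(1, 12)), c(1 + 2, 1 + 5, 1 + 8))
  # 3-plane extent: floor rounding maps 50% and 75% to the same plane
  expect_equal(quadrant_planes(c(4, 6)), c(4, 5))
})

test_that("constructed profiles with mid-plane nuclei are counted exactly", {
  dims <- c(40, 40, 5)
  marker <- array(FALSE, dims)
  nucleus <- array(FALSE, dims)
  at <- list(c(5, 5), c(18, 18), c(30, 8))
  for (ctr in at) {
    ys <- ctr[1]:(ctr[1] + 5); xs <- ctr[2]:(ctr[2] + 5)
    marker[ys, xs, 2:4] <- TRUE                 # 36 px per plane >= floor
    nucleus[ctr[1] + 2, ctr[2] + 2, 3] <- TRUE  # nucleus only on mid-plane
  }
  stack <- image_stack(list(SNAP25 = marker * 200, DAPI = nucleus * 200),
                       bit_depth = 8)
  rois <- make_roi(dims, TRUE)
  got <- count_profiles(stack, rois,
                        marker_mask = binary_mask(marker, "SNAP25", 0),
                        nucleus_mask = binary_mask(nucleus, "DAPI", 0))
  counts <- setNames(got$count, got$z)
  expect_equal(counts[["3"]], 3L)   # mid-plane: all three profiles
  expect_equal(counts[["2"]], 0L)   # no nucleus on the flanking planes
  expect_equal(counts[["4"]], 0L)

  # empty marker channel: all counts zero
  got0 <- count_profiles(stack, rois,
                         marker_mask = binary_mask(array(FALSE, dims), "S", 0),
                         nucleus_mask = binary_mask(nucleus, "DAPI", 0))
  expect_true(all(got0$count == 0))

  # ROI spanning < 3 planes is rejected
  thin <- array(0L, dims); thin[, , 3] <- 1L
  expect_error(count_profiles(stack, roi_set(thin, "bud"),
                              marker_mask = binary_mask(marker, "S", 0),
                              nucleus_mask = binary_mask(nucleus, "D", 0)),
               "at least 3")
})

test_that("profile counts track simulator truth within one cell per plane", {
  errs <- c()
  for (s in 1:6) {
    sim <- generate_bud_stack(
      bud_sim_params(n_buds = 4, stack_shape = c(z = 14, y = 280, x = 280),
                     fiber_density = 0.02, seed = 100 + s))
    cp <- count_profiles(sim$stack, sim$truth$roi)
    for (i in seq_len(nrow(cp))) {
      errs <- c(errs, abs(cp$count[i] -
                            expected_profile_count(sim$truth, cp$bud[i], cp$z[i])))
    }
  }
  expect_gte(length(errs), 60)
  expect_lte(mean(errs), 1)
})
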