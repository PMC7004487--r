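# substack projection, ROI measurement, normalization, mixture thresholding

test_that("substack partitioning follows the half-thickness remainder rule", {
  expect_equal(lengths(substack_indices(30, 1)), c(10L, 10L, 10L))
  # enumerate 21..30 slices at 1 um against the stated rule
  for (nz in 21:30) {
    idx <- substack_indices(nz, 1)
    rem <- nz - 20L
    if (rem == 0) {
      expect_equal(lengths(idx), c(10L, 10L))
    } else if (rem >= 5) {          # remainder >= half thickness: own substack
      expect_equal(lengths(idx), c(10L, 10L, rem))
    } else {                        # thin remainder merges into the previous
      expect_equal(lengths(idx), c(10L, 10L + rem))
    }
    expect_identical(sort(unlist(idx)), seq_len(nz))
  }
  expect_error(substack_indices(10, 2, thickness_um = 1), "thinner")
})

test_that("projection pixels are the elementwise max over member slices", {
  set.seed(14)
  arr <- array(sample(0:255, 6 * 6 * 25, TRUE), c(6, 6, 25))
  s <- image_stack(list(ch = arr), voxel_size = c(x = 1, y = 1, z = 1),
                   bit_depth = 8)
  projs <- project_substacks(s, thickness_um = 10)
  expect_length(projs, 3)   # 10 + 10 + 5 (remainder exactly half)
  for (p in projs) {
    expect_equal(p$channels$ch,
                 apply(arr[, , p$slices, drop = FALSE], c(1, 2), max))
  }
})

test_that("cell means equal the brute-force pixel average and ignore order", {
  set.seed(15)
  img <- matrix(runif(20 * 20, 0, 255), 20, 20)
  proj <- structure(list(channels = list(ch = img),
                         voxel_size = c(x = 1, y = 1, z = 1), bit_depth = 8),
                    class = "projection")
  lab <- matrix(0L, 20, 20)
  lab[2:6, 2:6] <- 1L
  lab[10:14, 10:14] <- 2L
  got <- measure_cells(proj, lab)
  expect_equal(got$mean_raw[got$cell == 1], mean(img[2:6, 2:6]))
  expect_equal(got$mean_raw[got$cell == 2], mean(img[10:14, 10:14]))

  # uniform ROI
  img2 <- img; img2[2:6, 2:6] <- 100
  proj2 <- proj; proj2$channels$ch <- img2
  expect_equal(measure_cells(proj2, lab)$mean_raw[1], 100)
})

test_that("normalization applies the background/99th-percentile convention", {
  # background pixels at 20; in-ROI pixels engineered so that the 99th
  # percentile of (pixel - background) is exactly 160; ROI mean 100
  img <- matrix(20, 50, 50)
  lab <- matrix(0L, 50, 50)
  lab[1:10, 1:10] <- 1L
  img[1:10, 1:10] <- 100
  lab[20:29, 20:29] <- 2L
  img[20:29, 20:29] <- 180   # sets the in-ROI 99th percentile at 180 - 20
  proj <- structure(list(channels = list(ch = img),
                         voxel_size = c(x = 1, y = 1, z = 1), bit_depth = 8),
                    class = "projection")
  tab <- normalize_intensities(measure_cells(proj, lab), proj, lab)
  expect_equal(tab$norm[tab$cell == 1], (100 - 20) / 160)
  expect_equal(tab$norm[tab$cell == 2], (180 - 20) / 160)

  # all-ROIs-at-background: normalized values are zero (scale from spread)
  img3 <- matrix(20, 30, 30); lab3 <- matrix(0L, 30, 30)
  lab3[1:5, 1:5] <- 1L; lab3[10:14, 10:14] <- 2L
  img3[10:14, 10:14] <- 30
  proj3 <- structure(list(channels = list(ch = img3),
                          voxel_size = c(x = 1, y = 1, z = 1), bit_depth = 8),
                     class = "projection")
  tab3 <- normalize_intensities(measure_cells(proj3, lab3), proj3, lab3)
  expect_equal(tab3$norm[tab3$cell == 1], 0)

  # blank channel errors
  imgb <- matrix(20, 30, 30)
  projb <- structure(list(channels = list(ch = imgb),
                          voxel_size = c(x = 1, y = 1, z = 1), bit_depth = 8),
                     class = "projection")
  expect_error(normalize_intensities(measure_cells(projb, lab3), projb, lab3),
               "blank")
})

test_that("normalized intensities are invariant to global intensity rescaling", {
  set.seed(16)
  img <- matrix(runif(40 * 40, 10, 200), 40, 40)
  lab <- matrix(0L, 40, 40); lab[5:12, 5:12] <- 1L; lab[25:32, 25:32] <- 2L
  mk <- function(im) structure(list(channels = list(ch = im),
                                    voxel_size = c(x = 1, y = 1, z = 1),
                                    bit_depth = NA),
                               class = "projection")
  t1 <- normalize_intensities(measure_cells(mk(img), lab), mk(img), lab)
  t2 <- normalize_intensities(measure_cells(mk(img * 3.7), lab),
                              mk(img * 3.7), lab)
  expect_equal(t1$norm, t2$norm)
})

test_that("bimodal threshold sits two lower-peak SDs above the lower median", {
  d <- generate_ganglion_intensities(1000, 0.5, seed = 33)
  m <- determine_threshold(d$value, "GFP")
  expect_equal(m$modality, "bimodal")
  expect_identical(m$threshold, m$m_low + 2 * m$s_low)
  expect_gt(m$threshold, 0.27)
  expect_lt(m$threshold, 0.33)
  # oracle: the same statistic computed from the true component labels
  lo <- d$value[!d$positive]
  expect_equal(m$threshold, median(lo) + 2 * sd(lo), tolerance = 0.02)

  # permutation invariance
  m2 <- determine_threshold(d$value[sample(1000)], "GFP")
  expect_equal(m2$threshold, m$threshold)
})

test_that("degenerate and unimodal inputs fall back to the extrapolated rule", {
  m <- determine_threshold(rep(0.4, 25))
  expect_equal(m$modality, "unimodal")
  expect_equal(m$threshold, 0.4)
  expect_true(m$extrapolated)
  # scoring with this threshold marks all cells negative (strict >)
  tab <- data.frame(cell = 1:25, substack = 1, channel = "ch",
                    mean_raw = 0.4, norm = rep(0.4, 25))
  sc <- score_cells(tab, list(ch = m))
  expect_false(any(sc$table$positive))

  set.seed(17)
  mu <- determine_threshold(rnorm(200, 0.5, 0.05))
  expect_equal(mu$modality, "unimodal")
  expect_true(mu$extrapolated)
  expect_equal(mu$threshold, mu$components$mean + 2 * mu$components$sd)
  expect_error(determine_threshold(runif(10)), "at least 20")
})

test_that("combination percentages partition the cells and respect boundaries", {
  vals <- data.frame(cell = rep(1:6, 2), substack = 1,
                     channel = rep(c("A", "B"), each = 6),
                     mean_raw = 0,
                     norm = c(0.1, 0.9, 0.9, 0.1, 0.5, 0.9,
                              0.9, 0.9, 0.1, 0.1, 0.5, 0.1))
  mods <- list(A = structure(list(threshold = 0.5), class = "threshold_model"),
               B = structure(list(threshold = 0.5), class = "threshold_model"))
  sc <- score_cells(vals, mods)
  # value exactly at the threshold scores negative
  expect_false(sc$table$positive[sc$table$cell == 5 & sc$table$channel == "A"])
  expect_equal(sum(sc$combinations$percent), 100)
  expect_equal(nrow(sc$combinations), 4)   # 2^2 combinations always reported
  expect_error(score_cells(vals, mods["A"]), "no threshold model")
})

test_that("image-rendered fields are scored against truth with few errors", {
  g <- generate_ganglion_field(ganglion_sim_params(n_cells = 35, seed = 6))
  projs <- project_substacks(g$stack)
  tabs <- do.call(rbind, lapply(seq_along(projs), function(s) {
    if (all(g$rois[[s]] == 0)) return(NULL)
    normalize_intensities(measure_cells(projs[[s]], g$rois[[s]], substack = s),
                          projs[[s]], g$rois[[s]])
  }))
  expect_equal(length(unique(tabs$cell)), 35)
  mods <- lapply(split(tabs$norm, tabs$channel), determine_threshold)
  sc <- score_cells(tabs, mods)
  m <- merge(sc$table, g$truth, by = c("cell", "channel"))
  expect_lt(mean(m$positive.x != m$positive.y), 0.1)
})
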