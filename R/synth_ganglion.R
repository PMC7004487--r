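#' Parameters for the synthetic geniculate ganglion field
#'
#' Emulates a cleared whole-mount ganglion imaged in a single field of view
#' with 1 um axial spacing: round neuronal somata scattered in a slab, with
#' per-channel intensities drawn from a two-component Gaussian mixture (a
#' dim "negative" and a bright "positive" population) according to a
#' per-channel positive fraction.
#'
#' @param n_cells number of somata.
#' @param positive_fraction named numeric in `[0,1]` per channel; channels of
#'   the simulated stack are taken from its names.  Defaults mirror a field
#'   where all neurons carry SNAP25, most carry P2X3, and a minority the
#'   5-HT3A GFP reporter.
#' @param lower_mean,upper_mean,lower_sd,upper_sd mixture component
#'   parameters on the normalized intensity scale.
#' @param fov named integer `c(y =, x =)` field size in pixels.
#' @param n_slices number of optical sections.
#' @param voxel_size named numeric `c(x =, y =, z =)` in micrometres.
#' @param cell_radius_um soma radius.
#' @param intensity_amplitude 8-bit units mapped to normalized intensity 1.
#' @param background background level (8-bit units).
#' @param noise_sd Gaussian noise SD (8-bit units).
#' @param seed integer RNG seed.
#' @return validated list of class `ganglion_sim_params`.
#' @export
ganglion_sim_params <- function(n_cells = 40,
                                positive_fraction = c(SNAP25 = 0.95,
                                                      P2X3 = 0.85,
                                                      GFP = 0.4),
                                lower_mean = 0.2, upper_mean = 0.8,
                                lower_sd = 0.05, upper_sd = 0.05,
                                fov = c(y = 128, x = 128), n_slices = 30,
                                voxel_size = c(x = 1, y = 1, z = 1),
                                cell_radius_um = 6,
                                intensity_amplitude = 200, background = 16,
                                noise_sd = 4, seed = 1) {
  assert_that(is.numeric(n_cells) && n_cells >= 0 && n_cells == floor(n_cells),
              "n_cells must be a nonnegative integer")
  assert_that(all(positive_fraction >= 0 & positive_fraction <= 1),
              "positive_fraction must lie in [0, 1]")
  assert_that(!is.null(names(positive_fraction)),
              "positive_fraction must be named by channel")
  assert_that(lower_mean < upper_mean,
              "mixture means must be ordered: lower_mean < upper_mean")
  assert_that(lower_sd > 0 && upper_sd > 0, "component SDs must be positive")
  structure(list(n_cells = as.integer(n_cells),
                 positive_fraction = positive_fraction,
                 lower_mean = lower_mean, upper_mean = upper_mean,
                 lower_sd = lower_sd, upper_sd = upper_sd,
                 fov = fov[c("y", "x")], n_slices = as.integer(n_slices),
                 voxel_size = voxel_size[c("x", "y", "z")],
                 cell_radius_um = cell_radius_um,
                 intensity_amplitude = intensity_amplitude,
                 background = background, noise_sd = noise_sd, seed = seed),
            class = "ganglion_sim_params")
}

#' Draw per-cell normalized intensities from the two-component mixture
#'
#' The value-level core of the ganglion simulator: each cell is positive with
#' probability `positive_fraction` and its normalized intensity is drawn from
#' the corresponding Gaussian component.  Used directly to exercise threshold
#' fitting and scoring at scale, and by [generate_ganglion_field()] to assign
#' soma intensities.
#'
#' @param n_cells number of cells.
#' @param positive_fraction probability a cell is positive.
#' @param lower_mean,upper_mean,lower_sd,upper_sd component parameters.
#' @param seed RNG seed.
#' @return data.frame with columns `cell`, `positive` (logical truth),
#'   `value` (normalized intensity draw).
#' @export
generate_ganglion_intensities <- function(n_cells, positive_fraction,
                                          lower_mean = 0.2, upper_mean = 0.8,
                                          lower_sd = 0.05, upper_sd = 0.05,
                                          seed = 1) {
  with_seed(seed, {
    pos <- runif(n_cells) < positive_fraction
    value <- ifelse(pos, rnorm(n_cells, upper_mean, upper_sd),
                    rnorm(n_cells, lower_mean, lower_sd))
    data.frame(cell = seq_len(n_cells), positive = pos, value = value)
  })
}

#' Generate a synthetic ganglion field stack with ground truth
#'
#' Places non-overlapping spherical somata in a slab and renders one channel
#' per entry of `positive_fraction`; each soma's rendered intensity encodes
#' its mixture draw (`background + value * intensity_amplitude`).  Ground
#' truth records every cell's true class and drawn normalized intensity, and
#' a per-substack 2D ROI label image is provided for measurement.
#'
#' @param params a [ganglion_sim_params()] object.
#' @return list with `stack` ([image_stack()]), `truth` (long data.frame:
#'   `cell`, `substack`, `channel`, `positive`, `true_value`), `rois` (list
#'   of 2D label matrices, one per substack), and `cells` (per-cell table
#'   with positions).
#' @export
generate_ganglion_field <- function(params) {
  stopifnot(inherits(params, "ganglion_sim_params"))
  p <- params
  with_seed(p$seed, {
    ny <- unname(p$fov["y"]); nx <- unname(p$fov["x"]); nz <- p$n_slices
    dims <- c(ny, nx, nz)
    r_px <- p$cell_radius_um / p$voxel_size["x"]
    r_pz <- p$cell_radius_um / p$voxel_size["z"]
    # rejection-sample non-overlapping (in-plane) soma centres
    centers <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(centers) < p$n_cells) {
      tries <- tries + 1
      assert_that(tries <= 20000,
                  "could not place %d non-overlapping cells in the field",
                  p$n_cells)
      cand <- c(runif(1, r_px + 1, ny - r_px),
                runif(1, r_px + 1, nx - r_px),
                runif(1, r_pz + 1, nz - r_pz))
      if (nrow(centers) == 0 ||
          all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >
                (1.9 * r_px)^2)) {
        centers <- rbind(centers, cand)
      }
    }
    channels <- names(p$positive_fraction)
    draws <- lapply(channels, function(ch) {
      d <- generate_ganglion_intensities(
        p$n_cells, p$positive_fraction[[ch]], p$lower_mean, p$upper_mean,
        p$lower_sd, p$upper_sd, seed = sample.int(.Machine$integer.max, 1))
      d$channel <- rep(ch, nrow(d))
      d
    })
    names(draws) <- channels

    sub_idx <- substack_indices(nz, p$voxel_size["z"], thickness_um = 10)
    cell_sub <- vapply(seq_len(p$n_cells), function(i) {
      z <- centers[i, 3]
      which(vapply(sub_idx, function(ix) z >= min(ix) - 0.5 & z <= max(ix) + 0.5,
                   TRUE))[1]
    }, 1L)

    stack_channels <- lapply(channels, function(ch) {
      arr <- array(p$background, dims)
      if (p$n_cells > 0) {
        for (i in seq_len(p$n_cells)) {
          lvl <- p$background +
            draws[[ch]]$value[i] * p$intensity_amplitude
          sph <- ellipsoid_mask(dims, centers[i, ], c(r_px, r_px, r_pz))
          arr[sph] <- lvl
        }
      }
      if (p$noise_sd > 0) arr <- arr + rnorm(length(arr), sd = p$noise_sd)
      array(pmin(pmax(round(arr), 0), 255), dims)
    })
    names(stack_channels) <- channels
    stack <- image_stack(stack_channels, voxel_size = p$voxel_size,
                         bit_depth = 8)

    rois <- lapply(seq_along(sub_idx), function(s) {
      lab <- matrix(0L, ny, nx)
      for (i in which(cell_sub == s)) {
        m <- ellipsoid_mask(c(ny, nx, 1L),
                            c(centers[i, 1], centers[i, 2], 1),
                            c(r_px * 0.7, r_px * 0.7, 1))[, , 1]
        lab[m] <- i
      }
      lab
    })

    truth <- if (p$n_cells == 0) {
      data.frame(cell = integer(), substack = integer(),
                 channel = character(), positive = logical(),
                 true_value = numeric())
    } else {
      do.call(rbind, lapply(channels, function(ch) {
        d <- draws[[ch]]
        data.frame(cell = d$cell, substack = cell_sub[d$cell], channel = ch,
                   positive = d$positive, true_value = d$value)
      }))
    }
    cells <- data.frame(cell = seq_len(p$n_cells),
                        y = centers[, 1], x = centers[, 2], z = centers[, 3],
                        substack = cell_sub)
    list(stack = stack, truth = truth, rois = rois, cells = cells)
  })
}
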