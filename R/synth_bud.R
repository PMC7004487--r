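#' Parameters for the synthetic taste-bud stack generator
#'
#' Defaults describe a compact fungiform-like taste bud imaged as a 12- to
#' 16-section confocal stack: 0.2 x 0.2 x 1.0 um voxels, an ellipsoidal bud
#' of ~24 um diameter containing elongate marker-positive cells with nuclei,
#' and tubular intragemmal nerve fibers in two co-labeled channels.
#'
#' @param stack_shape named integer vector `c(z =, y =, x =)` in voxels.
#' @param voxel_size named numeric `c(x =, y =, z =)` in micrometres.
#' @param n_buds number of buds, laid out on an in-plane grid.
#' @param cells_per_bud named numeric `c(type2 =, type3 =)`: expected number
#'   of cells of each type per bud (type III cells carry the marker label).
#' @param cell_count_model `"poisson"` (counts drawn per bud) or `"fixed"`.
#' @param bud_semiaxes_um,cell_semiaxes_um ellipsoid semi-axes `c(x, y, z)`
#'   of the bud and of a cell body, in micrometres.
#' @param nucleus_radius nucleus radius in micrometres.
#' @param fiber_density target fraction of bud volume occupied by fibers in
#'   the pan-fiber channel (P2X3).
#' @param fiber_radius fiber tube radius in micrometres.
#' @param channel_overlap_fraction fraction of in-bud fiber voxels that are
#'   positive in both fiber channels (GFP mask is a subset of the P2X3 mask).
#' @param intensity named numeric levels (8-bit units) for `cell`, `fiber`,
#'   `nucleus`, `background`.
#' @param gradient_amplitude amplitude of a linear background ramp across x.
#' @param noise_sd Gaussian read-noise SD (8-bit units); 0 disables.
#' @param poisson_gain photons per intensity unit for Poisson shot noise;
#'   0 disables.
#' @param psf_sigma named numeric `c(lateral =, axial =)` Gaussian PSF sigma
#'   in micrometres.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `bud_sim_params`.
#' @export
bud_sim_params <- function(stack_shape = c(z = 14, y = 160, x = 160),
                           voxel_size = c(x = 0.2, y = 0.2, z = 1.0),
                           n_buds = 1,
                           cells_per_bud = c(type2 = 14, type3 = 6),
                           cell_count_model = c("poisson", "fixed"),
                           bud_semiaxes_um = c(x = 12, y = 12, z = 6.5),
                           cell_semiaxes_um = c(x = 2, y = 2, z = 5),
                           nucleus_radius = 1.6,
                           fiber_density = 0.15,
                           fiber_radius = 0.7,
                           channel_overlap_fraction = 0.6,
                           intensity = c(cell = 140, fiber = 180,
                                         nucleus = 200, background = 12),
                           gradient_amplitude = 8,
                           noise_sd = 6,
                           poisson_gain = 1,
                           psf_sigma = c(lateral = 0.15, axial = 0.5),
                           seed = 1) {
  cell_count_model <- match.arg(cell_count_model)
  assert_that(all(stack_shape[c("z", "y", "x")] >= 1), "stack_shape must be positive")
  assert_that(all(voxel_size[c("x", "y", "z")] > 0), "voxel_size must be positive")
  assert_that(is_count(n_buds), "n_buds must be a positive integer")
  assert_that(fiber_density >= 0 && fiber_density <= 1,
              "fiber_density must be in [0, 1]")
  assert_that(fiber_density <= 0.65,
              "fiber_density %.2f is infeasible for a tube-packed bud volume",
              fiber_density)
  assert_that(channel_overlap_fraction >= 0 && channel_overlap_fraction <= 1,
              "channel_overlap_fraction must be in [0, 1]")
  assert_that(all(cells_per_bud >= 0), "cells_per_bud must be nonnegative")
  assert_that(noise_sd >= 0 && poisson_gain >= 0, "noise parameters must be >= 0")
  structure(list(stack_shape = stack_shape[c("z", "y", "x")],
                 voxel_size = voxel_size[c("x", "y", "z")],
                 n_buds = n_buds, cells_per_bud = cells_per_bud,
                 cell_count_model = cell_count_model,
                 bud_semiaxes_um = bud_semiaxes_um[c("x", "y", "z")],
                 cell_semiaxes_um = cell_semiaxes_um[c("x", "y", "z")],
                 nucleus_radius = nucleus_radius,
                 fiber_density = fiber_density, fiber_radius = fiber_radius,
                 channel_overlap_fraction = channel_overlap_fraction,
                 intensity = intensity,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, poisson_gain = poisson_gain,
                 psf_sigma = psf_sigma[c("lateral", "axial")], seed = seed),
            class = "bud_sim_params")
}

# Noise- and blur-free variant of the defaults, used for construction checks.
#' @rdname bud_sim_params
#' @param ... overrides passed on to [bud_sim_params()].
#' @export
bud_sim_params_noiseless <- function(...) {
  args <- list(...)
  defaults <- list(noise_sd = 0, poisson_gain = 0,
                   gradient_amplitude = 0,
                   psf_sigma = c(lateral = 0, axial = 0))
  do.call(bud_sim_params, utils::modifyList(defaults, args))
}

# Stamp an ellipsoid (semi-axes in voxels, order y,x,z) into a logical array;
# returns the linear indices of voxels newly set TRUE.
stamp_ellipsoid <- function(mask, center, semi) {
  d <- dim(mask)
  lo <- pmax(ceiling(center - semi), 1L)
  hi <- pmin(floor(center + semi), d)
  if (any(lo > hi)) return(list(mask = mask, new = integer(0)))
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  fy <- ((ys - center[1]) / semi[1])^2
  fx <- ((xs - center[2]) / semi[2])^2
  fz <- ((zs - center[3]) / semi[3])^2
  inside <- outer(outer(fy, fx, `+`), fz, `+`) <= 1
  idx <- which(inside)
  if (length(idx) == 0L) return(list(mask = mask, new = integer(0)))
  # convert sub-block indices to linear indices in the full array
  blk <- arrayInd(idx, dim(inside))
  lin <- (lo[1] - 1L + blk[, 1]) +
    (lo[2] - 2L + blk[, 2]) * d[1] +
    (lo[3] - 2L + blk[, 3]) * d[1] * d[2]
  new <- lin[!mask[lin]]
  mask[lin] <- TRUE
  list(mask = mask, new = new)
}

ellipsoid_mask <- function(dims, center, semi) {
  stamp_ellipsoid(array(FALSE, dims), center, semi)$mask
}

#' Generate a synthetic taste-bud stack with ground truth
#'
#' Produces a four-channel stack (`SNAP25` cell marker, `GFP` and `P2X3`
#' fiber channels, `DAPI` nuclei) together with exact ground truth: the bud
#' ROI label volume, a per-cell table, the true fiber masks, the true
#' innervation fraction per bud, and the true two-channel overlap fraction.
#' Fibers are grown as random-walk tubes; the in-bud fiber voxel count is
#' trimmed to the requested density target exactly (up to the one-voxel
#' rounding of `round(density * bud_volume)`), and the GFP mask is a subset
#' of the P2X3 mask hitting the requested overlap fraction the same way.
#' Deterministic given `params$seed`.
#'
#' @param params a [bud_sim_params()] object.
#' @return list with elements `stack` ([image_stack()]) and `truth` (list
#'   with `roi`, `cells`, `fiber_masks`, `innervation`, `overlap`,
#'   `marker_mask`, `nucleus_mask`).
#' @export
generate_bud_stack <- function(params) {
  stopifnot(inherits(params, "bud_sim_params"))
  with_seed(params$seed, generate_bud_stack_impl(params))
}

generate_bud_stack_impl <- function(p) {
  nz <- unname(p$stack_shape["z"]); ny <- unname(p$stack_shape["y"]); nx <- unname(p$stack_shape["x"])
  dims <- c(ny, nx, nz)
  vx <- p$voxel_size["x"]; vy <- p$voxel_size["y"]; vz <- p$voxel_size["z"]
  bud_semi <- c(p$bud_semiaxes_um["y"] / vy, p$bud_semiaxes_um["x"] / vx,
                p$bud_semiaxes_um["z"] / vz)

  # bud centres on an in-plane grid
  ncol_g <- ceiling(sqrt(p$n_buds))
  nrow_g <- ceiling(p$n_buds / ncol_g)
  cw <- nx / ncol_g; ch <- ny / nrow_g
  assert_that(2 * bud_semi[2] + 2 <= cw && 2 * bud_semi[1] + 2 <= ch,
              "stack in-plane size too small for %d bud(s) of the given semi-axes",
              p$n_buds)
  centers <- lapply(seq_len(p$n_buds), function(b) {
    gi <- (b - 1) %/% ncol_g; gj <- (b - 1) %% ncol_g
    c((gi + 0.5) * ch, (gj + 0.5) * cw, (nz + 1) / 2)
  })

  labels <- array(0L, dims)
  for (b in seq_len(p$n_buds)) {
    m <- ellipsoid_mask(dims, centers[[b]], bud_semi)
    labels[m] <- b
  }

  # ---- cells -------------------------------------------------------------
  cell_semi <- c(p$cell_semiaxes_um["y"] / vy, p$cell_semiaxes_um["x"] / vx,
                 p$cell_semiaxes_um["z"] / vz)
  nuc_semi <- c(p$nucleus_radius / vy, p$nucleus_radius / vx,
                p$nucleus_radius / vz)
  marker_mask <- array(FALSE, dims)
  nucleus_mask <- array(FALSE, dims)
  cells <- list()
  cid <- 0L
  for (b in seq_len(p$n_buds)) {
    for (type in c("type2", "type3")) {
      lambda <- p$cells_per_bud[[if (type == "type2") "type2" else "type3"]]
      n_cells <- if (p$cell_count_model == "poisson") rpois(1, lambda)
                 else as.integer(round(lambda))
      for (i in seq_len(n_cells)) {
        cid <- cid + 1L
        # centroid uniform in a shrunken bud ellipsoid so the soma stays inside
        repeat {
          u <- runif(3, -1, 1)
          if (sum(u^2) <= 1) break
        }
        ctr <- centers[[b]] + u * bud_semi * 0.7
        nuc <- stamp_ellipsoid(nucleus_mask, ctr, nuc_semi)
        nucleus_mask <- nuc$mask
        if (type == "type3") {
          marker_mask <- stamp_ellipsoid(marker_mask, ctr, cell_semi)$mask
        }
        nz_range <- range(1L + (nuc$new - 1L) %/% (ny * nx))
        cells[[cid]] <- data.frame(
          bud = b, cell = cid, type = type,
          y = ctr[1], x = ctr[2], z = ctr[3],
          nuc_zmin = if (length(nuc$new)) nz_range[1] else NA_integer_,
          nuc_zmax = if (length(nuc$new)) nz_range[2] else NA_integer_)
      }
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(bud = integer(), cell = integer(), type = character(),
               y = numeric(), x = numeric(), z = numeric(),
               nuc_zmin = integer(), nuc_zmax = integer())

  # ---- fibers ------------------------------------------------------------
  fiber_semi <- c(p$fiber_radius / vy, p$fiber_radius / vx, p$fiber_radius / vz)
  maskB <- array(FALSE, dims)
  vox_idx <- integer(0)    # in-bud painted voxels, in paint order
  vox_fiber <- integer(0)
  out_idx <- list()        # out-of-bud voxels per fiber
  innervation <- list()
  overlap <- list()
  maskA <- array(FALSE, dims)
  for (b in seq_len(p$n_buds)) {
    bud_lin <- which(labels == b)
    bud_vol <- length(bud_lin)
    target_b <- as.integer(round(p$fiber_density * bud_vol))
    in_bud <- array(FALSE, dims); in_bud[bud_lin] <- TRUE
    n_in <- 0L
    fiber_id <- 0L
    vb_idx <- integer(0); vb_fiber <- integer(0)
    total_steps <- 0L
    while (n_in < target_b) {
      fiber_id <- fiber_id + 1L
      total_steps <- total_steps + 1L
      assert_that(fiber_id <= 5000L && total_steps <= 500000L,
                  "fiber_density %.2f infeasible for bud %d", p$fiber_density, b)
      # start near the basal surface of the bud, heading inward/upward
      theta <- runif(1, 0, 2 * pi)
      pos <- centers[[b]] + c(sin(theta) * bud_semi[1] * 0.9,
                              cos(theta) * bud_semi[2] * 0.9,
                              -bud_semi[3] * 0.6)
      dir <- c(-sin(theta), -cos(theta), runif(1, 0.2, 0.8))
      dir <- dir / sqrt(sum(dir^2))
      out_idx[[fiber_id]] <- integer(0)
      n_steps <- sample(60:240, 1)
      for (s in seq_len(n_steps)) {
        total_steps <- total_steps + 1L
        st <- stamp_ellipsoid(maskB, pos, fiber_semi)
        maskB <- st$mask
        if (length(st$new)) {
          inb <- in_bud[st$new]
          if (any(inb)) {
            vb_idx <- c(vb_idx, st$new[inb])
            vb_fiber <- c(vb_fiber, rep(fiber_id, sum(inb)))
            n_in <- n_in + sum(inb)
          }
          if (any(!inb)) {
            out_idx[[fiber_id]] <- c(out_idx[[fiber_id]], st$new[!inb])
          }
        }
        if (n_in >= target_b) break
        dir <- dir + rnorm(3, sd = 0.35)
        dir <- dir / sqrt(sum(dir^2))
        # step of ~1 in-plane voxel; z advances on the physical scale
        step <- c(dir[1], dir[2], dir[3] * vx / vz)
        pos <- pos + step
        pos <- pmin(pmax(pos, 1), dims)
      }
    }
    # trim the overshoot of the last stamp so the in-bud count is exact
    if (n_in > target_b) {
      drop <- vb_idx[(target_b + 1L):n_in]
      maskB[drop] <- FALSE
      vb_idx <- vb_idx[seq_len(target_b)]
      vb_fiber <- vb_fiber[seq_len(target_b)]
    }
    innervation[[b]] <- data.frame(bud = b, channel = "P2X3",
                                   true_fraction = target_b / bud_vol,
                                   labeled_voxels = target_b,
                                   total_voxels = bud_vol)

    # GFP channel: whole fibers until the overlap target, then a partial one
    target_a <- as.integer(round(p$channel_overlap_fraction * target_b))
    if (target_a > 0) {
      fibers <- sample(unique(vb_fiber))
      taken <- 0L
      for (f in fibers) {
        f_vox <- vb_idx[vb_fiber == f]
        if (taken + length(f_vox) <= target_a) {
          maskA[f_vox] <- TRUE
          if (f <= length(out_idx)) maskA[out_idx[[f]]] <- TRUE
          taken <- taken + length(f_vox)
        } else {
          need <- target_a - taken
          if (need > 0) maskA[f_vox[seq_len(need)]] <- TRUE
          taken <- target_a
          break
        }
      }
    }
    overlap[[b]] <- data.frame(bud = b,
                               true_overlap = if (target_b > 0)
                                 target_a / target_b else NA_real_,
                               overlap_voxels = target_a,
                               fiber_voxels = target_b)
    vox_idx <- c(vox_idx, vb_idx); vox_fiber <- c(vox_fiber, vb_fiber)
  }

  # ---- render ------------------------------------------------------------
  ramp <- aperm(array(seq(0, 1, length.out = nx), c(nx, ny, nz)), c(2, 1, 3))
  base <- p$intensity["background"] + p$gradient_amplitude * ramp
  render <- function(struct_mask, level) {
    img <- base + level * struct_mask
    sig <- c(p$psf_sigma["lateral"] / vy, p$psf_sigma["lateral"] / vx,
             p$psf_sigma["axial"] / vz)
    if (any(sig > 0)) img <- blur3d(img, sig)
    if (p$poisson_gain > 0) {
      img <- array(rpois(length(img), p$poisson_gain * img) / p$poisson_gain,
                   dim = dim(img))
    }
    if (p$noise_sd > 0) img <- img + rnorm(length(img), sd = p$noise_sd)
    array(pmin(pmax(round(img), 0), 255), dim = dim(img))
  }
  stack <- image_stack(
    list(SNAP25 = render(marker_mask, p$intensity["cell"]),
         GFP = render(maskA, p$intensity["fiber"]),
         P2X3 = render(maskB, p$intensity["fiber"]),
         DAPI = render(nucleus_mask, p$intensity["nucleus"])),
    voxel_size = p$voxel_size, bit_depth = 8)

  truth <- list(
    roi = roi_set(labels, kind = "bud", voxel_size = p$voxel_size),
    cells = cells,
    fiber_masks = list(GFP = maskA, P2X3 = maskB),
    innervation = do.call(rbind, innervation),
    overlap = do.call(rbind, overlap),
    marker_mask = marker_mask,
    nucleus_mask = nucleus_mask,
    params = p)
  list(stack = stack, truth = truth)
}
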