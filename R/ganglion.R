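# Partition nz slices (z-step um) into consecutive substacks of the given
# thickness: full substacks of ceil(thickness/z-step) slices; a trailing
# remainder of at least half the thickness becomes its own substack,
# otherwise it merges into the previous one.
substack_indices <- function(nz, z_step, thickness_um = 10) {
  assert_that(nz >= 1, "stack has no slices")
  assert_that(thickness_um >= z_step,
              "substack thickness %.3g um is thinner than one slice (%.3g um)",
              thickness_um, z_step)
  k <- ceiling(thickness_um / z_step)
  n_full <- nz %/% k
  rem <- nz %% k
  if (n_full == 0) return(list(seq_len(nz)))
  idx <- split(seq_len(n_full * k), rep(seq_len(n_full), each = k))
  names(idx) <- NULL
  if (rem > 0) {
    tail_idx <- (n_full * k + 1L):nz
    if (rem * z_step >= thickness_um / 2) {
      idx[[n_full + 1L]] <- tail_idx
    } else {
      idx[[n_full]] <- c(idx[[n_full]], tail_idx)
    }
  }
  idx
}

#' Maximal projections of consecutive substacks
#'
#' Splits a stack into consecutive, non-overlapping substacks of the given
#' physical thickness and returns the per-channel maximal z-projection of
#' each.  A trailing remainder of at least half the thickness becomes its own
#' substack; a thinner remainder merges into the previous one.
#'
#' @param stack an [image_stack()].
#' @param thickness_um substack thickness in micrometres (default 10).
#' @return list of `projection` objects, each with `channels` (named list of
#'   2D matrices), `slices` (source slice indices), `voxel_size`, `bit_depth`.
#' @export
project_substacks <- function(stack, thickness_um = 10) {
  d <- dim_stack(stack)
  idx <- substack_indices(d[3], stack$voxel_size["z"], thickness_um)
  lapply(idx, function(ix) {
    chans <- lapply(stack$channels, function(arr) {
      apply(arr[, , ix, drop = FALSE], c(1, 2), max)
    })
    structure(list(channels = chans, slices = ix,
                   voxel_size = stack$voxel_size,
                   bit_depth = stack$bit_depth),
              class = "projection")
  })
}

#' Per-cell mean intensities over ROIs of a projection
#'
#' @param projection a `projection` from [project_substacks()].
#' @param cell_rois 2D integer label matrix (0 = background) matching the
#'   projection dimensions; positive labels identify cells.
#' @param substack substack identifier recorded in the output.
#' @return long data.frame of class `cell_intensity_table`: `cell`,
#'   `substack`, `channel`, `mean_raw`.
#' @export
measure_cells <- function(projection, cell_rois, substack = 1L) {
  assert_that(identical(dim(cell_rois), dim(projection$channels[[1]])),
              "cell ROI labels must match the projection dimensions")
  ids <- sort(unique(as.integer(cell_rois[cell_rois > 0])))
  assert_that(length(ids) > 0, "cell ROI set is empty")
  rows <- lapply(names(projection$channels), function(ch) {
    img <- projection$channels[[ch]]
    means <- vapply(ids, function(id) {
      px <- img[cell_rois == id]
      assert_that(length(px) > 0, "cell ROI %d is empty", id)
      mean(px)
    }, 0)
    data.frame(cell = ids, substack = substack, channel = ch,
               mean_raw = means)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cell_intensity_table", class(out))
  out
}

#' Background-subtract and image-normalize cell intensities
#'
#' Per projection and channel: the background is the median of pixels outside
#' every cell ROI; cell mean intensities are background-subtracted, clipped
#' at zero, and divided by the 99th percentile of the background-subtracted
#' in-ROI pixel values of that image, putting them on a dimensionless [0, ~1]
#' scale.  The constants used are recorded as an attribute.  The result is
#' invariant to rescaling all pixel intensities by a positive constant.
#'
#' @param table a `cell_intensity_table` from [measure_cells()].
#' @param projection the projection the table was measured on.
#' @param cell_rois the label matrix used for measurement.
#' @return the table with a `norm` column added; attribute
#'   `normalization` holds the per-channel background and scale constants.
#' @export
normalize_intensities <- function(table, projection, cell_rois) {
  consts <- list()
  table$norm <- NA_real_
  for (ch in unique(table$channel)) {
    img <- projection$channels[[ch]]
    bg <- median(img[cell_rois == 0])
    inroi <- img[cell_rois > 0] - bg
    scale <- unname(quantile(pmax(inroi, 0), 0.99, type = 7))
    assert_that(scale > 0, "channel '%s' is blank: normalization scale is 0", ch)
    sel <- table$channel == ch
    table$norm[sel] <- pmax(table$mean_raw[sel] - bg, 0) / scale
    consts[[ch]] <- c(background = bg, scale = scale)
  }
  attr(table, "normalization") <- consts
  table
}

#' Mixture-model intensity threshold for one channel
#'
#' Fits one- and two-component Gaussian mixtures to the normalized intensity
#' values (EM with deterministic model-based initialization) and selects the
#' modality by BIC.  For a bimodal channel, each value is assigned to its
#' maximum-responsibility component and the threshold is set two standard
#' deviations above the median of the lower-component values:
#' `T = m_low + 2 * s_low`.  For a unimodal channel the rule is extrapolated
#' as `T = mean + 2 * SD` of the single fit and flagged.
#'
#' @param values numeric vector of normalized intensities (>= 20 values).
#' @param channel channel name recorded in the model.
#' @param use_fitted_sigma if `TRUE`, use the fitted component sigma for
#'   `s_low` instead of the SD of the assigned values.
#' @return list of class `threshold_model`: `channel`, `modality`,
#'   `components` (data.frame weight/mean/sd), `m_low`, `s_low`,
#'   `threshold`, `extrapolated`, `bic`.
#' @export
determine_threshold <- function(values, channel = "channel",
                                use_fitted_sigma = FALSE) {
  assert_that(length(values) >= 20,
              "need at least 20 values to fit a threshold (got %d)",
              length(values))
  assert_that(all(is.finite(values)), "values must be finite")
  if (sd(values) == 0) {
    return(structure(list(channel = channel, modality = "unimodal",
                          components = data.frame(weight = 1,
                                                  mean = values[1], sd = 0),
                          m_low = values[1], s_low = 0,
                          threshold = values[1], extrapolated = TRUE,
                          bic = NA_real_),
                     class = "threshold_model"))
  }
  f1 <- Mclust(values, G = 1, verbose = FALSE)
  f2 <- Mclust(values, G = 2, verbose = FALSE)
  assert_that(!is.null(f1),
              "single-Gaussian fit failed for channel '%s' (n = %d)",
              channel, length(values))
  if (is.null(f2) || f1$bic >= f2$bic) {      # mclust BIC: larger is better
    mu <- f1$parameters$mean[1]
    s <- sqrt(f1$parameters$variance$sigmasq[1])
    return(structure(list(channel = channel, modality = "unimodal",
                          components = data.frame(weight = 1, mean = mu, sd = s),
                          m_low = mu, s_low = s, threshold = mu + 2 * s,
                          extrapolated = TRUE, bic = f1$bic),
                     class = "threshold_model"))
  }
  mu <- f2$parameters$mean
  sig <- sqrt(f2$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, 2)    # equal-variance model
  w <- f2$parameters$pro
  lower <- which.min(mu)
  assigned <- values[f2$classification == lower]
  m_low <- if (length(assigned) > 0) median(assigned) else mu[lower]
  # with < 2 assigned values the empirical SD is undefined; use the fitted
  # component sigma instead
  s_low <- if (use_fitted_sigma || length(assigned) < 2) sig[lower]
           else sd(assigned)
  ord <- order(mu)
  structure(list(channel = channel, modality = "bimodal",
                 components = data.frame(weight = w[ord], mean = mu[ord],
                                         sd = sig[ord]),
                 m_low = m_low, s_low = s_low,
                 threshold = m_low + 2 * s_low,
                 extrapolated = FALSE, bic = f2$bic),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> channel '%s': %s, T = %.4f%s\n", x$channel,
              x$modality, x$threshold,
              if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' Score cells positive/negative and summarize label combinations
#'
#' Flags each cell positive for a channel when its normalized intensity
#' strictly exceeds that channel's threshold, then tabulates the percent of
#' cells positive per channel and the percent of cells showing each
#' combination of labels (all `2^k` combinations, summing to 100%), overall
#' and per group when a `group` column is present.
#'
#' @param table a normalized `cell_intensity_table` (needs a `norm` column).
#' @param models named list of [determine_threshold()] models, one per
#'   channel appearing in `table`.
#' @return list of class `scored_cells`: `table` (long, with `positive`
#'   flag), `wide` (one row per cell with per-channel flags),
#'   `percent_positive`, `combinations`.
#' @export
score_cells <- function(table, models) {
  assert_that(!is.null(table$norm), "table must be normalized first")
  chans <- unique(table$channel)
  missing <- setdiff(chans, names(models))
  assert_that(length(missing) == 0, "no threshold model for channel(s): %s",
              paste(missing, collapse = ", "))
  thr <- vapply(models[chans], `[[`, 0, "threshold")
  table$positive <- table$norm > thr[table$channel]

  keys <- c("cell", "substack", if ("group" %in% names(table)) "group")
  wide <- stats::reshape(
    table[c(keys, "channel", "positive")],
    idvar = keys, timevar = "channel", direction = "wide")
  names(wide) <- sub("^positive\\.", "", names(wide))
  grp <- if ("group" %in% names(wide)) wide$group else rep("all", nrow(wide))

  pct_pos <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    data.frame(group = g, channel = chans,
               percent = vapply(chans,
                                function(ch) 100 * mean(wide[sel, ch]), 0),
               n = sum(sel), row.names = NULL)
  }))

  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(chans)))
  names(combos) <- chans
  combo_label <- function(flags) {
    on <- chans[as.logical(flags)]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }
  combinations <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- which(grp == g)
    key <- apply(as.matrix(wide[sel, chans, drop = FALSE]), 1,
                 function(r) paste(as.integer(r), collapse = ""))
    all_keys <- apply(as.matrix(combos), 1,
                      function(r) paste(as.integer(r), collapse = ""))
    counts <- table(factor(key, levels = all_keys))
    data.frame(group = g,
               combination = apply(as.matrix(combos), 1, combo_label),
               n = as.integer(counts),
               percent = 100 * as.integer(counts) / length(sel),
               row.names = NULL)
  }))
  structure(list(table = table, wide = wide,
                 percent_positive = pct_pos, combinations = combinations,
                 thresholds = thr),
            class = "scored_cells")
}
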