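#' Simulate a luciferase plate reading
#'
#' Relative light units are linear in ATP concentration:
#' `RLU = intercept + slope * concentration + noise`.  The returned table
#' contains standard wells at the given known concentrations and one sample
#' well per entry of `true_concentrations_nM` (named by condition), carrying
#' the generating concentration as ground truth.
#'
#' @param slope RLU per nM; must be positive.
#' @param intercept background RLU.
#' @param true_concentrations_nM named numeric: true sample concentrations;
#'   names give the condition labels.
#' @param noise_sd additive Gaussian RLU noise (applied to all wells).
#' @param seed RNG seed.
#' @param standard_concentrations known standard concentrations (nM).
#' @param preparation,genotype optional identifiers copied onto sample wells.
#' @return data.frame of class `plate_reading`: `well`, `type`
#'   (standard/sample), `condition`, `concentration_nM` (known for
#'   standards, true for samples), `rlu`, `preparation`, `genotype`.
#' @export
generate_atp_plate <- function(slope, intercept, true_concentrations_nM,
                               noise_sd = 0, seed = 1,
                               standard_concentrations = c(0, 12.5, 25, 50,
                                                           100, 200, 400),
                               preparation = NA, genotype = NA) {
  assert_that(slope > 0, "standard-curve slope must be positive")
  assert_that(all(true_concentrations_nM >= 0) &&
                all(standard_concentrations >= 0),
              "concentrations must be nonnegative")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  conds <- names(true_concentrations_nM) %||%
    paste0("sample_", seq_along(true_concentrations_nM))
  with_seed(seed, {
    conc <- c(standard_concentrations, unname(true_concentrations_nM))
    rlu <- intercept + slope * conc
    if (noise_sd > 0) rlu <- rlu + rnorm(length(rlu), sd = noise_sd)
    out <- data.frame(
      well = sprintf("W%02d", seq_along(conc)),
      type = rep(c("standard", "sample"),
                 c(length(standard_concentrations), length(conds))),
      condition = c(if (length(standard_concentrations))
        paste0("std_", standard_concentrations) else character(0), conds),
      concentration_nM = conc,
      rlu = pmax(rlu, 0),
      preparation = c(rep(NA, length(standard_concentrations)),
                      rep(preparation, length(conds))),
      genotype = c(rep(NA, length(standard_concentrations)),
                   rep(genotype, length(conds))))
    class(out) <- c("plate_reading", class(out))
    out
  })
}

#' Simulate a paired ATP-release study
#'
#' Per preparation, a matched artificial-saliva control and one stimulated
#' measurement whose true concentration is `effect` times the saliva level,
#' with per-measurement multiplicative lognormal noise, read out through the
#' same linear RLU curve.  Emulates single-stimulus Ussing-chamber trials
#' where each peeled epithelium preparation yields one saliva-referenced
#' reading.
#'
#' @param n_pairs number of preparations.
#' @param condition stimulated condition label (e.g. `"NaCl_500mM"`).
#' @param genotype genotype label copied onto wells.
#' @param saliva_mean_nM mean true saliva-evoked (background) concentration.
#' @param effect fold-change of the stimulated over the saliva concentration.
#' @param sdlog lognormal measurement noise on the concentration scale.
#' @param slope,intercept standard-curve parameters for the readout.
#' @param rlu_noise_sd additive RLU noise.
#' @param seed RNG seed.
#' @return `plate_reading` data.frame with standards plus two sample wells
#'   per preparation.
#' @export
generate_release_study <- function(n_pairs, condition = "NaCl_500mM",
                                   genotype = "WT", saliva_mean_nM = 20,
                                   effect = 2, sdlog = 0.3, slope = 2,
                                   intercept = 100, rlu_noise_sd = 2,
                                   seed = 1) {
  assert_that(is_count(n_pairs), "n_pairs must be a positive integer")
  with_seed(seed, {
    plates <- lapply(seq_len(n_pairs), function(i) {
      sal <- saliva_mean_nM * rlnorm(1, 0, sdlog)
      stim <- effect * saliva_mean_nM * rlnorm(1, 0, sdlog)
      conc <- c(artificial_saliva = sal, stim)
      names(conc)[2] <- condition
      generate_atp_plate(slope, intercept, conc, noise_sd = rlu_noise_sd,
                         seed = sample.int(.Machine$integer.max, 1),
                         standard_concentrations = if (i == 1)
                           c(0, 12.5, 25, 50, 100, 200, 400) else numeric(0),
                         preparation = i, genotype = genotype)
    })
    out <- do.call(rbind, plates)
    out$well <- sprintf("W%03d", seq_len(nrow(out)))
    out
  })
}

#' Fit the linear ATP standard curve
#'
#' Ordinary least squares of RLU on known concentration over the standard
#' wells; at least 3 distinct concentrations are required and the fitted
#' slope must be positive for a valid assay.
#'
#' @param plate a `plate_reading` data.frame (standard wells are used) or a
#'   data.frame with `concentration_nM` and `rlu` columns only.
#' @return list of class `standard_curve`: `slope` (RLU/nM), `intercept`
#'   (RLU), `r_squared`, `range` (concentration range fitted).
#' @export
fit_standard_curve <- function(plate) {
  std <- if ("type" %in% names(plate)) plate[plate$type == "standard", ] else plate
  assert_that(nrow(std) >= 3 && length(unique(std$concentration_nM)) >= 3,
              "at least 3 distinct standard concentrations are required")
  fit <- lm(rlu ~ concentration_nM, data = std)
  slope <- unname(coef(fit)[2])
  assert_that(slope > 0, "fitted standard-curve slope is non-positive (%.4g)",
              slope)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((std$rlu - mean(std$rlu))^2)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 range = range(std$concentration_nM), n = nrow(std)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> RLU = %.4g + %.4g * [ATP nM], R^2 = %.4f (%g-%g nM)\n",
              x$intercept, x$slope, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Invert the standard curve
#'
#' `concentration = (RLU - intercept) / slope`, clipped at zero with a flag;
#' values outside the fitted concentration range are flagged as extrapolated.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param rlu numeric RLU values.
#' @return data.frame `rlu`, `concentration_nM`, `clipped`, `extrapolated`.
#' @export
rlu_to_concentration <- function(curve, rlu) {
  raw <- (rlu - curve$intercept) / curve$slope
  data.frame(rlu = rlu, concentration_nM = pmax(raw, 0), clipped = raw < 0,
             extrapolated = raw < curve$range[1] | raw > curve$range[2])
}

#' Convert sample wells to concentrations and compare against saliva
#'
#' Back-calculates ATP concentrations for all sample wells, pairs each
#' stimulated well with the artificial-saliva well of the same preparation
#' (and genotype), reports saliva-relative ratios, and runs a paired t test
#' of each stimulated condition against artificial saliva.
#'
#' @param plate a `plate_reading` data.frame with sample wells carrying
#'   `condition`, `preparation`, `genotype`.
#' @param curve a [fit_standard_curve()] result.
#' @param saliva_label condition label of the control wells.
#' @return list of class `atp_comparison`: `samples` (per-well
#'   concentrations), `pairs` (one row per preparation x condition with the
#'   saliva-relative ratio), `tests` (per condition: paired t statistic, df,
#'   p-value, n).
#' @export
convert_and_compare <- function(plate, curve,
                                saliva_label = "artificial_saliva") {
  samples <- plate[plate$type == "sample", ]
  assert_that(nrow(samples) > 0, "plate contains no sample wells")
  cc <- rlu_to_concentration(curve, samples$rlu)
  samples$concentration_est <- cc$concentration_nM
  samples$clipped <- cc$clipped

  sal <- samples[samples$condition == saliva_label, ]
  stim <- samples[samples$condition != saliva_label, ]
  key <- function(d) paste(d$genotype, d$preparation, sep = "/")
  unmatched <- setdiff(key(stim), key(sal))
  assert_that(length(unmatched) == 0,
              "stimulated wells with no matched '%s' control: %s",
              saliva_label, paste(unique(unmatched), collapse = ", "))
  sal_conc <- setNames(sal$concentration_est, key(sal))
  pairs <- data.frame(genotype = stim$genotype, preparation = stim$preparation,
                      condition = stim$condition,
                      stimulated_nM = stim$concentration_est,
                      saliva_nM = unname(sal_conc[key(stim)]))
  pairs$ratio <- ifelse(pairs$saliva_nM > 0,
                        pairs$stimulated_nM / pairs$saliva_nM, NA_real_)

  tests <- do.call(rbind, lapply(split(pairs, pairs[c("condition", "genotype")],
                                       drop = TRUE), function(d) {
    # a single preparation cannot support a paired test; report NA
    tt <- if (nrow(d) >= 2) paired_t(d$stimulated_nM, d$saliva_nM)
          else list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
    data.frame(genotype = d$genotype[1], condition = d$condition[1],
               n = nrow(d), t = tt$statistic, df = tt$df, p_value = tt$p_value,
               mean_ratio = mean(d$ratio), row.names = NULL)
  }))
  structure(list(samples = samples, pairs = pairs, tests = tests,
                 curve = curve),
            class = "atp_comparison")
}
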