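# ground-truth self-consistency and determinism of the simulators

small_bud <- function(...) {
  bud_sim_params(stack_shape = c(z = 12, y = 110, x = 110),
                 bud_semiaxes_um = c(x = 9, y = 9, z = 5), ...)
}

test_that("stored innervation and overlap fractions equal recomputation from the masks", {
  sim <- generate_bud_stack(small_bud(fiber_density = 0.20,
                                      channel_overlap_fraction = 0.6,
                                      seed = 2))
  tr <- sim$truth
  inroi <- tr$roi$labels == 1
  expect_equal(sum(tr$fiber_masks$P2X3 & inroi) / sum(inroi),
               tr$innervation$true_fraction)
  expect_equal(sum(tr$fiber_masks$GFP & tr$fiber_masks$P2X3 & inroi) /
                 sum(tr$fiber_masks$P2X3 & inroi),
               tr$overlap$true_overlap)
  # fraction target met up to one-voxel quantization
  expect_lt(abs(tr$innervation$true_fraction - 0.20), 1 / sum(inroi))
  expect_lt(abs(tr$overlap$true_overlap - 0.6), 1 / sum(tr$fiber_masks$P2X3 & inroi))
  # every cell centroid lies inside its bud ROI
  cells <- tr$cells
  for (i in seq_len(nrow(cells))) {
    expect_equal(unname(tr$roi$labels[round(cells$y[i]), round(cells$x[i]),
                                      round(cells$z[i])]),
                 cells$bud[i])
  }
})

test_that("full channel overlap makes the two fiber masks identical", {
  sim <- generate_bud_stack(small_bud(channel_overlap_fraction = 1,
                                      fiber_density = 0.10, seed = 3))
  expect_identical(sim$truth$fiber_masks$GFP, sim$truth$fiber_masks$P2X3)
})

test_that("bud generator is bit-reproducible for a fixed seed", {
  p <- small_bud(seed = 9)
  s1 <- generate_bud_stack(p)
  s2 <- generate_bud_stack(p)
  expect_identical(s1$stack$channels, s2$stack$channels)
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- generate_bud_stack(small_bud(seed = 10))
  expect_false(identical(s1$stack$channels$P2X3, s3$stack$channels$P2X3))
})

test_that("infeasible fiber densities are rejected up front", {
  expect_error(bud_sim_params(fiber_density = 0.9), "infeasible")
  expect_error(bud_sim_params(fiber_density = -0.1), "\\[0, 1\\]")
})

test_that("ganglion mixture draws match their stored truth labels", {
  d <- generate_ganglion_intensities(100, 0.4, seed = 12)
  expect_equal(nrow(d), 100)
  # class counts are a fixed binomial draw for the seed; self-consistent
  d2 <- generate_ganglion_intensities(100, 0.4, seed = 12)
  expect_identical(d, d2)
  expect_true(sum(d$positive) > 0 && sum(d$positive) < 100)

  # empirical class means within 3 SE of the component means
  d3 <- generate_ganglion_intensities(1000, 0.5, lower_mean = 0.2,
                                      upper_mean = 0.8, lower_sd = 0.05,
                                      upper_sd = 0.05, seed = 4)
  lo <- d3$value[!d3$positive]; hi <- d3$value[d3$positive]
  expect_lt(abs(mean(lo) - 0.2), 3 * 0.05 / sqrt(length(lo)))
  expect_lt(abs(mean(hi) - 0.8), 3 * 0.05 / sqrt(length(hi)))

  # zero positive fraction: all cells drawn from the lower component
  d4 <- generate_ganglion_intensities(200, 0, seed = 5)
  expect_false(any(d4$positive))
  expect_true(all(d4$value < 0.5))
})

test_that("empty ganglion fields are valid with empty truth", {
  g <- generate_ganglion_field(ganglion_sim_params(n_cells = 0, seed = 1))
  expect_equal(nrow(g$truth), 0)
  expect_identical(dim_stack(g$stack), c(128L, 128L, 30L))
})

test_that("nerve traces hit the requested plateau and drift line", {
  p <- trace_sim_params("nerve", baseline_level = 1, noise_sd = 0,
                        rise_tau = 0, amplitudes = c(stim = 0.5))
  sim <- generate_nerve_trace(p)
  times <- (seq_along(sim$trace$values) - 1) / p$sampling_rate
  on <- p$schedule$onset[1]
  win <- times >= on & times < on + 30
  expect_true(all(sim$trace$values[win] == 1.5))
  expect_equal(sim$truth$true_R, 0.5)

  # zero amplitude: baseline (+ drift) everywhere
  p0 <- trace_sim_params("nerve", baseline_level = 2, drift_slope = 0.001,
                         noise_sd = 0, amplitudes = c(stim = 0))
  sim0 <- generate_nerve_trace(p0)
  t0 <- (seq_along(sim0$trace$values) - 1) / p0$sampling_rate
  expect_equal(sim0$trace$values, 2 + 0.001 * t0)

  # pre-stimulus window mean equals the closed-form line mean
  pre <- t0 >= p0$schedule$onset[1] - 10 & t0 < p0$schedule$onset[1]
  ts <- t0[pre]
  expect_equal(mean(sim0$trace$values[pre]),
               2 + 0.001 * (ts[1] + ts[length(ts)]) / 2)
})

test_that("calcium truth records the peak response exactly", {
  p <- trace_sim_params("calcium", baseline_level = 1, noise_sd = 0,
                        rise_tau = 0, amplitudes = c(ATP = 0.5))
  sim <- generate_calcium_trace(p)
  expect_equal(sim$truth$true_dR, 0.5)
  p0 <- trace_sim_params("calcium", noise_sd = 0, amplitudes = c(ATP = 0))
  expect_equal(generate_calcium_trace(p0)$truth$true_dR, 0)
  expect_error(trace_sim_params("calcium", amplitudes = c(x = 0.5),
                                schedule = data.frame(label = "x", onset = 5,
                                                      duration = 30)),
               "baseline")
})

test_that("plate simulation is linear in concentration", {
  pl <- generate_atp_plate(2, 100, c(stim = 50), noise_sd = 0)
  expect_equal(pl$rlu[pl$type == "sample"], 100 + 2 * 50)
  pl0 <- generate_atp_plate(2, 100, c(stim = 0), noise_sd = 0)
  expect_equal(pl0$rlu[pl0$type == "sample"], 100)
  expect_error(generate_atp_plate(-1, 0, c(a = 1)), "positive")
  expect_error(generate_atp_plate(2, 0, c(a = -5)), "nonnegative")
})
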