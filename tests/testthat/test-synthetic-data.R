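test_that("pattern cell counts follow the rounded truncated normal law", {
  # degenerate distribution: sd 0 pins every pattern at the mean
  cfg0 <- sim_chip_config(grid_rows = 2, grid_cols = 5, cells_mean = 4,
                          cells_sd = 0, seed = 1)
  expect_identical(simulate_pattern_counts(cfg0), rep(4L, 10))

  # same seed twice -> identical draws; different seed -> different draws
  cfg <- sim_chip_config(grid_rows = 10, grid_cols = 10, seed = 7)
  expect_identical(simulate_pattern_counts(cfg), simulate_pattern_counts(cfg))
  cfg2 <- sim_chip_config(grid_rows = 10, grid_cols = 10, seed = 8)
  expect_false(identical(simulate_pattern_counts(cfg),
                         simulate_pattern_counts(cfg2)))

  # moments at n = 1e4: sample mean within 3 SE of the truncation-corrected
  # expectation, and within 0.1 of the nominal 4.5 cells per pattern
  cfg_big <- sim_chip_config(grid_rows = 100, grid_cols = 100, seed = 3)
  counts <- simulate_pattern_counts(cfg_big)
  expect_true(all(counts >= 1L))
  mu <- expected_truncated_count(4.5, 2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_lt(abs(mean(counts) - 4.5), 0.1)
})

test_that("count validation rejects impossible configurations", {
  expect_error(sim_chip_config(grid_rows = 0), "grid_rows")
  expect_error(sim_chip_config(cells_mean = -1), "cells_mean")
  expect_error(sim_chip_config(pattern_diameter_um = 8, pixel_size_um = 1,
                               nucleus_radius_px = 5), "twice")
})

test_that("noiseless chip construction is exact", {
  # one pattern, 3 cells, no apoptosis: exactly 3 DAPI blobs, caspase
  # uniform at the control level over those blobs and zero elsewhere
  cfg <- sim_chip_config(grid_rows = 1, grid_cols = 1, cells_mean = 3,
                         cells_sd = 0, seed = 5)
  chip <- simulate_chip_image(cfg, apoptotic_fraction = 0)
  lab <- flood_label(chip$dapi > 0)
  expect_identical(max(lab), 3L)
  blob <- sort(which(chip$dapi > 0))
  expect_identical(blob, sort(unlist(chip$truth$pixels)))
  expect_setequal(unique(chip$caspase[blob]), 100)
  expect_true(all(chip$caspase[-blob] == 0))
  expect_identical(chip$truth$label, rep(0L, 3))
})

test_that("ground-truth table agrees with brute-force blob enumeration", {
  cfg <- sim_chip_config(grid_rows = 2, grid_cols = 3, seed = 21)
  chip <- simulate_chip_image(cfg, apoptotic_fraction = 0.5)
  lab <- flood_label(chip$dapi > 0)
  # one blob per ground-truth cell, and each truth pixel set is exactly one blob
  expect_identical(max(lab), nrow(chip$truth))
  for (k in seq_len(nrow(chip$truth))) {
    ids <- unique(lab[chip$truth$pixels[[k]]])
    expect_length(ids, 1L)
    expect_identical(sort(which(lab == ids)), chip$truth$pixels[[k]])
  }
  # blob counts per pattern equal the truth table's counts
  ctr <- pattern_centers(chip$layout, offset = chip$offset)
  blob_pattern <- vapply(seq_len(max(lab)), function(b) {
    idx <- which(lab == b)
    x <- mean((idx - 1) %/% nrow(lab)); y <- mean((idx - 1) %% nrow(lab))
    which.min((ctr$cx - x)^2 + (ctr$cy - y)^2)
  }, integer(1))
  expect_identical(as.integer(table(factor(blob_pattern, levels = ctr$pattern_id))),
                   as.integer(table(factor(chip$truth$pattern_id,
                                           levels = ctr$pattern_id))))
})

test_that("apoptotic fraction 0 and 1 produce deterministic labels", {
  cfg <- sim_chip_config(grid_rows = 2, grid_cols = 2, seed = 9)
  expect_true(all(simulate_chip_image(cfg, 1)$truth$label == 1L))
  expect_true(all(simulate_chip_image(cfg, 0)$truth$label == 0L))
  expect_error(simulate_chip_image(cfg, 1.5), "\\[0, 1\\]")
})

test_that("chip simulation is bit-reproducible under a seed", {
  cfg <- sim_chip_config(grid_rows = 2, grid_cols = 2, seed = 13,
                         noise_sd = 2)
  a <- simulate_chip_image(cfg, 0.3)
  b <- simulate_chip_image(cfg, 0.3)
  expect_identical(a$dapi, b$dapi)
  expect_identical(a$caspase, b$caspase)
  expect_identical(a$truth, b$truth)
})

test_that("time-lapse traces have the configured baseline and peak structure", {
  # no peak, no noise: every trace constant at its baseline
  cfg0 <- sim_trace_config(n_frames = 40, induction_frame = 10,
                           peak_shape = "none", seed = 2)
  tl0 <- simulate_timelapse(cfg0, n_cells = 5)
  per_cell <- split(tl0$truth$value, tl0$truth$cell_id)
  expect_true(all(vapply(per_cell, function(v) diff(range(v)) == 0,
                         logical(1))))
  # baselines are heterogeneous across cells
  expect_gt(diff(range(vapply(per_cell, function(v) v[1], numeric(1)))), 0)

  # broad transient: strictly positive integrated post-induction area
  cfg1 <- sim_trace_config(n_frames = 60, induction_frame = 15,
                           peak_shape = "broad", peak_amplitude = 30,
                           seed = 2)
  tl1 <- simulate_timelapse(cfg1, n_cells = 5)
  areas <- vapply(split(tl1$truth$value, tl1$truth$cell_id), function(v) {
    integrated_peak_area(normalize_trace(v), induction_frame = 15)
  }, numeric(1))
  expect_true(all(areas > 0))

  # sharp decays faster than broad: by 30 frames post induction the sharp
  # transient is gone while the broad one is still elevated
  cfg2 <- sim_trace_config(n_frames = 60, induction_frame = 15,
                           peak_shape = "sharp", peak_amplitude = 30,
                           seed = 2)
  tl2 <- simulate_timelapse(cfg2, n_cells = 1)
  v_sharp <- normalize_trace(dplyr::filter(tl2$truth, cell_id == 1)$value)
  v_broad <- normalize_trace(dplyr::filter(tl1$truth, cell_id == 1)$value)
  expect_lt(v_sharp[15 + 31], 0.01 * 30)
  expect_gt(v_broad[15 + 31], 0.1 * 30)
})

test_that("rendered stack re-measured over ground-truth masks reproduces true traces", {
  cfg <- sim_trace_config(n_frames = 45, induction_frame = 12,
                          peak_shape = "broad", peak_amplitude = 25, seed = 6)
  tl <- simulate_timelapse(cfg, n_cells = 4)
  traces <- extract_traces(tl$stack, tl$cells, induction_frame = 12,
                           dilation_px = 0)
  for (k in 1:4) {
    expect_equal(dplyr::filter(traces, cell_id == k)$value,
                 dplyr::filter(tl$truth, cell_id == k)$value,
                 tolerance = 1e-12)
  }
  # with noise, re-measurement stays within a few noise SDs of truth
  cfgN <- sim_trace_config(n_frames = 45, induction_frame = 12,
                           peak_shape = "broad", peak_amplitude = 25,
                           noise_sd = 2, seed = 6)
  tlN <- simulate_timelapse(cfgN, n_cells = 4)
  trN <- extract_traces(tlN$stack, tlN$cells, induction_frame = 12,
                        dilation_px = 0)
  err <- trN$value - tlN$truth$value
  npix <- length(tlN$cells$pixels[[1]])
  expect_lt(max(abs(err)), 6 * 2 / sqrt(npix))
})

test_that("binary dose-response draws follow the logistic law", {
  # near-degenerate intercept: all outcomes 0
  cfg0 <- sim_dose_config(-30, 0, c(0, 1e3, 1e6), 50, seed = 1)
  expect_true(all(simulate_binary_dose_response(cfg0)$outcome == 0L))

  # flat model: empirical positive fraction ~ plogis(-0.9490) = 0.279 at
  # every concentration
  p_true <- plogis(-0.9490)
  cfg1 <- sim_dose_config(-0.9490, 0, c(5e2, 5e4, 5e6), 4000, seed = 2)
  d <- simulate_binary_dose_response(cfg1)
  frac <- tapply(d$outcome, d$concentration_nM, mean)
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_true(all(abs(frac - p_true) < 3 * se))
  expect_lt(abs(mean(d$outcome) - 0.28), 0.02)

  # determinism
  expect_identical(simulate_binary_dose_response(cfg1),
                   simulate_binary_dose_response(cfg1))
  expect_error(sim_dose_config(0, 0, c(-1, 10), 5), "concentrations")
})
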