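#' Configuration for an end-to-end synthetic screening run
#'
#' Describes a complete simulated experiment for one compound: chips of
#' micropatterned cells partitioned into four wells (one vehicle control
#' plus up to three compound concentrations per chip, mirroring the
#' four-well chamber design), a ground-truth pattern-level logistic
#' apoptosis law used to simulate the images, and an optional TRPV1
#' component (a constant activation probability, or a simulated binary
#' dose-response to fit). Every stochastic stage derives its seed from
#' `seed`, and the full configuration is echoed into the run manifest so a
#' run can be reproduced from the manifest alone.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed.
#' @param compound Compound name for metadata.
#' @param concentrations Treated concentrations in nM; split into chips of
#'   up to 3 concentrations each.
#' @param true_beta0,true_beta1 Ground-truth logit intercept / slope (per
#'   nM) of the pattern-level apoptosis law.
#' @param trpv1 `NULL` (skip the combined profile), a scalar constant TRPV1
#'   activation probability, or a list `list(beta0=, beta1=,
#'   n_patterns_per_conc=)` to simulate and fit a TRPV1 binary
#'   dose-response over the same concentrations.
#' @param grid_rows,grid_cols Micropattern grid per chip.
#' @param noise_sd Pixel noise of the simulated images.
#' @param grid_offset_px Ground-truth grid misalignment per chip.
#' @param optimize_grid Register the ROI grid by displacement search before
#'   segmentation (otherwise the nominal origin is used).
#' @param iterations,max_shift_px Search settings for [optimize_roi_grid()].
#' @param min_area_px Minimum nucleus area for [segment_nuclei()].
#' @param threshold Apoptosis binarization threshold (relative excess).
#' @param strict Use the strict (> 50%) micropattern rule.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed, compound = "compound",
                       concentrations = c(1e2, 1e4, 1e6),
                       true_beta0 = -1.1057, true_beta1 = 1e-6,
                       trpv1 = NULL,
                       grid_rows = 6, grid_cols = 8,
                       noise_sd = 0, grid_offset_px = c(0L, 0L),
                       optimize_grid = FALSE, iterations = 500,
                       max_shift_px = 10, min_area_px = 20,
                       threshold = 0.20, strict = FALSE) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: every stochastic stage must be reproducible.")
  }
  if (length(concentrations) < 2L) {
    abort("Need at least 2 treated concentrations to fit a dose-response.")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), compound = compound,
         concentrations = as.numeric(concentrations),
         true_beta0 = true_beta0, true_beta1 = true_beta1, trpv1 = trpv1,
         grid_rows = grid_rows, grid_cols = grid_cols, noise_sd = noise_sd,
         grid_offset_px = as.integer(grid_offset_px),
         optimize_grid = optimize_grid, iterations = iterations,
         max_shift_px = max_shift_px, min_area_px = min_area_px,
         threshold = threshold, strict = strict),
    class = "run_config"
  )
}

# wrap a stage so failures surface with the stage name and context
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the end-to-end synthetic screening pipeline
#'
#' Simulate -> register -> segment -> quantify -> digitize -> fit ->
#' combine, writing every intermediate table (CSV), the chip images (TIFF),
#' the fitted models (JSON) and a manifest capturing the configuration,
#' seeds and outputs. Rerunning with the same configuration reproduces
#' identical outputs.
#'
#' Each chip carries its own vehicle-control well; the control mean used to
#' normalize caspase intensities is computed per chip from that chip's
#' control cells. Pattern-level outcomes of the treated wells (pooled over
#' chips) are fitted with [fit_logistic()]; when a TRPV1 component is
#' configured, the combined eye-irritation profile over the tested
#' concentrations is written as well.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  conc_groups <- split(config$concentrations,
                       (seq_along(config$concentrations) - 1L) %/% 3L)
  all_patterns <- list()
  files <- character()

  for (ci in seq_along(conc_groups)) {
    conc <- conc_groups[[ci]]
    chip_seed <- config$seed + ci
    wells <- tibble(
      well_id = seq_len(length(conc) + 1L),
      compound = c("vehicle", rep(config$compound, length(conc))),
      concentration_nM = c(0, conc),
      is_vehicle_control = c(TRUE, rep(FALSE, length(conc))))

    sim <- run_stage("simulate", {
      cfg <- sim_chip_config(
        grid_rows = config$grid_rows, grid_cols = config$grid_cols,
        noise_sd = config$noise_sd, grid_offset_px = config$grid_offset_px,
        seed = chip_seed)
      layout <- sim_chip_layout(cfg, wells = wells)
      ctr <- pattern_centers(layout)
      p_pattern <- plogis(config$true_beta0 + config$true_beta1 *
                            wells$concentration_nM[match(ctr$well_id,
                                                         wells$well_id)])
      p_pattern[wells$is_vehicle_control[match(ctr$well_id, wells$well_id)]] <- 0
      # pattern-level Bernoulli under the ground-truth law; colonies are
      # unanimous so noiseless digitization reproduces the draw exactly
      frac <- with_seed(chip_seed * 1000L + 1L,
                        as.numeric(rbinom(nrow(ctr), 1L, p_pattern)))
      chip <- simulate_chip_image(cfg, apoptotic_fraction = frac)
      chip$layout <- layout
      list(chip = chip, cfg = cfg, frac = frac)
    })
    chip <- sim$chip

    prefix <- file.path(config$out_dir, sprintf("chip%02d", ci))
    run_stage("write-images", {
      write_image_tiff(list(chip$dapi, chip$caspase),
                       paste0(prefix, "_image.tif"))
      write_cells_csv(chip$truth, paste0(prefix, "_truth.csv"))
      write_layout(chip$layout, paste0(prefix, "_layout.json"))
    })
    files <- c(files, paste0(prefix, c("_image.tif", "_truth.csv",
                                       "_layout.json")))

    offset <- c(0L, 0L)
    if (config$optimize_grid) {
      offset <- run_stage("register", {
        optimize_roi_grid(chip$dapi, chip$layout,
                          iterations = config$iterations,
                          max_shift_px = config$max_shift_px,
                          seed = chip_seed * 1000L + 2L)$offset
      })
    }

    cells <- run_stage("segment", {
      segment_nuclei(chip$dapi, chip$layout, offset = offset,
                     min_area_px = config$min_area_px) |>
        measure_cells(chip$caspase, channel = "caspase")
    })
    run_stage("write-cells",
              write_cells_csv(cells, paste0(prefix, "_cells.csv")))
    files <- c(files, paste0(prefix, "_cells.csv"))

    outcomes <- run_stage("digitize", {
      ctr <- pattern_centers(chip$layout)
      cells2 <- dplyr::left_join(cells,
                                 ctr[c("pattern_id", "well_id")],
                                 by = "pattern_id") |>
        dplyr::left_join(wells, by = "well_id")
      ctrl <- dplyr::filter(cells2, .data$is_vehicle_control)
      if (!nrow(ctrl)) {
        abort(sprintf(
          "no vehicle-control cells on chip %d (wells: %s)", ci,
          paste(sprintf("%d=%s@%gnM", wells$well_id, wells$compound,
                        wells$concentration_nM), collapse = ", ")))
      }
      treated <- dplyr::filter(cells2, !.data$is_vehicle_control)
      co <- apoptosis_cell_outcomes(treated, control = ctrl,
                                    threshold = config$threshold)
      po <- pattern_outcomes(co, strict = config$strict,
                             all_patterns = ctr$pattern_id[
                               !wells$is_vehicle_control[
                                 match(ctr$well_id, wells$well_id)]]) |>
        dplyr::left_join(ctr[c("pattern_id", "well_id")], by = "pattern_id") |>
        dplyr::left_join(wells[c("well_id", "compound", "concentration_nM")],
                         by = "well_id")
      list(cell = co, pattern = po)
    })
    run_stage("write-outcomes", {
      write_outcomes_csv(outcomes$cell, paste0(prefix, "_cell_outcomes.csv"))
      write_outcomes_csv(outcomes$pattern,
                         paste0(prefix, "_pattern_outcomes.csv"))
    })
    files <- c(files, paste0(prefix, c("_cell_outcomes.csv",
                                       "_pattern_outcomes.csv")))
    all_patterns[[ci]] <- outcomes$pattern
  }

  patterns <- dplyr::bind_rows(all_patterns)
  fit_apo <- run_stage("fit", fit_logistic(patterns))
  fit_path <- file.path(config$out_dir, "fit_apoptosis.json")
  write_fit_json(fit_apo, fit_path)
  files <- c(files, fit_path)

  profile <- NULL
  fit_trpv1 <- NULL
  if (!is.null(config$trpv1)) {
    comp <- run_stage("fit-trpv1", {
      if (is.numeric(config$trpv1) && length(config$trpv1) == 1L) {
        config$trpv1
      } else {
        d <- simulate_binary_dose_response(sim_dose_config(
          beta0 = config$trpv1$beta0, beta1 = config$trpv1$beta1,
          concentrations = config$concentrations,
          n_patterns_per_conc = config$trpv1$n_patterns_per_conc,
          seed = config$seed + 500L))
        fit_trpv1 <- fit_logistic(d)
        fit_trpv1
      }
    })
    profile <- run_stage("combine", {
      irritation_profile(fit_apo, comp,
                         concentrations = sort(unique(config$concentrations)))
    })
    prof_path <- file.path(config$out_dir, "irritation_profile.csv")
    write_table_csv(profile, prof_path)
    files <- c(files, prof_path)
    if (!is.null(fit_trpv1)) {
      tp <- file.path(config$out_dir, "fit_trpv1.json")
      write_fit_json(fit_trpv1, tp)
      files <- c(files, tp)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("eyescreen")),
    config = unclass(config)[setdiff(names(unclass(config)), "trpv1")],
    trpv1 = config$trpv1,
    fit_apoptosis = list(beta0 = fit_apo$beta0, beta1 = fit_apo$beta1,
                         n_obs = fit_apo$n_obs,
                         converged = fit_apo$converged,
                         separation = fit_apo$separation_flag),
    n_patterns = nrow(patterns),
    files = files)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
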