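#' Configuration for a simulated micropattern chip
#'
#' Describes the geometry and statistical structure of a synthetic chip:
#' an array of circular adhesive micropatterns, each carrying a small colony
#' of cells whose nuclei are rendered as bright discs on a dark background.
#' Defaults emulate 80 micrometre micropatterns holding 4.5 +/- 2 cells, the
#' regime in which colonies stay small enough for a 50%-of-cells binary
#' readout.
#'
#' @param grid_rows,grid_cols Number of micropattern rows / columns.
#' @param pattern_diameter_um Micropattern diameter in micrometres.
#' @param pixel_size_um Physical size of one pixel, micrometres.
#' @param cells_mean,cells_sd Mean and standard deviation of the per-pattern
#'   cell count law (rounded normal, truncated below at 1 cell).
#' @param nucleus_radius_px Rendered nucleus radius in pixels.
#' @param background_level Constant background intensity added to every pixel.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (0 = noiseless).
#' @param grid_offset_px Integer ground-truth misalignment (x, y) of the
#'   rendered grid relative to the nominal layout origin, in pixels.
#' @param seed Integer seed; fully determines all simulated output.
#'
#' @return A list of class `sim_chip_config`.
#' @examples
#' cfg <- sim_chip_config(grid_rows = 2, grid_cols = 2, seed = 1)
#' simulate_pattern_counts(cfg)
#' @export
sim_chip_config <- function(grid_rows = 10, grid_cols = 10,
                            pattern_diameter_um = 80, pixel_size_um = 1,
                            cells_mean = 4.5, cells_sd = 2,
                            nucleus_radius_px = 5,
                            background_level = 0, noise_sd = 0,
                            grid_offset_px = c(0L, 0L), seed = NULL) {
  cfg <- list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pattern_diameter_um = pattern_diameter_um, pixel_size_um = pixel_size_um,
    cells_mean = cells_mean, cells_sd = cells_sd,
    nucleus_radius_px = nucleus_radius_px,
    background_level = background_level, noise_sd = noise_sd,
    grid_offset_px = as.integer(round(grid_offset_px)), seed = seed
  )
  class(cfg) <- "sim_chip_config"
  validate_sim_chip_config(cfg)
}

validate_sim_chip_config <- function(cfg) {
  if (cfg$grid_rows < 1L || cfg$grid_cols < 1L) {
    abort("`grid_rows` and `grid_cols` must be >= 1.")
  }
  if (!is.finite(cfg$cells_mean) || cfg$cells_mean <= 0) {
    abort("`cells_mean` must be > 0.")
  }
  if (cfg$cells_sd < 0) abort("`cells_sd` must be >= 0.")
  if (cfg$pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  d_px <- cfg$pattern_diameter_um / cfg$pixel_size_um
  if (d_px < 2 * cfg$nucleus_radius_px) {
    abort("Pattern diameter in pixels must be at least twice the nucleus radius.")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(cfg$grid_offset_px) != 2L) {
    abort("`grid_offset_px` must be an integer 2-vector.")
  }
  cfg
}

#' Configuration for simulated binary dose-response data
#'
#' Defines a ground-truth logistic law on the linear nanomolar concentration
#' scale: the probability of a positive micropattern at concentration C is
#' `plogis(beta0 + beta1 * C)`.
#'
#' @param beta0 Logit intercept.
#' @param beta1 Logit slope per nM.
#' @param concentrations Numeric vector of tested concentrations, nM (>= 0).
#' @param n_patterns_per_conc Number of micropatterns (Bernoulli draws) per
#'   concentration.
#' @param seed Integer seed.
#'
#' @return A list of class `sim_dose_config`.
#' @examples
#' cfg <- sim_dose_config(-1.1057, 1e-6, c(1e2, 1e4, 1e6), 50, seed = 1)
#' head(simulate_binary_dose_response(cfg))
#' @export
sim_dose_config <- function(beta0, beta1, concentrations,
                            n_patterns_per_conc, seed = NULL) {
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    abort("`concentrations` must be finite and >= 0 (nM).")
  }
  if (n_patterns_per_conc < 1) abort("`n_patterns_per_conc` must be >= 1.")
  structure(
    list(beta0 = beta0, beta1 = beta1,
         concentrations = as.numeric(concentrations),
         n_patterns_per_conc = as.integer(n_patterns_per_conc), seed = seed),
    class = "sim_dose_config"
  )
}

#' Configuration for simulated calcium time-lapse traces
#'
#' Emulates Fluo-4 calcium-imaging of micropatterned cells: heterogeneous
#' per-cell baselines, and a transient added at the induction frame whose
#' shape distinguishes a sharp agonist-like response (fast rise, decay over
#' ~5 frames) from the broad response typical of surfactant irritants (slow
#' gamma-shaped decay over ~50 frames). Defaults correspond to 5 minutes of
#' imaging at 5 frames per second with compound addition after 1 minute.
#'
#' @param n_frames Number of frames (default 1500 = 5 min at 5 fps).
#' @param frame_rate_hz Acquisition rate, frames per second.
#' @param induction_frame 0-based index of the compound-addition frame
#'   (default 300 = 1 minute of baseline).
#' @param baseline_mean Mean baseline Fluo-4 intensity across cells.
#' @param baseline_cv Coefficient of variation of the per-cell baseline.
#' @param peak_shape One of `"sharp"`, `"broad"`, `"none"`.
#' @param peak_amplitude Peak height of the added transient.
#' @param noise_sd Additive Gaussian pixel/trace noise (0 = noiseless).
#' @param nucleus_radius_px Rendered nucleus radius in pixels.
#' @param seed Integer seed.
#'
#' @return A list of class `sim_trace_config`.
#' @examples
#' cfg <- sim_trace_config(n_frames = 60, induction_frame = 20, seed = 1)
#' tl <- simulate_timelapse(cfg, n_cells = 3)
#' dim(tl$stack)
#' @export
sim_trace_config <- function(n_frames = 1500, frame_rate_hz = 5,
                             induction_frame = 300,
                             baseline_mean = 100, baseline_cv = 0.25,
                             peak_shape = c("broad", "sharp", "none"),
                             peak_amplitude = 50, noise_sd = 0,
                             nucleus_radius_px = 5, seed = NULL) {
  peak_shape <- match.arg(peak_shape)
  cfg <- list(
    n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
    induction_frame = as.integer(induction_frame),
    baseline_mean = baseline_mean, baseline_cv = baseline_cv,
    peak_shape = peak_shape, peak_amplitude = peak_amplitude,
    noise_sd = noise_sd, nucleus_radius_px = nucleus_radius_px, seed = seed
  )
  if (cfg$induction_frame <= 0 || cfg$induction_frame >= cfg$n_frames - 20L) {
    abort("Need 0 < induction_frame < n_frames - 20 so the 20-frame window fits.")
  }
  if (cfg$baseline_cv < 0) abort("`baseline_cv` must be >= 0.")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(cfg, class = "sim_trace_config")
}
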