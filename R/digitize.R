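#' Normalize caspase intensity against the vehicle control
#'
#' Expresses each treated cell's caspase-3/7 intensity as the relative
#' excess over the mean intensity of the vehicle-control cells:
#' `(I - mean_ctrl) / mean_ctrl`. This makes the downstream 20% threshold
#' unit-free and invariant to a global intensity rescaling.
#'
#' @param treated_intensity Numeric vector of per-cell intensities.
#' @param vehicle_control_mean Mean intensity of control cells; must be > 0.
#' @return Numeric vector of normalized ratios.
#' @examples
#' normalize_apoptosis(c(100, 120, 90), 100)
#' @export
normalize_apoptosis <- function(treated_intensity, vehicle_control_mean) {
  if (!is.finite(vehicle_control_mean) || vehicle_control_mean <= 0) {
    abort("Vehicle control mean must be a positive finite number (control well missing or blank?).")
  }
  (treated_intensity - vehicle_control_mean) / vehicle_control_mean
}

#' Binarize a cell's apoptosis response
#'
#' A cell is scored apoptotic (1) when its normalized caspase ratio is
#' strictly above the threshold (default 20% above the vehicle-control
#' mean); a ratio of exactly 0.20 scores 0.
#'
#' @param normalized Numeric vector of normalized ratios.
#' @param threshold Relative-excess cutoff.
#' @return Integer vector of 0/1 outcomes.
#' @examples
#' binarize_cell_apoptosis(c(0.25, 0.20, -0.1))
#' @export
binarize_cell_apoptosis <- function(normalized, threshold = 0.20) {
  if (any(!is.finite(normalized))) abort("Normalized values must be finite.")
  as.integer(normalized > threshold)
}

#' Baseline-subtract a calcium trace
#'
#' Per-cell baseline Fluo-4 levels are heterogeneous, so each trace is
#' normalized by subtracting its own intensity at the initial frame (t0);
#' the first normalized value is therefore always 0.
#'
#' @param values Numeric vector, the trace ordered by frame (frame 0 first).
#' @return Numeric vector of the same length.
#' @examples
#' normalize_trace(c(5, 7, 4))
#' @export
normalize_trace <- function(values) {
  if (!length(values)) abort("Trace is empty.")
  values - values[1]
}

#' Integrated peak area of a normalized calcium trace
#'
#' Sums the baseline-subtracted trace over the frames from one frame after
#' induction through `window_frames` frames after induction (a rectangular
#' rule with dt = 1 frame; at 5 fps the default 20-frame window spans ~4 s
#' after compound addition). Frames are 0-based, matching
#' [extract_traces()].
#'
#' @param normalized_trace Numeric vector from [normalize_trace()], ordered
#'   by frame starting at frame 0.
#' @param induction_frame 0-based compound-addition frame.
#' @param window_frames Number of post-induction frames summed.
#' @return Scalar area (intensity x frames).
#' @examples
#' tr <- normalize_trace(c(10, 10, 12, 13, 11, 10))
#' integrated_peak_area(tr, induction_frame = 1, window_frames = 4)
#' @export
integrated_peak_area <- function(normalized_trace, induction_frame,
                                 window_frames = 20) {
  n <- length(normalized_trace)
  if (induction_frame < 0 ||
      induction_frame + window_frames + 1L > n) {
    abort(sprintf(
      "Integration window overruns the trace: need frames %d..%d but trace has frames 0..%d.",
      induction_frame + 1L, induction_frame + window_frames, n - 1L))
  }
  sum(normalized_trace[(induction_frame + 2L):(induction_frame + window_frames + 1L)])
}

#' Binarize a cell's calcium response
#'
#' A strictly positive integrated peak area scores 1; zero or negative
#' scores 0 (only a positive area is evidence of induced calcium influx).
#'
#' @param area Numeric vector of integrated peak areas.
#' @return Integer vector of 0/1 outcomes.
#' @examples
#' binarize_cell_calcium(c(3.7, -0.2, 0))
#' @export
binarize_cell_calcium <- function(area) {
  if (any(!is.finite(area))) abort("Integrated areas must be finite.")
  as.integer(area > 0)
}

#' Binarize one micropattern from its cells' outcomes
#'
#' A micropattern is positive when at least 50% of its cells are positive
#' (`strict = TRUE` switches to strictly more than 50%, the alternative
#' reading of the rule).
#'
#' @param outcomes Integer/logical vector of per-cell 0/1 outcomes; must be
#'   non-empty.
#' @param strict Use > 0.5 instead of >= 0.5.
#' @return 0 or 1.
#' @examples
#' binarize_pattern(c(1, 1, 0, 0))  # 50% meets the >= rule
#' @export
binarize_pattern <- function(outcomes, strict = FALSE) {
  if (!length(outcomes)) abort("Cannot binarize an empty micropattern (no cells).")
  frac <- mean(outcomes)
  as.integer(if (strict) frac > 0.5 else frac >= 0.5)
}

#' Cell-level apoptosis outcomes for a measured chip
#'
#' Normalizes every cell's caspase intensity against the pooled mean of the
#' vehicle-control cells and applies the 20% binarization rule.
#'
#' @param cells Cell tibble carrying an intensity column (see
#'   [measure_cells()]) and `pattern_id`/`cell_id`.
#' @param control Either the vehicle-control mean intensity (scalar) or a
#'   tibble of control cells with the same intensity column, whose mean is
#'   used.
#' @param threshold Relative-excess cutoff passed to
#'   [binarize_cell_apoptosis()].
#' @param intensity_col Name of the intensity column.
#' @return Tibble: `cell_id`, `pattern_id`, `assay` ("apoptosis"), `value`
#'   (normalized ratio), `outcome` (0/1).
#' @export
apoptosis_cell_outcomes <- function(cells, control, threshold = 0.20,
                                    intensity_col = "caspase_mean") {
  if (!intensity_col %in% names(cells)) {
    abort(sprintf("Column `%s` not found; run measure_cells() first.", intensity_col))
  }
  ctrl_mean <- if (is.numeric(control) && length(control) == 1L) {
    control
  } else {
    mean(control[[intensity_col]])
  }
  value <- normalize_apoptosis(cells[[intensity_col]], ctrl_mean)
  tibble(cell_id = cells$cell_id, pattern_id = cells$pattern_id,
         assay = "apoptosis", value = value,
         outcome = binarize_cell_apoptosis(value, threshold))
}

#' Cell-level calcium (TRPV1) outcomes from traces
#'
#' Baseline-subtracts each cell's trace at frame 0, integrates the
#' post-induction window, and binarizes on the sign of the area.
#'
#' @param traces Long trace tibble from [extract_traces()] (`cell_id`,
#'   `pattern_id`, `frame`, `value`).
#' @inheritParams integrated_peak_area
#' @return Tibble: `cell_id`, `pattern_id`, `assay` ("trpv1"), `value`
#'   (integrated peak area), `outcome` (0/1).
#' @export
calcium_cell_outcomes <- function(traces, induction_frame,
                                  window_frames = 20) {
  traces |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id, .data$pattern_id) |>
    dplyr::summarise(
      value = integrated_peak_area(normalize_trace(.data$value),
                                   induction_frame, window_frames),
      .groups = "drop") |>
    dplyr::mutate(assay = "trpv1",
                  outcome = binarize_cell_calcium(.data$value)) |>
    dplyr::select("cell_id", "pattern_id", "assay", "value", "outcome")
}

#' Micropattern outcomes from cell outcomes
#'
#' Applies the 50%-of-cells rule per micropattern. When `all_patterns` is
#' supplied, patterns with no segmented cells are excluded from the result
#' and recorded in the `exclusions` attribute (with a message) rather than
#' silently dropped - an empty pattern has no defined 50% readout.
#'
#' @param cell_outcomes Tibble from [apoptosis_cell_outcomes()] or
#'   [calcium_cell_outcomes()].
#' @param strict Passed to [binarize_pattern()].
#' @param all_patterns Optional integer vector of every pattern id expected
#'   on the chip.
#' @return Tibble: `pattern_id`, `assay`, `n_cells`, `n_positive`,
#'   `outcome`; attribute `exclusions` lists empty pattern ids.
#' @export
pattern_outcomes <- function(cell_outcomes, strict = FALSE,
                             all_patterns = NULL) {
  out <- cell_outcomes |>
    dplyr::group_by(.data$pattern_id, .data$assay) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_positive = sum(.data$outcome),
      outcome = binarize_pattern(.data$outcome, strict = strict),
      .groups = "drop")
  excluded <- integer()
  if (!is.null(all_patterns)) {
    excluded <- setdiff(as.integer(all_patterns), out$pattern_id)
    if (length(excluded)) {
      inform(sprintf("Excluded %d empty micropattern(s) with no cells: %s",
                     length(excluded),
                     paste(head(excluded, 10), collapse = ", ")))
    }
  }
  attr(out, "exclusions") <- excluded
  out
}
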