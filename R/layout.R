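#' Describe a micropattern chip layout
#'
#' A chip is a rectangular grid of circular micropattern regions of interest
#' (ROIs), partitioned into treatment wells (typically four: three compound
#' concentrations plus one vehicle control on the same substrate, so the
#' control is internal to every chip). Pixel coordinates are 0-based with
#' `(x, y) = (column, row)` and the origin at the top-left; an ROI is the
#' closed disc of diameter `pattern_diameter_px` around its grid node.
#'
#' @param grid_rows,grid_cols Grid dimensions.
#' @param pitch_px Centre-to-centre spacing of adjacent micropatterns,
#'   pixels; must exceed `pattern_diameter_px`.
#' @param pattern_diameter_px Micropattern (ROI) diameter, pixels.
#' @param origin_px Numeric `(x, y)` of the first (top-left) pattern centre.
#' @param wells Tibble/data frame with columns `well_id`, `compound`,
#'   `concentration_nM`, `is_vehicle_control`. Defaults to a single vehicle
#'   well.
#' @param pattern_well Integer vector of length `grid_rows * grid_cols`
#'   mapping each pattern (row-major id) to a `well_id`; defaults to
#'   contiguous column blocks, one per well.
#' @return A list of class `chip_layout`.
#' @examples
#' wells <- tibble::tibble(
#'   well_id = 1:2, compound = c("vehicle", "SLS"),
#'   concentration_nM = c(0, 1e5), is_vehicle_control = c(TRUE, FALSE))
#' chip_layout(4, 4, pitch_px = 100, pattern_diameter_px = 80,
#'             origin_px = c(60, 60), wells = wells)
#' @export
chip_layout <- function(grid_rows, grid_cols, pitch_px, pattern_diameter_px,
                        origin_px = NULL, wells = NULL, pattern_well = NULL) {
  if (is.null(origin_px)) {
    origin_px <- rep(ceiling(pattern_diameter_px / 2) + 13, 2)
  }
  if (is.null(wells)) {
    wells <- tibble(well_id = 1L, compound = "vehicle",
                    concentration_nM = 0, is_vehicle_control = TRUE)
  }
  wells <- as_tibble(wells)
  n_pat <- as.integer(grid_rows) * as.integer(grid_cols)
  if (is.null(pattern_well)) {
    # contiguous column blocks, one block per well
    block <- ceiling(grid_cols / nrow(wells))
    col_of <- rep(seq_len(grid_cols), times = grid_rows)
    pattern_well <- wells$well_id[pmin(nrow(wells),
                                       (col_of - 1L) %/% block + 1L)]
  }
  layout <- structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         pitch_px = pitch_px, pattern_diameter_px = pattern_diameter_px,
         origin_px = as.numeric(origin_px), wells = wells,
         pattern_well = as.integer(pattern_well)),
    class = "chip_layout"
  )
  validate_layout(layout)
}

#' Validate a chip layout
#'
#' Checks the geometric and treatment-design invariants: positive grid,
#' pitch exceeding the pattern diameter (ROIs must not overlap), well table
#' completeness, non-negative concentrations, vehicle wells at concentration
#' zero, and - when an image dimension is supplied - that every ROI lies
#' within image bounds. Exactly one vehicle-control well is the expected
#' design; zero vehicle wells triggers a warning (downstream apoptosis
#' normalization will fail), two or more triggers a warning that they are
#' pooled for the control mean.
#'
#' @param layout A `chip_layout` (or a list with the same fields, e.g. read
#'   from JSON).
#' @param image_dim Optional `c(nrow, ncol)` of the image the layout will be
#'   applied to.
#' @param max_shift_px Extra margin required around each ROI when the grid
#'   will be registered by a displacement search.
#' @return The validated layout, invisibly.
#' @export
validate_layout <- function(layout, image_dim = NULL, max_shift_px = 0) {
  req <- c("grid_rows", "grid_cols", "pitch_px", "pattern_diameter_px",
           "origin_px", "wells", "pattern_well")
  missing <- setdiff(req, names(layout))
  if (length(missing)) {
    abort(paste0("Layout is missing fields: ", paste(missing, collapse = ", ")))
  }
  if (layout$grid_rows < 1 || layout$grid_cols < 1) {
    abort("Layout grid must be at least 1 x 1.")
  }
  if (layout$pitch_px <= layout$pattern_diameter_px) {
    abort("`pitch_px` must exceed `pattern_diameter_px` (ROIs would overlap).")
  }
  w <- layout$wells
  wreq <- c("well_id", "compound", "concentration_nM", "is_vehicle_control")
  if (!all(wreq %in% names(w))) {
    abort(paste0("Wells table must have columns: ", paste(wreq, collapse = ", ")))
  }
  if (any(w$concentration_nM < 0)) abort("Concentrations must be >= 0 nM.")
  if (any(w$is_vehicle_control & w$concentration_nM != 0)) {
    abort("Vehicle-control wells must have concentration 0 of the test compound.")
  }
  n_veh <- sum(w$is_vehicle_control)
  if (n_veh == 0L) {
    warn("Layout has no vehicle-control well; apoptosis normalization will be impossible.")
  } else if (n_veh > 1L) {
    warn("Layout has multiple vehicle-control wells; their cells are pooled for the control mean.")
  }
  n_pat <- layout$grid_rows * layout$grid_cols
  if (length(layout$pattern_well) != n_pat ||
      !all(layout$pattern_well %in% w$well_id)) {
    abort("`pattern_well` must map every grid position to a known well_id.")
  }
  if (!is.null(image_dim)) {
    ctr <- pattern_centers(layout)
    r <- layout$pattern_diameter_px / 2 + max_shift_px
    if (min(ctr$cx) - r < 0 || min(ctr$cy) - r < 0 ||
        max(ctr$cx) + r > image_dim[2] - 1 ||
        max(ctr$cy) + r > image_dim[1] - 1) {
      abort("Layout ROIs (plus search margin) fall outside the image bounds.")
    }
  }
  invisible(layout)
}

#' Pattern centres of a chip layout
#'
#' @param layout A `chip_layout`.
#' @param offset Integer `(dx, dy)` shift applied to the whole grid, pixels.
#' @return Tibble: `pattern_id` (row-major), `grid_row`, `grid_col`,
#'   `cx`, `cy` (0-based pixel coordinates), `well_id`.
#' @export
pattern_centers <- function(layout, offset = c(0, 0)) {
  i <- rep(seq_len(layout$grid_rows), each = layout$grid_cols)
  j <- rep(seq_len(layout$grid_cols), times = layout$grid_rows)
  tibble(
    pattern_id = seq_len(layout$grid_rows * layout$grid_cols),
    grid_row = i, grid_col = j,
    cx = layout$origin_px[1] + (j - 1) * layout$pitch_px + offset[1],
    cy = layout$origin_px[2] + (i - 1) * layout$pitch_px + offset[2],
    well_id = layout$pattern_well
  )
}

#' Read / write a chip layout as JSON
#'
#' @param path File path.
#' @return `read_layout()` returns a validated `chip_layout`.
#' @rdname layout_io
#' @export
read_layout <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  layout <- structure(
    list(grid_rows = raw$grid_rows, grid_cols = raw$grid_cols,
         pitch_px = raw$pitch_px, pattern_diameter_px = raw$pattern_diameter_px,
         origin_px = as.numeric(raw$origin_px),
         wells = as_tibble(raw$wells),
         pattern_well = as.integer(raw$pattern_well)),
    class = "chip_layout"
  )
  validate_layout(layout)
  layout
}

#' @param layout A `chip_layout`.
#' @rdname layout_io
#' @export
write_layout <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
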