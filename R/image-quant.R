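#' Binarize a fluorescence image by Otsu auto-threshold
#'
#' Foreground is everything strictly above the Otsu threshold of the
#' intensity histogram (bright nuclei on a dark background). A constant
#' image has no foreground and yields an all-`FALSE` mask with a warning.
#'
#' @param image Single-channel numeric matrix, finite values.
#' @return Logical matrix of the same dimensions, with attribute
#'   `threshold` (NA for a constant image).
#' @examples
#' img <- matrix(c(rep(10, 90), rep(200, 10)), 10, 10)
#' sum(autothreshold_binarize(img))
#' @export
autothreshold_binarize <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (any(!is.finite(image))) abort("`image` must contain only finite values.")
  rng <- range(image)
  if (diff(rng) == 0) {
    warn("Constant image: no foreground found.")
    return(structure(matrix(FALSE, nrow(image), ncol(image)),
                     threshold = NA_real_))
  }
  th <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256L)
  structure(image > th, threshold = th)
}

# 8-connected components of a logical mask.
# EBImage::bwlabel is 4-connected, so components are taken from the
# 8-neighbour pixel adjacency graph instead (igraph does the heavy lifting).
# Returns list(idx = linear indices of foreground pixels, label = component
# id per foreground pixel).
label_components_8 <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(idx = integer(), label = integer()))
  h <- nrow(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- mask[nb]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        rbind(pos[idx[ok][hit]], pos[nb[hit]])
    }
  }
  ev <- if (length(edges)) as.vector(do.call(cbind, edges)) else integer()
  g <- igraph::make_graph(ev, n = length(idx), directed = FALSE)
  list(idx = idx, label = igraph::components(g)$membership)
}

#' Register the micropattern ROI grid by random displacement search
#'
#' Plate placement varies slightly between acquisitions, so the nominal ROI
#' grid is registered to the image by a rigid integer shift: the search
#' tries the nominal origin first and then `iterations` random offsets
#' uniform in `[-max_shift_px, max_shift_px]^2`, keeping the offset that
#' maximizes the total auto-threshold foreground area inside all ROI
#' circles. Ties go to the first-encountered maximum, so a perfectly
#' aligned grid returns `c(0, 0)`.
#'
#' @param dapi_image Nuclei-channel numeric matrix.
#' @param layout A [chip_layout()]; every ROI plus `max_shift_px` margin
#'   must lie inside the image.
#' @param iterations Number of random candidate offsets.
#' @param max_shift_px Maximum |shift| per axis, pixels.
#' @param seed Optional seed for the candidate draw.
#' @return List of class `roi_fit`: `offset` (integer `c(dx, dy)`), `score`
#'   (foreground pixels under the best offset), `blank` (TRUE with a warning
#'   when the image has no foreground, in which case the offset is
#'   `c(0, 0)`), and `n_candidates`.
#' @examples
#' cfg <- sim_chip_config(grid_rows = 2, grid_cols = 2, seed = 3,
#'                        grid_offset_px = c(4, -2))
#' chip <- simulate_chip_image(cfg)
#' optimize_roi_grid(chip$dapi, chip$layout, iterations = 200, seed = 1)$offset
#' @export
optimize_roi_grid <- function(dapi_image, layout, iterations = 500,
                              max_shift_px = 10, seed = NULL) {
  validate_layout(layout, image_dim = dim(dapi_image),
                  max_shift_px = max_shift_px)
  mask <- suppressWarnings(autothreshold_binarize(dapi_image))
  if (!any(mask)) {
    warn("Blank image (no foreground): ROI grid left at the nominal origin.")
    return(structure(list(offset = c(0L, 0L), score = 0L, blank = TRUE,
                          n_candidates = 0L), class = "roi_fit"))
  }
  h <- nrow(dapi_image)
  ctr <- pattern_centers(layout)
  r <- layout$pattern_diameter_px / 2
  base <- unlist(lapply(seq_len(nrow(ctr)), function(p) {
    disc_indices(dim(dapi_image), ctr$cx[p], ctr$cy[p], r)
  }))
  score_of <- function(dx, dy) sum(mask[base + dy + dx * h])
  cand <- with_seed(seed, {
    s <- max_shift_px
    cbind(c(0L, sample(seq(-s, s), iterations, replace = TRUE)),
          c(0L, sample(seq(-s, s), iterations, replace = TRUE)))
  })
  best <- c(0L, 0L); best_score <- score_of(0L, 0L)
  if (iterations > 0) {
    for (k in 2:nrow(cand)) {
      sc <- score_of(cand[k, 1], cand[k, 2])
      if (sc > best_score) { best_score <- sc; best <- cand[k, ] }
    }
  }
  structure(list(offset = as.integer(best), score = best_score, blank = FALSE,
                 n_candidates = nrow(cand)), class = "roi_fit")
}

#' @export
print.roi_fit <- function(x, ...) {
  cat("ROI grid registration: offset (", x$offset[1], ",", x$offset[2],
      ") px, foreground score", x$score,
      if (x$blank) "[blank image]" else "", "\n")
  invisible(x)
}

#' Segment nuclei and assign them to micropattern ROIs
#'
#' Auto-threshold binarization of the nuclei channel followed by 8-connected
#' component labelling. Components smaller than `min_area_px` are discarded
#' as specks; each surviving component becomes one cell, assigned to the
#' single ROI circle (closed disc) containing its centroid - components
#' whose centroid falls outside every ROI are dropped. Touching nuclei are
#' not split: on 80 micrometre patterns colonies are sparse enough that
#' watershed splitting is unnecessary.
#'
#' @inheritParams optimize_roi_grid
#' @param offset Integer grid shift from [optimize_roi_grid()] (or `c(0, 0)`).
#' @param min_area_px Minimum component area kept, pixels.
#' @return Tibble, one row per cell: `pattern_id`, `cell_id`, `x_px`, `y_px`
#'   (0-based centroid), `area_px`, and `pixels` (list-column of linear
#'   pixel indices into the image matrix).
#' @examples
#' chip <- simulate_chip_image(sim_chip_config(grid_rows = 2, grid_cols = 2,
#'                                             seed = 5))
#' cells <- segment_nuclei(chip$dapi, chip$layout)
#' dplyr::count(cells, pattern_id)
#' @export
segment_nuclei <- function(dapi_image, layout, offset = c(0L, 0L),
                           min_area_px = 20) {
  validate_layout(layout, image_dim = dim(dapi_image))
  mask <- suppressWarnings(autothreshold_binarize(dapi_image))
  lab <- label_components_8(mask)
  if (!length(lab$idx)) {
    return(tibble(pattern_id = integer(), cell_id = integer(),
                  x_px = numeric(), y_px = numeric(), area_px = integer(),
                  pixels = list()))
  }
  h <- nrow(dapi_image)
  x <- ((lab$idx - 1L) %/% h)          # 0-based column
  y <- ((lab$idx - 1L) %% h)           # 0-based row
  area <- tabulate(lab$label)
  cx <- as.vector(rowsum(x, lab$label)) / area
  cy <- as.vector(rowsum(y, lab$label)) / area
  keep <- which(area >= min_area_px)
  if (!length(keep)) {
    return(tibble(pattern_id = integer(), cell_id = integer(),
                  x_px = numeric(), y_px = numeric(), area_px = integer(),
                  pixels = list()))
  }
  # nearest grid node, then closed-disc membership test
  ctr <- pattern_centers(layout, offset = offset)
  jj <- pmin(pmax(round((cx[keep] - layout$origin_px[1] - offset[1]) /
                          layout$pitch_px) + 1, 1), layout$grid_cols)
  ii <- pmin(pmax(round((cy[keep] - layout$origin_px[2] - offset[2]) /
                          layout$pitch_px) + 1, 1), layout$grid_rows)
  pid <- (ii - 1L) * layout$grid_cols + jj
  d2 <- (cx[keep] - ctr$cx[pid])^2 + (cy[keep] - ctr$cy[pid])^2
  inside <- d2 <= (layout$pattern_diameter_px / 2)^2
  keep <- keep[inside]; pid <- pid[inside]
  if (!length(keep)) {
    return(tibble(pattern_id = integer(), cell_id = integer(),
                  x_px = numeric(), y_px = numeric(), area_px = integer(),
                  pixels = list()))
  }
  pix <- split(lab$idx, lab$label)[as.character(keep)]
  out <- tibble(pattern_id = as.integer(pid),
                x_px = cx[keep], y_px = cy[keep],
                area_px = as.integer(area[keep]),
                pixels = unname(pix)) |>
    dplyr::arrange(.data$pattern_id, .data$y_px, .data$x_px)
  out$cell_id <- seq_len(nrow(out))
  dplyr::select(out, "pattern_id", "cell_id", "x_px", "y_px", "area_px",
                "pixels")
}

# Euclidean closed-disc structuring-element offsets for radius d
disc_offsets <- function(d) {
  s <- -d:d
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= d^2, , drop = FALSE]
}

# dilate a set of linear pixel indices by a disc of radius d, clipped at
# the image border
dilate_indices <- function(idx, dim, d) {
  if (d <= 0) return(idx)
  h <- dim[1]; w <- dim[2]
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  off <- disc_offsets(d)
  r2 <- outer(rr, off$dr, `+`)
  c2 <- outer(cc, off$dc, `+`)
  ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
  unique((c2[ok] - 1L) * h + r2[ok])
}

#' Mean channel intensity over a (dilated) nucleus mask
#'
#' The nucleus mask is morphologically dilated by a Euclidean disc of radius
#' `dilation_px` (clipped at the image border) before averaging, so that
#' perinuclear signal such as cytoplasmic caspase-3/7 or Fluo-4 is captured
#' around each segmented nucleus.
#'
#' @param channel_image Numeric matrix of the channel to measure.
#' @param mask Logical matrix of the same dimensions, or an integer vector
#'   of linear pixel indices; must be non-empty.
#' @param dilation_px Dilation radius, pixels; 0 measures the exact mask.
#' @return Mean intensity (scalar).
#' @examples
#' img <- matrix(5, 9, 9)
#' measure_cell_intensity(img, img > 0, dilation_px = 2)
#' @export
measure_cell_intensity <- function(channel_image, mask, dilation_px = 2) {
  idx <- if (is.matrix(mask)) which(mask) else as.integer(mask)
  if (!length(idx)) abort("Empty nucleus mask: nothing to measure.")
  if (any(idx < 1L | idx > length(channel_image))) {
    abort("Mask indices fall outside the image.")
  }
  mean(channel_image[dilate_indices(idx, dim(channel_image), dilation_px)])
}

#' Measure every segmented cell in a channel image
#'
#' Tidy wrapper around [measure_cell_intensity()]: appends a
#' `<channel>_mean` column to a cell table from [segment_nuclei()].
#'
#' @param cells Cell tibble with a `pixels` list-column.
#' @param channel_image Numeric matrix.
#' @param channel Name used for the new column (`"<channel>_mean"`).
#' @inheritParams measure_cell_intensity
#' @return `cells` with the new intensity column.
#' @export
measure_cells <- function(cells, channel_image, channel = "caspase",
                          dilation_px = 2) {
  vals <- purrr::map_dbl(cells$pixels, function(idx) {
    measure_cell_intensity(channel_image, idx, dilation_px)
  })
  cells[[paste0(channel, "_mean")]] <- vals
  cells
}

#' Extract per-cell calcium traces from a time-lapse stack
#'
#' Each cell's nucleus mask is dilated by `dilation_px` to capture the
#' cytoplasmic Fluo-4 signal, and the mean intensity over the dilated mask
#' is recorded at every frame. Frames are numbered from 0 (the baseline
#' frame used later for normalization); the stack must extend at least 20
#' frames past the induction frame so the integrated-peak-area window fits.
#'
#' @param stack Numeric array `[row, col, frame]`, all frames the same shape.
#' @param cells Cell tibble with `cell_id`, `pattern_id` and a `pixels`
#'   list-column (from [segment_nuclei()] or a simulated ground truth).
#' @param induction_frame 0-based index of the compound-addition frame.
#' @inheritParams measure_cell_intensity
#' @return Long tibble: `cell_id`, `pattern_id`, `frame` (0-based), `value`.
#' @export
extract_traces <- function(stack, cells, induction_frame, dilation_px = 2) {
  if (length(dim(stack)) != 3L) {
    abort("`stack` must be a 3-d array [row, col, frame].")
  }
  n_frames <- dim(stack)[3]
  if (induction_frame < 0 || induction_frame + 21L > n_frames) {
    abort(sprintf(
      "Trace window does not fit: need at least %d frames (induction_frame + 21), stack has %d.",
      induction_frame + 21L, n_frames))
  }
  npix <- prod(dim(stack)[1:2])
  flat <- matrix(stack, npix, n_frames)
  per_cell <- purrr::map(seq_len(nrow(cells)), function(k) {
    idx <- dilate_indices(cells$pixels[[k]], dim(stack)[1:2], dilation_px)
    colMeans(flat[idx, , drop = FALSE])
  })
  tibble(
    cell_id = rep(cells$cell_id, each = n_frames),
    pattern_id = rep(cells$pattern_id, each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = nrow(cells)),
    value = unlist(per_cell)
  )
}
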