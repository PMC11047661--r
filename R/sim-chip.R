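# Intensity constants for rendered channels. DAPI nuclei are Gaussian-profile
# discs truncated at the nucleus radius, so the dimmest on-nucleus pixel is
# exp(-0.5) ~ 0.61 of the peak: with a dark background, any threshold in the
# gap recovers the disc support exactly, which is what makes noiseless
# round-trip segmentation exact.
DAPI_PEAK <- 1000
CASPASE_CONTROL_LEVEL <- 100

#' Draw per-micropattern cell counts
#'
#' Cell counts per micropattern follow a rounded normal law truncated below
#' at one cell, matching the reported moments of roughly 4.5 +/- 2 cells per
#' 80 micrometre pattern while guaranteeing no empty pattern (an empty
#' pattern has no 50%-of-cells readout).
#'
#' @param config A [sim_chip_config()].
#' @param n Number of counts to draw; defaults to the number of grid
#'   positions in `config`.
#' @return Integer vector of length `n`, all values >= 1.
#' @examples
#' counts <- simulate_pattern_counts(sim_chip_config(seed = 1))
#' mean(counts)
#' @export
simulate_pattern_counts <- function(config, n = NULL) {
  stopifnot(inherits(config, "sim_chip_config"))
  n <- n %||% (config$grid_rows * config$grid_cols)
  with_seed(config$seed, {
    raw <- rnorm(n, mean = config$cells_mean, sd = config$cells_sd)
    as.integer(pmax(1L, round(raw)))
  })
}

# pixel geometry derived from a chip config
chip_geometry <- function(config) {
  r_pat <- config$pattern_diameter_um / config$pixel_size_um / 2
  pitch <- as.integer(ceiling(2 * r_pat * 1.25)) # patterns separated by ~25%
  margin <- as.integer(ceiling(r_pat)) + 13L     # room for offsets up to ~10 px
  list(
    r_pat = r_pat, pitch = pitch, margin = margin,
    width  = 2L * margin + (config$grid_cols - 1L) * pitch,
    height = 2L * margin + (config$grid_rows - 1L) * pitch
  )
}

#' Nominal layout matching a simulated chip
#'
#' Returns the [chip_layout()] a user would supply when analysing an image
#' produced by [simulate_chip_image()]: the grid as designed, i.e. without
#' the ground-truth `grid_offset_px` misalignment.
#'
#' @inheritParams simulate_pattern_counts
#' @param wells Optional wells table passed to [chip_layout()].
#' @param pattern_well Optional pattern-to-well map passed to [chip_layout()].
#' @return A `chip_layout`.
#' @export
sim_chip_layout <- function(config, wells = NULL, pattern_well = NULL) {
  g <- chip_geometry(config)
  chip_layout(
    grid_rows = config$grid_rows, grid_cols = config$grid_cols,
    pitch_px = g$pitch, pattern_diameter_px = 2 * g$r_pat,
    origin_px = c(g$margin, g$margin),
    wells = wells, pattern_well = pattern_well
  )
}

# place n non-overlapping nucleus centres inside a pattern circle by
# rejection sampling; bounded retries, centres at least `min_dist` apart
place_nuclei <- function(n, cx, cy, r_pat, r_nuc, pattern_id,
                         max_retries = 100L) {
  r_place <- r_pat - r_nuc - 1
  if (r_place <= 0) abort("Pattern too small to hold a nucleus.")
  min_dist <- 2 * r_nuc + 5
  xs <- ys <- numeric(n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- r_place * sqrt(runif(1))
      x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
      if (k == 1L ||
          all((xs[seq_len(k - 1L)] - x)^2 + (ys[seq_len(k - 1L)] - y)^2 >=
              min_dist^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      abort(sprintf(
        "Could not place %d non-overlapping nuclei in pattern %d after %d retries.",
        n, pattern_id, max_retries))
    }
    xs[k] <- x; ys[k] <- y
  }
  list(x = xs, y = ys)
}

# truncated Gaussian-profile disc (sigma = radius, cut at radius) of peak
# `amp` centred at 0-based (cx, cy): linear indices and profile values.
# Kept as index/value pairs so whole chips render with one assignment
# instead of copying the full image matrix per cell.
gaussian_disc <- function(dim, cx, cy, radius, amp) {
  h <- dim[1]; w <- dim[2]
  r0 <- max(1L, floor(cy - radius) + 1L); r1 <- min(h, ceiling(cy + radius) + 1L)
  c0 <- max(1L, floor(cx - radius) + 1L); c1 <- min(w, ceiling(cx + radius) + 1L)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
  d2 <- outer(dy^2, dx^2, `+`)
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  list(idx = as.integer((cols[inside[, 2]] - 1L) * h + rows[inside[, 1]]),
       val = amp * exp(-d2[d2 <= radius^2] / (2 * radius^2)))
}

# set a uniform disc of value `val` centred at 0-based (cx, cy)
disc_indices <- function(dim, cx, cy, radius) {
  h <- dim[1]; w <- dim[2]
  r0 <- max(1L, floor(cy - radius) + 1L); r1 <- min(h, ceiling(cy + radius) + 1L)
  c0 <- max(1L, floor(cx - radius) + 1L); c1 <- min(w, ceiling(cx + radius) + 1L)
  rows <- r0:r1; cols <- c0:c1
  dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
  inside <- which(outer(dy^2, dx^2, `+`) <= radius^2, arr.ind = TRUE)
  as.integer((cols[inside[, 2]] - 1L) * h + rows[inside[, 1]])
}

#' Render a two-channel micropattern chip image with known ground truth
#'
#' Produces a DAPI (nuclei) channel and a caspase-3/7 channel for a simulated
#' chip. Nuclei are non-overlapping Gaussian-profile discs confined to the
#' pattern circles; the grid is shifted by the config's ground-truth
#' `grid_offset_px`. In the caspase channel, apoptotic cells carry an
#' elevated uniform intensity (`apoptotic_ratio` times the control level,
#' >= 1.2 by construction) over their nucleus disc while non-apoptotic cells
#' sit at the control level; Gaussian noise is added to both channels when
#' `noise_sd > 0`.
#'
#' @inheritParams simulate_pattern_counts
#' @param apoptotic_fraction Per-cell apoptosis probability, either a scalar
#'   or one value per pattern (recycled across that pattern's cells). Each
#'   cell's ground-truth label is an independent Bernoulli draw, so 0 and 1
#'   are deterministic.
#' @param apoptotic_ratio Caspase intensity of apoptotic cells relative to
#'   the control level; must be >= 1.2.
#' @return A list with elements `dapi` and `caspase` (numeric matrices,
#'   indexed \code{[row, col]}, 0-based pixel coordinates `x = col - 1`,
#'   `y = row - 1`), `truth` (tibble: pattern_id, cell_id, x_px, y_px, label,
#'   pixels), `layout` (the nominal [chip_layout()]) and `offset`
#'   (the ground-truth grid shift).
#' @examples
#' cfg <- sim_chip_config(grid_rows = 2, grid_cols = 2, seed = 7)
#' chip <- simulate_chip_image(cfg, apoptotic_fraction = 0.5)
#' chip$truth
#' @export
simulate_chip_image <- function(config, apoptotic_fraction = 0,
                                apoptotic_ratio = 1.4) {
  stopifnot(inherits(config, "sim_chip_config"))
  n_pat <- config$grid_rows * config$grid_cols
  frac <- rep_len(apoptotic_fraction, n_pat)
  if (any(frac < 0 | frac > 1)) {
    abort("`apoptotic_fraction` values must lie in [0, 1].")
  }
  if (apoptotic_ratio < 1.2) abort("`apoptotic_ratio` must be >= 1.2.")
  g <- chip_geometry(config)
  layout <- sim_chip_layout(config)
  centers <- pattern_centers(layout, offset = config$grid_offset_px)

  with_seed(config$seed, {
    counts <- as.integer(pmax(1L, round(
      rnorm(n_pat, config$cells_mean, config$cells_sd))))
    img_dim <- c(g$height, g$width)
    rows <- vector("list", n_pat)
    dapi_idx <- dapi_val <- casp_val <- vector("list", n_pat)
    cell_id0 <- 0L
    for (p in seq_len(n_pat)) {
      pos <- place_nuclei(counts[p], centers$cx[p], centers$cy[p],
                          g$r_pat, config$nucleus_radius_px, p)
      labels <- as.integer(runif(counts[p]) < frac[p])
      pix <- gi <- gv <- cv <- vector("list", counts[p])
      for (k in seq_len(counts[p])) {
        disc <- gaussian_disc(img_dim, pos$x[k], pos$y[k],
                              config$nucleus_radius_px, DAPI_PEAK)
        gi[[k]] <- disc$idx
        gv[[k]] <- disc$val
        lvl <- CASPASE_CONTROL_LEVEL * if (labels[k] == 1L) apoptotic_ratio else 1
        cv[[k]] <- rep(lvl, length(disc$idx))
        pix[[k]] <- sort(disc$idx)
      }
      dapi_idx[[p]] <- unlist(gi); dapi_val[[p]] <- unlist(gv)
      casp_val[[p]] <- unlist(cv)
      rows[[p]] <- tibble(
        pattern_id = p, cell_id = cell_id0 + seq_len(counts[p]),
        x_px = pos$x, y_px = pos$y, label = labels, pixels = pix
      )
      cell_id0 <- cell_id0 + counts[p]
    }
    # nuclei never overlap, so one indexed assignment renders each channel
    idx <- unlist(dapi_idx)
    dapi <- matrix(config$background_level, g$height, g$width)
    dapi[idx] <- dapi[idx] + unlist(dapi_val)
    caspase <- matrix(0, g$height, g$width)
    caspase[idx] <- unlist(casp_val)
    if (config$noise_sd > 0) {
      dapi <- dapi + rnorm(length(dapi), 0, config$noise_sd)
      caspase <- caspase + rnorm(length(caspase), 0, config$noise_sd)
    }
    list(dapi = dapi, caspase = caspase,
         truth = dplyr::bind_rows(rows), layout = layout,
         offset = config$grid_offset_px)
  })
}

#' Simulate binary micropattern outcomes under a logistic dose-response law
#'
#' For each configured concentration C, draws `n_patterns_per_conc`
#' independent Bernoulli outcomes with success probability
#' `plogis(beta0 + beta1 * C)`.
#'
#' @param config A [sim_dose_config()].
#' @return Tibble with columns `concentration_nM` and `outcome` (0/1).
#' @examples
#' cfg <- sim_dose_config(-0.949, 0, c(500, 5e3, 5e4), 100, seed = 1)
#' dplyr::count(simulate_binary_dose_response(cfg), outcome)
#' @export
simulate_binary_dose_response <- function(config) {
  stopifnot(inherits(config, "sim_dose_config"))
  with_seed(config$seed, {
    p <- plogis(config$beta0 + config$beta1 * config$concentrations)
    tibble(
      concentration_nM = rep(config$concentrations,
                             each = config$n_patterns_per_conc),
      outcome = as.integer(rbinom(
        length(config$concentrations) * config$n_patterns_per_conc,
        1L, rep(p, each = config$n_patterns_per_conc)))
    )
  })
}
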