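# intensity scale used when packing real-valued images into 16-bit TIFF
TIFF_SCALE <- 65535

#' Write / read multi-page grayscale TIFF images
#'
#' Channels (or frames) are written one per page as 16-bit grayscale;
#' intensities are divided by `scale` on write and multiplied back on read,
#' so integer-valued intensities up to `scale` round-trip exactly.
#'
#' @param images A numeric matrix, a list of matrices (one page each), or a
#'   3-d array `[row, col, page]`.
#' @param path File path.
#' @param scale Full-scale intensity mapped to the 16-bit maximum.
#' @return `read_image_tiff()` returns a list of numeric matrices.
#' @rdname tiff_io
#' @export
write_image_tiff <- function(images, path, scale = TIFF_SCALE) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  }
  if (is.matrix(images)) images <- list(images)
  pages <- lapply(images, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_image_tiff <- function(path, scale = TIFF_SCALE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * scale)
}

# CSV writers keep full double precision (15 significant digits) so that
# write -> read round-trips are lossless for downstream statistics.
write_table_csv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read cell records as CSV
#'
#' Columns: `pattern_id`, `cell_id`, `x_px`, `y_px`, `area_px` and any
#' `<channel>_mean` intensity columns. The `pixels` list-column (raw masks)
#' is not serialized.
#'
#' @param cells Cell tibble.
#' @param path File path.
#' @rdname cells_io
#' @export
write_cells_csv <- function(cells, path) {
  keep <- setdiff(names(cells), "pixels")
  write_table_csv(cells[keep], path)
}

#' @rdname cells_io
#' @export
read_cells_csv <- function(path) read_table_csv(path)

#' Write / read calcium traces as long CSV
#'
#' Long format, one row per cell and frame: `cell_id`, `pattern_id`,
#' `frame`, `value`.
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @rdname traces_io
#' @export
write_traces_csv <- function(traces, path) write_table_csv(traces, path)

#' @rdname traces_io
#' @export
read_traces_csv <- function(path) read_table_csv(path)

#' Write / read pattern outcomes as CSV
#'
#' Columns: `pattern_id`, `assay`, `n_cells`, `n_positive`, `outcome`, plus
#' any treatment metadata columns (e.g. `compound`, `concentration_nM`).
#'
#' @param outcomes Pattern-outcome tibble.
#' @param path File path.
#' @rdname outcomes_io
#' @export
write_outcomes_csv <- function(outcomes, path) write_table_csv(outcomes, path)

#' @rdname outcomes_io
#' @export
read_outcomes_csv <- function(path) read_table_csv(path)

#' Write a logistic fit as JSON
#'
#' Serializes coefficients, covariance, sizes and flags; readable with
#' [read_fit_json()].
#'
#' @param fit A `logistic_fit`.
#' @param path File path.
#' @rdname fit_io
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(beta0 = fit$beta0, beta1 = fit$beta1, cov = fit$vcov,
         n_obs = fit$n_obs, converged = fit$converged,
         separation = fit$separation_flag, log10_dose = fit$log10_dose),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_io
#' @export
read_fit_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- logistic_model(raw$beta0, raw$beta1, log10_dose = isTRUE(raw$log10_dose))
  f$vcov <- matrix(unlist(raw$cov), 2, 2)
  f$n_obs <- raw$n_obs
  f$converged <- raw$converged
  f$separation_flag <- raw$separation
  f
}
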