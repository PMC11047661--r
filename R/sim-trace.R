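# transient kernels, u = frames since induction (u >= 1)
peak_kernel <- function(shape, u) {
  switch(shape,
    none  = rep(0, length(u)),
    sharp = exp(-(u - 1) / 5),              # fast rise, ~5-frame decay
    broad = (u / 10) * exp(1 - u / 10)      # gamma-shaped, ~50-frame decay
  )
}

#' Simulate a Fluo-4 calcium time-lapse with ground-truth traces
#'
#' Renders `n_cells` nuclei as uniform-intensity discs whose value follows
#' each cell's true calcium trace frame by frame, plus a static DAPI
#' reference channel. Traces are a heterogeneous per-cell baseline plus, for
#' `peak_shape != "none"`, a transient starting one frame after the
#' induction frame: sharp transients rise instantly and decay over ~5
#' frames (capsaicin-like), broad transients follow a gamma-shaped kernel
#' decaying over ~50 frames (surfactant-irritant-like). Discs are rendered
#' at uniform intensity so that the mean over a cell's exact ground-truth
#' mask reproduces its true trace identically in the noiseless case.
#'
#' @param config A [sim_trace_config()].
#' @param n_cells Number of cells to render.
#' @return List with `stack` (array \code{[row, col, frame]}), `dapi`
#'   (matrix), `truth` (long tibble: cell_id, frame (0-based), value),
#'   `cells` (tibble: cell_id, pattern_id, x_px, y_px, pixels) and the
#'   echoed `config`.
#' @examples
#' cfg <- sim_trace_config(n_frames = 50, induction_frame = 10,
#'                         peak_shape = "broad", seed = 2)
#' tl <- simulate_timelapse(cfg, n_cells = 2)
#' head(tl$truth)
#' @export
simulate_timelapse <- function(config, n_cells) {
  stopifnot(inherits(config, "sim_trace_config"))
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  r <- config$nucleus_radius_px
  side <- ceiling(sqrt(n_cells) * (2 * r + 8)) + 2 * r + 10
  with_seed(config$seed, {
    # place cells freely, non-overlapping
    xs <- ys <- numeric(n_cells)
    min_dist <- 2 * r + 5
    for (k in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        x <- runif(1, r + 1, side - r - 2); y <- runif(1, r + 1, side - r - 2)
        if (k == 1L ||
            all((xs[seq_len(k - 1)] - x)^2 + (ys[seq_len(k - 1)] - y)^2 >=
                min_dist^2)) { ok <- TRUE; break }
      }
      if (!ok) abort("Could not place non-overlapping cells; too many cells for the frame.")
      xs[k] <- x; ys[k] <- y
    }
    baselines <- pmax(
      rnorm(n_cells, config$baseline_mean,
            config$baseline_cv * config$baseline_mean),
      0.05 * config$baseline_mean)

    frames0 <- seq_len(config$n_frames) - 1L        # 0-based frame index
    u <- frames0 - config$induction_frame
    kern <- numeric(config$n_frames)
    pos <- u >= 1
    kern[pos] <- peak_kernel(config$peak_shape, u[pos])
    # true traces: cells x frames
    traces <- outer(baselines, rep(1, config$n_frames)) +
      config$peak_amplitude * matrix(kern, n_cells, config$n_frames,
                                     byrow = TRUE)

    dapi <- matrix(0, side, side)
    pix <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      disc <- gaussian_disc(c(side, side), xs[k], ys[k], r, DAPI_PEAK)
      dapi[disc$idx] <- dapi[disc$idx] + disc$val
      pix[[k]] <- sort(disc$idx)
    }
    stack_flat <- matrix(0, side * side, config$n_frames)
    for (k in seq_len(n_cells)) {
      stack_flat[pix[[k]], ] <- matrix(traces[k, ], length(pix[[k]]),
                                       config$n_frames, byrow = TRUE)
    }
    if (config$noise_sd > 0) {
      stack_flat <- stack_flat +
        rnorm(length(stack_flat), 0, config$noise_sd)
    }
    stack <- array(stack_flat, dim = c(side, side, config$n_frames))

    list(
      stack = stack, dapi = dapi,
      truth = tibble(
        cell_id = rep(seq_len(n_cells), each = config$n_frames),
        frame = rep(frames0, times = n_cells),
        value = as.vector(t(traces))
      ),
      cells = tibble(cell_id = seq_len(n_cells), pattern_id = 1L,
                     x_px = xs, y_px = ys, pixels = pix),
      config = config
    )
  })
}
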