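#' Plot a logistic dose-response fit
#'
#' Fitted probability curve with its Wald confidence band and, when the fit
#' carries data, the observed positive fraction per concentration (point
#' size proportional to the number of micropatterns).
#'
#' @param object A `logistic_fit`.
#' @param concentrations Grid for the curve; defaults to a log-spaced grid
#'   over the fitted dose range (or 1e2..1e7 nM for a coefficient-only
#'   model).
#' @param level Confidence level for the band.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.logistic_fit <- function(object, concentrations = NULL,
                                  level = 0.95, ...) {
  if (is.null(concentrations)) {
    rng <- range(object$data$concentration[object$data$concentration > 0])
    if (!nrow(object$data) || any(!is.finite(rng))) rng <- c(1e2, 1e7)
    concentrations <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200)
  }
  band <- confidence_band(object, concentrations, level = level)
  p <- ggplot2::ggplot(band, ggplot2::aes(x = .data$concentration_nM)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration (nM)", y = "Response probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (nrow(object$data)) {
    obs <- dplyr::filter(object$data, .data$concentration > 0)
    p <- p + ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$concentration, y = .data$frac_positive,
                   size = .data$n), alpha = 0.6) +
      ggplot2::scale_size_area(max_size = 3, guide = "none")
  }
  p
}

#' Plot a combined eye-irritation probability profile
#'
#' Apoptosis, TRPV1 and combined union probabilities against concentration.
#'
#' @param object An `irritation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.irritation_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("p_apoptosis", "p_trpv1", "p_combined"),
    names_to = "component", values_to = "probability") |>
    dplyr::mutate(component = factor(
      .data$component, levels = c("p_apoptosis", "p_trpv1", "p_combined"),
      labels = c("Apoptosis", "TRPV1 activation", "Eye irritation (union)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$concentration_nM,
                                     y = .data$probability,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Concentration (nM)", y = "Probability",
                  colour = NULL)
}

#' Plot calcium traces
#'
#' One line per cell, optionally baseline-subtracted, with the induction
#' frame marked.
#'
#' @param traces Long tibble from [extract_traces()].
#' @param induction_frame 0-based induction frame to mark (optional).
#' @param normalize Subtract each cell's frame-0 baseline first.
#' @return A ggplot.
#' @export
plot_traces <- function(traces, induction_frame = NULL, normalize = FALSE) {
  d <- traces
  if (normalize) {
    d <- d |>
      dplyr::arrange(.data$cell_id, .data$frame) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(value = normalize_trace(.data$value)) |>
      dplyr::ungroup()
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$value,
                                       group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Frame", y = if (normalize) "Normalized Fluo-4 intensity"
                  else "Fluo-4 intensity")
  if (!is.null(induction_frame)) {
    p <- p + ggplot2::geom_vline(xintercept = induction_frame,
                                 linetype = "dashed")
  }
  p
}
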