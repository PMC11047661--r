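#' Fit a binary logistic dose-response model
#'
#' Maximum-likelihood logistic regression of binary micropattern outcomes on
#' compound concentration, on the linear nanomolar scale (the natural scale
#' for slopes quoted per nM; set `log10_dose = TRUE` for a log10
#' concentration predictor instead). Fitting is iteratively reweighted
#' least squares (via [stats::glm()]) with the covariance taken as the
#' inverse observed information. Quasi-complete separation is flagged when
#' the fitted linear predictor drifts beyond 1000 logit units or the
#' information matrix is numerically singular; data with a single
#' concentration or all-identical outcomes are rejected up front because
#' the model is not identifiable there.
#'
#' @param data Data frame of one record per micropattern.
#' @param dose,response Column names of the concentration (nM) and the 0/1
#'   outcome.
#' @param log10_dose Fit on `log10(C)` instead of linear C (zero
#'   concentrations are not allowed on the log scale).
#' @param tol IRLS convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return Object of class `logistic_fit`: coefficients `beta0`, `beta1`,
#'   `vcov` (2x2), `n_obs`, `converged`, `separation_flag`, per-dose
#'   summary `data`, and the log-likelihood.
#' @examples
#' d <- simulate_binary_dose_response(
#'   sim_dose_config(-1.1057, 1e-6, c(1e2, 1e4, 1e6, 1e7), 200, seed = 1))
#' fit <- fit_logistic(d)
#' tidy(fit)
#' ic50(fit)
#' @export
fit_logistic <- function(data, dose = "concentration_nM",
                         response = "outcome", log10_dose = FALSE,
                         tol = 1e-8, max_iter = 100) {
  if (!all(c(dose, response) %in% names(data))) {
    abort(sprintf("`data` must have columns `%s` and `%s`.", dose, response))
  }
  C <- as.numeric(data[[dose]])
  y <- as.integer(data[[response]])
  if (any(!y %in% c(0L, 1L))) abort("Outcomes must be 0/1.")
  if (length(unique(C)) < 2L) {
    abort("Need at least 2 distinct concentrations: the slope is not identifiable from one dose.")
  }
  if (all(y == y[1])) {
    abort(paste0(
      "All outcomes are ", y[1],
      ": complete separation, the logistic intercept diverges and no model can be fitted."))
  }
  x <- if (log10_dose) {
    if (any(C <= 0)) abort("log10 dose scale requires strictly positive concentrations.")
    log10(C)
  } else C
  fit <- suppressWarnings(glm(y ~ x, family = binomial(),
                              control = glm.control(epsilon = tol,
                                                    maxit = max_iter)))
  beta <- unname(coef(fit))
  eta <- fit$linear.predictors
  info_ok <- is.finite(rcond_2x2(vcov(fit)))
  separation <- any(!is.finite(beta)) || max(abs(eta)) > 1e3 ||
    !info_ok || any(abs(beta) > 1e3 & c(TRUE, log10_dose))
  dose_summary <- tibble(concentration = C, y = y) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(n = dplyr::n(), frac_positive = mean(.data$y),
                     .groups = "drop")
  structure(
    list(beta0 = beta[1], beta1 = beta[2], vcov = unname(vcov(fit)),
         n_obs = length(y), converged = fit$converged,
         separation_flag = isTRUE(separation), log10_dose = log10_dose,
         logLik = as.numeric(logLik(fit)), deviance = fit$deviance,
         data = dose_summary),
    class = "logistic_fit"
  )
}

rcond_2x2 <- function(m) {
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(ev)) || min(ev) <= 0) return(NA_real_)
  min(ev) / max(ev)
}

#' Construct a logistic fit from known coefficients
#'
#' Builds a `logistic_fit` directly from printed or otherwise known
#' coefficients (no data), e.g. to evaluate a published dose-response
#' equation. Covariance is zero and the fit is marked converged.
#'
#' @param beta0 Logit intercept.
#' @param beta1 Logit slope per nM (per log10 nM if `log10_dose`).
#' @param log10_dose Predictor scale flag.
#' @return A `logistic_fit`.
#' @examples
#' sls <- logistic_model(-1.1057, 1e-6)
#' predict(sls, 1.73e7)
#' @export
logistic_model <- function(beta0, beta1, log10_dose = FALSE) {
  structure(
    list(beta0 = beta0, beta1 = beta1, vcov = matrix(0, 2, 2),
         n_obs = 0L, converged = TRUE, separation_flag = FALSE,
         log10_dose = log10_dose, logLik = NA_real_, deviance = NA_real_,
         data = tibble(concentration = numeric(), n = integer(),
                       frac_positive = numeric())),
    class = "logistic_fit"
  )
}

#' Predicted response probability at given concentrations
#'
#' Evaluates `1 / (1 + exp(-(beta0 + beta1 * C)))`, clamped to the open
#' interval (0, 1).
#'
#' @param object A `logistic_fit`.
#' @param concentration Numeric vector of concentrations, nM (>= 0).
#' @param ... Unused.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @examples
#' predict(logistic_model(0, 0), 1e5)  # 0.5
#' @export
predict.logistic_fit <- function(object, concentration, ...) {
  if (any(concentration < 0)) abort("Concentrations must be >= 0 nM.")
  x <- if (object$log10_dose) log10(concentration) else concentration
  p <- plogis(object$beta0 + object$beta1 * x)
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' IC50 of a fitted logistic dose-response
#'
#' The concentration at which the fitted response probability is 0.5,
#' `-beta0 / beta1`. Undefined for a flat or protective model
#' (`beta1 <= 0`), e.g. a concentration-independent response with slope
#' zero: an error is raised.
#'
#' @param fit A `logistic_fit` with `beta1 > 0`.
#' @return IC50 in nM (in log10 nM units if the fit used `log10_dose`).
#' @examples
#' ic50(logistic_model(-1.1057, 1e-6))  # ~1.1e6 nM
#' @export
ic50 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!is.finite(fit$beta1) || fit$beta1 <= 0) {
    abort("IC50 is undefined: slope <= 0 (flat or protective dose-response, the 0.5 probability is never crossed).")
  }
  ic <- -fit$beta0 / fit$beta1
  if (fit$log10_dose) 10^ic else ic
}

#' Wald confidence band for the fitted probability curve
#'
#' Pointwise interval on the linear predictor (normal quantile at the given
#' level, variance from the coefficient covariance by the delta method),
#' mapped through the logistic function; the band therefore always contains
#' the point estimate.
#'
#' @param fit A converged `logistic_fit`.
#' @param concentrations Numeric grid of concentrations, nM.
#' @param level Confidence level.
#' @return Tibble: `concentration_nM`, `p`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, concentrations, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    abort("Confidence band requires a converged fit.")
  }
  x <- if (fit$log10_dose) log10(concentrations) else concentrations
  eta <- fit$beta0 + fit$beta1 * x
  se <- sqrt(fit$vcov[1, 1] + 2 * x * fit$vcov[1, 2] + x^2 * fit$vcov[2, 2])
  z <- qnorm(1 - (1 - level) / 2)
  tibble(concentration_nM = concentrations,
         p = plogis(eta),
         lower = plogis(eta - z * se),
         upper = plogis(eta + z * se))
}

#' Union probability of two assay readouts
#'
#' Combines the apoptosis and TRPV1-activation probabilities as the
#' probability of either mechanism firing,
#' `P(A) + P(B) - P(A and B)`, treating the two events as non-mutually
#' exclusive. The intersection defaults to the independence product
#' `pA * pB`; a custom intersection rule may be supplied as a function of
#' `(pA, pB)` and is validated against the Frechet bounds
#' `max(0, pA + pB - 1) <= P(A and B) <= min(pA, pB)`.
#'
#' @param p_apoptosis,p_trpv1 Probability vectors in \[0, 1\] (recycled).
#' @param intersection `NULL` for independence, or
#'   `function(pA, pB) -> P(A and B)`.
#' @return Numeric vector of combined probabilities.
#' @examples
#' combine_probabilities(0.2791, 0.8)  # ~0.856
#' @export
combine_probabilities <- function(p_apoptosis, p_trpv1, intersection = NULL) {
  pA <- p_apoptosis; pB <- p_trpv1
  if (any(!is.finite(pA)) || any(!is.finite(pB)) ||
      any(pA < 0 | pA > 1) || any(pB < 0 | pB > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  p_int <- if (is.null(intersection)) pA * pB else intersection(pA, pB)
  lo <- pmax(0, pA + pB - 1); hi <- pmin(pA, pB)
  if (any(p_int < lo - 1e-12 | p_int > hi + 1e-12)) {
    abort("Intersection rule violates the Frechet bounds max(0, pA+pB-1) <= P(A&B) <= min(pA, pB).")
  }
  pA + pB - p_int
}

#' Combined eye-irritation probability profile over a concentration grid
#'
#' Evaluates the apoptosis and TRPV1 response probabilities on a
#' concentration grid and combines them with the union rule. Either
#' component may be a fitted `logistic_fit` or a constant probability
#' (a scalar in \[0, 1\]) - the latter covers concentration-independent
#' responses, where the logistic slope is legitimately zero or
#' unidentifiable.
#'
#' @param fit_apoptosis,fit_trpv1 A `logistic_fit` or a scalar probability.
#' @param concentrations Numeric grid of concentrations, nM.
#' @inheritParams combine_probabilities
#' @return Tibble of class `irritation_profile`: `concentration_nM`,
#'   `p_apoptosis`, `p_trpv1`, `p_combined`; the intersection rule is
#'   recorded in the `intersection_rule` attribute.
#' @examples
#' prof <- irritation_profile(logistic_model(-1.1057, 1e-6), 0.5,
#'                            concentrations = 10^seq(2, 7, by = 0.5))
#' head(prof)
#' @export
irritation_profile <- function(fit_apoptosis, fit_trpv1, concentrations,
                               intersection = NULL) {
  eval_component <- function(f, label) {
    if (inherits(f, "logistic_fit")) {
      predict(f, concentrations)
    } else if (is.numeric(f) && length(f) == 1L && f >= 0 && f <= 1) {
      rep(f, length(concentrations))
    } else {
      abort(sprintf("`%s` must be a logistic_fit or a scalar probability in [0, 1].", label))
    }
  }
  pA <- eval_component(fit_apoptosis, "fit_apoptosis")
  pB <- eval_component(fit_trpv1, "fit_trpv1")
  out <- tibble(concentration_nM = concentrations,
                p_apoptosis = pA, p_trpv1 = pB,
                p_combined = combine_probabilities(pA, pB, intersection))
  class(out) <- c("irritation_profile", class(out))
  attr(out, "intersection_rule") <-
    if (is.null(intersection)) "independence" else "custom"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binary logistic dose-response fit",
      if (x$log10_dose) "(log10 nM scale)" else "(linear nM scale)", "\n")
  cat(sprintf("  logit(p) = %.4f + %.3g * C   (n = %d)\n",
              x$beta0, x$beta1, x$n_obs))
  cat(sprintf("  converged: %s, separation: %s\n",
              x$converged, x$separation_flag))
  invisible(x)
}

#' Tidy a logistic dose-response fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.logistic_fit <- function(x, ...) {
  est <- c(x$beta0, x$beta1)
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  tibble(term = c("(Intercept)", "concentration_nM"),
         estimate = est, std.error = se, statistic = stat,
         p.value = 2 * stats::pnorm(-abs(stat)))
}

#' One-row summary of a logistic dose-response fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `converged`, `separation_flag`,
#'   `logLik`, `deviance`, `AIC`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, converged = x$converged,
         separation_flag = x$separation_flag, logLik = x$logLik,
         deviance = x$deviance,
         AIC = if (is.na(x$logLik)) NA_real_ else -2 * x$logLik + 4)
}
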