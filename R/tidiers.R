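#' Tidy a thermal-motion calibration fit
#'
#' @param x A `thermal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`, `fixed`.
#' @exportS3Method generics::tidy
tidy.thermal_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors[names(x$estimates)]),
    fixed = names(x$estimates) %in% names(x$fixed)
  )
}

#' One-row summary of a thermal-motion calibration fit
#'
#' @param x A `thermal_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model key, number of points, free-parameter
#'   count, cost, log-likelihood, reduced chi-squared, support, p-value,
#'   AIC.
#' @exportS3Method generics::glance
glance.thermal_fit <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(model = x$model, n_y = x$n_y, K = x$K, cost = x$cost,
                 logLik = x$logLik, chi2_nu = d$chi2_nu,
                 support = d$support, p.value = d$p_value, AIC = d$AIC)
}

#' Per-point data of a thermal-motion calibration fit
#'
#' @param x A `thermal_fit`.
#' @param ... Unused.
#' @return The fit's per-point tibble: abscissa, experimental value, Gamma
#'   shape, fitted model value and normalized residual.
#' @exportS3Method generics::augment
augment.thermal_fit <- function(x, ...) x$data

#' Tidy MCMC posterior samples
#'
#' @param x A `thermal_posterior`.
#' @param ... Unused.
#' @return The posterior summary tibble (term, median, percentiles,
#'   std_error).
#' @exportS3Method generics::tidy
tidy.thermal_posterior <- function(x, ...) x$summary
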